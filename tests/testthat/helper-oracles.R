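# Independent oracles used by the tests. These deliberately share no code
# with the package implementation: everything is recomputed by direct
# pixel/element enumeration.

# Reverse complement via chartr + explicit reversal.
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# Separation scores by brute-force enumeration over all matrix pixels.
# Junction between bins b-1 and b (0-based); same geometry definition as
# documented for the package, but enumerated pixel by pixel.
oracle_separation <- function(M, b, k_max) {
  n <- nrow(M)
  out <- list()
  for (side in c("upper", "lower")) {
    S <- 0; S0 <- 0; L_sum <- 0; N_out_sum <- 0
    for (k in seq_len(k_max)) {
      inner <- c(); outer <- c()
      for (i in 0:(n - 2L)) for (j in (i + 1L):(n - 1L)) {
        if (j - i != k) next
        v <- M[i + 1L, j + 1L]
        if (i < b && j >= b) {
          outer <- c(outer, v)
        } else if (side == "upper" && j < b && i >= b - k_max) {
          inner <- c(inner, v)
        } else if (side == "lower" && i >= b && j <= b + k_max - 1L) {
          inner <- c(inner, v)
        }
      }
      n_in <- length(inner); n_out <- length(outer)
      if (n_in + n_out == 0L) next
      mu_in <- if (n_in) mean(inner) else 0
      mu_out <- if (n_out) mean(outer) else 0
      S <- S + n_in * n_out * (mu_in - mu_out)^2 / (n_in + n_out)^2
      S0 <- S0 + n_in * n_out * mu_in^2 / (n_in + n_out)^2
      if (n_in > 0L && n_out > 0L) {
        L_sum <- L_sum + sum(outer < mu_in)
        N_out_sum <- N_out_sum + n_out
      }
    }
    out[[paste0("S_", side)]] <- S
    out[[paste0("R_", side)]] <- if (N_out_sum > 0) L_sum / N_out_sum else 0
    out[[paste0("S_", side, "_0")]] <- S0
  }
  out
}

# Classical two-class between-class variance of values split into classes
# A and B: nA*nB*(muA-muB)^2/(nA+nB)^2 equals p*q*(muA-muB)^2 with
# p = nA/(nA+nB).
oracle_between_class_variance <- function(a, b) {
  nA <- length(a); nB <- length(b)
  if (nA == 0L || nB == 0L) return(0)
  p <- nA / (nA + nB); q <- nB / (nA + nB)
  p * q * (mean(a) - mean(b))^2
}

# N50 by explicit prefix-sum walk.
oracle_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(s) / 2
  acc <- 0
  for (x in s) {
    acc <- acc + x
    if (acc >= half) return(x)
  }
}

# Exhaustive phasing optimum: maximum number of satisfied links over all
# 2^(n-1) phase assignments (block 1 fixed at phase 0).
oracle_phase_optimum <- function(n_blocks, counts) {
  best <- -Inf
  for (mask in 0:(2^(n_blocks - 1L) - 1L)) {
    phase <- c(0L, as.integer(intToBits(mask)[seq_len(n_blocks - 1L)]))
    sat <- 0
    for (r in seq_len(nrow(counts))) {
      same <- phase[counts$i[r]] == phase[counts$j[r]]
      sat <- sat + if (same) counts$parallel[r] else counts$cross[r]
    }
    best <- max(best, sat)
  }
  best
}

# Satisfied links of a concrete phase assignment (named by block idx).
phase_satisfied <- function(phase, counts) {
  sat <- 0
  for (r in seq_len(nrow(counts))) {
    pi <- phase[[as.character(counts$i[r])]]
    pj <- phase[[as.character(counts$j[r])]]
    same <- pi == pj
    sat <- sat + if (same) counts$parallel[r] else counts$cross[r]
  }
  sat
}

# Greedy identity-ordered alignment selection by direct simulation on one
# read: sort candidates, accept non-overlapping in order.
oracle_greedy_selection <- function(df) {
  ord <- order(-df$nmatch / df$alen, -df$alen, df$tname, df$qstart)
  acc <- integer(0)
  for (i in ord) {
    ov <- FALSE
    for (j in acc)
      if (df$qstart[i] < df$qend[j] && df$qend[i] > df$qstart[j]) ov <- TRUE
    if (!ov) acc <- c(acc, i)
  }
  sort(acc)
}

# Windowed local-maximum peak finder by direct scan.
oracle_peaks <- function(s, w) {
  n <- length(s)
  out <- integer(0)
  for (b in seq_len(n) - 1L) {
    if (b < w || b > n - 1L - w) next
    v <- s[b + 1L]
    if (v <= 0) next
    win_before <- s[(b - w):(b - 1L) + 1L]
    win_after <- s[(b + 1L):(b + w) + 1L]
    if (all(win_before < v) && all(win_after <= v)) out <- c(out, b)
  }
  out
}

random_symmetric_matrix <- function(n, lambda = 5) {
  M <- matrix(rpois(n * n, lambda), n, n)
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  M
}

# A small diploid bundle shared across tests (built once per test run).
desk_bundle <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    tr <- sim_diploid(2, 1.2e5, 0.005,
                      type_probs = c(snv = 0.91, indel = 0.09, inv = 0),
                      seed = 101)
    frag <- fragment_to_style(tr, "paired_haplotype",
                              mean_fragment = 3e4, seed = 102)
    hic <- sim_hic(tr, coverage = 30, seed = 103)
    pairs <- contacts_to_pairs(hic, frag$fragments)
    reads <- sim_long_reads(tr, coverage = 20, seed = 104)
    paf <- truth_paf(reads, frag$fragments)
    cache <<- list(truth = tr, frag = frag, hic = hic, pairs = pairs,
                   reads = reads, paf = paf)
    cache
  }
})

frag_to_contigset <- function(frag) {
  d <- tempfile("frag")
  paths <- write_fragments(frag, d)
  on.exit(unlink(d, recursive = TRUE))
  switch(frag$style,
         paired_haplotype = read_assembly(paths$fasta, frag$style,
                                          pairing_sidecar = paths$sidecar),
         pseudo_haplotype = read_assembly(paths$fasta, frag$style,
                                          alternative_fasta =
                                            paths$alternative),
         read_assembly(paths$fasta, frag$style))
}
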