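# Diploid genome / sequencing-evidence simulator with full truth tracking.
# All generators are seed-deterministic: the seed argument fully determines
# the output.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a diploid genome with truth tracking
#'
#' Haplotype 0 is random DNA; haplotype 1 is derived from it by seeded
#' heterozygous variants: SNVs, small indels (1-10 bp) and optionally
#' inversions (1-10 kb), in the proportions given by \code{type_probs}.
#' A piecewise-linear liftover map between the two haplotypes is returned
#' alongside the full variant table.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome (bases, >= 5e4).
#' @param heterozygosity Per-base variant rate in [0, 0.05].
#' @param type_probs Named probabilities for variant types
#'   \code{c(snv=, indel=, inv=)}.
#' @param indel_range,inv_range Length ranges (bases) for indels and
#'   inversions.
#' @param seed Integer seed.
#' @return A \code{"diploid_truth"} list: \code{chrom} table (name, len0,
#'   len1), \code{hap0}/\code{hap1} named sequence vectors, \code{variants}
#'   table (chrom, pos0, pos1, type, len, ref, alt), and \code{segmap}, a
#'   per-chromosome liftover table (h0_start, h0_end, h1_start, h1_end,
#'   strand).
#' @export
sim_diploid <- function(n_chrom = 2L, chrom_length = 5e5,
                        heterozygosity = 0.005,
                        type_probs = c(snv = 0.90, indel = 0.09, inv = 0.01),
                        indel_range = c(1, 10), inv_range = c(1e3, 1e4),
                        seed = 1L) {
  if (heterozygosity < 0 || heterozygosity > 0.05)
    stop("heterozygosity must be in [0, 0.05]", call. = FALSE)
  if (chrom_length < 5e4) stop("chrom_length must be >= 5e4", call. = FALSE)
  if (any(type_probs < 0) || sum(type_probs) <= 0)
    stop("invalid type_probs", call. = FALSE)
  type_probs <- type_probs / sum(type_probs)
  set.seed(seed)
  chroms <- sprintf("chr%d", seq_len(n_chrom))
  hap0 <- hap1 <- stats::setNames(character(n_chrom), chroms)
  variants <- list()
  segmap <- list()
  for (ci in seq_len(n_chrom)) {
    L <- chrom_length
    s0 <- random_dna(L)
    n_var <- round(heterozygosity * L)
    types <- sample(names(type_probs), n_var, replace = TRUE,
                    prob = type_probs)
    # structural events (indels, inversions) first: they define the segments
    ev_type <- types[types != "snv"]
    ev <- data.frame(type = ev_type, stringsAsFactors = FALSE)
    if (nrow(ev)) {
      ev$len <- ifelse(ev$type == "indel",
                       sample(indel_range[1]:indel_range[2], nrow(ev),
                              replace = TRUE),
                       round(stats::runif(nrow(ev), inv_range[1],
                                          inv_range[2])))
      ev$ins <- ev$type == "indel" &
        sample(c(TRUE, FALSE), nrow(ev), replace = TRUE)
      ev$foot <- ifelse(ev$ins, 0L, ev$len)  # bases consumed on hap0
      ev$pos <- sort(sample.int(L - max(ev$len) - 1L, nrow(ev)))
      # drop events whose hap0 footprint overlaps the previous kept event
      keep <- logical(nrow(ev))
      last_end <- -1L
      ord <- order(ev$pos)
      for (i in ord) {
        if (ev$pos[i] > last_end) {
          keep[i] <- TRUE
          last_end <- ev$pos[i] + max(ev$foot[i], 1L)
        }
      }
      ev <- ev[keep, , drop = FALSE]
      ev <- ev[order(ev$pos), , drop = FALSE]
    }
    # walk hap0 building hap1 and the segment map
    segs <- list()
    parts <- list()
    vrows <- list()
    cur0 <- 0L; cur1 <- 0L
    emit_copy <- function(upto) {
      if (upto > cur0) {
        parts[[length(parts) + 1L]] <<- substr(s0, cur0 + 1L, upto)
        segs[[length(segs) + 1L]] <<-
          c(cur0, upto, cur1, cur1 + (upto - cur0), 1L)
        cur1 <<- cur1 + (upto - cur0)
        cur0 <<- upto
      }
    }
    if (nrow(ev)) {
      for (i in seq_len(nrow(ev))) {
        p <- ev$pos[i]; len <- ev$len[i]
        emit_copy(p)
        if (ev$type[i] == "inv") {
          sq <- revcomp(substr(s0, p + 1L, p + len))
          parts[[length(parts) + 1L]] <- sq
          segs[[length(segs) + 1L]] <- c(p, p + len, cur1, cur1 + len, -1L)
          vrows[[length(vrows) + 1L]] <- data.frame(
            chrom = chroms[ci], pos0 = p, pos1 = cur1, type = "inv",
            len = len, ref = "", alt = "", stringsAsFactors = FALSE)
          cur1 <- cur1 + len
          cur0 <- p + len
        } else if (ev$ins[i]) {
          sq <- random_dna(len)
          parts[[length(parts) + 1L]] <- sq
          vrows[[length(vrows) + 1L]] <- data.frame(
            chrom = chroms[ci], pos0 = p, pos1 = cur1, type = "ins",
            len = len, ref = "", alt = sq, stringsAsFactors = FALSE)
          cur1 <- cur1 + len
        } else {
          vrows[[length(vrows) + 1L]] <- data.frame(
            chrom = chroms[ci], pos0 = p, pos1 = NA_real_, type = "del",
            len = len, ref = substr(s0, p + 1L, p + len), alt = "",
            stringsAsFactors = FALSE)
          cur0 <- p + len
        }
      }
    }
    emit_copy(L)
    s1 <- paste(unlist(parts), collapse = "")
    sm <- do.call(rbind, segs)
    sm <- data.frame(h0_start = sm[, 1], h0_end = sm[, 2],
                     h1_start = sm[, 3], h1_end = sm[, 4],
                     strand = sm[, 5])
    # SNVs on plus-strand copied segments, outside event footprints
    n_snv <- sum(types == "snv")
    plus <- sm[sm$strand == 1L, , drop = FALSE]
    if (n_snv > 0 && nrow(plus)) {
      w <- plus$h0_end - plus$h0_start
      si <- sample.int(nrow(plus), n_snv, replace = TRUE, prob = w)
      off <- floor(stats::runif(n_snv) * w[si])
      p0 <- plus$h0_start[si] + off
      dup <- duplicated(p0)
      p0 <- p0[!dup]; si <- si[!dup]; off <- off[!dup]
      p1 <- plus$h1_start[si] + off
      ref <- substring(s0, p0 + 1L, p0 + 1L)
      alt <- vapply(ref, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L))
      # substitute in hap1
      s1v <- strsplit(s1, "")[[1L]]
      s1v[p1 + 1L] <- alt
      s1 <- paste(s1v, collapse = "")
      ord <- order(p0)
      vrows[[length(vrows) + 1L]] <- data.frame(
        chrom = chroms[ci], pos0 = p0[ord], pos1 = p1[ord], type = "snv",
        len = 1L, ref = ref[ord], alt = alt[ord], stringsAsFactors = FALSE)
    }
    hap0[ci] <- s0
    hap1[ci] <- s1
    segmap[[chroms[ci]]] <- sm
    v <- if (length(vrows)) do.call(rbind, vrows) else
      data.frame(chrom = character(0), pos0 = numeric(0), pos1 = numeric(0),
                 type = character(0), len = numeric(0), ref = character(0),
                 alt = character(0), stringsAsFactors = FALSE)
    variants[[ci]] <- v[order(v$pos0), , drop = FALSE]
  }
  variants <- do.call(rbind, variants)
  rownames(variants) <- NULL
  structure(list(
    chrom = data.frame(name = chroms,
                       len0 = nchar(hap0),
                       len1 = nchar(hap1),
                       stringsAsFactors = FALSE),
    hap0 = hap0, hap1 = hap1, variants = variants, segmap = segmap,
    seed = seed), class = "diploid_truth")
}

#' @export
print.diploid_truth <- function(x, ...) {
  cat(sprintf("diploid_truth: %d chromosomes, %s bp (hap0), %d variants\n",
              nrow(x$chrom), format(sum(x$chrom$len0), big.mark = ","),
              nrow(x$variants)))
  print(table(x$variants$type))
  invisible(x)
}

#' Lift positions between the two haplotypes of a simulated diploid
#'
#' @param truth A \code{diploid_truth}.
#' @param chrom Chromosome names (recycled).
#' @param pos 0-based positions on the source haplotype.
#' @param from Source haplotype (0 or 1).
#' @return Numeric vector of positions on the other haplotype; \code{NA}
#'   where the position falls in an unalignable (indel) gap.
#' @export
lift_position <- function(truth, chrom, pos, from = 0L) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  out <- rep(NA_real_, n)
  for (cn in unique(chrom)) {
    sm <- truth$segmap[[cn]]
    if (is.null(sm)) stop("unknown chromosome: ", cn, call. = FALSE)
    i <- which(chrom == cn)
    if (from == 0L) {
      s_start <- sm$h0_start; s_end <- sm$h0_end
      t_start <- sm$h1_start
    } else {
      s_start <- sm$h1_start; s_end <- sm$h1_end
      t_start <- sm$h0_start
    }
    idx <- findInterval(pos[i], s_start)
    ok <- idx >= 1L & pos[i] < s_end[pmax(idx, 1L)]
    idxok <- idx[ok]
    rel <- pos[i][ok] - s_start[idxok]
    fwd <- sm$strand[idxok] == 1L
    res <- numeric(length(idxok))
    res[fwd] <- t_start[idxok][fwd] + rel[fwd]
    # inversion: positions map in reverse within the segment
    seglen <- (s_end - s_start)[idxok]
    res[!fwd] <- t_start[idxok][!fwd] + (seglen[!fwd] - 1 - rel[!fwd])
    out[i][ok] <- res
  }
  out
}

hap_lengths <- function(truth, hap) {
  if (hap == 0L) stats::setNames(truth$chrom$len0, truth$chrom$name)
  else stats::setNames(truth$chrom$len1, truth$chrom$name)
}

# inverse-CDF sampler for P(d) ~ d^-alpha on [dmin, dmax]
rpowerlaw <- function(n, alpha, dmin, dmax) {
  u <- stats::runif(n)
  if (abs(alpha - 1) < 1e-9) {
    dmin * (dmax / dmin)^u
  } else {
    a1 <- 1 - alpha
    (dmin^a1 + u * (dmax^a1 - dmin^a1))^(1 / a1)
  }
}

#' Simulate Hi-C contacts on a diploid truth genome
#'
#' Intra-chromosomal contact separations follow a power law
#' \eqn{P(d) \propto d^{-decay}} between \code{min_sep} and the chromosome
#' length; a fraction \code{inter_frac} of pairs is uniform across
#' chromosomes. Each pair starts on one haplotype; with probability
#' \code{trans_hap_frac} the second end's haplotype is re-drawn uniformly
#' (its position lifted to the homolog), which dilutes the haplotype-specific
#' contact signal available for phasing (at 1 the parallel and cross phase
#' counts become statistically equal).
#'
#' @param truth A \code{diploid_truth} (only lengths and liftover are used).
#' @param coverage Haploid-equivalent depth; the number of pairs is
#'   \code{coverage * total_diploid_length / (2 * read_len)}.
#' @param decay_exponent Power-law exponent (default 1).
#' @param inter_frac Fraction of inter-chromosomal pairs.
#' @param trans_hap_frac Fraction of pairs whose mate haplotype is re-drawn.
#' @param read_len Nominal read length (only sets the pair count).
#' @param min_sep Minimum intra-chromosomal separation (bases).
#' @param n_pairs Optional explicit pair count overriding \code{coverage}.
#' @param seed Integer seed.
#' @return Data frame of truth-labelled contacts: \code{read_id, chrom_a,
#'   hap_a, pos_a, chrom_b, hap_b, pos_b} (positions 0-based on the named
#'   haplotype).
#' @export
sim_hic <- function(truth, coverage = 30, decay_exponent = 1.0,
                    inter_frac = 0.05, trans_hap_frac = 0.5,
                    read_len = 150, min_sep = 1e3, n_pairs = NULL,
                    seed = 1L) {
  if (is.null(n_pairs)) {
    total <- sum(truth$chrom$len0) + sum(truth$chrom$len1)
    n_pairs <- round(coverage * total / (2 * read_len))
  }
  set.seed(seed)
  n <- n_pairs
  cn <- truth$chrom$name
  hap_a <- sample(0:1, n, replace = TRUE)
  len_of <- function(chrom, hap)
    ifelse(hap == 0L, truth$chrom$len0[match(chrom, cn)],
           truth$chrom$len1[match(chrom, cn)])
  chrom_a <- sample(cn, n, replace = TRUE, prob = truth$chrom$len0)
  la <- len_of(chrom_a, hap_a)
  pos_a <- floor(stats::runif(n) * la)
  inter <- stats::runif(n) < inter_frac
  chrom_b <- chrom_a
  if (any(inter))
    chrom_b[inter] <- sample(cn, sum(inter), replace = TRUE,
                             prob = truth$chrom$len0)
  lb <- len_of(chrom_b, hap_a)
  pos_b <- numeric(n)
  if (any(inter)) pos_b[inter] <- floor(stats::runif(sum(inter)) * lb[inter])
  ii <- which(!inter)
  if (length(ii)) {
    d <- round(rpowerlaw(length(ii), decay_exponent, min_sep,
                         pmax(la[ii] - 1, min_sep + 1)))
    sgn <- sample(c(-1, 1), length(ii), replace = TRUE)
    pb <- pos_a[ii] + sgn * d
    flip <- pb < 0 | pb >= lb[ii]
    pb[flip] <- pos_a[ii][flip] - sgn[flip] * d[flip]
    pb <- pmin(pmax(pb, 0), lb[ii] - 1)
    pos_b[ii] <- pb
  }
  hap_b <- hap_a
  trans <- stats::runif(n) < trans_hap_frac
  if (any(trans)) hap_b[trans] <- sample(0:1, sum(trans), replace = TRUE)
  moved <- hap_b != hap_a
  if (any(moved)) {
    # lift per source haplotype (vectorised per group)
    for (h in unique(hap_a[moved])) {
      g <- moved & hap_a == h
      lifted_g <- lift_position(truth, chrom_b[g], pos_b[g], from = h)
      bad <- is.na(lifted_g)
      hap_b[g][bad] <- h            # unliftable: keep original haplotype
      pos_b[g][!bad] <- lifted_g[!bad]
    }
  }
  data.frame(read_id = sprintf("hic%07d", seq_len(n)),
             chrom_a = chrom_a, hap_a = hap_a, pos_a = pos_a,
             chrom_b = chrom_b, hap_b = hap_b, pos_b = pos_b,
             stringsAsFactors = FALSE)
}

#' Simulate long reads over a diploid truth genome
#'
#' Read lengths are exponential around \code{mean_len} (truncated at
#' \code{min_len}); reads are drawn per haplotype until each reaches the
#' requested depth. Sequences are only materialised on request; the truth
#' interval table is the primary output and feeds [truth_paf()].
#'
#' @param truth A \code{diploid_truth}.
#' @param coverage Per-haplotype depth.
#' @param mean_len,min_len Mean / minimum read length (bases).
#' @param error_rate Per-base substitution rate recorded in alignment
#'   identities (and applied to emitted sequences).
#' @param emit_sequences If TRUE, include read sequences.
#' @param seed Integer seed.
#' @return Data frame \code{read_id, chrom, hap, start, end, len} (+
#'   \code{seq} when requested); positions 0-based half-open on the read's
#'   haplotype.
#' @export
sim_long_reads <- function(truth, coverage = 20, mean_len = 1.5e4,
                           min_len = 1e3, error_rate = 0.0,
                           emit_sequences = FALSE, seed = 1L) {
  set.seed(seed)
  out <- list()
  for (h in 0:1) {
    lens <- hap_lengths(truth, h)
    for (cn in names(lens)) {
      L <- lens[[cn]]
      target <- coverage * L
      got <- 0
      rl <- numeric(0)
      while (got < target) {
        batch <- pmax(round(stats::rexp(256, 1 / mean_len)), min_len)
        batch <- pmin(batch, L)
        rl <- c(rl, batch)
        got <- got + sum(batch)
      }
      rl <- rl[cumsum(rl) - rl < target]
      start <- floor(stats::runif(length(rl)) * (L - rl + 1))
      out[[length(out) + 1L]] <- data.frame(
        chrom = cn, hap = h, start = start, end = start + rl, len = rl,
        stringsAsFactors = FALSE)
    }
  }
  reads <- do.call(rbind, out)
  reads <- data.frame(read_id = sprintf("lr%06d", seq_len(nrow(reads))),
                      reads, stringsAsFactors = FALSE)
  attr(reads, "error_rate") <- error_rate
  if (emit_sequences) {
    hap_seq <- function(h, cn) if (h == 0L) truth$hap0[[cn]] else
      truth$hap1[[cn]]
    reads$seq <- vapply(seq_len(nrow(reads)), function(i) {
      sq <- substr(hap_seq(reads$hap[i], reads$chrom[i]),
                   reads$start[i] + 1L, reads$end[i])
      if (error_rate > 0) {
        v <- strsplit(sq, "")[[1L]]
        k <- which(stats::runif(length(v)) < error_rate)
        if (length(k))
          v[k] <- vapply(v[k], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L))
        sq <- paste(v, collapse = "")
      }
      sq
    }, character(1L))
  }
  reads
}

#' Simulate paired-end reads as mapped pair records
#'
#' @param truth A \code{diploid_truth}.
#' @param coverage Per-haplotype depth.
#' @param insert_mean,insert_sd Insert-size distribution (bases).
#' @param read_len Read length (bases).
#' @param seed Integer seed.
#' @return List with \code{pairs} (read_id, chrom, hap, pos_a, pos_b: the
#'   5' mapping positions of the two mates, 0-based) and \code{library}
#'   (kind, a, d, read_len).
#' @export
sim_paired_end <- function(truth, coverage = 10, insert_mean = 500,
                           insert_sd = 50, read_len = 100, seed = 1L) {
  set.seed(seed)
  out <- list()
  for (h in 0:1) {
    lens <- hap_lengths(truth, h)
    for (cn in names(lens)) {
      L <- lens[[cn]]
      n <- round(coverage * L / (2 * read_len))
      ins <- pmax(round(stats::rnorm(n, insert_mean, insert_sd)),
                  2 * read_len)
      start <- floor(stats::runif(n) * pmax(L - ins, 1))
      out[[length(out) + 1L]] <- data.frame(
        chrom = cn, hap = h, pos_a = start,
        pos_b = pmin(start + ins - read_len, L - read_len),
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, out)
  pairs <- data.frame(read_id = sprintf("pe%07d", seq_len(nrow(pairs))),
                      pairs, stringsAsFactors = FALSE)
  list(pairs = pairs,
       library = list(kind = "paired_end", a = insert_mean, d = insert_sd,
                      read_len = read_len))
}

#' Fragment a diploid truth genome into one of the three contig styles
#'
#' Chromosomes are cut at seeded random points (breakpoints shared between
#' haplotypes through the liftover map, and kept out of inversions so the
#' map stays monotone). Fragments whose local variant density is below
#' \code{collapse_threshold} are emitted once as a collapsed contig; the
#' rest are emitted once per haplotype.
#'
#' @param truth A \code{diploid_truth}.
#' @param style \code{"paired_haplotype"}, \code{"pseudo_haplotype"} or
#'   \code{"haplotype_ignorant"}.
#' @param mean_fragment Target fragment length (bases, >= 5e4 / 3).
#' @param collapse_threshold Variant density (per base) below which a
#'   fragment is collapsed.
#' @param seed Integer seed.
#' @return A \code{"sim_fragments"} list: \code{style}; \code{seq} (named
#'   contig sequences; for pseudo-haplotype additionally split into
#'   \code{primary_ids}/\code{alternative_ids}); \code{sidecar} (pairing
#'   table for paired-haplotype); \code{fragments} truth table (contig_id,
#'   hap, chrom, start, end, orientation, collapsed) with one row per
#'   haplotype interval a contig represents.
#' @export
fragment_to_style <- function(truth, style, mean_fragment = 5e4,
                              collapse_threshold = 1e-4, seed = 1L) {
  style <- match.arg(style, c("paired_haplotype", "pseudo_haplotype",
                              "haplotype_ignorant"))
  set.seed(seed)
  seqs <- character(0)
  sidecar <- list()
  frows <- list()
  for (ci in seq_len(nrow(truth$chrom))) {
    cn <- truth$chrom$name[ci]
    L0 <- truth$chrom$len0[ci]
    nf <- max(1L, round(L0 / mean_fragment))
    if (nf > 1L) {
      bp0 <- round((seq_len(nf - 1L) / nf) * L0 +
                     stats::runif(nf - 1L, -0.2, 0.2) * mean_fragment)
      bp0 <- sort(unique(pmin(pmax(bp0, 1), L0 - 1)))
      # keep breakpoints out of inverted segments
      sm <- truth$segmap[[cn]]
      inv <- sm[sm$strand == -1L, , drop = FALSE]
      if (nrow(inv)) {
        for (k in seq_along(bp0)) {
          inside <- which(bp0[k] >= inv$h0_start & bp0[k] < inv$h0_end)
          if (length(inside)) bp0[k] <- inv$h0_start[inside[1L]]
        }
        bp0 <- sort(unique(bp0))
      }
      bp1 <- lift_position(truth, rep(cn, length(bp0)), bp0, from = 0L)
      # a breakpoint in an unliftable gap is nudged forward until it lifts
      while (anyNA(bp1)) {
        bad <- which(is.na(bp1))
        bp0[bad] <- bp0[bad] + 1L
        bp1 <- lift_position(truth, rep(cn, length(bp0)), bp0, from = 0L)
      }
    } else {
      bp0 <- bp1 <- numeric(0)
    }
    b0 <- c(0, bp0, L0)
    b1 <- c(0, bp1, truth$chrom$len1[ci])
    vpos <- truth$variants$pos0[truth$variants$chrom == cn]
    for (fi in seq_len(length(b0) - 1L)) {
      s0 <- b0[fi]; e0 <- b0[fi + 1L]
      s1 <- b1[fi]; e1 <- b1[fi + 1L]
      nv <- sum(vpos >= s0 & vpos < e0)
      dens <- nv / max(e0 - s0, 1)
      stem <- sprintf("%s_f%02d", cn, fi)
      if (dens < collapse_threshold) {
        id <- paste0(stem, "_c")
        seqs[id] <- substr(truth$hap0[[cn]], s0 + 1L, e0)
        frows[[length(frows) + 1L]] <- data.frame(
          contig_id = id, hap = c(0L, 1L), chrom = cn,
          start = c(s0, s1), end = c(e0, e1), orientation = "+",
          collapsed = TRUE, stringsAsFactors = FALSE)
        sidecar[[length(sidecar) + 1L]] <- data.frame(
          contig_id = id, partner_id = "-", coverage = 80,
          stringsAsFactors = FALSE)
      } else {
        idp <- paste0(stem, "_p"); ids <- paste0(stem, "_s")
        seqs[idp] <- substr(truth$hap0[[cn]], s0 + 1L, e0)
        seqs[ids] <- substr(truth$hap1[[cn]], s1 + 1L, e1)
        frows[[length(frows) + 1L]] <- data.frame(
          contig_id = c(idp, ids), hap = c(0L, 1L), chrom = cn,
          start = c(s0, s1), end = c(e0, e1), orientation = "+",
          collapsed = FALSE, stringsAsFactors = FALSE)
        sidecar[[length(sidecar) + 1L]] <- data.frame(
          contig_id = c(idp, ids), partner_id = c(ids, idp),
          coverage = c(40, 40), stringsAsFactors = FALSE)
      }
    }
  }
  fragments <- do.call(rbind, frows)
  rownames(fragments) <- NULL
  sidecar <- do.call(rbind, sidecar)
  res <- list(style = style, seq = seqs, sidecar = sidecar,
              fragments = fragments)
  if (style == "pseudo_haplotype") {
    # per fragment, the longer member is primary, its partner alternative
    prim <- character(0); alt <- character(0)
    for (i in seq_len(nrow(sidecar))) {
      id <- sidecar$contig_id[i]; p <- sidecar$partner_id[i]
      if (p == "-") { prim <- c(prim, id); next }
      if (id %in% c(prim, alt) || p %in% c(prim, alt)) next
      if (nchar(seqs[[id]]) >= nchar(seqs[[p]])) {
        prim <- c(prim, id); alt <- c(alt, p)
      } else {
        prim <- c(prim, p); alt <- c(alt, id)
      }
    }
    res$primary_ids <- prim
    res$alternative_ids <- alt
  }
  class(res) <- "sim_fragments"
  res
}

#' Express truth-labelled Hi-C contacts in contig coordinates
#'
#' Assigns each contact end to the simulated contig covering its (chrom,
#' haplotype, position); for collapsed contigs both haplotypes map to the
#' same contig. Ends falling outside every fragment are dropped.
#'
#' @param contacts Output of [sim_hic()].
#' @param fragments Fragment truth table from [fragment_to_style()].
#' @return A pairs data frame \code{read_id, seq_a, pos_a, seq_b, pos_b}
#'   (contig ids, 0-based contig positions).
#' @export
contacts_to_pairs <- function(contacts, fragments) {
  locate <- function(chrom, hap, pos) {
    ctg <- rep(NA_character_, length(pos))
    rel <- rep(NA_real_, length(pos))
    key <- paste(chrom, hap)
    for (k in unique(key)) {
      parts <- strsplit(k, " ")[[1L]]
      fr <- fragments[fragments$chrom == parts[1L] &
                        fragments$hap == as.integer(parts[2L]), ,
                      drop = FALSE]
      fr <- fr[order(fr$start), , drop = FALSE]
      i <- which(key == k)
      if (!nrow(fr)) next
      idx <- findInterval(pos[i], fr$start)
      ok <- idx >= 1L & pos[i] < fr$end[pmax(idx, 1L)]
      ctg[i][ok] <- fr$contig_id[idx[ok]]
      rel[i][ok] <- pos[i][ok] - fr$start[idx[ok]]
    }
    list(ctg = ctg, rel = rel)
  }
  a <- locate(contacts$chrom_a, contacts$hap_a, contacts$pos_a)
  b <- locate(contacts$chrom_b, contacts$hap_b, contacts$pos_b)
  keep <- !is.na(a$ctg) & !is.na(b$ctg)
  data.frame(read_id = contacts$read_id[keep],
             seq_a = a$ctg[keep], pos_a = a$rel[keep],
             seq_b = b$ctg[keep], pos_b = b$rel[keep],
             stringsAsFactors = FALSE)
}

#' Emit truth-derived PAF alignments of simulated long reads to contigs
#'
#' Each read interval is intersected with the fragment table of its
#' haplotype (collapsed fragments match both haplotypes), producing one PAF
#' row per overlapped contig with identity \code{1 - error_rate}.
#'
#' @param reads Output of [sim_long_reads()].
#' @param fragments Fragment truth table from [fragment_to_style()].
#' @param min_overlap Minimum read/contig overlap (bases) to report.
#' @return A PAF data frame as from [read_paf()].
#' @export
truth_paf <- function(reads, fragments, min_overlap = 200) {
  err <- attr(reads, "error_rate")
  if (is.null(err)) err <- 0
  out <- list()
  key <- paste(reads$chrom, reads$hap)
  for (k in unique(key)) {
    parts <- strsplit(k, " ")[[1L]]
    fr <- fragments[fragments$chrom == parts[1L] &
                      fragments$hap == as.integer(parts[2L]), , drop = FALSE]
    fr <- fr[order(fr$start), , drop = FALSE]
    if (!nrow(fr)) next
    rd <- reads[key == k, , drop = FALSE]
    # overlap join: fragments are disjoint tiles, reads short vs chromosome
    first <- findInterval(rd$start, fr$start)
    for (i in seq_len(nrow(rd))) {
      j <- max(first[i], 1L)
      while (j <= nrow(fr) && fr$start[j] < rd$end[i]) {
        ov_s <- max(rd$start[i], fr$start[j])
        ov_e <- min(rd$end[i], fr$end[j])
        if (ov_e - ov_s >= min_overlap) {
          alen <- ov_e - ov_s
          out[[length(out) + 1L]] <- data.frame(
            qname = rd$read_id[i], qlen = rd$len[i],
            qstart = ov_s - rd$start[i], qend = ov_e - rd$start[i],
            strand = "+", tname = fr$contig_id[j],
            tlen = fr$end[j] - fr$start[j],
            tstart = ov_s - fr$start[j], tend = ov_e - fr$start[j],
            nmatch = round(alen * (1 - err)), alen = alen, mapq = 60,
            stringsAsFactors = FALSE)
        }
        j <- j + 1L
      }
    }
  }
  if (!length(out))
    return(read_paf(textConnection(character(0))))
  paf <- do.call(rbind, out)
  rownames(paf) <- NULL
  paf
}

#' Write a simulated fragment set to FASTA (+ sidecar) files
#'
#' @param frag A \code{sim_fragments} object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named list of written paths (\code{fasta}, and per style
#'   \code{sidecar} or \code{alternative}).
#' @export
write_fragments <- function(frag, dir, prefix = "contigs") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  if (frag$style == "pseudo_haplotype") {
    paths$fasta <- file.path(dir, paste0(prefix, "_primary.fa"))
    paths$alternative <- file.path(dir, paste0(prefix, "_alternative.fa"))
    write_fasta_chr(frag$seq[frag$primary_ids], paths$fasta)
    write_fasta_chr(frag$seq[frag$alternative_ids], paths$alternative)
  } else if (frag$style == "paired_haplotype") {
    paths$fasta <- file.path(dir, paste0(prefix, ".fa"))
    paths$sidecar <- file.path(dir, paste0(prefix, "_pairing.tsv"))
    write_fasta_chr(frag$seq, paths$fasta)
    utils::write.table(frag$sidecar, paths$sidecar, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    paths$fasta <- file.path(dir, paste0(prefix, ".fa"))
    write_fasta_chr(frag$seq, paths$fasta)
  }
  paths
}
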