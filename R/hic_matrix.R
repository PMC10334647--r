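# Binned Hi-C contact matrices and the junction/misassembly statistics.
#
# A junction between bins b-1 and b is scored per diagonal distance k:
# inner pixels are same-side pixels at distance exactly k within a
# k_max-bin window adjacent to the junction; outer pixels are the
# cross-junction pixels at distance exactly k. The separation score S is
# the summed two-class between-class variance of inner vs outer pixel
# values (Otsu-style), and R is the fraction of outer pixels falling below
# the matching inner mean. Both are computed on the upper (left of the
# junction) and lower (right) sides.

#' Build a binned Hi-C contact matrix
#'
#' Positions are binned as \code{floor(pos / bin_size)}, offset by the bins
#' of preceding sequences; the trailing partial bin of each sequence is
#' dropped, and contacts falling into it are ignored. The matrix is
#' incremented symmetrically.
#'
#' @param seq_lengths Named lengths (bases) of one or two sequences; with
#'   two, the junction bin is set at their boundary.
#' @param contacts Data frame \code{seq_a, pos_a, seq_b, pos_b} with 0-based
#'   positions on those sequences.
#' @param bin_size Bin width (bases).
#' @param junction_bin Optional 0-based junction index (boundary between
#'   bins \code{junction_bin - 1} and \code{junction_bin}).
#' @return A \code{"hic_matrix"}: \code{M} (symmetric count matrix),
#'   \code{bin_size}, \code{n_bins}, \code{scaffold_ids}, \code{offsets}
#'   (starting bin per sequence) and \code{junction_bin}.
#' @export
build_contact_matrix <- function(seq_lengths, contacts, bin_size,
                                 junction_bin = NULL) {
  stopifnot(bin_size > 0, length(seq_lengths) >= 1L)
  ids <- names(seq_lengths)
  nb <- floor(seq_lengths / bin_size)
  offsets <- stats::setNames(cumsum(c(0, nb[-length(nb)])), ids)
  n <- sum(nb)
  M <- matrix(0, n, n)
  if (length(ids) == 2L && is.null(junction_bin))
    junction_bin <- unname(nb[1L])
  if (nrow(contacts)) {
    bad_a <- !(contacts$seq_a %in% ids)
    bad_b <- !(contacts$seq_b %in% ids)
    if (any(bad_a | bad_b))
      stop("contact references unknown sequence: ",
           c(contacts$seq_a[bad_a], contacts$seq_b[bad_b])[1L],
           call. = FALSE)
    if (any(contacts$pos_a >= seq_lengths[contacts$seq_a]) ||
        any(contacts$pos_b >= seq_lengths[contacts$seq_b]) ||
        any(contacts$pos_a < 0) || any(contacts$pos_b < 0))
      stop("contact position outside its sequence", call. = FALSE)
    ba <- floor(contacts$pos_a / bin_size)
    bb <- floor(contacts$pos_b / bin_size)
    ok <- ba < nb[contacts$seq_a] & bb < nb[contacts$seq_b]
    i <- offsets[contacts$seq_a[ok]] + ba[ok]
    j <- offsets[contacts$seq_b[ok]] + bb[ok]
    if (length(i)) {
      tab <- table(i * n + j)
      idx <- as.numeric(names(tab))
      ii <- idx %/% n; jj <- idx %% n
      M[cbind(ii + 1L, jj + 1L)] <- M[cbind(ii + 1L, jj + 1L)] + as.numeric(tab)
      off_diag <- ii != jj
      M[cbind(jj + 1L, ii + 1L)[off_diag, , drop = FALSE]] <-
        M[cbind(jj + 1L, ii + 1L)[off_diag, , drop = FALSE]] +
        as.numeric(tab)[off_diag]
    }
  }
  structure(list(M = M, bin_size = bin_size, n_bins = n,
                 scaffold_ids = ids, offsets = offsets,
                 junction_bin = junction_bin),
            class = "hic_matrix")
}

#' @export
print.hic_matrix <- function(x, ...) {
  cat(sprintf("hic_matrix: %d bins x %g bp (%s)%s, %g contacts\n",
              x$n_bins, x$bin_size, paste(x$scaffold_ids, collapse = " + "),
              if (!is.null(x$junction_bin))
                sprintf(", junction at bin %d", x$junction_bin) else "",
              sum(x$M[upper.tri(x$M, diag = TRUE)])))
  invisible(x)
}

# inner pixel values at distance exactly k on one side of junction b,
# within a k_max-bin window adjacent to the junction; M is the full matrix.
inner_pixels <- function(M, b, k, k_max, side) {
  n <- nrow(M)
  if (side == "upper") {
    lo <- max(0L, b - k_max)
    hi <- b - 1L - k
  } else {
    lo <- b
    hi <- min(n - 1L, b + k_max - 1L) - k
  }
  if (hi < lo) return(numeric(0))
  i <- seq.int(lo, hi)
  M[cbind(i + 1L, i + k + 1L)]
}

outer_pixels <- function(M, b, k) {
  n <- nrow(M)
  lo <- max(0L, b - k)
  hi <- min(b - 1L, n - 1L - k)
  if (hi < lo) return(numeric(0))
  i <- seq.int(lo, hi)
  M[cbind(i + 1L, i + k + 1L)]
}

#' Separation scores at a junction
#'
#' Computes the between-class-variance separation score \code{S}, the
#' sparse-map score \code{R}, and the zeroed-outer normalisers \code{S0}
#' for the upper and lower sides of the matrix's junction.
#'
#' @param mat A \code{hic_matrix} with \code{junction_bin} set.
#' @param k_max Largest diagonal distance (bins).
#' @return List \code{S_upper, S_lower, R_upper, R_lower, S_upper_0,
#'   S_lower_0}.
#' @export
separation_scores <- function(mat, k_max = 10L) {
  if (k_max < 1L) stop("k_max must be >= 1", call. = FALSE)
  b <- mat$junction_bin
  if (is.null(b)) stop("junction_bin is not set", call. = FALSE)
  M <- mat$M
  res <- list()
  for (side in c("upper", "lower")) {
    S <- S0 <- 0
    L_sum <- N_out_sum <- 0
    for (k in seq_len(k_max)) {
      pin <- inner_pixels(M, b, k, k_max, side)
      pout <- outer_pixels(M, b, k)
      n_in <- length(pin); n_out <- length(pout)
      if (n_in + n_out == 0L) next
      mu_in <- if (n_in) mean(pin) else 0
      mu_out <- if (n_out) mean(pout) else 0
      denom <- (n_in + n_out)^2
      S <- S + n_in * n_out * (mu_in - mu_out)^2 / denom
      S0 <- S0 + n_in * n_out * mu_in^2 / denom
      if (n_in > 0L && n_out > 0L) {
        L_sum <- L_sum + sum(pout < mu_in)
        N_out_sum <- N_out_sum + n_out
      }
    }
    R <- if (N_out_sum > 0) L_sum / N_out_sum else 0
    res[[paste0("S_", side)]] <- S
    res[[paste0("R_", side)]] <- R
    res[[paste0("S_", side, "_0")]] <- S0
  }
  res[c("S_upper", "S_lower", "R_upper", "R_lower",
        "S_upper_0", "S_lower_0")]
}

#' Erroneous-edge test from separation scores
#'
#' An edge (candidate junction) is called erroneous when both
#' \code{S_upper/S_upper_0 + S_lower/S_lower_0 >= s_threshold} and
#' \code{R_upper + R_lower >= r_threshold} hold. A zero normaliser
#' (degenerate sparse map) contributes a ratio of 0 for that side.
#'
#' @param scores Output of [separation_scores()].
#' @param s_threshold,r_threshold Decision thresholds (defaults 1.0, 1.6).
#' @return TRUE if the junction is surmised erroneous.
#' @export
is_erroneous_edge_hic <- function(scores, s_threshold = 1.0,
                                  r_threshold = 1.6) {
  ratio <- function(S, S0) if (S0 > 0) S / S0 else 0
  s_sum <- ratio(scores$S_upper, scores$S_upper_0) +
    ratio(scores$S_lower, scores$S_lower_0)
  r_sum <- scores$R_upper + scores$R_lower
  (s_sum >= s_threshold) && (r_sum >= r_threshold)
}

#' Genome-wide contact distance-decay profile
#'
#' Pooled mean pixel value at each diagonal distance \code{k = 1..k_max}
#' over the supplied matrices (all qualifying scaffolds' pixels pooled, not
#' a mean of per-scaffold means).
#'
#' @param mats List of \code{hic_matrix} objects.
#' @param k_max Largest distance (bins).
#' @return Numeric vector \code{mu_all} of length \code{k_max}.
#' @export
global_distance_profile <- function(mats, k_max = 10L) {
  if (!length(mats)) stop("no matrices supplied", call. = FALSE)
  mu <- numeric(k_max)
  for (k in seq_len(k_max)) {
    tot <- 0; cnt <- 0
    for (m in mats) {
      n <- m$n_bins
      if (n <= k) next
      i <- seq_len(n - k)
      v <- m$M[cbind(i, i + k)]
      tot <- tot + sum(v)
      cnt <- cnt + length(v)
    }
    mu[k] <- if (cnt > 0) tot / cnt else 0
  }
  mu
}

#' Per-bin misassembly score profile
#'
#' For each bin \code{b}, a triangular motif of pixels crossing \code{b}
#' (pixels \code{(i, i+k)} with \code{i <= b <= i+k}) is compared with the
#' genome-wide decay: \code{Score(b) = sum_k (mu_all_k - mu_target_k(b))^2
#' / mu_target_k(b)}. Target means of zero are replaced by
#' \code{zero_floor} (half a count) so sparse bins stay finite.
#'
#' @param mat A \code{hic_matrix} of the target scaffold.
#' @param mu_all Decay profile from [global_distance_profile()].
#' @param k_max Largest distance (bins); 10 matches the score's definition.
#' @param zero_floor Replacement for zero target means.
#' @return A \code{"misassembly_profile"}: \code{scores} (per bin),
#'   \code{mu_all}, \code{k_max}, \code{bin_size}, \code{n_bins}.
#' @export
misassembly_scores <- function(mat, mu_all, k_max = 10L, zero_floor = 0.5) {
  n <- mat$n_bins
  if (n < k_max + 1L) stop("matrix has fewer than k_max + 1 bins",
                           call. = FALSE)
  M <- mat$M
  diags <- lapply(seq_len(k_max), function(k) {
    i <- seq_len(n - k)
    M[cbind(i, i + k)]
  })
  scores <- numeric(n)
  for (b in 0:(n - 1L)) {
    sc <- 0
    for (k in seq_len(k_max)) {
      lo <- max(0L, b - k)
      hi <- min(b, n - 1L - k)
      if (hi < lo) next
      mu_t <- mean(diags[[k]][(lo:hi) + 1L])
      if (mu_t <= 0) mu_t <- zero_floor
      sc <- sc + (mu_all[k] - mu_t)^2 / mu_t
    }
    scores[b + 1L] <- sc
  }
  structure(list(scores = scores, mu_all = mu_all, k_max = k_max,
                 bin_size = mat$bin_size, n_bins = n),
            class = "misassembly_profile")
}

#' Detect peaks in a misassembly score profile
#'
#' A bin is a peak when its score is positive, at least as large as every
#' score within \code{window} bins, strictly larger than every earlier score
#' in the window (leftmost bin of a plateau), and its window is complete
#' (bins within \code{window} of either end are not eligible).
#'
#' @param profile A \code{misassembly_profile} (or bare numeric vector).
#' @param window Half-width in bins.
#' @return Integer vector of 0-based peak bin indices.
#' @export
detect_peaks <- function(profile, window = 2L) {
  s <- if (inherits(profile, "misassembly_profile")) profile$scores
  else as.numeric(profile)
  n <- length(s)
  peaks <- integer(0)
  if (n < 2L * window + 1L) return(peaks)
  for (b in window:(n - 1L - window)) {
    v <- s[b + 1L]
    if (v <= 0) next
    before <- s[(b - window):(b - 1L) + 1L]
    after <- s[(b + 1L):(b + window) + 1L]
    if (all(before < v) && all(after <= v)) peaks <- c(peaks, b)
  }
  peaks
}

#' Automatic misassembly threshold selection
#'
#' Sweeps the threshold \code{P} over \code{0} and the peak heights; for
#' each trial the scaffold is notionally split at every peak above \code{P}
#' and the summed separation score \code{S_upper + S_lower} is computed at
#' each cut. The selected \code{P} maximises the mean \code{S} over cuts
#' (ties resolved toward larger \code{P}, i.e. fewer splits). Flagged bins
#' are the peaks above the selected \code{P} that additionally pass the
#' erroneous-edge test at their boundary.
#'
#' @param profile A \code{misassembly_profile} of the target scaffold.
#' @param mat The matching \code{hic_matrix}.
#' @param config A \code{hapscaf_config} (thresholds, peak window, k_max).
#' @return List \code{P} (selected threshold; \code{Inf} when there are no
#'   peaks) and \code{flagged} (0-based bin indices).
#' @export
select_threshold <- function(profile, mat, config = scaffold_config()) {
  peaks <- detect_peaks(profile, config$peak_window)
  if (!length(peaks)) return(list(P = Inf, flagged = integer(0)))
  hts <- profile$scores[peaks + 1L]
  if (all(hts <= 0)) return(list(P = Inf, flagged = integer(0)))
  # a peak bin spans the misassembly, so the cut boundary may be at either
  # side of the bin; score both and keep the stronger
  boundary_scores <- lapply(peaks, function(b) {
    cand <- unique(pmin(pmax(c(b, b + 1L), 1L), mat$n_bins - 1L))
    scs <- lapply(cand, function(jb) {
      m2 <- mat
      m2$junction_bin <- jb
      separation_scores(m2, config$k_max)
    })
    Ssum <- vapply(scs, function(s) s$S_upper + s$S_lower, numeric(1L))
    scs[[which.max(Ssum)]]
  })
  cut_S <- vapply(boundary_scores, function(s) s$S_upper + s$S_lower,
                  numeric(1L))
  trials <- sort(unique(c(0, hts)))
  best_P <- NA_real_; best_mean <- -Inf
  for (P in trials) {
    use <- hts > P
    if (!any(use)) next
    mS <- mean(cut_S[use])
    if (mS > best_mean || (mS == best_mean && P > best_P)) {
      best_mean <- mS
      best_P <- P
    }
  }
  if (!is.finite(best_mean)) return(list(P = Inf, flagged = integer(0)))
  sel <- which(hts > best_P)
  keep <- vapply(sel, function(t)
    is_erroneous_edge_hic(boundary_scores[[t]], config$s_threshold,
                          config$r_threshold), logical(1L))
  list(P = best_P, flagged = peaks[sel][keep])
}

#' Write a contact matrix as a sparse TSV dump
#'
#' @param mat A \code{hic_matrix}.
#' @param path Output path (columns bin_i, bin_j, count; upper triangle).
#' @export
write_matrix_tsv <- function(mat, path) {
  idx <- which(upper.tri(mat$M, diag = TRUE) & mat$M > 0, arr.ind = TRUE)
  df <- data.frame(bin_i = idx[, 1L] - 1L, bin_j = idx[, 2L] - 1L,
                   count = mat$M[idx])
  df <- df[order(df$bin_i, df$bin_j), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
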