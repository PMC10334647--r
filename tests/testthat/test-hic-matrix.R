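# Contact-map statistics: binning, separation scores, distance profile,
# misassembly score, peak detection, automatic threshold.

test_that("binning matches direct coordinate arithmetic", {
  cc <- data.frame(seq_a = c("x", "x"), pos_a = c(5e4, 5e4),
                   seq_b = c("x", "x"), pos_b = c(15e4, 25e4))
  m <- build_contact_matrix(c(x = 3e5), cc, 1e5)
  expect_equal(m$n_bins, 3L)
  want <- matrix(0, 3, 3)
  want[1, 2] <- want[2, 1] <- 1
  want[1, 3] <- want[3, 1] <- 1
  expect_equal(m$M, want)
  # no contacts -> zero matrix
  m0 <- build_contact_matrix(c(x = 3e5), cc[0, ], 1e5)
  expect_true(all(m0$M == 0))
  # contacts in a dropped trailing partial bin are ignored
  cc2 <- data.frame(seq_a = "x", pos_a = 3.4e5, seq_b = "x", pos_b = 1e4)
  m2 <- build_contact_matrix(c(x = 3.5e5), cc2, 1e5)
  expect_true(all(m2$M == 0))
  expect_error(build_contact_matrix(c(x = 3e5),
                                    data.frame(seq_a = "x", pos_a = 3e5,
                                               seq_b = "x", pos_b = 0),
                                    1e5), "outside")
  expect_error(build_contact_matrix(c(x = 3e5),
                                    data.frame(seq_a = "zz", pos_a = 1,
                                               seq_b = "x", pos_b = 0),
                                    1e5), "unknown")
})

test_that("column sums of a simulated matrix match independent end
           counts", {
  b <- desk_bundle()
  tr <- b$truth
  cc <- b$hic[b$hic$hap_a == 0 & b$hic$hap_b == 0, ]
  df <- data.frame(seq_a = cc$chrom_a, pos_a = cc$pos_a,
                   seq_b = cc$chrom_b, pos_b = cc$pos_b)
  bs <- 5e3
  m <- build_contact_matrix(c(chr1 = tr$chrom$len0[1],
                              chr2 = tr$chrom$len0[2]), df, bs)
  # independent counting: per-bin contact-end tally (diagonal counted once
  # per self-contact pair, so add it once more to mirror symmetry)
  # chromosome lengths are exact bin multiples here, so no ends are lost
  nb1 <- floor(tr$chrom$len0[1] / bs)
  gbin <- function(chrom, pos) ifelse(chrom == "chr1", 0, nb1) +
    floor(pos / bs)
  ends <- c(gbin(df$seq_a, df$pos_a), gbin(df$seq_b, df$pos_b))
  cnt <- tabulate(ends + 1L, nbins = m$n_bins)
  expect_equal(unname(colSums(m$M) + diag(m$M)), cnt)
})

test_that("separation scores match the brute-force enumeration oracle", {
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(6:12, 1)
    M <- random_symmetric_matrix(n)
    b <- sample(2:(n - 2), 1)
    k_max <- sample(2:4, 1)
    mat <- structure(list(M = M, bin_size = 1, n_bins = n,
                          scaffold_ids = "s", junction_bin = b),
                     class = "hic_matrix")
    got <- separation_scores(mat, k_max)
    want <- oracle_separation(M, b, k_max)
    for (f in names(want)) expect_equal(got[[f]], want[[f]],
                                        tolerance = 1e-12)
  }
})

test_that("separation-score edge cases follow the definitions", {
  n <- 8; b <- 4
  # uniform matrix: mu_in = mu_out at every k -> S = 0 on both sides
  M <- matrix(10, n, n)
  mat <- structure(list(M = M, bin_size = 1, n_bins = n,
                        scaffold_ids = "s", junction_bin = b),
                   class = "hic_matrix")
  sc <- separation_scores(mat, 3)
  expect_equal(sc$S_upper, 0)
  expect_equal(sc$S_lower, 0)
  expect_equal(sc$R_upper, 0)  # no outer pixel is below its inner mean
  # all outer pixels zero, inner positive: S = S0 exactly and R = 1
  M2 <- matrix(0, n, n)
  for (k in 1:7) for (i in 1:(n - k)) {
    j <- i + k
    v <- if (j <= b || i > b) 5 else 0  # cross-junction pixels zeroed
    M2[i, j] <- v; M2[j, i] <- v
  }
  mat2 <- structure(list(M = M2, bin_size = 1, n_bins = n,
                         scaffold_ids = "s", junction_bin = b),
                    class = "hic_matrix")
  sc2 <- separation_scores(mat2, 3)
  expect_equal(sc2$S_upper, sc2$S_upper_0)
  expect_equal(sc2$S_lower, sc2$S_lower_0)
  expect_equal(sc2$R_upper, 1)
  expect_equal(sc2$R_lower, 1)
})

test_that("S scales quadratically under uniform matrix scaling", {
  set.seed(37)
  M <- random_symmetric_matrix(10)
  mat <- structure(list(M = M, bin_size = 1, n_bins = 10,
                        scaffold_ids = "s", junction_bin = 5),
                   class = "hic_matrix")
  s1 <- separation_scores(mat, 3)
  mat$M <- 3 * M
  s3 <- separation_scores(mat, 3)
  expect_equal(s3$S_upper, 9 * s1$S_upper)
  expect_equal(s3$S_lower, 9 * s1$S_lower)
  expect_equal(s3$R_upper, s1$R_upper)  # R is scale-free
})

test_that("per-k terms equal classical two-class between-class variance", {
  set.seed(41)
  n <- 10; b <- 5; k <- 2; k_max <- 2
  M <- random_symmetric_matrix(n)
  # isolate the k = 2 term by zeroing distance-1 pixels
  for (i in 1:(n - 1)) M[i, i + 1] <- M[i + 1, i] <- 0
  mat <- structure(list(M = M, bin_size = 1, n_bins = n,
                        scaffold_ids = "s", junction_bin = b),
                   class = "hic_matrix")
  sc <- separation_scores(mat, k_max)
  # enumerate the same pixel classes directly
  inner_u <- c(); inner_l <- c(); outer <- c()
  for (i in 0:(n - 2)) for (j in (i + 1):(n - 1)) {
    if (j - i != k) next
    if (i < b && j >= b) outer <- c(outer, M[i + 1, j + 1])
    else if (j < b && i >= b - k_max) inner_u <- c(inner_u, M[i + 1, j + 1])
    else if (i >= b && j <= b + k_max - 1) inner_l <- c(inner_l,
                                                        M[i + 1, j + 1])
  }
  # distance-1 terms are all-zero pixels: between-class variance 0, but
  # they still count pixels, so compare only to the k = 2 contribution
  expect_equal(sc$S_upper, oracle_between_class_variance(inner_u, outer))
  expect_equal(sc$S_lower, oracle_between_class_variance(inner_l, outer))
})

test_that("erroneous-edge rule combines both thresholds", {
  sc <- list(S_upper = 0.6, S_lower = 0.6, R_upper = 0.9, R_lower = 0.9,
             S_upper_0 = 1, S_lower_0 = 1)
  expect_true(is_erroneous_edge_hic(sc, 1.0, 1.6))    # 1.2 >= 1, 1.8 >= 1.6
  sc$R_upper <- 0.6
  expect_false(is_erroneous_edge_hic(sc, 1.0, 1.6))   # R sum 1.5 < 1.6
  sc$R_upper <- 0.9; sc$S_upper <- 0.2; sc$S_lower <- 0.2
  expect_false(is_erroneous_edge_hic(sc, 1.0, 1.6))   # S sum 0.4 < 1
  # zero normaliser contributes ratio 0
  sc0 <- list(S_upper = 5, S_lower = 5, R_upper = 1, R_lower = 1,
              S_upper_0 = 0, S_lower_0 = 0)
  expect_false(is_erroneous_edge_hic(sc0, 1.0, 1.6))
})

test_that("global distance profile pools pixels, not per-scaffold means", {
  mk <- function(M) structure(list(M = M, bin_size = 1, n_bins = nrow(M),
                                   scaffold_ids = "s",
                                   junction_bin = NULL),
                              class = "hic_matrix")
  # constant off-diagonals
  A <- matrix(3, 4, 4)
  mu <- global_distance_profile(list(mk(A)), 3)
  expect_equal(mu, c(3, 3, 3))
  # two matrices of different sizes: pooled mean weights by pixel count
  B <- matrix(9, 7, 7)
  mu2 <- global_distance_profile(list(mk(A), mk(B)), 2)
  expect_equal(mu2[1], (3 * 3 + 9 * 6) / 9)   # 3 pixels from A, 6 from B
  expect_equal(mu2[2], (3 * 2 + 9 * 5) / 7)
})

test_that("misassembly score vanishes on matching decay and follows the
           halved-band closed form", {
  n <- 40; k_max <- 10
  v <- 20 - (1:k_max)                  # band value at distance k
  M <- matrix(0, n, n)
  for (k in 1:k_max) for (i in 1:(n - k)) {
    M[i, i + k] <- v[k]; M[i + k, i] <- v[k]
  }
  mat <- structure(list(M = M, bin_size = 1e3, n_bins = n,
                        scaffold_ids = "s", junction_bin = NULL),
                   class = "hic_matrix")
  prof0 <- misassembly_scores(mat, mu_all = v, k_max = k_max)
  expect_true(all(abs(prof0$scores) < 1e-12))
  # band means halved relative to mu_all: Score = sum_k mu_all_k / 2
  prof1 <- misassembly_scores(mat, mu_all = 2 * v, k_max = k_max)
  expect_equal(unique(round(prof1$scores, 9)), round(sum(2 * v) / 2, 9))
})

test_that("peak detection equals the windowed local-max oracle", {
  s <- c(0, 1, 5, 1, 0, 2, 7, 2, 0)
  expect_equal(detect_peaks(s, 1L), c(2L, 6L))
  # flat profile: no peaks; monotone profile: no interior peak
  expect_equal(length(detect_peaks(rep(3, 9), 1L)), 0L)
  expect_equal(length(detect_peaks(1:9, 2L)), 0L)
  # plateau takes the leftmost bin
  expect_equal(detect_peaks(c(0, 0, 4, 4, 0, 0, 0), 1L), 2L)
  set.seed(43)
  for (rep in 1:50) {
    s <- rpois(sample(8:30, 1), 2)
    w <- sample(1:3, 1)
    expect_equal(detect_peaks(s, w), oracle_peaks(s, w))
  }
})

test_that("automatic threshold selection flags a constructed two-break
           matrix and nothing on empty profiles", {
  cfg <- scaffold_config(bin_size = 1e3, min_matrix_scaffold = 5e3)
  # three segments with no cross contacts: breaks at bins 20 and 40
  n <- 60
  M <- matrix(0, n, n)
  seg <- function(i) (i - 1) %/% 20
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (seg(i) == seg(j) && j - i <= 10) {
      M[i, j] <- M[j, i] <- max(12 - (j - i), 1)
    }
  }
  mat <- structure(list(M = M, bin_size = 1e3, n_bins = n,
                        scaffold_ids = "s", junction_bin = NULL),
                   class = "hic_matrix")
  mu <- global_distance_profile(list(mat), cfg$k_max)
  prof <- misassembly_scores(mat, mu, cfg$k_max)
  sel <- select_threshold(prof, mat, cfg)
  hit <- vapply(c(20, 40), function(b)
    any(abs(sel$flagged - b) <= 1), logical(1L))
  expect_true(all(hit))
  # no peaks above zero -> P = Inf, no candidates
  flat <- structure(list(scores = rep(0, n), mu_all = mu,
                         k_max = cfg$k_max, bin_size = 1e3, n_bins = n),
                    class = "misassembly_profile")
  sel0 <- select_threshold(flat, mat, cfg)
  expect_equal(sel0$P, Inf)
  expect_equal(length(sel0$flagged), 0L)
})
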