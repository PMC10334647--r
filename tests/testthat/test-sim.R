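# Diploid simulator: determinism, variant rates, liftover, contact decay,
# read emission, fragmentation styles.

test_that("zero heterozygosity gives identical haplotypes; seeds are
           deterministic", {
  tr0 <- sim_diploid(1, 6e4, 0, seed = 5)
  expect_identical(tr0$hap0, tr0$hap1)
  expect_equal(nrow(tr0$variants), 0L)
  a <- sim_diploid(2, 6e4, 0.01, seed = 7)
  b <- sim_diploid(2, 6e4, 0.01, seed = 7)
  expect_identical(a$hap0, b$hap0)
  expect_identical(a$hap1, b$hap1)
  expect_identical(a$variants, b$variants)
  c2 <- sim_diploid(2, 6e4, 0.01, seed = 8)
  expect_false(identical(a$hap1, c2$hap1))
})

test_that("realised variant counts match the requested rate", {
  counts <- vapply(1:5, function(s)
    nrow(sim_diploid(1, 2e5, 0.005,
                     type_probs = c(snv = 0.91, indel = 0.09, inv = 0),
                     seed = s)$variants), numeric(1L))
  # 0.005 * 2e5 = 1000 requested; small losses from footprint collisions
  expect_true(all(abs(counts - 1000) <= 50))
  # SNV share dominates as configured
  v <- sim_diploid(1, 2e5, 0.01, seed = 3)$variants
  expect_gt(mean(v$type == "snv"), 0.8)
})

test_that("liftover maps are mutually inverse outside indels", {
  tr <- sim_diploid(1, 1e5, 0.01, seed = 11)
  pos <- seq(0, tr$chrom$len0[1] - 1, by = 17)
  up <- lift_position(tr, "chr1", pos, from = 0)
  ok <- !is.na(up)
  back <- lift_position(tr, "chr1", up[ok], from = 1)
  expect_true(all(back == pos[ok]))
  # variant table SNV coordinates agree with the maps
  snv <- tr$variants[tr$variants$type == "snv", ]
  expect_equal(lift_position(tr, snv$chrom, snv$pos0, from = 0), snv$pos1)
  # SNV alleles really differ between haplotypes
  r0 <- substring(tr$hap0[["chr1"]], snv$pos0 + 1, snv$pos0 + 1)
  r1 <- substring(tr$hap1[["chr1"]], snv$pos1 + 1, snv$pos1 + 1)
  expect_true(all(r0 != r1))
  expect_identical(r0, snv$ref)
  expect_identical(r1, snv$alt)
})

test_that("inversions are reverse-complemented and lift reversed", {
  tr <- sim_diploid(1, 1e5, 0.004,
                    type_probs = c(snv = 0, indel = 0, inv = 1),
                    inv_range = c(2e3, 4e3), seed = 13)
  inv <- tr$variants[tr$variants$type == "inv", ][1, ]
  seg0 <- substr(tr$hap0[["chr1"]], inv$pos0 + 1, inv$pos0 + inv$len)
  seg1 <- substr(tr$hap1[["chr1"]], inv$pos1 + 1, inv$pos1 + inv$len)
  expect_identical(seg1, oracle_revcomp(seg0))
  # interior position maps to the mirrored offset
  mid <- inv$pos0 + 10
  expect_equal(lift_position(tr, "chr1", mid, from = 0),
               inv$pos1 + inv$len - 1 - 10)
})

test_that("Hi-C separations follow the configured power-law decay", {
  tr <- sim_diploid(1, 5e5, 0, seed = 17)
  cc <- sim_hic(tr, inter_frac = 0, trans_hap_frac = 0, n_pairs = 1e5,
                seed = 18)
  d <- abs(cc$pos_b - cc$pos_a)
  d <- d[d >= 1e3 & d < 2e5]
  h <- hist(log10(d), breaks = 30, plot = FALSE)
  # counts in equal log bins are flat for P(d) ~ 1/d; the density in d then
  # falls with slope -1. Edge bins are partial and excluded from the fit.
  dens <- h$counts / (10^h$mids)
  keep <- seq_along(dens) %in% 2:(length(dens) - 1) & h$counts > 20
  fit <- lm(log10(dens[keep]) ~ h$mids[keep])
  expect_lt(abs(unname(coef(fit)[2]) - (-1)), 0.1)
})

test_that("inter_frac and trans_hap_frac behave as labelled", {
  tr <- sim_diploid(2, 6e4, 0.01, seed = 19)
  cc0 <- sim_hic(tr, inter_frac = 0, n_pairs = 5000, seed = 20)
  expect_true(all(cc0$chrom_a == cc0$chrom_b))
  cc1 <- sim_hic(tr, inter_frac = 1, n_pairs = 5000, seed = 20)
  expect_gt(mean(cc1$chrom_a != cc1$chrom_b), 0.4)
  # trans_hap_frac 1: mate haplotype independent of the first end
  cc2 <- sim_hic(tr, trans_hap_frac = 1, inter_frac = 0, n_pairs = 20000,
                 seed = 21)
  expect_lt(abs(mean(cc2$hap_a == cc2$hap_b) - 0.5), 0.02)
  cc3 <- sim_hic(tr, trans_hap_frac = 0, inter_frac = 0, n_pairs = 5000,
                 seed = 22)
  expect_true(all(cc3$hap_a == cc3$hap_b))
})

test_that("long-read bases approximate the requested depth and reads are
           exact substrings at zero error", {
  tr <- sim_diploid(2, 6e4, 0.005, seed = 23)
  rd <- sim_long_reads(tr, coverage = 10, mean_len = 5e3,
                       emit_sequences = TRUE, error_rate = 0, seed = 24)
  total_target <- 10 * (sum(tr$chrom$len0) + sum(tr$chrom$len1))
  expect_lt(abs(sum(rd$len) - total_target) / total_target, 0.05)
  for (i in sample(nrow(rd), 10)) {
    src <- if (rd$hap[i] == 0) tr$hap0[[rd$chrom[i]]] else
      tr$hap1[[rd$chrom[i]]]
    expect_identical(rd$seq[i], substr(src, rd$start[i] + 1, rd$end[i]))
  }
  rd2 <- sim_long_reads(tr, coverage = 10, mean_len = 5e3, seed = 24)
  expect_identical(rd$start, rd2$start)
})

test_that("fragmentation styles package the truth as labelled", {
  tr <- sim_diploid(1, 1e5, 0.01, seed = 31)
  # collapse_threshold 0: fully phased pairs everywhere
  fp <- fragment_to_style(tr, "paired_haplotype", mean_fragment = 2.5e4,
                          collapse_threshold = 0, seed = 32)
  expect_true(all(!fp$fragments$collapsed))
  expect_true(all(fp$sidecar$partner_id != "-"))
  # fragments tile each haplotype without overlap
  for (h in 0:1) {
    fr <- fp$fragments[fp$fragments$hap == h, ]
    fr <- fr[order(fr$start), ]
    expect_equal(fr$start[-1], fr$end[-nrow(fr)])
    expect_equal(fr$start[1], 0)
    expect_equal(fr$end[nrow(fr)],
                 if (h == 0) tr$chrom$len0[1] else tr$chrom$len1[1])
  }
  # zero heterozygosity: one collapsed copy regardless of style
  tr0 <- sim_diploid(1, 1e5, 0, seed = 33)
  f0 <- fragment_to_style(tr0, "haplotype_ignorant", mean_fragment = 2.5e4,
                          seed = 34)
  expect_true(all(f0$fragments$collapsed))
  expect_equal(length(f0$seq), length(unique(f0$fragments$contig_id)))
  # pseudo style: primary is the longer member of each pair
  ps <- fragment_to_style(tr, "pseudo_haplotype", mean_fragment = 2.5e4,
                          collapse_threshold = 0, seed = 35)
  for (k in seq_along(ps$primary_ids)) {
    a <- ps$alternative_ids[k]
    if (is.na(a)) next
    expect_gte(nchar(ps$seq[[ps$primary_ids[k]]]), nchar(ps$seq[[a]]))
  }
})

test_that("truth PAF alignments are exact substrings at zero error", {
  b <- desk_bundle()
  paf <- b$paf
  expect_true(all(paf$qend > paf$qstart))
  expect_true(all(paf$tend <= paf$tlen))
  expect_true(all(paf$nmatch == paf$alen))
  # spot-check sequence agreement between read interval and contig interval
  frag <- b$frag; tr <- b$truth; reads <- b$reads
  set.seed(1)
  for (i in sample(nrow(paf), 5)) {
    row <- paf[i, ]
    rd <- reads[reads$read_id == row$qname, ]
    src <- if (rd$hap == 0) tr$hap0[[rd$chrom]] else tr$hap1[[rd$chrom]]
    read_seq <- substr(src, rd$start + row$qstart + 1, rd$start + row$qend)
    ctg_seq <- substr(frag$seq[[row$tname]], row$tstart + 1, row$tend)
    expect_identical(read_seq, ctg_seq)
  }
})

test_that("contact lifting to contigs preserves positions through the
           fragment table", {
  b <- desk_bundle()
  pr <- b$pairs
  fr <- b$frag$fragments
  idx <- match(pr$seq_a, fr$contig_id)
  # re-derive chromosome coordinates and compare with the truth labels
  hit <- fr[idx, ]
  joined <- merge(data.frame(read_id = pr$read_id, pos = hit$start + pr$pos_a,
                             hap = hit$hap, collapsed = hit$collapsed),
                  b$hic[, c("read_id", "pos_a", "hap_a")], by = "read_id")
  # non-collapsed contigs are haplotype-specific: the recovered chromosome
  # coordinate must match the truth label exactly
  strict <- !joined$collapsed
  expect_true(all(joined$hap[strict] == joined$hap_a[strict]))
  expect_true(all(joined$pos[strict] == joined$pos_a[strict]))
})
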