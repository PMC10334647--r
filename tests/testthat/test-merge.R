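# Haplotig merging: self-alignment, opposite assignment, mincing,
# coverage classification, consensus construction.

rand_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

mutate_seq <- function(s, rate, seed) {
  set.seed(seed)
  v <- strsplit(s, "")[[1L]]
  k <- which(runif(length(v)) < rate)
  v[k] <- vapply(v[k], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L))
  paste(v, collapse = "")
}

test_that("self-alignment keeps near-identical pairs and filters diverged
           or unrelated ones", {
  skip_if(Sys.which("minimap2") == "", "minimap2 not on PATH")
  s <- rand_seq(10000, 1)
  cs <- hapscaf:::new_contigset(
    c(a = s, b = mutate_seq(s, 0.01, 2),      # ~99% identical pair
      c = rand_seq(10000, 3),                 # unrelated
      d = mutate_seq(s, 0.28, 4)),            # far below 80% identity
    coverage = rep(NA_real_, 4), style = rep("plain", 4))
  al <- self_align_contigs(cs, scaffold_config())
  pairs <- unique(paste(pmin(al$qname, al$tname),
                        pmax(al$qname, al$tname)))
  expect_true("a b" %in% pairs)
  expect_false(any(grepl("c", pairs)))
  expect_false("a d" %in% pairs)
  expect_true(all(al$identity >= 0.8))
})

test_that("opposite assignment follows longest-alignment greedy with
           repeat removal", {
  # constructed alignment table: A-B long, A-C short, D overlaps A's claim
  cs <- hapscaf:::new_contigset(
    setNames(vapply(c(12000, 12000, 4000, 4000), function(n)
      rand_seq(n, n), character(1L)), c("A", "B", "C", "D")),
    coverage = rep(NA_real_, 4), style = rep("plain", 4))
  paf <- data.frame(
    qname = c("A", "A", "D"), qlen = c(12000, 12000, 4000),
    qstart = c(0, 8000, 0), qend = c(8000, 10000, 2000),
    strand = "+", tname = c("B", "C", "B"),
    tlen = c(12000, 4000, 12000),
    tstart = c(0, 0, 1000), tend = c(8000, 2000, 3000),
    nmatch = c(7900, 1900, 1900), alen = c(8000, 2000, 2000),
    mapq = 60, stringsAsFactors = FALSE)
  al <- self_align_contigs(cs, scaffold_config(), paf = paf)
  asg <- assign_opposites(cs, al, scaffold_config())
  # longest wins: opposite(A) = B
  expect_true(any(asg$assoc$contig == "A" & asg$assoc$opposite == "B"))
  # D's claim on B overlaps A's claim -> D removed as repeat
  expect_true("D" %in% asg$removed)
  expect_true("C" %in% asg$unpaired)
  # disjoint claim on B instead: D is paired with B's unclaimed region
  paf2 <- paf
  paf2$tstart[3] <- 9000; paf2$tend[3] <- 11000
  asg2 <- assign_opposites(cs, self_align_contigs(cs, scaffold_config(),
                                                  paf = paf2),
                           scaffold_config())
  expect_false("D" %in% asg2$removed)
  expect_true(any(asg2$assoc$contig == "D" & asg2$assoc$opposite == "B"))
})

test_that("mincing cuts at association boundaries with C / 2C coverage", {
  s <- rand_seq(10000, 7)
  o <- substr(s, 2001, 7000)
  cs <- hapscaf:::new_contigset(c(u = s, v = o),
                               coverage = rep(NA_real_, 2),
                               style = rep("plain", 2))
  paf <- data.frame(qname = "u", qlen = 10000, qstart = 2000, qend = 7000,
                    strand = "+", tname = "v", tlen = 5000, tstart = 0,
                    tend = 5000, nmatch = 5000, alen = 5000, mapq = 60,
                    stringsAsFactors = FALSE)
  cfg <- scaffold_config()
  asg <- assign_opposites(cs, self_align_contigs(cs, cfg, paf = paf), cfg)
  mt <- mince_and_tag(cs, asg, cfg)
  pieces <- mt$provenance[mt$provenance$source == "u", ]
  expect_equal(pieces$length, c(2000, 5000, 3000))
  cov <- mt$contigs$info$coverage[match(pieces$piece, mt$contigs$info$id)]
  expect_equal(cov, c(80, 40, 80))
  # the associated middle piece pairs with v (fully associated, one piece)
  mid <- pieces$piece[2]
  expect_equal(mt$contigs$info$partner[mt$contigs$info$id == mid], "v")
  expect_equal(mt$contigs$info$coverage[mt$contigs$info$id == "v"], 40)
  # conservation: pieces add up to the input contig
  expect_equal(paste0(mt$contigs$seq[pieces$piece], collapse = ""), s)
})

test_that("coverage classification of non-bubbles uses the strict
           threshold", {
  expect_equal(classify_nonbubble(40, 40, 1.75), "heterozygous_unpaired")
  expect_equal(classify_nonbubble(80, 40, 1.75), "homozygous")
  expect_equal(classify_nonbubble(70, 40, 1.75), "homozygous")  # boundary
  expect_equal(classify_nonbubble(69.999, 40, 1.75),
               "heterozygous_unpaired")
  expect_error(classify_nonbubble(40, 0), "positive")
})

test_that("array T covers every contig exactly once", {
  seqs <- c(a = rand_seq(400, 1), b = rand_seq(380, 2),
            c = rand_seq(300, 3), d = rand_seq(290, 4),
            e = rand_seq(500, 5), f = rand_seq(200, 6))
  cs <- hapscaf:::new_contigset(
    seqs, coverage = c(40, 40, 40, 40, 85, 40),
    style = c("primary_bubble", "secondary_bubble", "primary_bubble",
              "secondary_bubble", "non_bubble", "non_bubble"),
    partner = c("b", "a", "d", "c", NA, NA))
  cons <- build_consensus(cs, scaffold_config())
  expect_equal(nrow(cons$T), 4L)
  expect_setequal(cons$T$class,
                  c("het_paired", "het_paired", "homo", "het_unpaired"))
  expect_equal(cons$T$member1[cons$T$member0 == "e"], "e")
  expect_equal(cons$T$member1[cons$T$member0 == "f"], "-")
  # every contig in exactly one entry
  members <- c(cons$T$member0, setdiff(cons$T$member1, c("-")))
  expect_setequal(unique(members), names(seqs))
  # consensus sequence is the primary member's, verbatim
  expect_identical(unname(cons$seq[cons$T$id[cons$T$member0 == "a"]]),
                   unname(seqs["a"]))
  # empty input
  cons0 <- build_consensus(hapscaf:::new_contigset(
    character(0), numeric(0), character(0)), scaffold_config())
  expect_equal(nrow(cons0$T), 0L)
})

test_that("merge is idempotent on paired-haplotype input and conserves
           bases", {
  b <- desk_bundle()
  ctg <- frag_to_contigset(b$frag)
  mg <- merge_haplotigs(ctg, desk_config())
  # idempotence: no mincing, no removals; members are the input contigs
  expect_equal(mg$provenance$piece, mg$provenance$source)
  expect_equal(length(mg$removed), 0L)
  expect_setequal(c(mg$consensus$T$member0,
                    setdiff(mg$consensus$T$member1, "-")),
                  ctg$info$id)
  # conservation: all non-removed bases appear across T members
  total_in <- sum(ctg$info$length)
  mm <- mg$consensus$member_map
  expect_equal(sum(mm$length), total_in)
})

test_that("haplotype-ignorant input at 1% heterozygosity recovers the
           truth pairing", {
  skip_if(Sys.which("minimap2") == "", "minimap2 not on PATH")
  tr <- sim_diploid(1, 2e5, 0.01,
                    type_probs = c(snv = 0.91, indel = 0.09, inv = 0),
                    seed = 41)
  frag <- fragment_to_style(tr, "haplotype_ignorant",
                            mean_fragment = 4e4, collapse_threshold = 0,
                            seed = 42)
  ctg <- frag_to_contigset(frag)
  mg <- merge_haplotigs(ctg, desk_config())
  # truth pairing: fragments k of hap0 and hap1 share the stem id
  fr <- frag$fragments
  stem <- function(id) sub("_[psc]$", "", id)
  Ttab <- mg$consensus$T
  paired <- Ttab[Ttab$class == "het_paired", ]
  mm <- mg$consensus$member_map
  mlen <- setNames(mm$length, mm$member)
  src <- function(piece) sub("\\..*$", "", piece)
  good <- stem(src(paired$member0)) == stem(src(paired$member1))
  good_bases <- sum(mlen[paired$member0[good]])
  hap0_total <- sum(fr$end[fr$hap == 0] - fr$start[fr$hap == 0])
  expect_gte(good_bases / hap0_total, 0.9)
})
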