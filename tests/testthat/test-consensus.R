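test_that("family grouping partitions reads by exact key", {
  fam <- make_family(5, "ACGTACGT", umi = "AAAAAA")
  other <- make_family(2, "ACGTACGT", umi = "AAAAAT")  # one UMI mismatch
  fams <- group_families(bind_reads(fam, other))
  expect_length(fams, 2L)
  expect_setequal(vapply(fams, `[[`, integer(1), "size"), c(5L, 2L))
  # partition property
  expect_equal(sum(vapply(fams, `[[`, integer(1), "size")), 7L)
})

test_that("single-base UMI differences found distinct families", {
  r1 <- make_read(0, "ACGT", umi = "AAAAAA")
  r2 <- make_read(0, "ACGT", umi = "AAAAAC")
  fams <- group_families(bind_reads(r1, r2))
  expect_length(fams, 2L)
  expect_true(all(vapply(fams, `[[`, integer(1), "size") == 1L))
})

test_that("duplex strand rotations are not combined at step 1", {
  top <- make_read(0, "ACGTACGT", umi = "AAACCC", strand = "top")
  bot <- make_read(0, "ACGTACGT", umi = "CCCAAA", strand = "bottom")
  fams <- group_families(bind_reads(top, bot), scheme = "duplex")
  expect_length(fams, 2L)
})

test_that("reads with missing UMIs are rejected with a count", {
  r1 <- make_read(0, "ACGT", umi = "AAAAAA")
  r2 <- make_read(0, "ACGT", umi = NA_character_)
  expect_warning(fams <- group_families(bind_reads(r1, r2)), "1 read")
  expect_length(fams, 1L)
  expect_equal(attr(fams, "n_rejected"), 1L)
})

test_that("the concordance rule follows the strict 0.66 threshold", {
  # 2/3 concordance (0.667 > 0.66): predominant base, max quality among
  # the reads carrying it
  fam <- make_family(3, "A", subs = list(NULL, NULL, c(pos = 1, base = "G")),
                     qual = 30L)
  fam$qual <- c(intToUtf8(30 + 33), intToUtf8(35 + 33), intToUtf8(38 + 33))
  cons <- call_consensus(group_families(fam)[[1]])
  expect_equal(cons$seq, "A")
  expect_equal(utf8ToInt(cons$qual) - 33L, 35L)  # max among the two A reads
  expect_equal(cons$family_size, 3L)

  # 1/2 tie: N with zero quality
  fam2 <- make_family(2, "A", subs = list(NULL, c(pos = 1, base = "G")))
  cons2 <- call_consensus(group_families(fam2)[[1]])
  expect_equal(cons2$seq, "N")
  expect_equal(utf8ToInt(cons2$qual) - 33L, 0L)

  # 3/5 (0.6 <= 0.66): N
  fam3 <- make_family(5, "A", subs = list(NULL, NULL, NULL,
                                          c(pos = 1, base = "G"),
                                          c(pos = 1, base = "G")))
  cons3 <- call_consensus(group_families(fam3)[[1]])
  expect_equal(cons3$seq, "N")
  expect_error(call_consensus(structure(list(members = NULL),
                                        class = "read_family")), "empty")
})

test_that("consensus of a single read is the read itself", {
  r <- make_read(3, "ACGTN", qual = c(37L, 37L, 11L, 37L, 0L))
  cons <- call_consensus(group_families(r)[[1]])
  expect_equal(cons$seq, r$seq)
  expect_equal(cons$qual, r$qual)
  expect_equal(cons$left, r$left)
  # idempotence: collapsing the consensus again changes nothing
  cons_as_read <- make_read(3, cons$seq, qual = utf8ToInt(cons$qual) - 33L)
  again <- call_consensus(group_families(cons_as_read)[[1]])
  expect_equal(again$seq, cons$seq)
})

test_that("members of unequal span use the covering subset as denominator", {
  r1 <- make_read(0, "AAAA")          # covers 0..3
  r2 <- make_read(0, "AAAA")
  r3 <- make_read(0, "AAAAGG")        # covers 0..5 alone
  reads <- bind_reads(r1, r2, r3)
  reads$mate_start <- 10L; reads$start <- 0L  # force one family key
  fam <- group_families(reads)[[1]]
  cons <- call_consensus(fam)
  # positions 4,5 covered only by r3: 1/1 > 0.66
  expect_equal(cons$seq, "AAAAGG")
})

test_that("whole-library collapse agrees with per-family calls", {
  cfg <- tiny_config(seed = 10)
  truth <- generate_cohort(cfg)
  lib <- simulate_library(truth, 1, cfg)
  cons <- collapse_families(lib)
  expect_equal(sum(cons$family_size), nrow(lib))   # partition property
  fams <- group_families(lib)
  one_by_one <- do.call(rbind, lapply(fams, call_consensus))
  key <- function(d) paste(d$start, d$mate_start, d$umi)
  m <- match(key(cons), key(one_by_one))
  expect_false(anyNA(m))
  expect_equal(cons$seq, one_by_one$seq[m])
  expect_equal(cons$qual, one_by_one$qual[m])
  expect_equal(cons$family_size, one_by_one$family_size[m])
})

test_that("duplex step 2 collapses rotated pairs and Ns disagreements", {
  top <- make_read(0, "ACGTACGT", umi = "AAACCC", strand = "top")
  bot <- make_read(0, "ACGTACGT", umi = "CCCAAA", strand = "bottom")
  s1 <- collapse_families(bind_reads(top, bot))
  s2 <- pair_duplex_strands(s1)
  expect_equal(nrow(s2), 1L)
  expect_equal(s2$seq, "ACGTACGT")
  expect_equal(s2$duplex_step, "step2_paired")
  expect_equal(s2$family_size, 2L)
  expect_equal(attr(s2, "fraction_consensus_paired"), 1)

  # one-position disagreement between the strands becomes N
  bot2 <- make_read(0, "ACGTACTT", umi = "CCCAAA", strand = "bottom")
  s2b <- pair_duplex_strands(collapse_families(bind_reads(top, bot2)))
  expect_equal(s2b$seq, "ACGTACNT")
  expect_equal(utf8ToInt(s2b$qual)[7] - 33L, 0L)

  # unpaired reads pass through flagged step 1
  lone <- make_read(10, "ACGT", umi = "GGGTTT", strand = "top")
  s2c <- pair_duplex_strands(collapse_families(bind_reads(top, bot, lone)))
  expect_equal(nrow(s2c), 2L)
  expect_setequal(s2c$duplex_step, c("step2_paired", "step1_single_strand"))
  expect_equal(attr(s2c, "fraction_reads_paired"), 2 / 3)
})

test_that("family-size filtering keeps thresholds and identity", {
  cons <- data.frame(family_size = c(1L, 2L, 3L))
  expect_equal(filter_by_family_size(cons, 1), cons)
  expect_equal(filter_by_family_size(cons, 2)$family_size, c(2L, 3L))
  expect_error(filter_by_family_size(cons, 0))
})

test_that("first-cycle errors pass singleton consensus but duplex step 2 yields N", {
  # Build the early-error scenario: the error is present in >66% of the
  # sampled members of one strand family (over-representation of the
  # erroneous first-cycle clade), so the singleton consensus is a false
  # positive at that position.
  seq0 <- "ACGTACGTAC"
  err <- "ACGTACGTGC"  # G at position 9
  fam_top <- make_family(4, seq0, umi = "AAACCC", strand = "top",
                         subs = list(c(pos = 9, base = "G"),
                                     c(pos = 9, base = "G"),
                                     c(pos = 9, base = "G"), NULL))
  cons_top <- call_consensus(group_families(fam_top)[[1]])
  expect_equal(cons_top$seq, err)   # false positive under singleton logic

  # The complementary strand family has no error; duplex step 2 pairing
  # turns the disagreement into N.
  fam_bot <- make_family(3, seq0, umi = "CCCAAA", strand = "bottom")
  s1 <- rbind(cons_top, call_consensus(group_families(fam_bot)[[1]]))
  class(s1) <- c("consensus_reads", class(s1))
  s2 <- pair_duplex_strands(s1)
  expect_equal(nrow(s2), 1L)
  expect_equal(substr(s2$seq, 9, 9), "N")
})

test_that("consensus error for clean PCR is far below the sequencing error", {
  # with seq error e and no PCR error, consensus at family size >= 2
  # requires coincident identical errors: empirical rate << e
  e <- 0.005
  cfg <- do.call(tiny_config,
                 c(list(seed = 12, pcr_error_rate = 0, seq_error_rate = e,
                        molecules_per_sample = 150L, reads_sampled = 1500L),
                   no_truth()))
  truth <- generate_cohort(cfg)
  lib <- simulate_library(truth, 1, cfg)
  cons <- filter_by_family_size(collapse_families(lib), 2)
  rep <- estimate_error_rates(build_pileup(cons, truth$reference),
                              min_depth = 20)
  expect_gt(rep$total_quality_bases, 1e4)
  expect_lt(rep$error_rate, e / 5)
})

test_that("family-size filtering lowers stochastic error in expectation", {
  # Pure stochastic channels (no molecule-level truth): consensus at
  # family size >= 2 removes nearly all sequencing-layer error, so the
  # filtered series sits far below the unfiltered one. (Note that beyond
  # size 2 the expectation is not strictly monotone: a 2-member family
  # needs unanimity while 2-of-3 passes the 0.66 rule, so size-2 families
  # are the least permissive to clonal PCR errors.)
  rates <- matrix(NA_real_, 10, 3)
  for (s in 1:10) {
    cfg <- do.call(tiny_config, c(list(seed = 100 + s), no_truth()))
    truth <- generate_cohort(cfg)
    cons <- collapse_families(simulate_library(truth, 1, cfg))
    for (f in 1:3) {
      rep <- estimate_error_rates(
        build_pileup(filter_by_family_size(cons, f), truth$reference),
        min_depth = 20)
      rates[s, f] <- rep$error_rate
    }
  }
  m <- colMeans(rates)
  expect_lt(m[2], m[1])
  expect_lt(m[3], m[1])
})
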