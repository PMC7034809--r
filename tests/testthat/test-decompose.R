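nra_df <- function(pos, alt = "A", ref = "G", af = 0.1, depth = 200L,
                   chrom = "ref") {
  n <- max(length(pos), length(alt), length(af))
  data.frame(chrom = chrom, pos = rep_len(pos, n), ref = rep_len(ref, n),
             alt = rep_len(alt, n),
             alt_count = as.integer(round(rep_len(af, n) * depth)),
             depth = depth, af = rep_len(af, n), stringsAsFactors = FALSE)
}

test_that("CHIP detection applies the AF window and recurrence cutoff", {
  # variant below the window, variant in-window in one sample, variant
  # recurrent in 6 of 7 samples
  per_sample <- lapply(1:7, function(s) {
    x <- nra_df(pos = c(10L, 20L), af = c(0.10, 0.12))
    if (s > 6) x <- x[x$pos != 20L, ]          # pos 20 in 6 samples only
    if (s == 1) x <- rbind(x, nra_df(30L, af = 0.01))  # below window
    if (s == 2) x <- rbind(x, nra_df(40L, af = 0.25))  # singleton CHIP
    x
  })
  names(per_sample) <- as.character(1:7)
  chip <- detect_chip(per_sample, recurrence_cutoff = 6L)
  expect_false(any(chip$variants$pos == 10))   # recurrent in 7 >= 6
  expect_false(any(chip$variants$pos == 20))   # recurrent in exactly 6
  expect_false(any(chip$variants$pos == 30))   # below AF window
  expect_equal(chip$variants$pos[chip$variants$sample_id == "2"], 40L)
  expect_setequal(chip$excluded_recurrent$pos, c(10L, 20L))
  expect_error(detect_chip(per_sample, af_low = 0.3, af_high = 0.2), "af_low")
})

test_that("patterned positions respect the relatedness threshold", {
  per_sample <- lapply(1:7, function(s) {
    if (s <= 3) nra_df(c(5L, 9L)) else nra_df(9L)
  })
  expect_setequal(patterned_positions(per_sample, 3)$pos, c(5L, 9L))
  expect_equal(patterned_positions(per_sample, 4)$pos, 9L)
  expect_equal(patterned_positions(per_sample, 7)$pos, 9L)
  # k = 1: every position with any NRA
  expect_setequal(patterned_positions(per_sample, 1)$pos, c(5L, 9L))
  expect_error(patterned_positions(per_sample, 8), "relatedness_k")
})

test_that("patterned set sizes are non-increasing in relatedness k", {
  set.seed(77)
  for (rep_i in 1:5) {
    per_sample <- lapply(1:6, function(s)
      nra_df(sample(0:50, sample(5:20, 1))))
    sizes <- vapply(1:6, function(k)
      nrow(patterned_positions(per_sample, k)), integer(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("duplicate intersection matches on position and allele", {
  a <- nra_df(c(1L, 2L, 3L), alt = c("A", "C", "T"))
  b <- nra_df(c(2L, 3L, 4L), alt = c("C", "A", "T"))
  expect_equal(nrow(intersect_duplicates(a, a)), 3L)          # identity
  expect_equal(nrow(intersect_duplicates(a, nra_df(9L))), 0L) # disjoint
  got <- intersect_duplicates(a, b)
  expect_equal(got$pos, 2L)                                   # allele must match
  got_pos <- intersect_duplicates(a, b, match_on_alt = FALSE)
  expect_setequal(got_pos$pos, c(2L, 3L))
})

test_that("stochastic errors are suppressed >= 10-fold by full duplicates", {
  # truth-labelled Monte-Carlo: count surviving stochastic (PCR/sequencing)
  # NRA records before and after duplicate confirmation, pooled over seeds
  single <- 0L; confirmed <- 0L
  for (s in 1:10) {
    cfg <- do.call(tiny_config, c(list(seed = 200 + s), no_truth()))
    truth <- generate_cohort(cfg)
    cohort <- list(config = cfg, truth = truth, samples = lapply(1:3, function(k)
      list(ccf1 = simulate_library(truth, k, cfg, replicate_id = 1),
           ccf2 = simulate_library(truth, k, cfg, replicate_id = 2),
           seqdup = NULL, buffy = NULL)))
    class(cohort) <- "ccf_cohort"
    dec <- run_decomposition(cohort, corrections = "D", family_sizes = 2L,
                             min_depth = 30)
    base <- dec$reports[["2"]][["baseline"]]
    dcor <- dec$reports[["2"]][["D"]]
    single <- single + sum(vapply(base, function(r)
      nrow(ccfnoise:::centers_to_nras(r$centers)), integer(1)))
    confirmed <- confirmed + sum(vapply(dcor, function(r)
      nrow(ccfnoise:::centers_to_nras(r$centers)), integer(1)))
  }
  expect_gt(single, 50)                 # enough events to be meaningful
  expect_lt(confirmed, single / 10)
})

test_that("error reduction arithmetic and edge cases", {
  expect_equal(error_reduction(4e-4, 1e-4), 75)
  expect_equal(error_reduction(4e-4, 4e-4), 0)
  expect_equal(error_reduction(4e-4, 0), 100)
  expect_equal(error_reduction(0, 0), 0)
  expect_warning(r <- error_reduction(0, 1e-5), "undefined")
  expect_true(is.na(r))
})

test_that("substitution spectrum covers the 12 ordered types", {
  x <- nra_df(1:5, ref = "G", alt = "A")
  sp <- substitution_spectrum(x, weight = "records")
  expect_equal(sum(sp$count), 5L)
  expect_equal(sp$percent[sp$substitution_type == "G>A"], 100)
  empty <- substitution_spectrum(nra_df(integer(0))[0, ])
  expect_true(all(empty$count == 0))
  expect_equal(nrow(empty), 12L)

  # uniform substitution model: 12 bins uniform within chi-square tolerance
  set.seed(91)
  refs <- sample(c("A", "C", "G", "T"), 2400, replace = TRUE)
  alts <- vapply(refs, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  u <- data.frame(chrom = "ref", pos = seq_along(refs), ref = refs,
                  alt = alts, alt_count = 1L, depth = 100L, af = 0.01,
                  stringsAsFactors = FALSE)
  spu <- substitution_spectrum(u, weight = "records")
  expect_gt(chisq.test(spu$count)$p.value, 0.001)
})

test_that("AF bins partition the records and sum to one", {
  x <- nra_df(1:3, af = c(0.0005, 0.005, 0.05), depth = 10000L)
  b <- af_bins(x)
  expect_equal(b$count, c(1L, 1L, 1L))
  expect_equal(sum(b$fraction), 1)
  all_low <- af_bins(nra_df(1:4, af = 0.0005, depth = 10000L))
  expect_equal(all_low$fraction[1], 1)
  set.seed(12)
  rnd <- af_bins(nra_df(1:50, af = runif(50, 1e-4, 0.4), depth = 100000L))
  expect_equal(sum(rnd$fraction), 1)
})

test_that("corrections compose, commute, and never increase error", {
  cfg <- tiny_config(seed = 300)
  cohort <- simulate_cohort(cfg)
  dec <- run_decomposition(cohort, corrections = c("C", "P", "D"),
                           family_sizes = 2L, min_depth = 30,
                           recurrence_cutoff = 3L)
  base <- dec$reports[["2"]][["baseline"]][[1]]
  chip <- dec$chip; pat <- dec$patterned
  cp <- apply_corrections(base, c("C", "P"), chip = chip, patterned = pat,
                          sample_id = 1)
  pc <- apply_corrections(apply_corrections(base, "P", patterned = pat),
                          "C", chip = chip, sample_id = 1)
  expect_equal(cp$error_rate, pc$error_rate)
  expect_equal(cp$n_passing_positions, pc$n_passing_positions)

  tab <- dec$table[dec$table$family_size == 2, ]
  for (s in unique(tab$sample_id)) {
    sub <- tab[tab$sample_id == s, ]
    b0 <- sub$error_rate[sub$corrections == ""]
    expect_true(all(sub$error_rate <= b0 + 1e-12))
    # footprint shrinks only via P
    expect_true(all(sub$footprint[!grepl("P", sub$corrections)] ==
                      sub$footprint[sub$corrections == ""]))
  }
  # missing inputs are informative errors
  expect_error(apply_corrections(base, "C"), "chip_set")
  expect_error(apply_corrections(base, "P"), "patterned_set")
  expect_error(apply_corrections(base, "D"), "partner")
})

test_that("decomposition demands the libraries its corrections need", {
  cfg <- tiny_config(seed = 301)
  cohort <- simulate_cohort(cfg, buffy = FALSE)
  expect_error(run_decomposition(cohort, corrections = "C"), "buffy")
  cohort2 <- simulate_cohort(cfg, duplicates = FALSE, seq_duplicates = FALSE)
  expect_error(run_decomposition(cohort2, corrections = "D"), "ccf2")
  # baseline-only run works without them
  dec <- run_decomposition(cohort2, corrections = character(0),
                           family_sizes = 2L, min_depth = 30)
  expect_equal(unique(dec$table$corrections), "")
})
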