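test_that("cohort truth is empty when no truth channels are configured", {
  cfg <- sim_config(chip_variants = 0L, patterned_positions = 0L,
                    spike_variants = data.frame(position = integer(0),
                                                af = numeric(0)),
                    seed = 11)
  truth <- generate_cohort(cfg)
  expect_equal(nchar(truth$reference), cfg$reference_length)
  expect_true(all(strsplit(truth$reference, "")[[1]] %in% c("A", "C", "G", "T")))
  expect_equal(nrow(truth$chip_set), 0L)
  expect_equal(nrow(truth$patterned_set), 0L)
  expect_equal(nrow(truth$spike_set), 0L)
})

test_that("cohort truth is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 42)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- sim_config(seed = 43)
  expect_false(identical(generate_cohort(cfg), generate_cohort(cfg2)))
})

test_that("degenerate Bernoulli hit probability affects every sample", {
  cfg <- sim_config(patterned_positions = 50L, patterned_hit_prob = 1,
                    n_samples = 7L, seed = 5)
  truth <- generate_cohort(cfg)
  tab <- table(truth$patterned_set$position)
  expect_equal(length(tab), 50L)
  expect_true(all(tab == 7L))
})

test_that("truth validation rejects bad configurations", {
  expect_error(sim_config(chip_af_range = c(0.01, 0.3)), "0.02")
  expect_error(sim_config(pcr_cycles = 0), "pcr_cycles")
  expect_error(sim_config(adapter_scheme = "duplex", umi_length = 8), "umi_length")
  expect_error(sim_config(spike_variants = data.frame(position = 5000L, af = 0.1)),
               "reference")
  expect_error(sim_config(pcr_efficiency = 1.2), "rates")
})

test_that("error-free PCR at full efficiency doubles both strands each cycle", {
  set.seed(1)
  frag <- random_ref(40, 2)
  pool <- simulate_pcr(frag, "singleton", cycles = 3, efficiency = 1,
                       error_rate = 0)
  expect_equal(nrow(pool), 2 * 2^3)
  expect_true(all(pool$sequence == frag))
  expect_equal(sort(unique(pool$lineage)), c("bottom", "top"))
  # two lineages, two independent UMI families
  expect_equal(length(unique(pool$umi)), 2L)
  expect_equal(unname(table(pool$lineage)["top"]), 8L)
})

test_that("duplex UMIs of the two lineages are mutual rotations", {
  set.seed(2)
  pool <- simulate_pcr(random_ref(30, 3), "duplex", cycles = 2,
                       efficiency = 1, error_rate = 0)
  u_top <- unique(pool$umi[pool$lineage == "top"])
  u_bot <- unique(pool$umi[pool$lineage == "bottom"])
  expect_equal(nchar(u_top), 6L)
  expect_equal(rotate_umi(u_top), u_bot)
})

test_that("a forced first-cycle error propagates to exactly half its lineage", {
  frag <- random_ref(50, 4)
  for (cyc in c(3, 5)) {
    set.seed(cyc)
    pool <- simulate_pcr(frag, "singleton", cycles = cyc, efficiency = 1,
                         error_rate = 0,
                         inject = list(strand = "top", pos = 10L, offset = 1L))
    top <- pool[pool$lineage == "top", ]
    carriers <- vapply(top$muts, function(m) nrow(m) > 0, logical(1))
    # descendants of the first copy are half of the 2^cyc top amplicons
    expect_equal(sum(carriers), 2^(cyc - 1))
    expect_equal(sum(carriers) / nrow(top), 0.5)
    expect_true(all(vapply(top$muts[carriers], function(m) all(m$first),
                           logical(1))))
    # the bottom lineage is untouched
    expect_true(all(vapply(pool$muts[pool$lineage == "bottom"], nrow,
                           integer(1)) == 0))
  }
})

test_that("branching process matches its expected pool size", {
  # E[pool] = 2 * (1 + efficiency)^cycles per molecule
  set.seed(99)
  sizes <- replicate(600, nrow(simulate_pcr("ACGTACGTAC", "singleton",
                                            cycles = 8, efficiency = 0.5,
                                            error_rate = 0)))
  expected <- 2 * 1.5^8
  expect_lt(abs(mean(sizes) - expected) / expected, 0.05)
})

test_that("PCR input validation", {
  expect_error(simulate_pcr("", "singleton", 3, 1, 0.01), "zero-length")
  expect_error(simulate_pcr("ACGT", "singleton", 0, 1, 0), "cycles")
})

test_that("a clean library measures exactly zero error end to end", {
  cfg <- do.call(tiny_config,
                 c(list(seed = 3, pcr_error_rate = 0, seq_error_rate = 0,
                        q_low = 0), no_truth()))
  truth <- generate_cohort(cfg)
  lib <- simulate_library(truth, 1, cfg)
  cons <- collapse_families(lib)
  rep <- estimate_error_rates(build_pileup(cons, truth$reference),
                              min_depth = 20)
  expect_gt(rep$total_quality_bases, 0)
  expect_equal(rep$total_nra_observations, 0)
  expect_equal(rep$error_rate, 0)
})

test_that("spiked variant carrier fraction is binomially consistent", {
  cfg <- sim_config(molecules_per_sample = 2000L, reads_sampled = 3000L,
                    chip_variants = 0L, patterned_positions = 0L,
                    spike_variants = data.frame(position = 500L, af = 0.10,
                                                sample_id = 1L),
                    seed = 8)
  truth <- generate_cohort(cfg)
  lib <- simulate_library(truth, 1, cfg)
  mols <- attr(lib, "molecules")
  covering <- sum(mols$starts <= 500 & 500 < mols$starts + cfg$fragment_length)
  carriers <- length(unique(mols$variants$mol[mols$variants$pos == 500]))
  ci <- qnorm(0.995) * sqrt(0.1 * 0.9 / covering)
  expect_lt(abs(carriers / covering - 0.10), ci)
})

test_that("sequencing duplicates share the PCR pool but not the read sample", {
  cfg <- tiny_config(seed = 4)
  truth <- generate_cohort(cfg)
  rep1 <- simulate_library(truth, 1, cfg, replicate_id = 1)
  sdup <- simulate_library(truth, 1, cfg, replicate_id = 3,
                           mode = "seq_duplicate", duplicate_of = 1)
  # same pool: identical molecule starts and variant assignments
  expect_identical(attr(rep1, "molecules")$starts, attr(sdup, "molecules")$starts)
  expect_identical(attr(rep1, "molecules")$variants,
                   attr(sdup, "molecules")$variants)
  # different sampled read sets
  expect_false(identical(rep1$seq, sdup$seq))
  # full duplicate draws fresh molecules
  rep2 <- simulate_library(truth, 1, cfg, replicate_id = 2)
  expect_false(identical(attr(rep1, "molecules")$starts,
                         attr(rep2, "molecules")$starts))
})

test_that("reads exceeding the amplicon pool is an informative error", {
  cfg <- tiny_config(seed = 5)
  cfg$reads_sampled <- 10000000L
  truth <- generate_cohort(cfg)
  expect_error(simulate_library(truth, 1, cfg), "short by")
})

test_that("every read descends from exactly one molecule with full provenance", {
  cfg <- tiny_config(seed = 6)
  truth <- generate_cohort(cfg)
  lib <- simulate_library(truth, 2, cfg)
  expect_true(all(lib$mol >= 1 & lib$mol <= cfg$molecules_per_sample))
  starts <- attr(lib, "molecules")$starts
  expect_true(all(lib$left == starts[lib$mol]))
  # truth tags sit inside the read span
  for (i in sample(nrow(lib), 50)) {
    tags <- lib$truth_tags[[i]]
    if (!length(tags)) next
    pos <- as.integer(sub(".*@", "", tags))
    expect_true(all(pos >= lib$left[i] & pos < lib$left[i] + nchar(lib$seq[i])))
  }
})

test_that("UMI read errors inflate the family count", {
  cfg0 <- tiny_config(seed = 7)
  cfg1 <- tiny_config(seed = 7, umi_error_rate = 0.02)
  truth0 <- generate_cohort(cfg0)
  truth1 <- generate_cohort(cfg1)
  n0 <- nrow(collapse_families(simulate_library(truth0, 1, cfg0)))
  n1 <- nrow(collapse_families(simulate_library(truth1, 1, cfg1)))
  expect_gt(n1, n0)
})

test_that("UDI simulation conserves reads and respects hop_rate = 0", {
  u0 <- simulate_udi_counts(4, 1000, 0, seed = 1)
  expect_true(all(u0$counts[upper.tri(u0$counts) | lower.tri(u0$counts)] == 0))
  expect_equal(sum(u0$counts), 4000)
  for (s in 1:3) {
    u <- simulate_udi_counts(5, 2000, 0.03, seed = s)
    expect_equal(sum(u$counts) + u$undetermined, 5 * 2000)
  }
  expect_error(simulate_udi_counts(1, 100, 0.01), "2 samples")
  expect_error(simulate_udi_counts(4, 100, 1), "hop_rate")
})
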