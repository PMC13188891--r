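test_that("pooled counts have binomial structure around the pool frequency", {
  map <- tiny_map()
  pop <- make_backcross("BC1_female_informative", map, 500, tiny_causal,
                        seed = 21)
  # error-free sequencing of a pool fixed for the susceptible allele
  fixed_s <- subset_pop <- apply_selection(pop, selection_by_r2(1, 0),
                                           seed = 22)
  counts <- simulate_pool_counts(fixed_s, mean_depth = 200, error_rate = 0,
                                 seed = 23)
  expect_true(all(counts$depth_R == 0))

  expect_error(simulate_pool_counts(
    make_backcross("BC1_female_informative", map, 0, tiny_causal)),
    "empty")
  expect_error(simulate_pool_counts(pop, mean_depth = 0), "mean_depth")
  expect_error(simulate_pool_counts(pop, error_rate = 0.6), "error_rate")
})

test_that("error-free sequencing is unbiased for the true pool frequency", {
  map <- scan_map(n_chrom = 2, markers = 100)
  causal <- list(chrom = "chr1", pos = map$markers$pos[5])
  pop <- make_backcross("BC1_female_informative", map, 300, causal, seed = 31)
  f_true <- (colSums(pop$hap_m) + colSums(pop$hap_p)) /
    (2 * n_individuals(pop))
  counts <- simulate_pool_counts(pop, mean_depth = 10000, error_rate = 0,
                                 seed = 32)
  # each marker's AF within 4 binomial SEs of its true pool frequency
  se <- sqrt(pmax(f_true * (1 - f_true), 1e-12) / 10000)
  dev <- abs(counts$af - f_true)
  expect_true(all(dev <= 4 * se + 1e-9))
})

test_that("unselected BC1 pool allele frequencies center on 0.25", {
  map <- scan_map(n_chrom = 4, markers = 60)
  causal <- list(chrom = "chr3", pos = map$markers$pos[
    which(map$markers$chrom == "chr3")[30]])
  pop <- make_backcross("BC1_female_informative", map, 2000, causal,
                        seed = 41)
  counts <- simulate_pool_counts(pop, mean_depth = 1000, error_rate = 0.001,
                                 seed = 42)
  expect_equal(mean(counts$af), 0.25, tolerance = 0.03 / 0.25)
})

test_that("amplicon pools behave like deep targeted sequencing", {
  map <- tiny_map()
  amps <- tibble::tibble(chrom = "chr1", pos = c(5e5, 1e6))
  pop <- make_backcross("BC2_male_informative", map, 400, tiny_causal,
                        seed = 51)
  clean <- simulate_amplicon_counts(pop, amps, mean_reads = 38000,
                                    nonspecific_prob = 0, seed = 52)
  # without contamination the control-pool AF sits in a band around 0.25
  expect_true(all(abs(clean$af - 0.25) < 0.1))
  expect_true(all(clean$depth_R + clean$depth_S > 500))
  expect_false(any(clean$contaminated))

  # forced contamination with a fixed susceptible allele drags AF below the
  # nonspecific-amplification QC band: f_obs ~ (1-u) * 0.25 with u >= 0.3
  dirty <- simulate_amplicon_counts(pop, amps, mean_reads = 38000,
                                    nonspecific_prob = 1,
                                    contaminant_allele = "S", seed = 53)
  expect_true(all(dirty$contaminated))
  expect_true(all(dirty$af < 0.25 * 0.7 + 0.02))
})

test_that("contamination mixture arithmetic matches direct computation", {
  # off-target fraction 0.9 of fixed susceptible allele on a 0.25-AF pool:
  # observed frequency 0.1 * 0.25 = 0.025, below the 0.125 QC bound
  f <- 0.25; u <- 0.9
  f_obs <- (1 - u) * f + u * 0
  expect_equal(f_obs, 0.025)
  expect_lt(f_obs, 0.125)
})

test_that("expression generator reproduces null and perturbed ratios", {
  counts <- simulate_expression_counts(rep(1000, 10), fold_changes = 1,
                                       dispersion = 0.05,
                                       n_reps_per_strain = 6, seed = 61)
  res <- expression_screen(counts, "susceptible", "resistant",
                           totals = stats::setNames(rep(1e6, 12),
                                                    unique(counts$sample_id)))
  expect_true(all(abs(res$ratio_pct - 100) < 40))

  # tiny replicate number and huge dispersion must not crash
  rough <- simulate_expression_counts(c(50, 5000), fold_changes = c(1, 0.5),
                                      dispersion = 5, n_reps_per_strain = 2,
                                      seed = 62)
  expect_s3_class(suppressWarnings(expression_screen(rough)), "tbl_df")

  expect_error(simulate_expression_counts(c(-1, 10)), "positive")
  expect_error(simulate_expression_counts(10, dispersion = 0), "dispersion")
  expect_error(simulate_expression_counts(10, n_reps_per_strain = 1), "reps")
})
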