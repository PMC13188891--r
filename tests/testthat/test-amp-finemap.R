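mk_record <- function(id, pos, sel_r, sel_s, ctrl_r, ctrl_s,
                      chrom = "chr9") {
  tibble::tibble(amplicon_id = id, chrom = chrom, snp_pos = pos,
                 sel_depth_R = sel_r, sel_depth_S = sel_s,
                 ctrl_depth_R = ctrl_r, ctrl_depth_S = ctrl_s,
                 sel_af = sel_r / (sel_r + sel_s),
                 ctrl_af = ctrl_r / (ctrl_r + ctrl_s),
                 delta_af = sel_r / (sel_r + sel_s) -
                   ctrl_r / (ctrl_r + ctrl_s))
}

test_that("amplicon QC removes shallow and nonspecific amplicons", {
  recs <- dplyr::bind_rows(
    mk_record(1, 100, 500, 500, 50, 950),    # ctrl AF 0.05 -> nonspecific
    mk_record(2, 200, 500, 500, 200, 800),   # ctrl AF 0.20 -> keep
    mk_record(3, 300, 500, 500, 400, 600),   # ctrl AF 0.40 -> keep
    mk_record(4, 400, 500, 500, 600, 400),   # ctrl AF 0.60 -> nonspecific
    mk_record(5, 500, 500, 500, 120, 280)    # ctrl AF 0.30, 400 reads -> shallow
  )
  kept <- qc_amplicons(recs)
  expect_equal(kept$amplicon_id, c(2, 3))
  expect_equal(qc_amplicons(kept), kept)  # idempotent
  # boundaries are retained: AF exactly 0.125 and 0.5 pass
  edge <- dplyr::bind_rows(mk_record(1, 100, 500, 500, 125, 875),
                           mk_record(2, 200, 500, 500, 500, 500))
  expect_equal(nrow(qc_amplicons(edge)), 2)
  # a uniformly clean panel is untouched
  clean <- mk_record(1:10, (1:10) * 100, 19000, 19000, 9500, 28500)
  expect_equal(nrow(qc_amplicons(clean)), 10)
})

test_that("delta_af keeps its sign convention", {
  expect_equal(delta_af(0.50, 0.25), 0.25)
  expect_equal(delta_af(0.30, 0.30), 0)
  expect_equal(delta_af(0.20, 0.30), -0.10)
  expect_error(delta_af(NA_real_, 0.3), "undefined")
})

test_that("the one-sided z-test matches the exact two-binomial oracle", {
  # strong enrichment: p far below 1e-6
  r1 <- mk_record(1, 100, 500, 500, 250, 750)
  t1 <- test_markers(r1)
  expect_lt(t1$p_raw, 1e-6)
  expect_equal(t1$z, 11.547, tolerance = 1e-3)

  # identical counts: one-sided p at the null center
  t2 <- test_markers(mk_record(1, 100, 250, 750, 250, 750))
  expect_equal(t2$p_raw, 0.5, tolerance = 1e-6)

  # shift in the wrong direction: p > 0.5
  t3 <- test_markers(mk_record(1, 100, 200, 800, 250, 750))
  expect_gt(t3$p_raw, 0.5)

  # oracle agreement within 10% relative error for p in ~[1e-4, 0.5]
  cases <- list(c(290, 1000, 250, 1000), c(300, 1000, 250, 1000),
                c(320, 1000, 250, 1000), c(160, 500, 125, 500),
                c(275, 1000, 250, 1000), c(255, 1000, 250, 1000),
                c(700, 2000, 600, 2000), c(520, 2000, 500, 2000))
  for (cs in cases) {
    rec <- mk_record(1, 100, cs[1], cs[2] - cs[1], cs[3], cs[4] - cs[3])
    p_z <- test_markers(rec)$p_raw
    p_exact <- exact_two_binomial_p(cs[1], cs[2], cs[3], cs[4])
    expect_lt(abs(p_z - p_exact) / p_exact, 0.10)
  }
})

test_that("interval calling reproduces the printed boundary arithmetic", {
  pos <- c(1270927, 1767453, 2000000, 2442587, 3000000)
  sig <- c(FALSE, TRUE, TRUE, TRUE, FALSE)
  results <- tibble::tibble(
    amplicon_id = 1:5, chrom = "chr9", snp_pos = pos,
    delta_af = ifelse(sig, 0.25, 0.01),
    p_adjusted = ifelse(sig, 1e-8, 0.8)
  )
  iv <- call_interval(results)
  expect_equal(iv$start, 1767453)
  expect_equal(iv$end, 2442587)
  expect_equal(iv$width_bp, 675134)
  expect_equal(iv$width_kb_display, 675L)
  expect_equal(iv$amplicon_ids, 2:4)
  expect_equal(tidy(iv)$width_kb_display, 675L)

  # no significant marker -> no interval
  none <- dplyr::mutate(results, p_adjusted = 1)
  expect_null(call_interval(none))

  # a single significant marker -> zero-width interval
  one <- dplyr::mutate(results, p_adjusted = ifelse(pos == 2000000, 1e-8, 1))
  iv1 <- call_interval(one)
  expect_equal(iv1$start, iv1$end)
  expect_equal(iv1$width_bp, 0)

  # significance requires the effect-size floor too
  deep_only <- dplyr::mutate(results, delta_af = 0.05)
  expect_null(call_interval(deep_only))

  expect_error(call_interval(results[c(2, 1, 3:5), ]), "sorted")
  expect_error(call_interval(dplyr::mutate(results, chrom = c(
    "chr9", "chr9", "chr8", "chr9", "chr9"))), "single chromosome")
})

test_that("isolated significant markers are reported, not spliced out", {
  results <- tibble::tibble(
    amplicon_id = 1:6, chrom = "chr9", snp_pos = (1:6) * 1e5,
    delta_af = c(0.3, 0.3, 0.01, 0.01, 0.01, 0.3),
    p_adjusted = c(1e-8, 1e-8, 1, 1, 1, 1e-8)
  )
  iv <- call_interval(results)
  expect_equal(c(iv$start, iv$end), c(1e5, 6e5))
  expect_equal(iv$isolated, 6L)
})

test_that("fine mapping recovers the causal position at panel geometry", {
  map <- build_genome_map(1, 12.5e6, 50, marker_spacing = 12.5e6,
                          labels = "chr9")
  amps <- tni_chr9_amplicons()
  causal <- list(chrom = "chr9", pos = 2.1e6)
  map <- add_markers(map, dplyr::bind_rows(
    tibble::tibble(chrom = "chr9", pos = 2.1e6), amps[, c("chrom", "pos")]))
  model <- selection_by_r2(0, 1)
  set.seed(101)
  hits <- logical(40)
  for (i in seq_len(40)) {
    pop <- make_backcross("BC2_male_informative", map, 506, causal)
    surv <- apply_selection(pop, model)
    rec <- amplicon_records(
      simulate_amplicon_counts(surv, amps, pool_size = 253),
      simulate_amplicon_counts(pop, amps, pool_size = 257))
    iv <- amp_finemap(rec)$interval
    hits[i] <- !is.null(iv) && iv$start <= 2.1e6 && iv$end >= 2.1e6
  }
  expect_gte(mean(hits), 0.95)
})

test_that("expected allele-frequency change decays with distance from the locus", {
  map <- build_genome_map(1, 12.5e6, 50, marker_spacing = 12.5e6,
                          labels = "chr9")
  amps <- tni_chr9_amplicons()[seq(1, 48, by = 4), ]  # 12 spread amplicons
  causal <- list(chrom = "chr9", pos = 2.1e6)
  map <- add_markers(map, dplyr::bind_rows(
    tibble::tibble(chrom = "chr9", pos = 2.1e6), amps[, c("chrom", "pos")]))
  model <- selection_by_r2(0, 1)
  j <- vapply(seq_len(nrow(amps)), function(i) {
    biphasr:::marker_index(map, amps$chrom[i], amps$pos[i])
  }, integer(1))
  set.seed(102)
  acc <- matrix(0, nrow = 250, ncol = length(j))
  for (i in seq_len(250)) {
    pop <- make_backcross("BC2_male_informative", map, 200, causal)
    surv <- apply_selection(pop, model)
    # expected delta-AF from the true pool frequencies (no sequencing noise)
    f_sel <- (colSums(surv$hap_m[, j, drop = FALSE]) +
                colSums(surv$hap_p[, j, drop = FALSE])) /
      (2 * n_individuals(surv))
    f_all <- (colSums(pop$hap_m[, j, drop = FALSE]) +
                colSums(pop$hap_p[, j, drop = FALSE])) /
      (2 * n_individuals(pop))
    acc[i, ] <- f_sel - f_all
  }
  mean_delta <- colMeans(acc)
  dist <- abs(amps$pos - causal$pos)
  expect_equal(which.max(mean_delta), which.min(dist))
  # non-increasing with distance, up to Monte-Carlo wobble
  ord <- order(dist)
  expect_true(all(diff(mean_delta[ord]) <= 0.02))
})
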