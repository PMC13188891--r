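test_that("a fully homozygous parent transmits its only haplotype", {
  map <- scan_map()
  for (sex in c("female", "male")) {
    parent <- bc_individual(map, maternal = 1, paternal = 1, sex = sex)
    g <- simulate_gamete(parent, seed = 7)
    expect_equal(g, rep(1L, n_markers(map)))
  }
})

test_that("female meiosis is achiasmatic: intact chromosomes only", {
  map <- scan_map(n_chrom = 6, markers = 40)
  parent <- bc_individual(map, maternal = 1, paternal = 0, sex = "female")
  set.seed(11)
  for (i in 1:50) {
    g <- simulate_gamete(parent)
    per_chrom <- split(g, map$markers$chrom)
    # each chromosome is all-resistant or all-susceptible, never mixed
    expect_true(all(vapply(per_chrom, function(x) length(unique(x)) == 1L,
                           logical(1))))
  }
})

test_that("achiasmy holds across a whole BC1 population", {
  map <- scan_map(n_chrom = 5, markers = 30)
  pop <- make_backcross("BC1_female_informative", map, 400,
                        causal = list(chrom = "chr2", pos = map$markers$pos[
                          which(map$markers$chrom == "chr2")[10]]),
                        seed = 3)
  chrom_of <- map$markers$chrom
  recombinant <- apply(pop$hap_m, 1, function(h) {
    any(vapply(split(h, chrom_of), function(x) length(unique(x)) > 1L,
               logical(1)))
  })
  expect_equal(sum(recombinant), 0)
})

test_that("male crossover count follows the Poisson genetic-map mean", {
  map <- build_genome_map(1, 1e6, 50, marker_spacing = 1e3)  # dense markers
  parent <- bc_individual(map, maternal = 1, paternal = 0, sex = "male")
  set.seed(5)
  n <- 10000
  gam <- biphasr:::gametes_recombinant(parent$maternal, parent$paternal,
                                       map, n)
  # observed allele switches along the chromosome lower-bound the crossover
  # count; with 1-kb marker spacing virtually every crossover is observed
  switches <- rowSums(abs(gam[, -1, drop = FALSE] -
                            gam[, -ncol(gam), drop = FALSE]))
  expect_equal(mean(switches), 0.5, tolerance = 3 * sqrt(0.5 / n) / 0.5)
})

test_that("backcross genotype ratios and R1 background match the designs", {
  map <- tiny_map()
  pop <- make_backcross("BC1_female_informative", map, 10000, tiny_causal,
                        seed = 2)
  frac_ss <- mean(r2_genotypes(pop) == "S2S2")
  expect_equal(frac_ss, 0.5, tolerance = 4 * 0.5 / sqrt(10000) / 0.5)
  expect_true(all(pop$r1 == "R1R1"))
  expect_true(all(r2_genotypes(pop) %in% c("S2S2", "S2R2")))

  dom <- make_backcross("dominance_backcross", map, 10000, tiny_causal,
                        seed = 4)
  expect_true(all(r2_genotypes(dom) %in% c("S2R2", "R2R2")))
  expect_equal(mean(dom$r1 == "R1S1"), 0.5, tolerance = 0.02)

  empty <- make_backcross("BC2_male_informative", map, 0, tiny_causal)
  expect_equal(n_individuals(empty), 0)
  expect_error(make_backcross("BC1_female_informative", map, -1, tiny_causal),
               "count")
})

test_that("unselected segregation rejects the 1:1 null at the nominal rate", {
  map <- tiny_map()
  set.seed(9)
  n <- 200
  pvals <- replicate(400, {
    pop <- make_backcross("BC1_female_informative", map, n, tiny_causal)
    k <- sum(r2_genotypes(pop) == "S2R2")
    chi_square_1to1(k, n - k)$p_value
  })
  rate <- mean(pvals < 0.05)
  # binomial band around 0.05 over 400 replicates (discreteness widens it)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.10)
})

test_that("selection retains genotypes according to the survival model", {
  map <- tiny_map()
  pop <- make_backcross("BC1_female_informative", map, 2000, tiny_causal,
                        seed = 12)
  # deterministic survival: only heterozygotes survive
  surv <- apply_selection(pop, selection_by_r2(0, 1), seed = 13)
  expect_true(all(r2_genotypes(surv) == "S2R2"))
  expect_true(surv$selected)

  # all-ones model is the identity on membership
  all_live <- apply_selection(pop, selection_by_r2(1, 1, 1), seed = 14)
  expect_equal(n_individuals(all_live), n_individuals(pop))
  expect_equal(all_live$hap_m, pop$hap_m)

  # recessive model on a dominance backcross: no heterozygous survivors
  dom <- make_backcross("dominance_backcross", map, 2000, tiny_causal,
                        seed = 15)
  surv2 <- apply_selection(dom, selection_by_r2(0, 0, 1), seed = 16)
  expect_equal(sum(r2_genotypes(surv2) == "S2R2"), 0)

  # model must cover every genotype present
  partial <- selection_model(data.frame(r1 = "R1R1", r2 = "S2S2", w = 1))
  expect_error(apply_selection(pop, partial), "lacks survival")
})
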