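#' Run the full biphasic mapping workflow on simulated data
#'
#' End-to-end demonstration of the two-phase design on synthetic data, with
#' every stage of the package exercised:
#'
#' 1. *Phase 1 (chromosome assignment)* — simulate a female-informative
#'    backcross (BC1), select with toxin (susceptible R2 homozygotes die),
#'    sequence selected and control pools, and run the KDE peak-shift scan.
#' 2. *Phase 2 (fine mapping)* — simulate a male-informative backcross
#'    (BC2), amplicon-sequence selected and control pools on the called
#'    chromosome, and call the candidate interval.
#' 3. *Dominance* — simulate backcrosses to the resistant strain under two
#'    genetic backgrounds with different heterozygote survival, genotype the
#'    survivors by diagnostic-PCR fragment sizes, and estimate h.
#' 4. *Expression* — simulate a locus-sized gene panel with one
#'    down-regulated and one up-regulated gene and run the RPKM screen.
#'
#' @param seed Integer seed controlling all randomness.
#' @param n_chromosomes Number of anchored chromosomes in the scaled-down
#'   genome (default 9 so the causal chromosome keeps its usual label;
#'   `chr0` is appended).
#' @param markers_per_chromosome Approximate marker count per chromosome.
#' @param n_bc1 BC1 offspring before selection (default 320).
#' @param bc1_pools Pool sizes (selected, control) for BSA-seq
#'   (default 160, 86).
#' @param n_bc2 BC2 offspring before selection (default 506).
#' @param bc2_pools Pool sizes (selected, control) for Amp-seq
#'   (default 253, 257).
#' @param depth BSA-seq mean depth per marker.
#' @param amplicon_reads Mean reads per amplicon.
#' @param n_dominance Dominance-backcross offspring per background.
#' @param w_het Named survival probabilities of the heterozygous R2 genotype
#'   under the two backgrounds.
#' @return A list of class `biphasr_report` with elements `params`,
#'   `linkage`, `finemap`, `dominance`, `expression`.
#' @export
run_biphasic_demo <- function(seed = 1,
                              n_chromosomes = 9,
                              markers_per_chromosome = 80,
                              n_bc1 = 320, bc1_pools = c(160, 86),
                              n_bc2 = 506, bc2_pools = c(253, 257),
                              depth = 1000, amplicon_reads = 38000,
                              n_dominance = 500,
                              w_het = c(cornell = 0.2, benzon = 0.9)) {
  seed <- as.integer(seed)
  map <- tni_genome_map(marker_spacing = 11e6 %/% markers_per_chromosome,
                        n_chromosomes = n_chromosomes)
  causal <- list(chrom = "chr9", pos = 2.1e6)
  amps <- tni_chr9_amplicons()
  map <- add_markers(map, dplyr::bind_rows(
    tibble::tibble(chrom = causal$chrom, pos = causal$pos),
    amps[, c("chrom", "pos")]
  ))
  complete_sel <- selection_by_r2(w_s2s2 = 0, w_s2r2 = 1, w_r2r2 = 1,
                                  dose_label = "2 ug/cm2")

  # Phase 1: chromosome-level scan on the female-informative backcross
  bc1 <- make_backcross("BC1_female_informative", map, n_bc1, causal,
                        seed = seed)
  bc1_sel <- apply_selection(bc1, complete_sel, seed = seed + 1L)
  sel_pool <- simulate_pool_counts(bc1_sel, mean_depth = depth,
                                   pool_size = bc1_pools[1],
                                   seed = seed + 2L)
  ctrl_pool <- simulate_pool_counts(bc1, mean_depth = depth,
                                    pool_size = bc1_pools[2],
                                    seed = seed + 3L)
  scan <- bsa_scan(sel_pool, ctrl_pool)

  # Phase 2: amplicon fine mapping on the male-informative backcross
  bc2 <- make_backcross("BC2_male_informative", map, n_bc2, causal,
                        seed = seed + 4L)
  bc2_sel <- apply_selection(bc2, complete_sel, seed = seed + 5L)
  amp_sel <- simulate_amplicon_counts(bc2_sel, amps,
                                      mean_reads = amplicon_reads,
                                      pool_size = bc2_pools[1],
                                      seed = seed + 6L)
  amp_ctrl <- simulate_amplicon_counts(bc2, amps,
                                       mean_reads = amplicon_reads,
                                       pool_size = bc2_pools[2],
                                       seed = seed + 7L)
  fm <- amp_finemap(amplicon_records(amp_sel, amp_ctrl))

  # Dominance under two genetic backgrounds
  dom <- purrr::imap(w_het, function(w, bg) {
    pop <- make_backcross("dominance_backcross", map, n_dominance, causal,
                          seed = seed + 8L + match(bg, names(w_het)))
    model <- selection_model(
      tidyr::expand_grid(r1 = c("R1R1", "R1S1"),
                         r2 = c("S2S2", "S2R2", "R2R2")) |>
        dplyr::mutate(w = dplyr::case_when(
          r2 == "R2R2" ~ 1, r2 == "S2R2" ~ w, TRUE ~ 0)),
      dose_label = "7 ug/cm2", background_label = bg)
    surv <- apply_selection(pop, model, seed = seed + 20L)
    geno <- simulate_fragment_profiles(surv, "APN1")$genotype
    counts <- count_genotypes(geno, family = bg,
                              selection_dose = "250 ug/mL")
    dominance_table(counts)
  })

  # Expression screen: 37-gene locus panel, 25 genes midgut-expressed, one
  # strongly down- and one strongly up-regulated. Totals are fixed at a
  # genome-wide scale (1e7 mapped reads/sample) so the RPKM cutoff is
  # meaningful for a locus-restricted table.
  base_means <- c(5000, 800, rep(c(300, 5000, 900, 20000, 50),
                                 length.out = 23), rep(1, 12))
  folds <- c(0.016, 13.249, rep(1, 35))
  counts <- simulate_expression_counts(
    base_means, folds, gene_lengths = rep(c(1500, 2500), length.out = 37),
    dispersion = 0.05, n_reps_per_strain = 6,
    strains = c("susceptible", "resistant"), seed = seed + 30L)
  totals <- stats::setNames(rep(1e7, 12), unique(counts$sample_id))
  screen <- expression_screen(counts, "susceptible", "resistant",
                              totals = totals)

  report <- list(
    params = list(seed = seed, n_bc1 = n_bc1, n_bc2 = n_bc2, depth = depth,
                  amplicon_reads = amplicon_reads,
                  causal = paste0(causal$chrom, ":", causal$pos)),
    linkage = list(called_chrom = scan$called_chrom,
                   shifts = scan$shifts[, c("chrom", "peak_selected",
                                            "peak_control", "shift")]),
    finemap = if (is.null(fm$interval)) NULL else tidy(fm$interval),
    dominance = dplyr::bind_rows(dom),
    expression = list(
      n_expressed = nrow(detect_expressed(screen)),
      candidates = flag_candidates(screen)[, c("gene_id", "ratio_pct",
                                               "p_value")]
    )
  )
  structure(report, class = c("biphasr_report", "list"))
}

#' @export
print.biphasr_report <- function(x, ...) {
  cat("== Biphasic mapping demo (seed ", x$params$seed, ") ==\n", sep = "")
  cat("Phase 1 linkage call: ", x$linkage$called_chrom,
      " (true causal marker ", x$params$causal, ")\n", sep = "")
  if (!is.null(x$finemap)) {
    cat("Phase 2 interval: ", x$finemap$chrom, ":", x$finemap$start, "-",
        x$finemap$end, " (", x$finemap$width_kb_display, " kb)\n", sep = "")
  } else {
    cat("Phase 2: no interval called\n")
  }
  cat("Dominance h by background:\n")
  print(as.data.frame(x$dominance[, c("family", "n_hom_R", "n_het",
                                      "p_value", "h_display")]))
  cat("Expression: ", x$expression$n_expressed, " genes expressed, ",
      nrow(x$expression$candidates), " candidate(s): ",
      paste(x$expression$candidates$gene_id, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
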