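#' Simulate pooled whole-genome allele counts (BSA-seq stand-in)
#'
#' Models pooled Illumina sequencing of a bulk of larvae. For each marker the
#' true pool frequency of the resistant-strain allele is
#' `f = (# resistant alleles) / (2 * pool size)`; site depth is Poisson with
#' mean `mean_depth`, and the resistant-allele depth is Binomial with success
#' probability `f * (1 - e) + (1 - f) * e` where `e` is the per-read
#' substitution rate (symmetric allele flip).
#'
#' @param pop A `bc_population` (nonempty).
#' @param mean_depth Mean site depth in reads (> 0).
#' @param error_rate Per-read allele-flip probability in `[0, 0.5)`.
#' @param pool_size Optional: sequence a random subsample of this many
#'   individuals (defaults to the whole population).
#' @param seed Optional integer seed.
#' @return A tibble with columns `chrom`, `pos`, `depth_R`, `depth_S`, `af`
#'   (`af` is `NA` where total depth is zero).
#' @export
simulate_pool_counts <- function(pop, mean_depth = 1000, error_rate = 0.001,
                                 pool_size = NULL, seed = NULL) {
  stopifnot(inherits(pop, "bc_population"))
  if (n_individuals(pop) == 0L) {
    stop("cannot sequence an empty population", call. = FALSE)
  }
  if (mean_depth <= 0) stop("`mean_depth` must be > 0", call. = FALSE)
  if (error_rate < 0 || error_rate >= 0.5) {
    stop("`error_rate` must be in [0, 0.5)", call. = FALSE)
  }
  set_seed_if(seed)
  if (!is.null(pool_size)) {
    pool_size <- min(pool_size, n_individuals(pop))
    keep <- sample.int(n_individuals(pop), pool_size)
    pop <- subset_population(pop, keep)
  }
  n <- n_individuals(pop)
  f <- (colSums(pop$hap_m) + colSums(pop$hap_p)) / (2 * n)
  p <- f * (1 - error_rate) + (1 - f) * error_rate
  m <- length(f)
  depth <- stats::rpois(m, mean_depth)
  depth_r <- stats::rbinom(m, depth, p)
  tibble::tibble(
    chrom = pop$map$markers$chrom,
    pos = pop$map$markers$pos,
    depth_R = depth_r,
    depth_S = depth - depth_r,
    af = ifelse(depth > 0, depth_r / depth, NA_real_)
  )
}

#' Simulate amplicon-sequencing counts for one pool
#'
#' Deep sequencing of targeted PCR amplicons, each carrying one diagnostic
#' SNP. Read totals per amplicon are lognormal around `mean_reads`
#' (`sdlog = sigma`). With probability `nonspecific_prob` an amplicon suffers
#' nonspecific amplification: a fraction `u ~ Uniform(0.3, 0.9)` of its reads
#' derives from an off-target template fixed for one allele, distorting the
#' observed allele frequency (this is what the control-pool AF filter of
#' [qc_amplicons()] is designed to catch).
#'
#' @param pop A `bc_population`.
#' @param amplicons Data frame with columns `chrom`, `pos` (and optionally
#'   `amplicon_id`); every position must be a marker of the population's map.
#' @param mean_reads Mean reads per amplicon (default 38,000, the scale of a
#'   NextSeq amplicon pool).
#' @param sigma Lognormal sdlog of the per-amplicon read total.
#' @param nonspecific_prob Probability that an amplicon is contaminated.
#' @param contaminant_allele Allele carried by the off-target template:
#'   `"S"`, `"R"`, or `"random"` (per amplicon).
#' @param error_rate Per-read allele-flip probability.
#' @param pool_size Optional subsample size.
#' @param seed Optional integer seed.
#' @return A tibble with `amplicon_id`, `chrom`, `pos`, `depth_R`, `depth_S`,
#'   `af`, `contaminated`.
#' @export
simulate_amplicon_counts <- function(pop, amplicons, mean_reads = 38000,
                                     sigma = 0.4, nonspecific_prob = 0,
                                     contaminant_allele = c("S", "R", "random"),
                                     error_rate = 0.001, pool_size = NULL,
                                     seed = NULL) {
  stopifnot(inherits(pop, "bc_population"))
  contaminant_allele <- match.arg(contaminant_allele)
  if (n_individuals(pop) == 0L) {
    stop("cannot sequence an empty population", call. = FALSE)
  }
  set_seed_if(seed)
  amplicons <- tibble::as_tibble(amplicons)
  if (!"amplicon_id" %in% names(amplicons)) {
    amplicons$amplicon_id <- seq_len(nrow(amplicons))
  }
  if (!is.null(pool_size)) {
    pool_size <- min(pool_size, n_individuals(pop))
    keep <- sample.int(n_individuals(pop), pool_size)
    pop <- subset_population(pop, keep)
  }
  n <- n_individuals(pop)
  j <- vapply(seq_len(nrow(amplicons)), function(i) {
    marker_index(pop$map, amplicons$chrom[i], amplicons$pos[i])
  }, integer(1))
  f <- (colSums(pop$hap_m[, j, drop = FALSE]) +
          colSums(pop$hap_p[, j, drop = FALSE])) / (2 * n)
  k <- nrow(amplicons)
  reads <- pmax(1L, as.integer(round(stats::rlnorm(
    k, meanlog = log(mean_reads) - sigma^2 / 2, sdlog = sigma))))
  contaminated <- stats::runif(k) < nonspecific_prob
  u <- stats::runif(k, 0.3, 0.9)
  fixed <- switch(contaminant_allele,
                  S = rep(0, k),
                  R = rep(1, k),
                  random = stats::rbinom(k, 1, 0.5))
  p_true <- ifelse(contaminated, (1 - u) * f + u * fixed, f)
  p <- p_true * (1 - error_rate) + (1 - p_true) * error_rate
  depth_r <- stats::rbinom(k, reads, p)
  tibble::tibble(
    amplicon_id = amplicons$amplicon_id,
    chrom = amplicons$chrom,
    pos = amplicons$pos,
    depth_R = depth_r,
    depth_S = reads - depth_r,
    af = depth_r / reads,
    contaminated = contaminated
  )
}

#' Pair selected- and control-pool amplicon counts into one record table
#'
#' @param selected,control Tibbles from [simulate_amplicon_counts()] (or read
#'   from disk) for the Cry1Ac-selected and unselected pools of the same
#'   amplicon panel.
#' @return A tibble of amplicon records: `amplicon_id`, `chrom`, `snp_pos`,
#'   `sel_depth_R`, `sel_depth_S`, `ctrl_depth_R`, `ctrl_depth_S`, `sel_af`,
#'   `ctrl_af`, `delta_af`.
#' @export
amplicon_records <- function(selected, control) {
  sel <- dplyr::select(tibble::as_tibble(selected), "amplicon_id", "chrom",
                       snp_pos = "pos", sel_depth_R = "depth_R",
                       sel_depth_S = "depth_S")
  ctl <- dplyr::select(tibble::as_tibble(control), "amplicon_id",
                       ctrl_depth_R = "depth_R", ctrl_depth_S = "depth_S")
  out <- dplyr::inner_join(sel, ctl, by = "amplicon_id")
  if (nrow(out) != nrow(sel)) {
    stop("selected and control pools cover different amplicons", call. = FALSE)
  }
  out$sel_af <- with(out, ifelse(sel_depth_R + sel_depth_S > 0,
                                 sel_depth_R / (sel_depth_R + sel_depth_S),
                                 NA_real_))
  out$ctrl_af <- with(out, ifelse(ctrl_depth_R + ctrl_depth_S > 0,
                                  ctrl_depth_R / (ctrl_depth_R + ctrl_depth_S),
                                  NA_real_))
  out$delta_af <- out$sel_af - out$ctrl_af
  out
}

#' Simulate negative-binomial expression counts for two strains
#'
#' Emulates midgut RNA-seq of a susceptible and a resistant strain: counts
#' for gene g, strain 2 are negative binomial with mean
#' `base_means[g] * fold_changes[g]` and dispersion `dispersion`
#' (`size = 1 / dispersion`); strain 1 uses `base_means[g]`.
#'
#' @param base_means Positive per-gene mean counts in strain 1.
#' @param fold_changes Per-gene fold change of strain 2 relative to strain 1
#'   (recycled).
#' @param gene_lengths Gene lengths in bp (recycled).
#' @param dispersion Negative-binomial dispersion (> 0).
#' @param n_reps_per_strain Biological replicates per strain (>= 2).
#' @param strains Labels of (strain 1, strain 2).
#' @param gene_ids Optional gene identifiers.
#' @param seed Optional integer seed.
#' @return A long tibble: `gene_id`, `length_bp`, `sample_id`, `strain`,
#'   `count`.
#' @export
simulate_expression_counts <- function(base_means, fold_changes = 1,
                                       gene_lengths = 1500,
                                       dispersion = 0.05,
                                       n_reps_per_strain = 6,
                                       strains = c("susceptible", "resistant"),
                                       gene_ids = NULL, seed = NULL) {
  if (any(!is.finite(base_means)) || any(base_means <= 0)) {
    stop("`base_means` must be positive", call. = FALSE)
  }
  if (dispersion <= 0) stop("`dispersion` must be > 0", call. = FALSE)
  if (n_reps_per_strain < 2) {
    stop("`n_reps_per_strain` must be >= 2", call. = FALSE)
  }
  stopifnot(length(strains) == 2L)
  set_seed_if(seed)
  n_genes <- length(base_means)
  fold_changes <- rep_len(fold_changes, n_genes)
  gene_lengths <- rep_len(gene_lengths, n_genes)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%02d", seq_len(n_genes))
  size <- 1 / dispersion

  grid <- tidyr::expand_grid(
    gene_i = seq_len(n_genes),
    strain = strains,
    rep = seq_len(n_reps_per_strain)
  )
  mu <- ifelse(grid$strain == strains[2],
               base_means[grid$gene_i] * fold_changes[grid$gene_i],
               base_means[grid$gene_i])
  tibble::tibble(
    gene_id = gene_ids[grid$gene_i],
    length_bp = gene_lengths[grid$gene_i],
    sample_id = paste0(grid$strain, "_", grid$rep),
    strain = grid$strain,
    count = stats::rnbinom(nrow(grid), mu = mu, size = size)
  )
}
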