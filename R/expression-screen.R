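#' RPKM normalization
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `1e9 * count / (gene_length * total_mapped)`. Vectorized.
#'
#' @param count Aligned read count(s) for the gene.
#' @param gene_length Transcript length in bp (> 0).
#' @param total_mapped Total mapped reads of the sample (> 0).
#' @return Numeric RPKM value(s).
#' @export
rpkm <- function(count, gene_length, total_mapped) {
  if (any(gene_length <= 0)) stop("`gene_length` must be > 0", call. = FALSE)
  if (any(total_mapped <= 0)) stop("`total_mapped` must be > 0", call. = FALSE)
  if (any(count < 0)) stop("`count` must be >= 0", call. = FALSE)
  1e9 * count / (gene_length * total_mapped)
}

#' Add per-sample RPKM to a long count table
#'
#' @param counts Long tibble with columns `gene_id`, `length_bp`,
#'   `sample_id`, `strain`, `count` (as from
#'   [simulate_expression_counts()] or [read_expression_counts()]).
#' @param totals Optional named vector of per-sample total mapped reads; by
#'   default the per-sample column sums of the table are used (appropriate
#'   for locus-restricted toy tables; supply genome-wide totals when
#'   available).
#' @return The table with an `rpkm` column appended.
#' @export
add_rpkm <- function(counts, totals = NULL) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("gene_id", "length_bp", "sample_id", "count") %in%
                  names(counts)))
  if (is.null(totals)) {
    totals_tbl <- counts |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(total_mapped = sum(.data$count), .groups = "drop")
    if (any(totals_tbl$total_mapped == 0)) {
      warning("sample(s) with zero mapped reads; their RPKM is set to 0",
              call. = FALSE)
      totals_tbl$total_mapped <- pmax(totals_tbl$total_mapped, 1)
    }
  } else {
    totals_tbl <- tibble::tibble(sample_id = names(totals),
                                 total_mapped = unname(totals))
  }
  counts |>
    dplyr::left_join(totals_tbl, by = "sample_id") |>
    dplyr::mutate(rpkm = rpkm(.data$count, .data$length_bp,
                              .data$total_mapped)) |>
    dplyr::select(-"total_mapped")
}

welch_p <- function(x, y) {
  out <- tryCatch(stats::t.test(x, y)$p.value, error = function(e) NA_real_)
  out
}

#' Per-gene strain comparison of midgut expression
#'
#' For each gene: mean RPKM per strain, the strain-2/strain-1 expression
#' ratio in percent, and a Welch two-sample t-test on the per-replicate RPKM
#' values. The `expressed` flag marks genes whose mean RPKM reaches `cutoff`
#' in at least one strain (inclusive boundary); the `candidate` flag marks
#' expressed genes whose between-strain difference is at least `fold`-fold
#' (in either direction) with `p_value <= alpha` (per-gene rule; no
#' multiplicity correction — an optional BH column is appended for
#' reference).
#'
#' @param counts Long count tibble (see [add_rpkm()]).
#' @param strain1,strain2 Strain labels: the reference (susceptible) and
#'   comparison (resistant) strain. Defaults are the first two labels in the
#'   table, in order of appearance.
#' @param cutoff Expressed-gene mean-RPKM cutoff (default 0.5).
#' @param fold Candidate fold-change threshold (default 3).
#' @param alpha Candidate per-gene significance level (default 0.01).
#' @param totals Optional per-sample totals, see [add_rpkm()].
#' @return A tibble with one row per gene: `gene_id`, `mean_rpkm_1`,
#'   `mean_rpkm_2`, `ratio_pct` (`100 * mean_2 / mean_1`), `p_value`,
#'   `p_bh`, `expressed`, `candidate`.
#' @export
expression_screen <- function(counts, strain1 = NULL, strain2 = NULL,
                              cutoff = 0.5, fold = 3, alpha = 0.01,
                              totals = NULL) {
  counts <- add_rpkm(counts, totals = totals)
  strains <- unique(counts$strain)
  if (is.null(strain1)) strain1 <- strains[1]
  if (is.null(strain2)) strain2 <- setdiff(strains, strain1)[1]
  stopifnot(strain1 %in% strains, strain2 %in% strains)
  reps <- counts |>
    dplyr::filter(.data$strain %in% c(strain1, strain2)) |>
    dplyr::count(.data$strain, .data$sample_id)
  if (any(table(reps$strain) < 2)) {
    stop("need >= 2 replicates per strain", call. = FALSE)
  }
  out <- counts |>
    dplyr::filter(.data$strain %in% c(strain1, strain2)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      mean_rpkm_1 = mean(.data$rpkm[.data$strain == strain1]),
      mean_rpkm_2 = mean(.data$rpkm[.data$strain == strain2]),
      p_value = welch_p(.data$rpkm[.data$strain == strain1],
                        .data$rpkm[.data$strain == strain2]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ratio_pct = dplyr::if_else(.data$mean_rpkm_1 > 0,
                                 100 * .data$mean_rpkm_2 / .data$mean_rpkm_1,
                                 NA_real_),
      p_bh = stats::p.adjust(.data$p_value, method = "BH"),
      expressed = .data$mean_rpkm_1 >= cutoff | .data$mean_rpkm_2 >= cutoff
    )
  out$candidate <- flag_rule(out$ratio_pct, out$p_value, fold, alpha) &
    out$expressed
  dplyr::select(out, "gene_id", "mean_rpkm_1", "mean_rpkm_2", "ratio_pct",
                "p_value", "p_bh", "expressed", "candidate")
}

flag_rule <- function(ratio_pct, p_value, fold, alpha) {
  !is.na(ratio_pct) & !is.na(p_value) &
    (ratio_pct <= 100 / fold | ratio_pct >= 100 * fold) &
    p_value <= alpha
}

#' Genes expressed in the midgut
#'
#' Subset of screen results with mean RPKM at or above the cutoff in at
#' least one strain.
#'
#' @param results Tibble from [expression_screen()].
#' @param cutoff Mean-RPKM cutoff (default 0.5, inclusive).
#' @return The expressed subset.
#' @export
detect_expressed <- function(results, cutoff = 0.5) {
  results <- tibble::as_tibble(results)
  dplyr::filter(results, .data$mean_rpkm_1 >= cutoff |
                  .data$mean_rpkm_2 >= cutoff)
}

#' Candidate genes by the fold-change / significance rule
#'
#' Genes whose expression differs by at least `fold`-fold between strains
#' (ratio at most `100/fold`% or at least `100*fold`%) with a per-gene
#' p-value at most `alpha`.
#'
#' @param results Tibble from [expression_screen()].
#' @param fold Fold-change threshold (default 3).
#' @param alpha Per-gene significance level (default 0.01).
#' @return The flagged subset.
#' @export
flag_candidates <- function(results, fold = 3, alpha = 0.01) {
  results <- tibble::as_tibble(results)
  results[flag_rule(results$ratio_pct, results$p_value, fold, alpha), ]
}

#' Strain expression ratio and t-test for one gene
#'
#' Single-gene view of [expression_screen()].
#'
#' @param counts Long count tibble.
#' @param gene A `gene_id` present in the table.
#' @inheritParams expression_screen
#' @return One-row tibble as in [expression_screen()].
#' @export
strain_ratio_test <- function(counts, gene, strain1 = NULL, strain2 = NULL,
                              cutoff = 0.5, fold = 3, alpha = 0.01,
                              totals = NULL) {
  counts <- tibble::as_tibble(counts)
  if (!gene %in% counts$gene_id) {
    stop("gene ", gene, " not in the count table", call. = FALSE)
  }
  res <- expression_screen(counts, strain1, strain2, cutoff, fold, alpha,
                           totals = totals)
  res <- res[res$gene_id == gene, ]
  if (res$mean_rpkm_1 == 0) {
    stop("expression ratio undefined: reference-strain mean RPKM is zero",
         call. = FALSE)
  }
  res
}
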