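#' QC-filter amplicon records
#'
#' Two reliability filters before fine mapping:
#' * read depth: both pools must have at least `min_reads` total reads at the
#'   amplicon (shallow amplicons are unreliable);
#' * control-pool AF: in an unselected backcross pool the resistant allele is
#'   expected at 0.25, so a control AF outside `[ctrl_lower, ctrl_upper]`
#'   (default `[0.125, 0.5]`, boundaries retained) indicates nonspecific PCR
#'   amplification and the amplicon is excluded.
#'
#' Order-preserving and idempotent.
#'
#' @param records Amplicon record tibble (see [amplicon_records()]).
#' @param min_reads Minimum total reads per pool (default 500).
#' @param ctrl_lower,ctrl_upper Control-pool AF retention band.
#' @return The retained records.
#' @export
qc_amplicons <- function(records, min_reads = 500, ctrl_lower = 0.125,
                         ctrl_upper = 0.5) {
  stopifnot(ctrl_lower < ctrl_upper, ctrl_lower >= 0, ctrl_upper <= 1)
  records <- tibble::as_tibble(records)
  dplyr::filter(
    records,
    .data$sel_depth_R + .data$sel_depth_S >= min_reads,
    .data$ctrl_depth_R + .data$ctrl_depth_S >= min_reads,
    !is.na(.data$ctrl_af),
    .data$ctrl_af >= ctrl_lower,
    .data$ctrl_af <= ctrl_upper
  )
}

#' Allele-frequency change under selection
#'
#' `delta_af = sel_af - ctrl_af`: the change of the resistant-allele
#' frequency between the toxin-selected and the unselected pool. Positive at
#' markers linked to the selected locus.
#'
#' @param sel_af,ctrl_af Allele frequencies (vectorized).
#' @return Signed frequency differences in `[-1, 1]`.
#' @export
delta_af <- function(sel_af, ctrl_af) {
  if (any(is.na(sel_af) | is.na(ctrl_af))) {
    stop("delta_af undefined where an allele frequency is undefined",
         call. = FALSE)
  }
  sel_af - ctrl_af
}

# one-sided two-proportion z-test (pooled variance), alternative p1 > p2
prop_z_test <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- ifelse(se > 0, (p1 - p2) / se, 0)
  list(z = z, p = stats::pnorm(z, lower.tail = FALSE))
}

#' Test markers for selection-increased allele frequency
#'
#' One-sided two-proportion z-test per amplicon (pooled-variance normal
#' approximation; the pooled depths are in the tens of thousands, so the
#' approximation is accurate): alternative is selected-pool AF greater than
#' control-pool AF. Raw p-values are Benjamini-Hochberg adjusted across the
#' supplied records.
#'
#' @param records QC-passed amplicon records.
#' @param adjust Multiplicity adjustment method for [stats::p.adjust()]
#'   (default `"BH"`).
#' @return The records with columns `delta_af` (recomputed), `z`, `p_raw`,
#'   `p_adjusted` appended.
#' @export
test_markers <- function(records, adjust = "BH") {
  records <- tibble::as_tibble(records)
  n1 <- records$sel_depth_R + records$sel_depth_S
  n2 <- records$ctrl_depth_R + records$ctrl_depth_S
  if (any(n1 == 0 | n2 == 0)) {
    stop("zero total depth; run qc_amplicons() first", call. = FALSE)
  }
  zt <- prop_z_test(records$sel_depth_R, n1, records$ctrl_depth_R, n2)
  records$delta_af <- delta_af(records$sel_depth_R / n1,
                               records$ctrl_depth_R / n2)
  records$z <- zt$z
  records$p_raw <- zt$p
  records$p_adjusted <- stats::p.adjust(zt$p, method = adjust)
  records
}

#' Call the candidate interval from marker tests
#'
#' A marker is significant when its adjusted p-value is at most `alpha` and
#' its allele-frequency increase is at least `min_delta` (the effect-size
#' floor prevents significance by depth alone). The candidate interval spans
#' the outermost significant SNP positions on the chromosome; a single
#' significant marker yields a zero-width interval, no significant marker
#' yields `NULL`. Significant markers not adjacent (in marker order) to
#' another significant marker are echoed in an `isolated` attribute as a
#' warning list rather than excluded.
#'
#' @param results Output of [test_markers()] for a single chromosome, sorted
#'   by `snp_pos`.
#' @param alpha Significance level on the adjusted p-value (default 0.01).
#' @param min_delta Minimum `delta_af` (default 0.1).
#' @return An object of class `mapped_interval` (or `NULL`): list with
#'   `chrom`, `start`, `end`, `width_bp`, `width_kb_display` (integer kb,
#'   `round(width_bp / 1000)`), `amplicon_ids`, `isolated`.
#' @export
call_interval <- function(results, alpha = 0.01, min_delta = 0.1) {
  results <- tibble::as_tibble(results)
  stopifnot(all(c("chrom", "snp_pos", "delta_af", "p_adjusted") %in%
                  names(results)))
  if (length(unique(results$chrom)) > 1L) {
    stop("interval calling expects markers from a single chromosome",
         call. = FALSE)
  }
  if (is.unsorted(results$snp_pos, strictly = TRUE)) {
    stop("marker results must be sorted by position", call. = FALSE)
  }
  sig <- results$p_adjusted <= alpha & results$delta_af >= min_delta
  if (!any(sig)) return(NULL)
  idx <- which(sig)
  runs <- cumsum(c(1L, diff(idx) > 1L))
  isolated <- if (length(idx) > 1L) {
    idx[runs %in% which(tabulate(runs) == 1L)]
  } else {
    integer(0)
  }
  pos <- results$snp_pos[idx]
  structure(list(
    chrom = results$chrom[1],
    start = min(pos),
    end = max(pos),
    width_bp = max(pos) - min(pos),
    width_kb_display = as.integer(round((max(pos) - min(pos)) / 1000)),
    amplicon_ids = results$amplicon_id[idx],
    isolated = results$amplicon_id[isolated]
  ), class = "mapped_interval")
}

#' @export
print.mapped_interval <- function(x, ...) {
  cat("<mapped_interval> ", x$chrom, ":",
      format(x$start, big.mark = ","), "-", format(x$end, big.mark = ","),
      " (", x$width_kb_display, " kb, ", length(x$amplicon_ids),
      " significant markers)\n", sep = "")
  if (length(x$isolated)) {
    cat("  warning: isolated significant marker(s): ",
        paste(x$isolated, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.mapped_interval <- function(x, ...) {
  tibble::tibble(
    chrom = x$chrom, start = x$start, end = x$end,
    width_bp = x$width_bp, width_kb_display = x$width_kb_display,
    n_markers = length(x$amplicon_ids)
  )
}

#' Run the whole amplicon fine-mapping stage
#'
#' Chains [qc_amplicons()], [test_markers()] and [call_interval()].
#'
#' @param records Amplicon record tibble.
#' @inheritParams qc_amplicons
#' @inheritParams test_markers
#' @inheritParams call_interval
#' @return A list with `results` (per-marker test tibble) and `interval`
#'   (a `mapped_interval` or `NULL`).
#' @export
amp_finemap <- function(records, min_reads = 500, ctrl_lower = 0.125,
                        ctrl_upper = 0.5, alpha = 0.01, min_delta = 0.1,
                        adjust = "BH") {
  kept <- qc_amplicons(records, min_reads, ctrl_lower, ctrl_upper)
  if (nrow(kept) == 0L) {
    return(list(results = kept, interval = NULL))
  }
  tested <- test_markers(dplyr::arrange(kept, .data$snp_pos), adjust = adjust)
  list(results = tested,
       interval = call_interval(tested, alpha = alpha, min_delta = min_delta))
}
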