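#' Plot per-chromosome allele-frequency density profiles
#'
#' Faceted KDE curves of the selected and control pools per chromosome — the
#' visual form of the linkage scan.
#'
#' @param scan A `linkage_call` from [bsa_scan()] / [call_linkage_group()].
#' @return A ggplot object.
#' @export
plot_kde_profiles <- function(scan) {
  stopifnot(inherits(scan, "linkage_call"))
  unnest_profiles <- function(profiles, pool) {
    profiles |>
      dplyr::select("chrom", "profile") |>
      tidyr::unnest("profile") |>
      dplyr::mutate(pool = pool)
  }
  df <- dplyr::bind_rows(
    unnest_profiles(scan$selected_profiles, "selected"),
    unnest_profiles(scan$control_profiles, "control")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$af, y = .data$density,
                                   colour = .data$pool)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chrom) +
    ggplot2::labs(x = "allele frequency (resistant-strain allele)",
                  y = "density",
                  title = paste0("KDE linkage scan",
                                 if (!is.na(scan$called_chrom))
                                   paste0(" - called: ", scan$called_chrom))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.linkage_call <- function(object, ...) plot_kde_profiles(object)

#' Plot allele-frequency change along the fine-mapped chromosome
#'
#' Per-amplicon `delta_af` against SNP position, with significant markers
#' highlighted and the called interval shaded.
#'
#' @param results Per-marker tibble from [test_markers()] /
#'   [amp_finemap()].
#' @param interval Optional `mapped_interval` to shade.
#' @param alpha,min_delta Significance rule used for highlighting (defaults
#'   as in [call_interval()]).
#' @return A ggplot object.
#' @export
plot_delta_af <- function(results, interval = NULL, alpha = 0.01,
                          min_delta = 0.1) {
  results <- tibble::as_tibble(results)
  results$significant <- results$p_adjusted <= alpha &
    results$delta_af >= min_delta
  p <- ggplot2::ggplot(results,
                       ggplot2::aes(x = .data$snp_pos / 1e6,
                                    y = .data$delta_af,
                                    colour = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red3")) +
    ggplot2::labs(x = "position (Mb)",
                  y = expression(Delta * "AF (selected - control)")) +
    ggplot2::theme_minimal()
  if (!is.null(interval)) {
    p <- p + ggplot2::annotate("rect", xmin = interval$start / 1e6,
                               xmax = interval$end / 1e6,
                               ymin = -Inf, ymax = Inf,
                               alpha = 0.15, fill = "red3")
  }
  p
}

#' Plot the expression screen
#'
#' Mean RPKM per strain for each gene (log10 scale), candidates highlighted.
#'
#' @param results Tibble from [expression_screen()].
#' @return A ggplot object.
#' @export
plot_expression_screen <- function(results) {
  df <- tibble::as_tibble(results) |>
    tidyr::pivot_longer(c("mean_rpkm_1", "mean_rpkm_2"),
                        names_to = "strain", values_to = "mean_rpkm")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_id, y = .data$mean_rpkm,
                                   fill = .data$strain)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "mean RPKM") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
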