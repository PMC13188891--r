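#' Pooled allele frequency
#'
#' Frequency of the resistant-strain-derived allele among the reads covering
#' a marker, `depth_R / (depth_R + depth_S)`. Vectorized.
#'
#' @param depth_R,depth_S Nonnegative read depths.
#' @return Numeric vector of allele frequencies in `[0, 1]`.
#' @export
compute_af <- function(depth_R, depth_S) {
  if (any(depth_R < 0 | depth_S < 0)) {
    stop("depths must be nonnegative", call. = FALSE)
  }
  total <- depth_R + depth_S
  if (any(total == 0)) {
    stop("allele frequency undefined at zero total depth", call. = FALSE)
  }
  depth_R / total
}

#' Filter SNPs by allele frequency
#'
#' Removes near-fixed SNPs, which are uninformative for a segregating
#' backcross: records with `af < lower` or `af > upper` are dropped
#' (boundaries retained). Records with undefined (`NA`) AF are also dropped.
#' Order-preserving and idempotent.
#'
#' @param records Tibble with an `af` column (e.g. from
#'   [simulate_pool_counts()] or [read_allele_depths()]).
#' @param lower,upper Retention band, `0 <= lower < upper <= 1`
#'   (defaults 0.05 / 0.95).
#' @return The retained records.
#' @export
filter_af <- function(records, lower = 0.05, upper = 0.95) {
  stopifnot(lower >= 0, upper <= 1, lower < upper)
  records <- tibble::as_tibble(records)
  dplyr::filter(records, !is.na(.data$af),
                .data$af >= lower, .data$af <= upper)
}

#' Kernel density profile of allele frequencies
#'
#' Gaussian-kernel density estimate of a set of per-SNP allele frequencies,
#' evaluated on a fixed grid over `[0, 1]`. The peak is the grid point of
#' maximum density (ties broken toward the lowest AF).
#'
#' @param afs Numeric vector of allele frequencies (>= 2 finite values).
#' @param bandwidth Either a bandwidth selection method understood by
#'   [stats::density()] (default `"nrd0"`, Silverman's rule) or a numeric
#'   bandwidth.
#' @param grid_step Grid resolution on `[0, 1]` (default 0.005).
#' @param jitter_if_degenerate If the input has zero variance the Silverman
#'   bandwidth is undefined; by default this errors, with `TRUE` a tiny
#'   jitter (sd `1e-6`) is added instead.
#' @return A list of class `kde_profile`: `grid`, `density`, `peak_af`,
#'   `n_snps`, `bw`.
#' @export
kde_profile <- function(afs, bandwidth = "nrd0", grid_step = 0.005,
                        jitter_if_degenerate = FALSE) {
  afs <- afs[is.finite(afs)]
  if (length(afs) < 2L) {
    stop("need at least 2 finite allele frequencies for a density profile",
         call. = FALSE)
  }
  if (stats::sd(afs) == 0 && !is.numeric(bandwidth)) {
    if (!jitter_if_degenerate) {
      stop("allele frequencies have zero variance; supply a numeric ",
           "bandwidth or set `jitter_if_degenerate = TRUE`", call. = FALSE)
    }
    afs <- afs + stats::rnorm(length(afs), sd = 1e-6)
  }
  n_grid <- round(1 / grid_step) + 1L
  d <- stats::density(afs, bw = bandwidth, kernel = "gaussian",
                      from = 0, to = 1, n = n_grid)
  peak <- d$x[which.max(d$y)]
  structure(list(grid = d$x, density = d$y, peak_af = peak,
                 n_snps = length(afs), bw = d$bw),
            class = "kde_profile")
}

#' @export
print.kde_profile <- function(x, ...) {
  cat("<kde_profile> n_snps = ", x$n_snps, ", bw = ", signif(x$bw, 3),
      ", peak_af = ", x$peak_af, "\n", sep = "")
  invisible(x)
}

#' Per-chromosome KDE profiles of a pool
#'
#' Applies [kde_profile()] to each chromosome's allele frequencies.
#'
#' @param records Tibble with columns `chrom` and `af`.
#' @inheritParams kde_profile
#' @return A tibble with one row per chromosome: `chrom`, `n_snps`, `bw`,
#'   `peak_af`, and a `profile` list-column of `(af, density)` tibbles.
#' @export
kde_profiles <- function(records, bandwidth = "nrd0", grid_step = 0.005,
                         jitter_if_degenerate = FALSE) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("chrom", "af") %in% names(records)))
  records |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(prof = list(kde_profile(
      .data$af, bandwidth = bandwidth, grid_step = grid_step,
      jitter_if_degenerate = jitter_if_degenerate)), .groups = "drop") |>
    dplyr::mutate(
      n_snps = vapply(.data$prof, function(p) p$n_snps, integer(1)),
      bw = vapply(.data$prof, function(p) p$bw, numeric(1)),
      peak_af = vapply(.data$prof, function(p) p$peak_af, numeric(1)),
      profile = lapply(.data$prof, function(p) {
        tibble::tibble(af = p$grid, density = p$density)
      })
    ) |>
    dplyr::select("chrom", "n_snps", "bw", "peak_af", "profile")
}

#' Call the linkage group by KDE peak shift
#'
#' Compares per-chromosome allele-frequency density profiles between a
#' toxin-selected and an unselected pool. The statistic is the absolute
#' difference of the density peak locations; the chromosome with the largest
#' shift is called if the shift exceeds `shift_threshold`. A
#' Kolmogorov-Smirnov-style distance between the two (grid-integrated)
#' distributions is reported as a secondary diagnostic.
#'
#' @param selected_profiles,control_profiles Tibbles from [kde_profiles()]
#'   over the same chromosome set.
#' @param shift_threshold Minimum peak shift to call linkage (default 0.1).
#' @return An object of class `linkage_call`: list with `called_chrom`
#'   (`NA_character_` if no call), `shifts` (per-chromosome tibble),
#'   `threshold`, and the two profile tables.
#' @export
call_linkage_group <- function(selected_profiles, control_profiles,
                               shift_threshold = 0.1) {
  sel <- tibble::as_tibble(selected_profiles)
  ctl <- tibble::as_tibble(control_profiles)
  if (!setequal(sel$chrom, ctl$chrom)) {
    stop("selected and control profiles cover different chromosome sets",
         call. = FALSE)
  }
  ctl <- ctl[match(sel$chrom, ctl$chrom), ]
  ks <- vapply(seq_len(nrow(sel)), function(i) {
    ps <- sel$profile[[i]]; pc <- ctl$profile[[i]]
    step <- diff(ps$af[1:2])
    cdf_s <- cumsum(ps$density) * step
    cdf_c <- cumsum(pc$density) * step
    max(abs(cdf_s / max(cdf_s) - cdf_c / max(cdf_c)))
  }, numeric(1))
  shifts <- tibble::tibble(
    chrom = sel$chrom,
    peak_selected = sel$peak_af,
    peak_control = ctl$peak_af,
    shift = abs(sel$peak_af - ctl$peak_af),
    ks_distance = ks
  )
  top <- which.max(shifts$shift)
  called <- if (shifts$shift[top] > shift_threshold) {
    shifts$chrom[top]
  } else {
    NA_character_
  }
  structure(list(called_chrom = called, shifts = shifts,
                 threshold = shift_threshold,
                 selected_profiles = sel, control_profiles = ctl),
            class = "linkage_call")
}

#' Run the whole BSA-seq linkage scan
#'
#' Convenience wrapper chaining the AF filter, per-chromosome KDE profiling
#' of both pools, and the peak-shift linkage call.
#'
#' @param selected,control Allele-depth tibbles (`chrom`, `pos`, `depth_R`,
#'   `depth_S`, `af`) for the selected and control pools.
#' @param lower,upper AF retention band (see [filter_af()]).
#' @inheritParams call_linkage_group
#' @inheritParams kde_profile
#' @return A `linkage_call`.
#' @export
bsa_scan <- function(selected, control, lower = 0.05, upper = 0.95,
                     bandwidth = "nrd0", grid_step = 0.005,
                     shift_threshold = 0.1) {
  sel <- filter_af(selected, lower, upper)
  ctl <- filter_af(control, lower, upper)
  call_linkage_group(
    kde_profiles(sel, bandwidth = bandwidth, grid_step = grid_step),
    kde_profiles(ctl, bandwidth = bandwidth, grid_step = grid_step),
    shift_threshold = shift_threshold
  )
}

#' @export
print.linkage_call <- function(x, ...) {
  if (is.na(x$called_chrom)) {
    cat("<linkage_call> no linkage group called (max peak shift ",
        signif(max(x$shifts$shift), 3), " <= threshold ", x$threshold,
        ")\n", sep = "")
  } else {
    i <- match(x$called_chrom, x$shifts$chrom)
    cat("<linkage_call> ", x$called_chrom, ": control peak ",
        x$shifts$peak_control[i], " -> selected peak ",
        x$shifts$peak_selected[i], " (shift ",
        signif(x$shifts$shift[i], 3), ", threshold ", x$threshold, ")\n",
        sep = "")
  }
  invisible(x)
}

#' @export
tidy.linkage_call <- function(x, ...) {
  dplyr::mutate(x$shifts, called = .data$chrom %in% x$called_chrom)
}

#' @export
glance.linkage_call <- function(x, ...) {
  tibble::tibble(
    called_chrom = x$called_chrom,
    max_shift = max(x$shifts$shift),
    threshold = x$threshold,
    n_chromosomes = nrow(x$shifts)
  )
}
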