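FRAGMENT_SIZES <- list(
  ABCC2 = c(R = 102, S = 120),  # diagnostic PCR products, bp
  APN1  = c(R = 327, S = 234)
)

#' Call a genotype from diagnostic PCR fragment sizes
#'
#' The diagnostic PCRs amplify allele-specific products (ABCC2: 102 bp from
#' the resistant allele, 120 bp from the susceptible; APN1: 327 bp resistant,
#' 234 bp susceptible). Both sizes present = heterozygote; a single size =
#' the corresponding homozygote.
#'
#' @param locus `"ABCC2"` or `"APN1"`.
#' @param fragment_lengths Nonempty numeric set of observed product sizes.
#' @return `"R/R"`, `"R/S"`, or `"S/S"`.
#' @export
genotype_from_fragments <- function(locus = c("ABCC2", "APN1"),
                                    fragment_lengths) {
  locus <- match.arg(locus)
  sizes <- FRAGMENT_SIZES[[locus]]
  fragment_lengths <- unique(fragment_lengths)
  if (length(fragment_lengths) == 0L) {
    stop("empty fragment profile", call. = FALSE)
  }
  unknown <- setdiff(fragment_lengths, sizes)
  if (length(unknown)) {
    stop("unrecognized ", locus, " fragment size(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  has_r <- sizes[["R"]] %in% fragment_lengths
  has_s <- sizes[["S"]] %in% fragment_lengths
  if (has_r && has_s) "R/S" else if (has_r) "R/R" else "S/S"
}

#' Diagnostic-PCR fragment profiles for a population
#'
#' Maps each individual's genotype at the requested locus (ABCC2 uses the
#' tracked R1 genotype, APN1 the R2 causal-marker genotype) to the fragment
#' sizes its diagnostic PCR would produce.
#'
#' @param pop A `bc_population`.
#' @param locus `"ABCC2"` or `"APN1"`.
#' @return A tibble: `individual`, `locus`, `fragments` (list-column of
#'   numeric size sets), `genotype` (called back through
#'   [genotype_from_fragments()]).
#' @export
simulate_fragment_profiles <- function(pop, locus = c("ABCC2", "APN1")) {
  locus <- match.arg(locus)
  sizes <- FRAGMENT_SIZES[[locus]]
  geno <- if (locus == "ABCC2") {
    unname(c(R1R1 = "R/R", R1S1 = "R/S")[pop$r1])
  } else {
    unname(c(S2S2 = "S/S", S2R2 = "R/S", R2R2 = "R/R")[r2_genotypes(pop)])
  }
  frags <- lapply(geno, function(g) {
    switch(g,
           "R/R" = sizes[["R"]],
           "S/S" = sizes[["S"]],
           "R/S" = unname(sizes))
  })
  called <- vapply(frags, function(f) genotype_from_fragments(locus, f),
                   character(1))
  tibble::tibble(
    individual = seq_along(geno),
    locus = locus,
    fragments = frags,
    genotype = called
  )
}

#' Tabulate homozygous- and heterozygous-resistant genotype counts
#'
#' @param genotypes Character vector of `"R/R"` / `"R/S"` calls (e.g. from
#'   [simulate_fragment_profiles()]).
#' @param family,selection_dose Optional annotations.
#' @return One-row tibble: `family`, `selection_dose`, `n_hom_R`, `n_het`.
#' @export
count_genotypes <- function(genotypes, family = NA_character_,
                            selection_dose = NA_character_) {
  tibble::tibble(
    family = family,
    selection_dose = selection_dose,
    n_hom_R = sum(genotypes == "R/R"),
    n_het = sum(genotypes == "R/S")
  )
}

#' Chi-square test of a 1:1 segregation ratio
#'
#' Pearson goodness-of-fit chi-square (1 df, no continuity correction)
#' against expected equal counts of the two genotype classes.
#'
#' @param n1,n2 Observed counts of the two classes (`n1 + n2 > 0`).
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
chi_square_1to1 <- function(n1, n2) {
  stopifnot(length(n1) == 1L, length(n2) == 1L, n1 >= 0, n2 >= 0)
  if (n1 + n2 == 0) {
    stop("both counts are zero; segregation test undefined", call. = FALSE)
  }
  ct <- stats::chisq.test(c(n1, n2), p = c(0.5, 0.5))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value))
}

new_dominance_result <- function(h_raw, method, inputs) {
  clamped <- h_raw < 0 || h_raw > 1
  if (clamped) {
    warning("raw dominance estimate ", signif(h_raw, 4),
            " outside [0, 1]; clamped (sampling noise)", call. = FALSE)
  }
  h <- min(max(h_raw, 0), 1)
  structure(list(h = h, h_raw = h_raw,
                 h_display = round(h, 2),  # round-half-even, 2 decimals
                 method = method, clamped = clamped, inputs = inputs),
            class = "dominance_result")
}

#' Dominance of resistance from survivor genotype counts
#'
#' For a backcross of F1 (resistant x susceptible) to the resistant strain,
#' toxin-selected at a dose that no susceptible homozygote survives, and with
#' equal pre-selection numbers of the two surviving genotype classes, the
#' dominance coefficient of resistance simplifies to
#' `h = (# heterozygous survivors) / (# homozygous-resistant survivors)`.
#' Only apply when those two conditions hold (`w_SS = 0`, 1:1 pre-selection
#' ratio); otherwise use [estimate_h_survival()].
#'
#' @param n_het_survivors,n_homR_survivors Survivor counts
#'   (`n_homR_survivors > 0`).
#' @return A `dominance_result` (h clamped to `[0, 1]`; `h_display` rounded
#'   to 2 decimals, raw value retained).
#' @export
estimate_h_counts <- function(n_het_survivors, n_homR_survivors) {
  stopifnot(n_het_survivors >= 0)
  if (n_homR_survivors <= 0) {
    stop("h undefined with zero homozygous-resistant survivors",
         call. = FALSE)
  }
  new_dominance_result(n_het_survivors / n_homR_survivors,
                       method = "count_ratio",
                       inputs = list(n_het = n_het_survivors,
                                     n_homR = n_homR_survivors))
}

#' Dominance of resistance from genotype survival rates
#'
#' The general definition
#' `h = (w_RS - w_SS) / (w_RR - w_SS)`:
#' 0 = fully recessive, 1 = fully dominant resistance.
#'
#' @param w_RR,w_RS,w_SS Survival proportions of the three genotypes in
#'   `[0, 1]`, with `w_RR > w_SS`.
#' @return A `dominance_result`.
#' @export
estimate_h_survival <- function(w_RR, w_RS, w_SS) {
  stopifnot(all(c(w_RR, w_RS, w_SS) >= 0), all(c(w_RR, w_RS, w_SS) <= 1))
  if (w_RR <= w_SS) {
    stop("h undefined unless w_RR > w_SS", call. = FALSE)
  }
  new_dominance_result((w_RS - w_SS) / (w_RR - w_SS),
                       method = "survival_formula",
                       inputs = list(w_RR = w_RR, w_RS = w_RS, w_SS = w_SS))
}

#' @export
print.dominance_result <- function(x, ...) {
  cat("<dominance_result> h = ", format(x$h_display, nsmall = 2),
      " (", x$method,
      if (x$clamped) ", clamped", ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.dominance_result <- function(x, ...) {
  tibble::tibble(h = x$h, h_raw = x$h_raw, h_display = x$h_display,
                 method = x$method, clamped = x$clamped)
}

#' @export
glance.dominance_result <- function(x, ...) tidy.dominance_result(x, ...)

#' Segregation and dominance summary for genotyped survivors
#'
#' Data-frame-first convenience: takes a genotype count table (one row per
#' family/treatment, as from [count_genotypes()]) and appends the 1:1
#' chi-square test and, for selected rows, the count-ratio dominance
#' estimate.
#'
#' @param counts Tibble with columns `n_hom_R`, `n_het` (plus annotations).
#' @param estimate_h Logical vector (recycled): estimate h for this row?
#'   Rows with unselected controls should be `FALSE`.
#' @return The input with `chisq_statistic`, `p_value`, `h`, `h_display`
#'   columns appended (`NA` where not estimated).
#' @export
dominance_table <- function(counts, estimate_h = TRUE) {
  counts <- tibble::as_tibble(counts)
  estimate_h <- rep_len(estimate_h, nrow(counts))
  tests <- purrr::map2_dfr(counts$n_hom_R, counts$n_het, chi_square_1to1)
  hs <- purrr::pmap(list(counts$n_het, counts$n_hom_R, estimate_h),
                    function(het, hom, do) {
                      if (!do || hom == 0) {
                        tibble::tibble(h = NA_real_, h_display = NA_real_)
                      } else {
                        r <- estimate_h_counts(het, hom)
                        tibble::tibble(h = r$h, h_display = r$h_display)
                      }
                    })
  dplyr::bind_cols(counts,
                   chisq_statistic = tests$statistic,
                   p_value = tests$p_value,
                   dplyr::bind_rows(hs))
}
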