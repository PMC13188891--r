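#' @importFrom rlang .data
NULL

set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    stopifnot(is.finite(seed))
    set.seed(seed)
  }
  invisible(NULL)
}

R2_GENOTYPES <- c("S2S2", "S2R2", "R2R2")
R1_GENOTYPES <- c("R1R1", "R1S1")

#' Construct a single individual
#'
#' An individual carries two phased haplotypes over all markers of a genome
#' map (allele 1 = derived from the resistant strain, 0 = from the
#' susceptible/knockout strain), a sex, an ABCC2-locus (R1) genotype carried
#' as a label (the locus lies outside the simulated marker scaffold), and the
#' identity of the causal R2 marker.
#'
#' @param map A [genome_map][build_genome_map].
#' @param maternal,paternal Integer vectors of 0/1 alleles, one per marker of
#'   `map`, or a single 0/1 recycled.
#' @param sex `"female"` or `"male"`.
#' @param r1 `"R1R1"` or `"R1S1"`.
#' @param causal List or data frame with `chrom` and `pos` naming the causal
#'   R2 marker (must exist in `map`).
#' @return An object of class `bc_individual`.
#' @export
bc_individual <- function(map, maternal, paternal, sex = c("female", "male"),
                          r1 = "R1R1", causal = NULL) {
  sex <- match.arg(sex)
  r1 <- match.arg(r1, R1_GENOTYPES)
  m <- n_markers(map)
  maternal <- as.integer(rep_len(maternal, m))
  paternal <- as.integer(rep_len(paternal, m))
  stopifnot(all(maternal %in% 0:1), all(paternal %in% 0:1))
  if (!is.null(causal)) marker_index(map, causal$chrom, causal$pos)
  structure(list(map = map, maternal = maternal, paternal = paternal,
                 sex = sex, r1 = r1, causal = causal),
            class = "bc_individual")
}

#' Simulate one gamete from an individual
#'
#' Implements Lepidoptera-style sex-dependent meiosis. Females are
#' achiasmatic: each chromosome of the gamete is an intact copy of one of the
#' two parental haplotypes (fair coin per chromosome, independent across
#' chromosomes). Males recombine: the crossover count per chromosome is
#' Poisson with mean `genetic_length / 100` (Morgans), crossover positions
#' are uniform in genetic coordinates, and there is no interference
#' (Haldane model).
#'
#' @param parent A [bc_individual()].
#' @param map A `genome_map`; defaults to the parent's map.
#' @param seed Optional integer seed.
#' @return Integer vector of 0/1 alleles, one per marker.
#' @export
simulate_gamete <- function(parent, map = parent$map, seed = NULL) {
  stopifnot(inherits(parent, "bc_individual"))
  set_seed_if(seed)
  if (parent$sex == "female") {
    gametes_achiasmatic(parent$maternal, parent$paternal, map, 1L)[1L, ]
  } else {
    gametes_recombinant(parent$maternal, parent$paternal, map, 1L)[1L, ]
  }
}

# n intact-chromosome gametes from one parent's haplotype pair; rows = gametes
gametes_achiasmatic <- function(hap_a, hap_b, map, n) {
  if (n == 0L) {
    return(matrix(integer(0), nrow = 0, ncol = length(hap_a)))
  }
  chrom_of <- match(map$markers$chrom, map$chromosomes$chrom)
  n_chr <- nrow(map$chromosomes)
  pick_b <- matrix(stats::runif(n * n_chr) < 0.5, nrow = n, ncol = n_chr)
  out <- matrix(rep(hap_a, each = n), nrow = n)
  sel <- pick_b[, chrom_of, drop = FALSE]
  bmat <- matrix(rep(hap_b, each = n), nrow = n)
  out[sel] <- bmat[sel]
  storage.mode(out) <- "integer"
  out
}

# n recombinant gametes (Haldane: Poisson crossover count, uniform placement)
gametes_recombinant <- function(hap_a, hap_b, map, n) {
  m <- length(hap_a)
  if (n == 0L) return(matrix(integer(0), nrow = 0, ncol = m))
  out <- matrix(0L, nrow = n, ncol = m)
  for (c_i in seq_len(nrow(map$chromosomes))) {
    chrom <- map$chromosomes$chrom[c_i]
    len_cm <- map$chromosomes$length_cm[c_i]
    cols <- which(map$markers$chrom == chrom)
    if (length(cols) == 0L) next
    marker_cm <- map$markers$pos[cols] / map$chromosomes$length_bp[c_i] * len_cm
    a <- hap_a[cols]
    b <- hap_b[cols]
    k <- stats::rpois(n, len_cm / 100)
    start_b <- stats::runif(n) < 0.5
    for (g in seq_len(n)) {
      if (k[g] == 0L) {
        phase <- rep(start_b[g], length(cols))
      } else {
        xo <- sort(stats::runif(k[g], 0, len_cm))
        seg <- findInterval(marker_cm, xo)
        phase <- xor(start_b[g], seg %% 2L == 1L)
      }
      out[g, cols] <- ifelse(phase, b, a)
    }
  }
  storage.mode(out) <- "integer"
  out
}

#' Describe a backcross design
#'
#' The three designs of the biphasic mapping workflow:
#' * `BC1_female_informative`: F1 female x knockout-strain male. Female
#'   achiasmy transmits intact chromosomes, so the scan resolves linkage at
#'   whole-chromosome level.
#' * `BC2_male_informative`: F1 male x knockout-strain female. Male meiosis
#'   recombines, enabling fine mapping within the called chromosome.
#' * `dominance_backcross`: F1 (resistant x susceptible) x resistant strain,
#'   used to measure the dominance of resistance; both the R1 (ABCC2) and the
#'   R2 locus segregate 1:1.
#'
#' @param name One of the three design names.
#' @param n_offspring Intended number of offspring (informational).
#' @param f1_sex Sex of the F1 parent in `dominance_backcross` (the mapping
#'   designs fix it by definition).
#' @return A list of class `cross_design`.
#' @export
cross_design <- function(name = c("BC1_female_informative",
                                  "BC2_male_informative",
                                  "dominance_backcross"),
                         n_offspring = NA_integer_,
                         f1_sex = c("female", "male")) {
  name <- match.arg(name)
  f1_sex <- switch(name,
    BC1_female_informative = "female",
    BC2_male_informative = "male",
    dominance_backcross = match.arg(f1_sex)
  )
  structure(list(name = name,
                 informative_parent_sex = f1_sex,
                 recurrent_parent = if (name == "dominance_backcross")
                   "resistant" else "knockout",
                 n_offspring = n_offspring),
            class = "cross_design")
}

new_population <- function(map, design, hap_m, hap_p, sex, r1, causal,
                           selected = FALSE) {
  stopifnot(nrow(hap_m) == nrow(hap_p), nrow(hap_m) == length(sex),
            length(r1) == length(sex))
  structure(list(map = map, design = design, hap_m = hap_m, hap_p = hap_p,
                 sex = sex, r1 = r1, causal = causal, selected = selected),
            class = "bc_population")
}

#' @export
print.bc_population <- function(x, ...) {
  cat("<bc_population> ", x$design$name, ": ", n_individuals(x),
      " individuals", if (isTRUE(x$selected)) " (post-selection)", "\n",
      sep = "")
  if (n_individuals(x) > 0) {
    print(table(r2 = r2_genotypes(x), r1 = x$r1))
  }
  invisible(x)
}

#' Number of individuals in a population
#' @param pop A `bc_population`.
#' @export
n_individuals <- function(pop) nrow(pop$hap_m)

#' R2-locus genotype labels of a population
#'
#' Reads the genotype at the causal marker off the two haplotypes.
#'
#' @param pop A `bc_population`.
#' @return Character vector in `{"S2S2", "S2R2", "R2R2"}`.
#' @export
r2_genotypes <- function(pop) {
  j <- marker_index(pop$map, pop$causal$chrom, pop$causal$pos)
  R2_GENOTYPES[pop$hap_m[, j] + pop$hap_p[, j] + 1L]
}

#' @export
tidy.bc_population <- function(x, ...) {
  tibble::tibble(
    individual = seq_len(n_individuals(x)),
    sex = x$sex,
    r1_genotype = x$r1,
    r2_genotype = r2_genotypes(x)
  )
}

#' @export
as_tibble.bc_population <- function(x, ...) tidy.bc_population(x, ...)

#' Simulate a backcross population
#'
#' Generates `n` offspring of the requested design over a genome map. In the
#' mapping designs (`BC1`/`BC2`) the F1 parent is heterozygous
#' resistant/susceptible at every marker and the recurrent knockout-strain
#' parent contributes an all-susceptible haplotype, so the causal R2 marker
#' segregates S2S2 : S2R2 at 1:1 in expectation and every individual is R1R1
#' (both parents carry knocked-out ABCC2). In `dominance_backcross` the
#' recurrent parent is the resistant strain (all-resistant haplotype, R1R1)
#' and the F1 carries one susceptible-strain haplotype and is R1S1, so both
#' loci segregate 1:1 (R2R2 : S2R2 and R1R1 : R1S1).
#'
#' @param design A [cross_design()] or a design name.
#' @param map A `genome_map`.
#' @param n Number of offspring (0 allowed).
#' @param causal List/row with `chrom`, `pos` of the causal R2 marker.
#' @param seed Optional integer seed.
#' @return A `bc_population`.
#' @export
make_backcross <- function(design, map, n, causal, seed = NULL) {
  if (is.character(design)) design <- cross_design(design)
  stopifnot(inherits(design, "cross_design"), inherits(map, "genome_map"))
  if (length(n) != 1L || is.na(n) || n < 0) {
    stop("`n` must be a single count >= 0", call. = FALSE)
  }
  n <- as.integer(n)
  marker_index(map, causal$chrom, causal$pos)
  set_seed_if(seed)

  m <- n_markers(map)
  het_a <- rep(1L, m)  # resistant-strain haplotype of the F1
  het_b <- rep(0L, m)  # susceptible/knockout haplotype of the F1
  f1_gam <- if (design$informative_parent_sex == "female") {
    gametes_achiasmatic(het_a, het_b, map, n)
  } else {
    gametes_recombinant(het_a, het_b, map, n)
  }
  if (design$name == "dominance_backcross") {
    other <- matrix(1L, nrow = n, ncol = m)       # resistant recurrent parent
    r1 <- sample(R1_GENOTYPES, n, replace = TRUE) # ABCC2 segregates 1:1
  } else {
    other <- matrix(0L, nrow = n, ncol = m)       # knockout recurrent parent
    r1 <- rep("R1R1", n)
  }
  if (design$informative_parent_sex == "female") {
    hap_m <- f1_gam; hap_p <- other
  } else {
    hap_m <- other; hap_p <- f1_gam
  }
  sex <- sample(c("female", "male"), n, replace = TRUE)
  new_population(map, design, hap_m, hap_p, sex, r1,
                 causal = list(chrom = causal$chrom, pos = causal$pos))
}

#' Define genotype-dependent survival under toxin selection
#'
#' Survival probabilities are indexed by the two-locus genotype
#' (R1 = ABCC2 background, R2 = the mapped locus). Helpers:
#' [selection_by_r2()] for models that depend only on the R2 genotype (the
#' mapping crosses are uniformly R1R1) and [selection_by_r1()] for models
#' driven by the ABCC2 genotype.
#'
#' @param w A data frame with columns `r1`, `r2`, `w` (survival probability
#'   in `[0, 1]`).
#' @param dose_label,background_label Free-text annotations (e.g.
#'   `"7 ug/cm2"`, `"Benzon"`).
#' @return A list of class `selection_model`.
#' @export
selection_model <- function(w, dose_label = NA_character_,
                            background_label = NA_character_) {
  w <- tibble::as_tibble(w)
  stopifnot(all(c("r1", "r2", "w") %in% names(w)))
  if (any(!is.finite(w$w)) || any(w$w < 0 | w$w > 1)) {
    stop("survival probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(w[, c("r1", "r2")])) {
    stop("duplicate genotype rows in selection model", call. = FALSE)
  }
  structure(list(w = w, dose_label = dose_label,
                 background_label = background_label),
            class = "selection_model")
}

#' @rdname selection_model
#' @param w_s2s2,w_s2r2,w_r2r2 Survival of the three R2-locus genotypes.
#' @export
selection_by_r2 <- function(w_s2s2, w_s2r2, w_r2r2 = 1, ...) {
  grid <- tidyr::expand_grid(r1 = R1_GENOTYPES, r2 = R2_GENOTYPES)
  grid$w <- c(S2S2 = w_s2s2, S2R2 = w_s2r2, R2R2 = w_r2r2)[grid$r2]
  selection_model(grid, ...)
}

#' @rdname selection_model
#' @param w_r1r1,w_r1s1 Survival of the two ABCC2 genotypes (applied across
#'   all R2 genotypes).
#' @param ... Passed to [selection_model()].
#' @export
selection_by_r1 <- function(w_r1r1, w_r1s1, ...) {
  grid <- tidyr::expand_grid(r1 = R1_GENOTYPES, r2 = R2_GENOTYPES)
  grid$w <- c(R1R1 = w_r1r1, R1S1 = w_r1s1)[grid$r1]
  selection_model(grid, ...)
}

#' Apply toxin selection to a population
#'
#' Each individual survives independently with the probability its two-locus
#' genotype has in the model. Survivors form the returned population with
#' `selected = TRUE`.
#'
#' @param pop A `bc_population`.
#' @param model A [selection_model()].
#' @param seed Optional integer seed.
#' @return The surviving `bc_population`.
#' @export
apply_selection <- function(pop, model, seed = NULL) {
  stopifnot(inherits(pop, "bc_population"), inherits(model, "selection_model"))
  set_seed_if(seed)
  key <- paste(pop$r1, r2_genotypes(pop))
  wkey <- paste(model$w$r1, model$w$r2)
  if (!all(key %in% wkey)) {
    stop("selection model lacks survival for genotype(s): ",
         paste(unique(setdiff(key, wkey)), collapse = ", "), call. = FALSE)
  }
  w <- model$w$w[match(key, wkey)]
  keep <- stats::runif(length(w)) < w
  subset_population(pop, keep, selected = TRUE)
}

subset_population <- function(pop, keep, selected = pop$selected) {
  new_population(pop$map, pop$design,
                 pop$hap_m[keep, , drop = FALSE],
                 pop$hap_p[keep, , drop = FALSE],
                 pop$sex[keep], pop$r1[keep], pop$causal,
                 selected = selected)
}
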