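#' Build a marker map over a set of chromosomes
#'
#' Constructs the marker scaffold used by the cross simulator: each chromosome
#' gets a physical length (bp), a genetic length (cM) and markers placed at
#' regular physical intervals (`marker_spacing`, `2 * marker_spacing`, ... up
#' to the chromosome length). Placement is deterministic. Genetic positions are
#' obtained by uniform cM/bp interpolation within each chromosome.
#'
#' @param n_chromosomes Number of chromosomes (>= 1).
#' @param physical_lengths Integer vector of chromosome lengths in bp, length 1
#'   (recycled) or `n_chromosomes`.
#' @param genetic_lengths Numeric vector of genetic lengths in centiMorgan,
#'   recycled like `physical_lengths`. Default 50 cM (one expected crossover
#'   per bivalent in male meiosis).
#' @param marker_spacing Distance between consecutive markers in bp (> 0).
#' @param labels Chromosome labels; default `chr1 ... chrN`. A virtual
#'   unanchored group (e.g. `"chr0"`) is an ordinary label.
#' @return An object of class `genome_map`: a list with tibbles `chromosomes`
#'   (`chrom`, `length_bp`, `length_cm`) and `markers` (`chrom`, `pos`).
#' @examples
#' build_genome_map(1, 1e6, 50, marker_spacing = 1e5)
#' @export
build_genome_map <- function(n_chromosomes, physical_lengths,
                             genetic_lengths = 50, marker_spacing,
                             labels = NULL) {
  if (length(n_chromosomes) != 1L || is.na(n_chromosomes) || n_chromosomes < 1) {
    stop("`n_chromosomes` must be a single integer >= 1", call. = FALSE)
  }
  n_chromosomes <- as.integer(n_chromosomes)
  if (any(!is.finite(physical_lengths)) || any(physical_lengths <= 0)) {
    stop("`physical_lengths` must be positive", call. = FALSE)
  }
  if (any(!is.finite(genetic_lengths)) || any(genetic_lengths < 0)) {
    stop("`genetic_lengths` must be >= 0", call. = FALSE)
  }
  if (length(marker_spacing) != 1L || !is.finite(marker_spacing) ||
      marker_spacing <= 0) {
    stop("`marker_spacing` must be a single value > 0", call. = FALSE)
  }
  physical_lengths <- rep_len(as.numeric(physical_lengths), n_chromosomes)
  genetic_lengths <- rep_len(as.numeric(genetic_lengths), n_chromosomes)
  if (is.null(labels)) labels <- paste0("chr", seq_len(n_chromosomes))
  if (length(labels) != n_chromosomes || anyDuplicated(labels)) {
    stop("`labels` must be ", n_chromosomes, " unique chromosome labels",
         call. = FALSE)
  }

  chromosomes <- tibble::tibble(
    chrom = as.character(labels),
    length_bp = physical_lengths,
    length_cm = genetic_lengths
  )
  markers <- purrr::pmap_dfr(chromosomes, function(chrom, length_bp, length_cm) {
    pos <- seq_len(floor(length_bp / marker_spacing)) * marker_spacing
    tibble::tibble(chrom = chrom, pos = as.numeric(pos))
  })
  new_genome_map(chromosomes, markers)
}

new_genome_map <- function(chromosomes, markers) {
  validate_genome_map(chromosomes, markers)
  structure(list(chromosomes = chromosomes, markers = markers),
            class = "genome_map")
}

validate_genome_map <- function(chromosomes, markers) {
  stopifnot(all(markers$chrom %in% chromosomes$chrom))
  len <- stats::setNames(chromosomes$length_bp, chromosomes$chrom)
  if (any(markers$pos < 1 | markers$pos > len[markers$chrom])) {
    stop("marker positions must satisfy 1 <= pos <= chromosome length",
         call. = FALSE)
  }
  ok <- vapply(split(markers$pos, markers$chrom),
               function(p) !is.unsorted(p, strictly = TRUE), logical(1))
  if (!all(ok)) {
    stop("marker positions must be strictly increasing within a chromosome",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Add markers to an existing genome map
#'
#' Used to inject specific diagnostic sites (e.g. amplicon SNPs, the causal
#' resistance site) into an evenly spaced scaffold.
#'
#' @param map A `genome_map`.
#' @param positions A data frame with columns `chrom` and `pos`.
#' @return The `genome_map` with the union of markers, sorted.
#' @export
add_markers <- function(map, positions) {
  stopifnot(inherits(map, "genome_map"))
  positions <- dplyr::distinct(tibble::as_tibble(positions[, c("chrom", "pos")]))
  markers <- dplyr::bind_rows(map$markers, positions)
  markers <- dplyr::arrange(dplyr::distinct(markers), match(.data$chrom, map$chromosomes$chrom), .data$pos)
  new_genome_map(map$chromosomes, markers)
}

#' @export
print.genome_map <- function(x, ...) {
  cat("<genome_map> ", nrow(x$chromosomes), " chromosomes, ",
      nrow(x$markers), " markers\n", sep = "")
  print(x$chromosomes, n = 5)
  invisible(x)
}

n_markers <- function(map) nrow(map$markers)

marker_index <- function(map, chrom, pos) {
  j <- which(map$markers$chrom == chrom & map$markers$pos == pos)
  if (length(j) != 1L) {
    stop("no marker at ", chrom, ":", pos, " in the genome map", call. = FALSE)
  }
  j
}

#' Default cabbage-looper-like genome map
#'
#' A 32-group map (31 chromosomes plus the virtual unanchored group `chr0`)
#' with ~11-12.5 Mb chromosomes and 50 cM genetic length each, mirroring the
#' scale of the *Trichoplusia ni* assembly used for resistance mapping.
#' Chromosome 9 is slightly longer (12.5 Mb) so that the fine-mapping amplicon
#' panel of [tni_chr9_amplicons()] fits on it.
#'
#' @param marker_spacing Marker spacing in bp (default 55 kb, i.e. ~200
#'   markers per chromosome).
#' @param n_chromosomes Number of anchored chromosomes (default 31); `chr0` is
#'   always appended.
#' @return A `genome_map`.
#' @export
tni_genome_map <- function(marker_spacing = 55000, n_chromosomes = 31) {
  labels <- c(paste0("chr", seq_len(n_chromosomes)), "chr0")
  lengths <- rep(11e6, n_chromosomes + 1L)
  if (n_chromosomes >= 9) lengths[9] <- 12.5e6
  build_genome_map(n_chromosomes + 1L, lengths, 50, marker_spacing,
                   labels = labels)
}

#' Chromosome-9 amplicon panel
#'
#' The 48-amplicon fine-mapping panel on chromosome 9: amplicon identifier,
#' forward-primer position, PCR product size, and the position of the
#' diagnostic SNP assayed by each amplicon (taken as the product midpoint
#' except for amplicons 3 and 12, whose diagnostic SNPs sit at the known locus
#' boundaries 1,767,453 and 2,442,587).
#'
#' @return A tibble with columns `amplicon_id`, `chrom`, `fwd_pos`,
#'   `product_bp`, `pos`.
#' @export
tni_chr9_amplicons <- function() {
  fwd <- c(1270927, 1528061, 1767405, 1867402, 1975571, 2024328, 2073992,
           2094322, 2162567, 2253615, 2342930, 2442248, 2546746, 2636392,
           2721717, 2813373, 2911624, 3327419, 3667757, 3782249, 4635304,
           4731012, 4826566, 4953916, 5062280, 5154509, 5255852, 6649406,
           6762647, 6864555, 9011689, 9981535, 10087559, 10189242, 10287749,
           10398424, 10511091, 10622622, 10734239, 10839102, 10917949,
           11065021, 11229448, 11329127, 11429199, 11498404, 11584169,
           12015084)
  product <- c(544, 661, 584, 547, 562, 378, 433, 353, 377, 362, 572, 389,
               714, 496, 302, 356, 503, 478, 345, 749, 395, 694, 356, 295,
               273, 514, 504, 323, 565, 390, 471, 267, 614, 560, 440, 677,
               396, 556, 401, 576, 516, 382, 395, 649, 411, 615, 398, 676)
  pos <- fwd + product %/% 2
  pos[3] <- 1767453
  pos[12] <- 2442587
  tibble::tibble(
    amplicon_id = seq_along(fwd),
    chrom = "chr9",
    fwd_pos = fwd,
    product_bp = product,
    pos = pos
  )
}
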