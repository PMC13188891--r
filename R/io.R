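#' Read a pooled allele-depth table
#'
#' Primary format: a TSV with columns `chrom`, `pos`, `depth_R`, `depth_S`
#' (1-based positions; `depth_R` counts reads supporting the
#' resistant-strain-derived allele). An optional VCF path parses per-sample
#' `AD` fields via the vcfR package; an orientation table then says which
#' VCF allele is the resistant-strain one.
#'
#' Malformed TSV rows (non-numeric or negative depths, missing fields) are
#' dropped with a warning and collected — with their line numbers — in the
#' `problems` attribute of the result.
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"vcf"`.
#' @param sample For VCF input: sample name holding the pool's `AD` field
#'   (default: first sample).
#' @param orientation For VCF input: a data frame `chrom`, `pos`,
#'   `resistant_allele` (`"REF"` or `"ALT"`); default `"ALT"` everywhere.
#' @return A tibble `chrom`, `pos`, `depth_R`, `depth_S`, `af`.
#' @export
read_allele_depths <- function(path, format = c("tsv", "vcf"), sample = NULL,
                               orientation = NULL) {
  format <- match.arg(format)
  if (format == "vcf") {
    return(read_allele_depths_vcf(path, sample, orientation))
  }
  raw <- utils::read.delim(path, header = TRUE, colClasses = "character")
  required <- c("chrom", "pos", "depth_R", "depth_S")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("allele-depth table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pos <- suppressWarnings(as.numeric(raw$pos))
  dr <- suppressWarnings(as.numeric(raw$depth_R))
  ds <- suppressWarnings(as.numeric(raw$depth_S))
  bad <- is.na(pos) | is.na(dr) | is.na(ds) | dr < 0 | ds < 0 | pos < 1
  out <- tibble::tibble(
    chrom = raw$chrom[!bad], pos = pos[!bad],
    depth_R = dr[!bad], depth_S = ds[!bad]
  )
  out$af <- ifelse(out$depth_R + out$depth_S > 0,
                   out$depth_R / (out$depth_R + out$depth_S), NA_real_)
  if (any(bad)) {
    problems <- tibble::tibble(line = which(bad) + 1L,
                               content = do.call(paste, c(raw[bad, ], sep = "\t")))
    warning(sum(bad), " malformed row(s) dropped from ", path,
            "; see attr(., 'problems')", call. = FALSE)
    attr(out, "problems") <- problems
  }
  out
}

read_allele_depths_vcf <- function(path, sample = NULL, orientation = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF input requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(sample)) sample <- colnames(ad)[1]
  ad <- ad[, sample]
  parts <- strsplit(ad, ",", fixed = TRUE)
  ref_d <- as.numeric(vapply(parts, `[`, "", 1))
  alt_d <- as.numeric(vapply(parts, `[`, "", 2))
  chrom <- vcfR::getCHROM(v)
  pos <- vcfR::getPOS(v)
  res_allele <- rep("ALT", length(pos))
  if (!is.null(orientation)) {
    key <- paste0(orientation$chrom, ":",
                  format(orientation$pos, scientific = FALSE, trim = TRUE))
    hit <- match(paste0(chrom, ":",
                        format(pos, scientific = FALSE, trim = TRUE)), key)
    res_allele[!is.na(hit)] <- orientation$resistant_allele[hit[!is.na(hit)]]
  }
  depth_r <- ifelse(res_allele == "ALT", alt_d, ref_d)
  depth_s <- ifelse(res_allele == "ALT", ref_d, alt_d)
  tibble::tibble(
    chrom = chrom, pos = pos, depth_R = depth_r, depth_S = depth_s,
    af = ifelse(depth_r + depth_s > 0, depth_r / (depth_r + depth_s),
                NA_real_)
  )
}

#' Write a pooled allele-depth table
#'
#' @param records Tibble with `chrom`, `pos`, `depth_R`, `depth_S`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_allele_depths <- function(records, path) {
  records <- tibble::as_tibble(records)[, c("chrom", "pos", "depth_R",
                                            "depth_S")]
  readr::write_tsv(records, path)
  invisible(path)
}

#' Read / write amplicon record tables
#'
#' TSV with columns `amplicon_id`, `chrom`, `snp_pos`, `sel_depth_R`,
#' `sel_depth_S`, `ctrl_depth_R`, `ctrl_depth_S`; AFs and `delta_af` are
#' recomputed on read.
#'
#' @param path File path.
#' @return `read_amplicon_records()`: an amplicon record tibble.
#' @export
read_amplicon_records <- function(path) {
  required <- c("amplicon_id", "chrom", "snp_pos", "sel_depth_R",
                "sel_depth_S", "ctrl_depth_R", "ctrl_depth_S")
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols)) {
    stop("amplicon table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tbl$sel_af <- with(tbl, ifelse(sel_depth_R + sel_depth_S > 0,
                                 sel_depth_R / (sel_depth_R + sel_depth_S),
                                 NA_real_))
  tbl$ctrl_af <- with(tbl, ifelse(ctrl_depth_R + ctrl_depth_S > 0,
                                  ctrl_depth_R / (ctrl_depth_R + ctrl_depth_S),
                                  NA_real_))
  tbl$delta_af <- tbl$sel_af - tbl$ctrl_af
  tbl
}

#' @rdname read_amplicon_records
#' @param records Amplicon record tibble.
#' @export
write_amplicon_records <- function(records, path) {
  cols <- c("amplicon_id", "chrom", "snp_pos", "sel_depth_R", "sel_depth_S",
            "ctrl_depth_R", "ctrl_depth_S")
  readr::write_tsv(tibble::as_tibble(records)[, cols], path)
  invisible(path)
}

#' Write a mapped interval as BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' the exported line is `chrom, start - 1, end`. The name field carries the
#' display width (e.g. `"675kb"`). A `NULL` interval writes a header-only
#' file.
#'
#' @param interval A `mapped_interval` or `NULL`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interval_bed <- function(interval, path) {
  header <- "# candidate interval (BED: 0-based half-open)"
  if (is.null(interval)) {
    writeLines(header, path)
    return(invisible(path))
  }
  line <- paste(interval$chrom, format(interval$start - 1, scientific = FALSE),
                format(interval$end, scientific = FALSE),
                paste0(interval$width_kb_display, "kb"), sep = "\t")
  writeLines(c(header, line), path)
  invisible(path)
}

#' Read a BED interval back to 1-based inclusive coordinates
#'
#' @param path BED path written by [write_interval_bed()].
#' @return A tibble `chrom`, `start`, `end` (1-based inclusive), or an empty
#'   tibble for a header-only file.
#' @export
read_interval_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    chrom = vapply(parts, `[`, "", 1),
    start = as.numeric(vapply(parts, `[`, "", 2)) + 1,
    end = as.numeric(vapply(parts, `[`, "", 3))
  )
}

#' Read / write long expression count tables
#'
#' TSV with columns `gene_id`, `length_bp`, `sample_id`, `strain`, `count`.
#'
#' @param path File path.
#' @return `read_expression_counts()`: a long count tibble.
#' @export
read_expression_counts <- function(path) {
  required <- c("gene_id", "length_bp", "sample_id", "strain", "count")
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols)) {
    stop("expression table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tbl
}

#' @rdname read_expression_counts
#' @param counts Long count tibble.
#' @export
write_expression_counts <- function(counts, path) {
  cols <- c("gene_id", "length_bp", "sample_id", "strain", "count")
  readr::write_tsv(tibble::as_tibble(counts)[, cols], path)
  invisible(path)
}

#' Write a workflow report as JSON
#'
#' Serializes a report list (e.g. from [run_biphasic_demo()]) to pretty
#' JSON. No timestamps are included, so identical runs produce
#' byte-identical files.
#'
#' @param report A list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
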