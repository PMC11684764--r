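# Genomic region lists used for pre-PCA exclusion.

#' Construct a region list
#'
#' A region list is a tibble of genomic intervals (columns `chrom`,
#' `start_bp`, `end_bp`; 1-based, inclusive on both ends) used to exclude
#' variants prior to PCA, sorted by chromosome and start.
#'
#' @param chrom Chromosome labels.
#' @param start_bp,end_bp 1-based inclusive interval bounds.
#' @param build_label Free-text genome build annotation (advisory only).
#' @return A tibble of class `region_list` with attribute `build_label`.
#' @export
region_list <- function(chrom, start_bp, end_bp, build_label = "") {
  stopifnot(length(chrom) == length(start_bp),
            length(start_bp) == length(end_bp))
  if (any(end_bp < start_bp)) abort("regions must have start_bp <= end_bp.")
  out <- tibble::tibble(chrom = as.character(chrom),
                        start_bp = as.numeric(start_bp),
                        end_bp = as.numeric(end_bp)) |>
    dplyr::arrange(.data$chrom, .data$start_bp)
  attr(out, "build_label") <- build_label
  class(out) <- c("region_list", class(out))
  out
}

#' High-LD regions recommended for exclusion before PCA
#'
#' Returns the catalogue of autosomal regions with high, long-range, or
#' otherwise unusual linkage disequilibrium (e.g., the LCT locus, the HLA
#' region, and the chromosome 8 and 17 inversions) that the literature
#' recommends excluding before running PCA for ancestry inference.
#' Coordinates are genome build 38; the list ships with the package as a
#' plain TSV.
#'
#' @return A [region_list()] with build label `"hg38"`.
#' @examples
#' head(high_ld_regions())
#' @export
high_ld_regions <- function() {
  path <- system.file("extdata", "high_ld_regions_hg38.tsv",
                      package = "pccollide", mustWork = TRUE)
  read_region_tsv(path, build_label = "hg38")
}

#' Read a region table in TSV form
#'
#' Reads a tab-separated region table with columns `chrom`, `start_bp`,
#' `end_bp` (1-based inclusive).
#'
#' @param path File path.
#' @param build_label Genome build annotation to attach.
#' @return A [region_list()].
#' @export
read_region_tsv <- function(path, build_label = "") {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("chrom", "start_bp", "end_bp") %in% names(x)))
  region_list(x$chrom, x$start_bp, x$end_bp, build_label = build_label)
}

#' Read regions from a BED file
#'
#' BED intervals are 0-based, half-open; they are converted to the package's
#' 1-based inclusive convention (`start_bp = start + 1`, `end_bp = end`).
#'
#' @param path BED file path (first three columns used).
#' @param build_label Genome build annotation to attach.
#' @return A [region_list()].
#' @export
read_bed_regions <- function(path, build_label = "") {
  x <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                       show_col_types = FALSE)
  if (ncol(x) < 3L) abort("BED file must have at least 3 columns.")
  region_list(x[[1]], as.numeric(x[[2]]) + 1, as.numeric(x[[3]]),
              build_label = build_label)
}

#' Write a region list as BED
#'
#' Converts the 1-based inclusive intervals back to BED's 0-based half-open
#' convention.
#'
#' @param regions A [region_list()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed_regions <- function(regions, path) {
  readr::write_tsv(
    tibble::tibble(chrom = regions$chrom,
                   start = as.integer(regions$start_bp - 1),
                   end = as.integer(regions$end_bp)),
    path, col_names = FALSE)
  invisible(path)
}
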