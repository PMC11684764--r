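# Readers/writers: cohort VCF + sidecar, panel TSV, PCA results.

#' Write a simulated cohort as VCF plus sidecar TSV
#'
#' Writes genotypes as an uncompressed VCF (GT field, unphased diploid
#' calls derived from the dosage), with the ancestral allele frequencies
#' and feature membership stored per variant in the INFO column (keys
#' `P1`, `P0`, `FEAT`). Individual-level truth that has no VCF slot —
#' the true admixture proportions and latent feature indicators — goes to
#' a sidecar TSV.
#'
#' @param cohort An `admix_cohort`.
#' @param vcf_path Output VCF path.
#' @param sidecar_path Output TSV path for per-individual truth; `NULL`
#'   skips the sidecar.
#' @return Invisibly, `vcf_path`.
#' @export
write_cohort_vcf <- function(cohort, vcf_path, sidecar_path = NULL) {
  G <- cohort$G
  n <- nrow(G)
  panel <- cohort$panel
  gt <- matrix(c("0/0", "0/1", "1/1")[G + 1L], nrow = n)
  info <- sprintf("P1=%.6g;P0=%.6g%s", panel$p1, panel$p0,
                  ifelse(is.na(panel$feature_id), "",
                         paste0(";FEAT=", panel$feature_id)))
  body <- cbind(panel$chrom, format(panel$pos_bp, scientific = FALSE,
                                    trim = TRUE),
                paste0("var", panel$variant), "A", "T", ".", "PASS",
                info, "GT", t(gt))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pccollide",
    "##INFO=<ID=P1,Number=1,Type=Float,Description=\"Allele frequency in ancestral population 1\">",
    "##INFO=<ID=P0,Number=1,Type=Float,Description=\"Allele frequency in ancestral population 0\">",
    "##INFO=<ID=FEAT,Number=1,Type=String,Description=\"Latent feature id\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sprintf("sample%04d", seq_len(n))), collapse = "\t")
  )
  writeLines(c(header, apply(body, 1, paste, collapse = "\t")), vcf_path)
  if (!is.null(sidecar_path)) {
    side <- tibble::tibble(sample = sprintf("sample%04d", seq_len(n)),
                           pi_true = cohort$pi_true)
    if (!is.null(cohort$f)) {
      fmat <- as.data.frame(cohort$f)
      names(fmat) <- paste0("f_", colnames(cohort$f) %||%
                              seq_len(ncol(cohort$f)))
      side <- dplyr::bind_cols(side, fmat)
    }
    readr::write_tsv(side, sidecar_path)
  }
  invisible(vcf_path)
}

#' Read a cohort VCF written by [write_cohort_vcf()]
#'
#' Parses the VCF with the vcfR package and reconstructs the dosage matrix,
#' variant panel (from the INFO keys), and — when a sidecar is given — the
#' true admixture proportions and feature indicators.
#'
#' @param vcf_path VCF path.
#' @param sidecar_path Optional sidecar TSV path.
#' @return A list with `G`, `panel`, and (if sidecar present) `pi_true`
#'   and `f`.
#' @export
read_cohort_vcf <- function(vcf_path, sidecar_path = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package.")
  }
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  G <- t(matrix(c(`0/0` = 0L, `0/1` = 1L, `1/0` = 1L, `1/1` = 2L)[gt],
                nrow = nrow(gt)))
  info <- v@fix[, "INFO"]
  grab <- function(key) {
    val <- sub(sprintf(".*(?:^|;)%s=([^;]*).*", key), "\\1", info)
    ifelse(grepl(sprintf("(^|;)%s=", key), info), val, NA_character_)
  }
  panel <- variant_panel(
    chrom = v@fix[, "CHROM"],
    pos_bp = as.numeric(v@fix[, "POS"]),
    p1 = as.numeric(grab("P1")),
    p0 = as.numeric(grab("P0")),
    feature_id = grab("FEAT")
  )
  out <- list(G = unname(G), panel = panel)
  if (!is.null(sidecar_path)) {
    side <- readr::read_tsv(sidecar_path, show_col_types = FALSE)
    out$pi_true <- side$pi_true
    fcols <- grep("^f_", names(side), value = TRUE)
    if (length(fcols)) out$f <- as.matrix(side[fcols])
  }
  out
}

#' Write / read a variant panel as TSV
#'
#' @param panel A [variant_panel()].
#' @param path File path.
#' @return `write_panel_tsv` returns `path` invisibly; `read_panel_tsv`
#'   returns a [variant_panel()].
#' @export
write_panel_tsv <- function(panel, path) {
  readr::write_tsv(tibble::as_tibble(panel), path)
  invisible(path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  variant_panel(x$chrom, x$pos_bp, x$p1, x$p0,
                feature_id = x$feature_id %||% NA_character_)
}

#' Write PCA scores and loadings as TSV
#'
#' @param pca An `admix_pca`.
#' @param scores_path,loadings_path Output paths (`NULL` skips either).
#' @return Invisibly, the paths written.
#' @export
write_pca_tsv <- function(pca, scores_path = NULL, loadings_path = NULL) {
  if (!is.null(scores_path)) {
    readr::write_tsv(tidy(pca, "scores") |>
                       tidyr::pivot_wider(names_from = "pc",
                                          names_prefix = "PC",
                                          values_from = "score"),
                     scores_path)
  }
  if (!is.null(loadings_path)) {
    readr::write_tsv(tidy(pca, "loadings") |>
                       tidyr::pivot_wider(names_from = "pc",
                                          names_prefix = "PC",
                                          values_from = "loading"),
                     loadings_path)
  }
  invisible(c(scores_path, loadings_path))
}

#' Write a kept-variant index list as TSV
#'
#' @param panel A [variant_panel()].
#' @param keep Integer indices of retained variants.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_kept_variants_tsv <- function(panel, keep, path) {
  readr::write_tsv(dplyr::slice(tibble::as_tibble(panel), keep), path)
  invisible(path)
}
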