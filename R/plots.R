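# ggplot2 displays for the package's result types.

# cumulative genome coordinate for Manhattan-style x axes
genome_coords <- function(chrom, pos_bp) {
  d <- tibble::tibble(chrom = chrom, pos_bp = pos_bp)
  offsets <- d |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$pos_bp), .groups = "drop") |>
    dplyr::mutate(offset = cumsum(dplyr::lag(.data$len, default = 0)))
  dplyr::left_join(d, offsets, by = "chrom") |>
    dplyr::mutate(x = .data$offset + .data$pos_bp) |>
    dplyr::pull(.data$x)
}

#' Manhattan plot of an association scan
#'
#' Plots -log10(p) against genome position, coloured by chromosome, with a
#' dashed line at the significance threshold.
#'
#' @param object An `assoc_result` from [marginal_gwas()].
#' @param alpha Significance threshold drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot assoc_result
#' @export
autoplot.assoc_result <- function(object, alpha = 5e-8, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::filter(!is.na(.data$p)) |>
    dplyr::mutate(x = genome_coords(.data$chrom, .data$pos_bp),
                  logp = -log10(pmax(.data$p, 1e-300)))
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$logp,
                                  colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = "genome position", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' PC-genotype correlation plot
#'
#' The diagnostic display for spotting PCs that capture local genomic
#' features: |correlation| between each PC and every genotype, against
#' genome position, one panel per PC. Isolated peaks indicate a PC driven
#' by a few regions rather than genome-wide ancestry.
#'
#' @param object A `pc_corr` tibble from [pc_genotype_correlation()].
#' @param pcs Which PCs to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pc_corr
#' @export
autoplot.pc_corr <- function(object, pcs = 1:4, ...) {
  d <- dplyr::filter(tibble::as_tibble(object), .data$pc %in% pcs) |>
    dplyr::mutate(x = genome_coords(.data$chrom, .data$pos_bp))
  ggplot2::ggplot(d, ggplot2::aes(.data$x, abs(.data$corr),
                                  colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$pc)) +
    ggplot2::labs(x = "genome position", y = "|correlation(PC, genotype)|") +
    ggplot2::theme_minimal()
}

#' Expected-coefficient display for a bias table
#'
#' Expected large-sample effect estimates per adjustment model at the causal
#' and neutral variants, with the truth marked.
#'
#' @param object A `bias_table` from [bias_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bias_table
#' @export
autoplot.bias_table <- function(object, ...) {
  d <- dplyr::mutate(tibble::as_tibble(object),
                     variant = paste("variant", .data$variant))
  ggplot2::ggplot(d, ggplot2::aes(.data$model, .data$expected)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$truth),
                        linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$variant)) +
    ggplot2::labs(x = NULL, y = "expected effect estimate") +
    ggplot2::theme_minimal()
}

#' Spurious-association summary across strategies
#'
#' Mean spurious-chromosome count against causal effect size, one line per
#' adjustment strategy.
#'
#' @param object An `experiment_report` from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot experiment_report
#' @export
autoplot.experiment_report <- function(object, ...) {
  d <- summarize_experiment(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$beta, .data$mean_spurious,
                                  colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$class)) +
    ggplot2::labs(x = "causal effect size",
                  y = "mean spurious chromosomes") +
    ggplot2::theme_minimal()
}

#' Sorted admixture-proportion bar plot
#'
#' The conventional display of ancestral heterogeneity: one thin vertical
#' bar per individual, sorted by ancestry proportion.
#'
#' @param pi Vector of admixture proportions.
#' @return A ggplot object.
#' @export
plot_admixture <- function(pi) {
  d <- tibble::tibble(individual = seq_along(pi), pi = sort(pi)) |>
    tidyr::pivot_longer(-"individual", names_to = "component",
                        values_to = "proportion")
  ggplot2::ggplot(d, ggplot2::aes(.data$individual, .data$proportion)) +
    ggplot2::geom_col(width = 1, fill = "#2166ac") +
    ggplot2::labs(x = "individual (sorted)",
                  y = "ancestry proportion (population 1)") +
    ggplot2::theme_minimal()
}
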