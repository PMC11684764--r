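# Config-driven simulation-study orchestration: cohorts -> PCA regimes ->
# adjustment strategies -> association scans -> spurious-association report.

#' Configure a simulation experiment
#'
#' Bundles the full factorial design of the simulation study: cohort
#' parameters, causal-variant selection rules, the effect-size grid, the
#' adjustment strategies to compare, pre-processing regimes, significance
#' threshold, replicate count and master seed.
#'
#' A strategy is a list with elements `label` (unique), `type` (one of
#' `"none"`, `"admixture"`, `"pcs"`, `"custom"`), and for `type = "pcs"`
#' the number of components `k` and the pre-processing `regime`; for
#' `type = "custom"` a function `make(cohort, pca_list, trait)` returning a
#' covariate matrix.
#'
#' @param n Individuals per cohort.
#' @param panel A [variant_panel()] shared by all replicates.
#' @param admixture An [admixture_model()].
#' @param features List of [feature_spec()] objects.
#' @param betas Effect-size grid for the causal variant; default the
#'   conventional grid `c(0, 0.25, 0.5, 1, 2, 4, 8)`.
#' @param beta_pi Direct ancestry effect on the trait (0 in the standard
#'   design).
#' @param strategies List of strategy specs (see Details); default compares
#'   no adjustment, estimated admixture proportions, 1 PC and 4 PCs without
#'   pre-processing, and 4 PCs after exclusion plus pruning.
#' @param regimes Pre-processing regimes needed by the strategies.
#' @param selection_rules Passed to [select_causal_variants()].
#' @param causal_per_class How many causal variants to draw per class.
#' @param alpha Genome-wide significance threshold (5e-8 array-like preset;
#'   use 5e-9 for sequence-like panels).
#' @param replicates Number of simulation replicates (>= 1).
#' @param k Number of PCs to compute per regime.
#' @param exclude_regions_list A [region_list()] for exclusion regimes;
#'   `NULL` means none available.
#' @param seed Master seed.
#' @return An `experiment_config` object (a validated list).
#' @export
experiment_config <- function(n = 2000,
                              panel = synthetic_panel(6, 2000, seed = 100),
                              admixture = admixture_model("beta", 8, 2),
                              features = list(),
                              betas = c(0, 0.25, 0.5, 1, 2, 4, 8),
                              beta_pi = 0,
                              strategies = default_strategies(),
                              regimes = character(0),
                              selection_rules = list(),
                              causal_per_class = 1L,
                              alpha = 5e-8,
                              replicates = 50L,
                              k = 4L,
                              exclude_regions_list = NULL,
                              seed = 1L) {
  labels <- vapply(strategies, `[[`, "", "label")
  if (anyDuplicated(labels)) abort("strategy labels must be unique.")
  if (replicates < 1) abort("`replicates` must be >= 1.")
  needed <- unique(c("none", unlist(lapply(strategies, function(s)
    if (identical(s$type, "pcs")) s$regime else NULL))))
  structure(list(n = n, panel = panel, admixture = admixture,
                 features = features, betas = betas, beta_pi = beta_pi,
                 strategies = strategies,
                 regimes = unique(c(regimes, needed)),
                 selection_rules = selection_rules,
                 causal_per_class = as.integer(causal_per_class),
                 alpha = alpha, replicates = as.integer(replicates),
                 k = as.integer(k),
                 exclude_regions_list = exclude_regions_list,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' @describeIn experiment_config The default strategy set.
#' @export
default_strategies <- function() {
  list(
    list(label = "none", type = "none"),
    list(label = "admixture", type = "admixture"),
    list(label = "pc1_none", type = "pcs", k = 1L, regime = "none"),
    list(label = "pc4_none", type = "pcs", k = 4L, regime = "none"),
    list(label = "pc4_both", type = "pcs", k = 4L, regime = "both")
  )
}

#' Label causal-variant classes from loadings and frequency differences
#'
#' Reproduces the causal-variant design of the simulation study: for each of
#' the first `n_pcs` PCs, the `top_per_chrom` variants per chromosome with
#' the highest absolute loadings form the `high_loading` class (with the
#' per-chromosome maxima additionally labelled `highest_on_chromosome`);
#' variants with |loading| < `loading_max` on all those PCs are
#' `low_loading`, split into `low_loading_large_delta`
#' (ancestral frequency difference |Delta| > `delta_large`) and
#' `low_loading_small_delta` (|Delta| < `delta_small`). Defaults follow the
#' conventional thresholds (|loading| < 0.0008, |Delta| > 0.6 or < 0.005);
#' note the loading threshold is calibrated to array-scale panels of
#' hundreds of thousands of variants and should be rescaled (loadings are
#' unit-norm, so typical magnitude is m'^-1/2) for small synthetic panels.
#'
#' @param pca An `admix_pca` computed without LD-based pre-processing.
#' @param panel The matching [variant_panel()].
#' @param loading_max Low-loading threshold.
#' @param delta_large,delta_small Frequency-difference cutoffs.
#' @param top_per_chrom High-loading variants per chromosome per PC.
#' @param n_pcs Number of leading PCs inspected.
#' @return Tibble `variant`, `chrom`, `class` (one row per variant-class
#'   membership). Empty classes trigger a warning and are omitted.
#' @export
select_causal_variants <- function(pca, panel, loading_max = 8e-4,
                                   delta_large = 0.6, delta_small = 0.005,
                                   top_per_chrom = 10L, n_pcs = 4L) {
  n_pcs <- min(n_pcs, ncol(pca$loadings))
  ld <- tibble::tibble(
    variant = rep(pca$used_variants, n_pcs),
    pc = rep(seq_len(n_pcs), each = length(pca$used_variants)),
    loading = as.vector(pca$loadings[, seq_len(n_pcs), drop = FALSE])
  ) |>
    dplyr::left_join(dplyr::select(panel, "variant", "chrom", "p1", "p0"),
                     by = "variant") |>
    dplyr::mutate(delta = .data$p1 - .data$p0)
  high <- ld |>
    dplyr::group_by(.data$pc, .data$chrom) |>
    dplyr::slice_max(abs(.data$loading), n = top_per_chrom,
                     with_ties = FALSE) |>
    dplyr::ungroup()
  highest <- ld |>
    dplyr::group_by(.data$pc, .data$chrom) |>
    dplyr::slice_max(abs(.data$loading), n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
  low_all <- ld |>
    dplyr::group_by(.data$variant, .data$chrom, .data$delta) |>
    dplyr::summarise(max_abs_loading = max(abs(.data$loading)),
                     .groups = "drop") |>
    dplyr::filter(.data$max_abs_loading < loading_max)
  classes <- dplyr::bind_rows(
    dplyr::transmute(dplyr::filter(low_all, abs(.data$delta) > delta_large),
                     .data$variant, .data$chrom,
                     class = "low_loading_large_delta"),
    dplyr::transmute(dplyr::filter(low_all, abs(.data$delta) < delta_small),
                     .data$variant, .data$chrom,
                     class = "low_loading_small_delta"),
    dplyr::transmute(high, .data$variant, .data$chrom,
                     class = "high_loading"),
    dplyr::transmute(highest, .data$variant, .data$chrom,
                     class = "highest_on_chromosome")
  ) |>
    dplyr::distinct(.data$variant, .data$class, .keep_all = TRUE)
  expected <- c("low_loading_large_delta", "low_loading_small_delta",
                "high_loading", "highest_on_chromosome")
  missing <- setdiff(expected, unique(classes$class))
  if (length(missing)) {
    warn(sprintf("empty causal-variant class(es) skipped: %s",
                 paste(missing, collapse = ", ")))
  }
  classes
}

#' Run the full factorial simulation experiment
#'
#' For each replicate: simulates a cohort, runs PCA under each required
#' pre-processing regime, selects causal variants by class from the
#' unprocessed-regime loadings, simulates a trait for every (causal variant,
#' effect size) pair, fits every adjustment strategy with
#' [marginal_gwas()], and records the spurious-chromosome count, the
#' genomic inflation factor, and the effect estimate at the causal variant.
#' Deterministic given the config seed; failures in any cell are recorded
#' in the `error` column and the run continues.
#'
#' @param config An [experiment_config()].
#' @param progress Emit per-replicate progress messages to stderr.
#' @return A tibble of class `experiment_report` with one row per
#'   (replicate, causal variant class, causal variant, beta, strategy).
#' @export
run_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- list()
  for (rep_i in seq_len(config$replicates)) {
    t0 <- Sys.time()
    rep_seed <- child_seed(config$seed, paste0("replicate-", rep_i))
    cohort <- simulate_cohort(config$n, config$panel, config$admixture,
                              features = config$features, seed = rep_seed)
    pca_list <- list()
    regions <- config$exclude_regions_list %||%
      region_list(character(0), numeric(0), numeric(0))
    for (regime in config$regimes) {
      keep <- preprocess_variants(cohort$G, cohort$panel, regime = regime,
                                  regions = regions)
      pca_list[[regime]] <- run_pca(cohort$G, keep, k = config$k)
    }
    classes <- rlang::exec(select_causal_variants,
                           pca = pca_list[["none"]], panel = cohort$panel,
                           !!!config$selection_rules)
    picked <- classes |>
      dplyr::group_by(.data$class) |>
      dplyr::slice_head(n = config$causal_per_class) |>
      dplyr::ungroup()
    pihat <- estimate_admixture(cohort$A)
    for (ci in seq_len(nrow(picked))) {
      causal <- picked$variant[ci]
      causal_chrom <- cohort$panel$chrom[causal]
      for (beta in config$betas) {
        y <- simulate_trait(cohort, causal, beta1 = beta,
                            beta_pi = config$beta_pi,
                            seed = child_seed(rep_seed,
                                              paste0("trait-", causal, "-", beta)))
        for (strat in config$strategies) {
          row <- tibble::tibble(
            replicate = rep_i, class = picked$class[ci],
            causal_variant = causal, causal_chrom = causal_chrom,
            beta = beta, strategy = strat$label,
            n_spurious_chroms = NA_integer_, lambda = NA_real_,
            beta_hat_causal = NA_real_, error = NA_character_)
          res <- tryCatch({
            covs <- switch(strat$type,
              none = NULL,
              admixture = cbind(pihat = pihat),
              pcs = pca_list[[strat$regime]]$scores[, seq_len(strat$k),
                                                    drop = FALSE],
              custom = strat$make(cohort, pca_list, y))
            scan <- marginal_gwas(y, cohort$G, cohort$panel, covs,
                                  label = strat$label)
            row$n_spurious_chroms <-
              count_spurious_chromosomes(scan, causal_chrom, config$alpha)
            row$lambda <- genomic_inflation(scan)
            row$beta_hat_causal <- scan$beta[causal]
            row
          }, error = function(e) {
            row$error <- conditionMessage(e)
            row
          })
          rows[[length(rows) + 1L]] <- res
        }
      }
    }
    if (progress) {
      message(sprintf("replicate %d/%d done in %.1fs", rep_i,
                      config$replicates,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("experiment_report", class(out))
  attr(out, "config") <- config
  out
}

#' Aggregate an experiment report
#'
#' Group means of the spurious-association count, inflation factor and
#' causal-variant effect estimate over replicates, by strategy, causal-variant
#' class and effect size.
#'
#' @param report An `experiment_report` from [run_experiment()].
#' @return A tibble of per-cell means with replicate counts.
#' @export
summarize_experiment <- function(report) {
  report |>
    dplyr::filter(is.na(.data$error)) |>
    dplyr::group_by(.data$strategy, .data$class, .data$beta) |>
    dplyr::summarise(
      mean_spurious = mean(.data$n_spurious_chroms),
      mean_lambda = mean(.data$lambda),
      mean_beta_hat = mean(.data$beta_hat_causal),
      n_reps = dplyr::n(), .groups = "drop")
}

#' Write experiment outputs as TSV tables
#'
#' Writes the raw per-cell report and its aggregation; both are plain TSV.
#'
#' @param report An `experiment_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  raw <- file.path(dir, "experiment_cells.tsv")
  agg <- file.path(dir, "experiment_summary.tsv")
  readr::write_tsv(tibble::as_tibble(report), raw)
  readr::write_tsv(summarize_experiment(report), agg)
  invisible(c(raw, agg))
}
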