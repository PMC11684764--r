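# PCA pre-processing (MAF filter, region exclusion, LD pruning), SVD-based
# PCA of standardized genotypes, and loading/correlation diagnostics.

#' Filter variants by minor allele frequency
#'
#' Retains variants whose sample minor allele frequency is at least
#' `maf_min`. The default 0.01 reproduces the conventional pre-PCA filter.
#'
#' @param G Dosage matrix (n x m), entries in \{0, 1, 2\}.
#' @param panel A [variant_panel()] (used only for dimension checking).
#' @param maf_min Minimum minor allele frequency, in \[0, 0.5\].
#' @return Integer vector of retained variant indices.
#' @export
maf_filter <- function(G, panel = NULL, maf_min = 0.01) {
  if (maf_min < 0 || maf_min > 0.5) abort("`maf_min` must lie in [0, 0.5].")
  if (!is.null(panel)) stopifnot(nrow(panel) == ncol(G))
  p <- colMeans(G) / 2
  maf <- pmin(p, 1 - p)
  which(maf >= maf_min)
}

#' Exclude variants falling in listed regions
#'
#' Retains variants whose (chrom, pos) fall inside none of the regions.
#' Regions are 1-based inclusive; a variant exactly on a boundary counts as
#' inside and is excluded.
#'
#' @param panel A [variant_panel()].
#' @param regions A [region_list()] (e.g., [high_ld_regions()]).
#' @return Integer vector of retained variant indices.
#' @export
exclude_regions <- function(panel, regions) {
  if (is.null(regions) || nrow(regions) == 0L) return(seq_len(nrow(panel)))
  inside <- rep(FALSE, nrow(panel))
  for (r in seq_len(nrow(regions))) {
    inside <- inside | (panel$chrom == regions$chrom[r] &
                          panel$pos_bp >= regions$start_bp[r] &
                          panel$pos_bp <= regions$end_bp[r])
  }
  which(!inside)
}

#' Greedy sliding-window LD pruning
#'
#' Left-to-right scan per chromosome: a candidate variant is kept iff its
#' squared Pearson correlation (on dosages) with every already-kept variant
#' within `window_bp` base pairs is below `r2_max`. The scan guarantees that
#' no kept pair within the window has \eqn{r^2 \ge} `r2_max`; when two
#' variants conflict, the leftmost is kept. Zero-variance columns are
#' treated as uncorrelated with everything (they are normally removed
#' earlier by [maf_filter()]).
#'
#' @param G Dosage matrix (n x m).
#' @param panel A [variant_panel()]; variants must be position-sorted within
#'   chromosome.
#' @param r2_max Squared-correlation threshold in (0, 1\]; default 0.1.
#' @param window_bp Physical window in base pairs; default 5e5 (0.5 Mb).
#' @param candidates Optional integer vector restricting the scan to a subset
#'   of variants (e.g., the output of [maf_filter()]).
#' @return Integer vector of kept variant indices (subset of `candidates`).
#' @export
ld_prune <- function(G, panel, r2_max = 0.1, window_bp = 5e5,
                     candidates = seq_len(ncol(G))) {
  if (r2_max <= 0 || r2_max > 1) abort("`r2_max` must lie in (0, 1].")
  if (window_bp <= 0) abort("`window_bp` must be positive.")
  keep_all <- integer(0)
  for (ch in unique(panel$chrom[candidates])) {
    idx <- candidates[panel$chrom[candidates] == ch]
    idx <- idx[order(panel$pos_bp[idx])]
    Gc <- G[, idx, drop = FALSE]
    mu <- colMeans(Gc)
    cent <- sweep(Gc, 2, mu, "-")
    ss <- colSums(cent^2)
    kept <- integer(0) # positions within idx
    for (j in seq_along(idx)) {
      if (ss[j] == 0) { kept <- c(kept, j); next } # zero variance: r2 == 0
      near <- kept[panel$pos_bp[idx[kept]] > panel$pos_bp[idx[j]] - window_bp &
                     ss[kept] > 0]
      ok <- TRUE
      if (length(near)) {
        num <- crossprod(cent[, near, drop = FALSE], cent[, j])^2
        r2 <- num / (ss[near] * ss[j])
        if (any(r2 >= r2_max)) ok <- FALSE
      }
      if (ok) kept <- c(kept, j)
    }
    keep_all <- c(keep_all, idx[kept])
  }
  sort(keep_all)
}

#' Apply a named pre-processing regime
#'
#' Convenience composition of [maf_filter()], [exclude_regions()] and
#' [ld_prune()] in the four regimes compared throughout the package:
#' `"none"` (MAF filter only), `"exclude"` (MAF + region exclusion),
#' `"prune"` (MAF + LD pruning), and `"both"`.
#'
#' @param G Dosage matrix.
#' @param panel A [variant_panel()].
#' @param regime One of `"none"`, `"exclude"`, `"prune"`, `"both"`.
#' @param regions A [region_list()] for the exclusion regimes.
#' @param maf_min,r2_max,window_bp Filter parameters.
#' @return Integer vector of retained variant indices.
#' @export
preprocess_variants <- function(G, panel,
                                regime = c("none", "exclude", "prune", "both"),
                                regions = NULL, maf_min = 0.01,
                                r2_max = 0.1, window_bp = 5e5) {
  regime <- match.arg(regime)
  keep <- maf_filter(G, panel, maf_min)
  if (regime %in% c("exclude", "both")) {
    if (is.null(regions)) abort("`regions` required for exclusion regimes.")
    keep <- intersect(keep, exclude_regions(panel, regions))
  }
  if (regime %in% c("prune", "both")) {
    keep <- ld_prune(G, panel, r2_max = r2_max, window_bp = window_bp,
                     candidates = keep)
  }
  sort(keep)
}

#' Principal component analysis of standardized genotypes
#'
#' Computes the top-k singular value decomposition \eqn{X = U D V^\top} of
#' the standardized genotype matrix
#' \eqn{x_{ij} = (g_{ij} - 2\hat p_j)/\sqrt{2 \hat p_j (1 - \hat p_j)}},
#' with \eqn{\hat p_j} the sample allele frequency, restricted to the kept
#' variants. The factorization is obtained through an eigendecomposition of
#' the smaller Gram matrix (the genetic relationship matrix \eqn{XX^\top}
#' when n <= m', else \eqn{X^\top X}), which is algebraically equivalent to
#' the SVD and is how genotype-PCA software computes it at scale. Loading
#' signs follow the convention that each loading column's largest-magnitude
#' entry is positive.
#'
#' @param G Dosage matrix (n x m).
#' @param keep Integer vector of variant indices to use (e.g., from
#'   [preprocess_variants()]).
#' @param k Number of components (k <= min(n, length(keep))).
#' @return An object of class `admix_pca`: list with `scores` (n x k, columns
#'   of U, unit norm), `singular_values` (length k, non-increasing),
#'   `loadings` (m' x k, columns of V), and `used_variants` (= `keep`).
#' @export
run_pca <- function(G, keep = seq_len(ncol(G)), k = 10) {
  n <- nrow(G)
  mp <- length(keep)
  if (k > min(n, mp)) abort("`k` must not exceed min(n, number of kept variants).")
  Gk <- G[, keep, drop = FALSE]
  p <- colMeans(Gk) / 2
  if (any(p <= 0) || any(p >= 1) ||
      any(colMeans(Gk^2) - (2 * p)^2 <= 0)) {
    abort("zero-variance variant among kept columns; run maf_filter first.")
  }
  X <- sweep(sweep(Gk, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
  if (n <= mp) {
    e <- eigen(tcrossprod(X), symmetric = TRUE)
    d <- sqrt(pmax(e$values[seq_len(k)], 0))
    U <- e$vectors[, seq_len(k), drop = FALSE]
    V <- crossprod(X, U)
    V <- sweep(V, 2, ifelse(d > 0, d, 1), "/")
  } else {
    e <- eigen(crossprod(X), symmetric = TRUE)
    d <- sqrt(pmax(e$values[seq_len(k)], 0))
    V <- e$vectors[, seq_len(k), drop = FALSE]
    U <- X %*% V
    U <- sweep(U, 2, ifelse(d > 0, d, 1), "/")
  }
  # sign convention: largest-|entry| of each loading column is positive
  for (j in seq_len(k)) {
    s <- sign(V[which.max(abs(V[, j])), j])
    if (s < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
  }
  structure(list(scores = U, singular_values = d, loadings = V,
                 used_variants = keep, allele_freq = p),
            class = "admix_pca")
}

#' @export
print.admix_pca <- function(x, ...) {
  cat(sprintf("<admix_pca> %d samples, %d variants, %d components\n",
              nrow(x$scores), length(x$used_variants),
              length(x$singular_values)))
  cat("  singular values:", paste(signif(head(x$singular_values, 5), 4),
                                  collapse = ", "), "...\n")
  invisible(x)
}

#' @describeIn run_pca Tidy scores (`matrix = "scores"`), loadings
#'   (`"loadings"`), or singular values (`"d"`) as a long tibble.
#' @param x An `admix_pca` object.
#' @param matrix Which component to tidy.
#' @param ... Unused.
#' @method tidy admix_pca
#' @export
tidy.admix_pca <- function(x, matrix = c("scores", "loadings", "d"), ...) {
  matrix <- match.arg(matrix)
  k <- length(x$singular_values)
  switch(matrix,
    scores = tibble::tibble(
      sample = rep(seq_len(nrow(x$scores)), k),
      pc = rep(seq_len(k), each = nrow(x$scores)),
      score = as.vector(x$scores)),
    loadings = tibble::tibble(
      variant = rep(x$used_variants, k),
      pc = rep(seq_len(k), each = nrow(x$loadings)),
      loading = as.vector(x$loadings)),
    d = tibble::tibble(pc = seq_len(k), singular_value = x$singular_values,
                       variance_explained = x$singular_values^2 /
                         sum(x$singular_values^2))
  )
}

#' @describeIn run_pca One-row summary (dimensions, variance captured by the
#'   retained components).
#' @method glance admix_pca
#' @export
glance.admix_pca <- function(x, ...) {
  tibble::tibble(n = nrow(x$scores), m_used = length(x$used_variants),
                 k = length(x$singular_values),
                 d1 = x$singular_values[1])
}

#' Correlation between PC scores and genotypes
#'
#' Pearson correlation of each PC score vector with each variant's dosage
#' vector, computed for all panel variants (not only those used in the PCA).
#' Peaks of |correlation| localized to a few regions indicate that a PC
#' captures a local genomic feature rather than genome-wide ancestry.
#' Zero-variance genotype columns get correlation 0 with `zero_variance`
#' flagged.
#'
#' @param pca An `admix_pca` from [run_pca()].
#' @param G Dosage matrix for the same cohort (all variants).
#' @param panel The matching [variant_panel()].
#' @return A tibble of class `pc_corr` with columns `variant`, `chrom`,
#'   `pos_bp`, `pc`, `corr`, `zero_variance`.
#' @export
pc_genotype_correlation <- function(pca, G, panel) {
  stopifnot(nrow(G) == nrow(pca$scores), ncol(G) == nrow(panel))
  s <- apply(G, 2, sd)
  zv <- s == 0 | !is.finite(s)
  CC <- matrix(0, ncol(G), ncol(pca$scores))
  if (any(!zv)) {
    CC[!zv, ] <- t(suppressWarnings(cor(pca$scores, G[, !zv, drop = FALSE])))
  }
  k <- ncol(pca$scores)
  out <- tibble::tibble(
    variant = rep(panel$variant, k),
    chrom = rep(panel$chrom, k),
    pos_bp = rep(panel$pos_bp, k),
    pc = rep(seq_len(k), each = nrow(panel)),
    corr = as.vector(CC),
    zero_variance = rep(zv, k)
  )
  class(out) <- c("pc_corr", class(out))
  out
}

#' Detect loading peaks in a PC-genotype correlation table
#'
#' Automates the visual inspection of PC-genotype correlation plots: for
#' each PC, finds maximal runs of variants with |correlation| >=
#' `abs_corr_min`, merging runs whose flagged variants are within
#' `window_bp` of each other on the same chromosome. An empty result means
#' no PC shows localized structure at that threshold.
#'
#' @param corr_table A `pc_corr` tibble from [pc_genotype_correlation()].
#' @param window_bp Merge distance in base pairs; default 5e5.
#' @param abs_corr_min Absolute-correlation threshold; default 0.3.
#' @return Tibble with columns `pc`, `chrom`, `start_bp`, `end_bp`,
#'   `n_variants`, `max_abs_corr` (zero rows if no peaks).
#' @export
detect_loading_peaks <- function(corr_table, window_bp = 5e5,
                                 abs_corr_min = 0.3) {
  hits <- dplyr::filter(corr_table, abs(.data$corr) >= abs_corr_min,
                        !.data$zero_variance)
  if (nrow(hits) == 0L) {
    return(tibble::tibble(pc = integer(), chrom = character(),
                          start_bp = numeric(), end_bp = numeric(),
                          n_variants = integer(), max_abs_corr = numeric()))
  }
  hits |>
    dplyr::group_by(.data$pc, .data$chrom) |>
    dplyr::arrange(.data$pos_bp, .by_group = TRUE) |>
    dplyr::mutate(gap = c(0, diff(.data$pos_bp)),
                  run = cumsum(.data$gap > window_bp)) |>
    dplyr::group_by(.data$pc, .data$chrom, .data$run) |>
    dplyr::summarise(start_bp = min(.data$pos_bp),
                     end_bp = max(.data$pos_bp),
                     n_variants = dplyr::n(),
                     max_abs_corr = max(abs(.data$corr)),
                     .groups = "drop") |>
    dplyr::select(-"run") |>
    dplyr::arrange(.data$pc, .data$chrom, .data$start_bp)
}
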