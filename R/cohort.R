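# Simulated admixed cohorts: local ancestry, genotypes, traits, colliders.

#' Draw local ancestry counts
#'
#' Generates the n x m matrix `A` of local ancestry counts
#' \eqn{a_{ij} \in \{0, 1, 2\}}: the number of allele copies individual `i`
#' inherited from ancestral population 1 at variant `j`. Under
#' `mode = "independent"` (the default), \eqn{a_{ij} \sim
#' \mathrm{Binomial}(2, \pi_i)} independently across variants, the exact
#' assumption underlying the closed-form effect-size theory. Under
#' `mode = "markov"`, each of the two ancestry chains per individual follows a
#' two-state Markov chain along physical position with stationary probability
#' \eqn{\pi_i} and the given ancestry-switch rate, giving positionally
#' autocorrelated ancestry tracts.
#'
#' @param pi Vector of admixture proportions in \[0, 1\].
#' @param panel A [variant_panel()] supplying chromosome/position structure.
#' @param mode `"independent"` or `"markov"`.
#' @param switch_rate_per_mb Expected ancestry switches per megabase
#'   (markov mode only).
#' @param seed Integer seed.
#' @return Integer matrix A (n x m) with entries in \{0, 1, 2\}.
#' @examples
#' panel <- synthetic_panel(n_chrom = 1, variants_per_chrom = 20, seed = 1)
#' A <- draw_local_ancestry(c(0, 0.5, 1), panel, seed = 2)
#' rowMeans(A) / 2
#' @export
draw_local_ancestry <- function(pi, panel, mode = c("independent", "markov"),
                                switch_rate_per_mb = 1, seed = 1) {
  mode <- match.arg(mode)
  check_prob(pi, "pi")
  n <- length(pi)
  m <- nrow(panel)
  with_seed(seed, {
    if (mode == "independent") {
      A <- matrix(rbinom(n * m, 2L, rep(pi, m)), n, m)
    } else {
      A <- matrix(0L, n, m)
      for (ch in unique(panel$chrom)) {
        idx <- which(panel$chrom == ch)
        pos <- panel$pos_bp[idx]
        # two independent haploid chains per individual
        h1 <- rbinom(n, 1L, pi)
        h2 <- rbinom(n, 1L, pi)
        A[, idx[1]] <- h1 + h2
        if (length(idx) > 1L) {
          for (s in 2:length(idx)) {
            stay <- exp(-switch_rate_per_mb * (pos[s] - pos[s - 1]) / 1e6)
            flip1 <- runif(n) > stay
            flip2 <- runif(n) > stay
            h1 <- ifelse(flip1, rbinom(n, 1L, pi), h1)
            h2 <- ifelse(flip2, rbinom(n, 1L, pi), h2)
            A[, idx[s]] <- h1 + h2
          }
        }
      }
      A
    }
  })
}

#' Draw genotype dosages given local ancestry
#'
#' Generates the n x m dosage matrix `G` with entries in \{0, 1, 2\}. Each
#' allele copy inherited from ancestral population k carries the counted
#' allele with probability \eqn{p_{jk}}, so that for a non-feature variant
#' \eqn{g_{ij} \mid \pi_i \sim \mathrm{Binomial}(2, q_j(\pi_i))} with
#' \eqn{q_j(\pi) = \pi p_{j1} + (1 - \pi) p_{j0}} when local ancestry is
#' binomial. Inside the regions of each [feature_spec()], both ancestral
#' frequencies are shifted by `+strength` for carriers of the latent
#' indicator and `-strength` for non-carriers, then clipped to
#' \[0.01, 0.99\]; this induces strong mutual correlation among the
#' feature's variants across all its regions.
#'
#' @param A Local ancestry matrix from [draw_local_ancestry()].
#' @param panel A [variant_panel()].
#' @param features List of [feature_spec()] objects (may be empty).
#' @param f Matrix (n x length(features)) or vector of latent 0/1 carrier
#'   indicators, one column per feature.
#' @param seed Integer seed.
#' @return Integer dosage matrix G (n x m).
#' @export
draw_genotypes <- function(A, panel, features = list(), f = NULL, seed = 1) {
  n <- nrow(A)
  m <- ncol(A)
  stopifnot(nrow(panel) == m)
  if (length(features) && is.null(f)) {
    abort("latent indicators `f` are required when features are supplied.")
  }
  if (!is.null(f)) f <- as.matrix(f)
  feat_cols <- integer(0)
  feat_shift <- list()
  for (k in seq_along(features)) {
    memb <- feature_members(panel, features[[k]])
    if (!any(memb)) next
    feat_cols <- c(feat_cols, which(memb))
    s <- features[[k]]$strength * (2 * f[, k] - 1) # +s carriers, -s otherwise
    feat_shift <- c(feat_shift, rep(list(s), sum(memb)))
  }
  with_seed(seed, {
    G <- matrix(0L, n, m)
    # bulk columns: probabilities constant within column
    bulk <- setdiff(seq_len(m), feat_cols)
    block <- 2000L
    for (start in if (length(bulk)) seq(1, length(bulk), by = block) else integer(0)) {
      cols <- bulk[start:min(start + block - 1L, length(bulk))]
      Ab <- A[, cols, drop = FALSE]
      p1 <- rep(panel$p1[cols], each = n)
      p0 <- rep(panel$p0[cols], each = n)
      G[, cols] <- rbinom(length(Ab), Ab, p1) +
        rbinom(length(Ab), 2L - Ab, p0)
    }
    # feature columns: per-individual shifted probabilities
    for (i in seq_along(feat_cols)) {
      j <- feat_cols[i]
      p1 <- pmin(pmax(panel$p1[j] + feat_shift[[i]], 0.01), 0.99)
      p0 <- pmin(pmax(panel$p0[j] + feat_shift[[i]], 0.01), 0.99)
      G[, j] <- rbinom(n, A[, j], p1) + rbinom(n, 2L - A[, j], p0)
    }
    G
  })
}

#' Simulate a two-way admixed cohort
#'
#' One-stop generator: draws admixture proportions, latent feature
#' indicators, local ancestry, and genotypes, expanding `seed` into
#' deterministic per-stage child seeds (recorded in `seed_record`).
#'
#' @param n Number of individuals.
#' @param panel A [variant_panel()]; defaults to [synthetic_panel()].
#' @param admixture An [admixture_model()].
#' @param features List of [feature_spec()] objects.
#' @param ancestry_mode Passed to [draw_local_ancestry()].
#' @param switch_rate_per_mb Passed to [draw_local_ancestry()].
#' @param seed Integer seed.
#' @return An object of class `admix_cohort`: a list with dosage matrix `G`,
#'   local-ancestry matrix `A`, true proportions `pi_true`, `panel`, latent
#'   indicator matrix `f`, and `seed_record`.
#' @examples
#' ch <- simulate_cohort(n = 50, panel = synthetic_panel(2, 30, seed = 1),
#'                       seed = 7)
#' dim(ch$G)
#' @export
simulate_cohort <- function(n,
                            panel = synthetic_panel(),
                            admixture = admixture_model("beta", 8, 2),
                            features = list(),
                            ancestry_mode = "independent",
                            switch_rate_per_mb = 1,
                            seed = 1) {
  seeds <- c(
    admixture = child_seed(seed, "admixture"),
    feature = child_seed(seed, "feature"),
    ancestry = child_seed(seed, "ancestry"),
    genotype = child_seed(seed, "genotype")
  )
  pi_true <- draw_admixture(admixture, n, seeds[["admixture"]])
  f <- NULL
  if (length(features)) {
    f <- with_seed(seeds[["feature"]], vapply(
      features, function(ft) rbinom(n, 1L, ft$carrier_freq), integer(n)
    ))
    f <- matrix(f, nrow = n)
    colnames(f) <- vapply(features, `[[`, "", "id")
  }
  A <- draw_local_ancestry(pi_true, panel, mode = ancestry_mode,
                           switch_rate_per_mb = switch_rate_per_mb,
                           seed = seeds[["ancestry"]])
  G <- draw_genotypes(A, panel, features = features, f = f,
                      seed = seeds[["genotype"]])
  structure(list(G = G, A = A, pi_true = pi_true, panel = panel, f = f,
                 features = features, seed_record = seeds),
            class = "admix_cohort")
}

#' @export
print.admix_cohort <- function(x, ...) {
  cat(sprintf("<admix_cohort> %d individuals x %d variants (%d chromosomes)\n",
              nrow(x$G), ncol(x$G), length(unique(x$panel$chrom))))
  cat(sprintf("  mean pi = %.3f, var pi = %.4f, features: %d\n",
              mean(x$pi_true), var(x$pi_true), length(x$features)))
  invisible(x)
}

#' @describeIn simulate_cohort Variant-level summary: panel metadata plus
#'   sample allele frequency.
#' @param x An `admix_cohort`.
#' @param ... Unused.
#' @method tidy admix_cohort
#' @export
tidy.admix_cohort <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x$panel),
                freq = colMeans(x$G) / 2,
                delta = .data$p1 - .data$p0)
}

#' @describeIn simulate_cohort One-row cohort summary.
#' @method glance admix_cohort
#' @export
glance.admix_cohort <- function(x, ...) {
  tibble::tibble(n = nrow(x$G), m = ncol(x$G),
                 n_chrom = length(unique(x$panel$chrom)),
                 mean_pi = mean(x$pi_true), var_pi = var(x$pi_true),
                 n_features = length(x$features))
}

#' Simulate a quantitative trait
#'
#' Generates \eqn{y_i = \beta_1 g_{i j^*} + \beta_\pi \pi_i + \epsilon_i}
#' with \eqn{\epsilon_i \sim N(0, \mathrm{noise\_sd}^2)} i.i.d.: a trait
#' driven by a single causal variant plus an optional direct effect of global
#' ancestry.
#'
#' @param cohort An `admix_cohort`.
#' @param causal_index Column index \eqn{j^*} of the causal variant.
#' @param beta1 Effect size per allele of the causal variant.
#' @param beta_pi Direct effect of global ancestry on the trait.
#' @param noise_sd Residual standard deviation (> 0); default 1.
#' @param seed Integer seed.
#' @return Numeric trait vector of length n.
#' @export
simulate_trait <- function(cohort, causal_index, beta1, beta_pi = 0,
                           noise_sd = 1, seed = 1) {
  stopifnot(inherits(cohort, "admix_cohort"),
            causal_index >= 1, causal_index <= ncol(cohort$G))
  if (!is.finite(noise_sd) || noise_sd <= 0) {
    abort("`noise_sd` must be > 0.")
  }
  with_seed(seed,
    beta1 * cohort$G[, causal_index] + beta_pi * cohort$pi_true +
      rnorm(nrow(cohort$G), 0, noise_sd))
}

#' Construct an artificial collider covariate
#'
#' Builds \eqn{z = w_1\,\mathrm{std}(g_\mathrm{causal}) +
#' w_2\,\mathrm{std}(g_\mathrm{other}) + \mathrm{noise}}, re-standardized to
#' mean 0 and variance 1, where std() is sample standardization. Such a
#' variable mimics a principal component that captures the genotypes of two
#' specific variants rather than genome-wide ancestry: adjusting for it when
#' testing `g_other` opens a collider path through `g_causal`.
#'
#' @param g_causal,g_other Dosage vectors of equal length. The two variants
#'   are expected to sit on distinct chromosomes; pass `chrom` to have this
#'   checked.
#' @param w1,w2 Construction weights (not both 0). Default
#'   \eqn{1/\sqrt{2}} each.
#' @param noise_sd Standard deviation of the added noise; default 0.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param chrom Optional length-2 vector of chromosome labels for the two
#'   variants; a same-chromosome pair triggers a warning.
#' @return Numeric vector z with sample mean 0 and variance 1.
#' @examples
#' g1 <- rbinom(100, 2, 0.5); g2 <- rbinom(100, 2, 0.5)
#' z <- make_collider_covariate(g1, g2, seed = 1)
#' round(c(mean(z), var(z)), 10)
#' @export
make_collider_covariate <- function(g_causal, g_other,
                                    w1 = 1 / sqrt(2), w2 = 1 / sqrt(2),
                                    noise_sd = 0, seed = 1, chrom = NULL) {
  stopifnot(length(g_causal) == length(g_other))
  if (w1 == 0 && w2 == 0) abort("weights w1 and w2 must not both be 0.")
  if (!is.null(chrom) && length(chrom) == 2L && chrom[1] == chrom[2]) {
    warn("collider covariate built from two variants on the same chromosome; the construction assumes unlinked variants.")
  }
  std <- function(g, nm) {
    s <- sd(g)
    if (!is.finite(s) || s == 0) {
      abort(sprintf("cannot standardize zero-variance genotype vector `%s`.", nm))
    }
    (g - mean(g)) / s
  }
  z <- w1 * std(g_causal, "g_causal") + w2 * std(g_other, "g_other")
  if (noise_sd > 0) {
    z <- z + with_seed(seed, rnorm(length(z), 0, noise_sd))
  }
  (z - mean(z)) / sd(z)
}

#' Estimate admixture proportions from local ancestry
#'
#' Computes the genome-wide average local ancestry
#' \eqn{\hat\pi_i = \frac{1}{2m}\sum_j a_{ij}}, the standard estimator of the
#' global ancestry proportion from local-ancestry calls.
#'
#' @param A Local ancestry matrix with entries in \{0, 1, 2\}.
#' @return Numeric vector of estimates in \[0, 1\].
#' @examples
#' estimate_admixture(matrix(c(0, 1, 2, 1), 1))
#' @export
estimate_admixture <- function(A) {
  A <- as.matrix(A)
  if (ncol(A) == 0L) abort("cannot estimate admixture from zero variants.")
  if (any(A < 0) || any(A > 2)) abort("local ancestry entries must be in {0, 1, 2}.")
  rowSums(A) / (2 * ncol(A))
}
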