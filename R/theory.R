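# Closed-form expected large-sample effect-size estimates for GWAS models
# under the two-variant admixed trait model, with a Monte-Carlo oracle.

#' Parameters of the two-variant theory model
#'
#' Collects the population quantities that determine expected large-sample
#' GWAS effect-size estimates: the admixture-proportion moments
#' \eqn{\mu_\pi = E[\pi]} and \eqn{V_\pi = Var(\pi)}; the ancestral allele
#' frequencies of the causal variant (`p11`, `p10`) and of an unlinked
#' neutral variant on another chromosome (`p21`, `p20`); the trait
#' coefficients \eqn{\beta_1} (causal effect) and \eqn{\beta_\pi} (direct
#' ancestry effect); and the construction of the extraneous covariate z
#' (weights `w1`, `w2` on the standardized genotypes of variants 1 and 2,
#' plus independent noise), mirroring [make_collider_covariate()] at the
#' population level.
#'
#' @param mu_pi Mean admixture proportion, in (0, 1).
#' @param v_pi Variance of admixture proportions, with
#'   `0 <= v_pi <= mu_pi * (1 - mu_pi)`.
#' @param p11,p10 Causal-variant allele frequencies in ancestral populations
#'   1 and 0.
#' @param p21,p20 Neutral-variant allele frequencies.
#' @param beta1 Causal-variant effect size.
#' @param beta_pi Direct effect of global ancestry on the trait.
#' @param w1,w2 z-construction weights (not both 0).
#' @param z_noise_sd Standard deviation of the independent noise added to z.
#' @param trait_noise_sd Residual SD of the trait; default 1.
#' @return An object of class `theory_params`.
#' @examples
#' theory_params(mu_pi = 0.8, v_pi = 0.0145, p11 = 0.9, p10 = 0.1,
#'               p21 = 0.9, p20 = 0.1, beta1 = 2)
#' @export
theory_params <- function(mu_pi, v_pi, p11, p10, p21, p20,
                          beta1, beta_pi = 0,
                          w1 = 1 / sqrt(2), w2 = 1 / sqrt(2),
                          z_noise_sd = 1, trait_noise_sd = 1) {
  check_prob(c(mu_pi, p11, p10, p21, p20), "frequencies")
  if (v_pi < 0 || v_pi > mu_pi * (1 - mu_pi)) {
    abort("`v_pi` must satisfy 0 <= v_pi <= mu_pi * (1 - mu_pi).")
  }
  if (w1 == 0 && w2 == 0) abort("weights w1 and w2 must not both be 0.")
  structure(list(mu_pi = mu_pi, v_pi = v_pi, p11 = p11, p10 = p10,
                 p21 = p21, p20 = p20, beta1 = beta1, beta_pi = beta_pi,
                 w1 = w1, w2 = w2, z_noise_sd = z_noise_sd,
                 trait_noise_sd = trait_noise_sd),
            class = "theory_params")
}

#' Model-implied moments of (g1, g2, pi, z, y)
#'
#' Closed-form first and second moments under the generative model
#' \eqn{\pi \sim (\mu_\pi, V_\pi)}, \eqn{g_j \mid \pi \sim
#' \mathrm{Binomial}(2, p_{j0} + \Delta_j \pi)} with
#' \eqn{\Delta_j = p_{j1} - p_{j0}}, trait
#' \eqn{y = \beta_1 g_1 + \beta_\pi \pi + \epsilon}, and z the
#' population-standardized linear construction from `params`. Writing
#' \eqn{\bar q_j = p_{j0} + \Delta_j \mu_\pi}:
#' \deqn{E[g_j] = 2\bar q_j, \quad Cov(g_j, \pi) = 2\Delta_j V_\pi,}
#' \deqn{Var(g_j) = 2\bar q_j(1-\bar q_j) + 2\Delta_j^2 V_\pi, \quad
#'       Cov(g_1, g_2) = 4\Delta_1\Delta_2 V_\pi,}
#' and the z and y moments follow by linear propagation. Note the two
#' unlinked variants are marginally correlated whenever both are
#' differentiated and the population is heterogeneous — the root of
#' confounding by global ancestry.
#'
#' @param params A [theory_params()].
#' @return An object of class `moment_structure`: list with `mean` (named
#'   length-5 vector) and `cov` (5 x 5 symmetric PSD matrix) over
#'   (g1, g2, pi, z, y).
#' @export
model_moments <- function(params) {
  p <- params
  d1 <- p$p11 - p$p10
  d2 <- p$p21 - p$p20
  q1 <- p$p10 + d1 * p$mu_pi
  q2 <- p$p20 + d2 * p$mu_pi
  v_g1 <- 2 * q1 * (1 - q1) + 2 * d1^2 * p$v_pi
  v_g2 <- 2 * q2 * (1 - q2) + 2 * d2^2 * p$v_pi
  c_12 <- 4 * d1 * d2 * p$v_pi
  c_1pi <- 2 * d1 * p$v_pi
  c_2pi <- 2 * d2 * p$v_pi
  sd1 <- sqrt(v_g1)
  sd2 <- sqrt(v_g2)
  # z0 = w1 g1/sd1 + w2 g2/sd2 + noise (centering drops out of covariances)
  v_z0 <- p$w1^2 + p$w2^2 + 2 * p$w1 * p$w2 * c_12 / (sd1 * sd2) +
    p$z_noise_sd^2
  s <- sqrt(v_z0)
  c_1z <- (p$w1 * v_g1 / sd1 + p$w2 * c_12 / sd2) / s
  c_2z <- (p$w2 * v_g2 / sd2 + p$w1 * c_12 / sd1) / s
  c_piz <- (p$w1 * c_1pi / sd1 + p$w2 * c_2pi / sd2) / s
  c_1y <- p$beta1 * v_g1 + p$beta_pi * c_1pi
  c_2y <- p$beta1 * c_12 + p$beta_pi * c_2pi
  c_piy <- p$beta1 * c_1pi + p$beta_pi * p$v_pi
  c_zy <- p$beta1 * c_1z + p$beta_pi * c_piz
  v_y <- p$beta1^2 * v_g1 + p$beta_pi^2 * p$v_pi +
    2 * p$beta1 * p$beta_pi * c_1pi + p$trait_noise_sd^2
  vars <- c("g1", "g2", "pi", "z", "y")
  S <- matrix(0, 5, 5, dimnames = list(vars, vars))
  diag(S) <- c(v_g1, v_g2, p$v_pi, 1, v_y)
  S["g1", "g2"] <- S["g2", "g1"] <- c_12
  S["g1", "pi"] <- S["pi", "g1"] <- c_1pi
  S["g2", "pi"] <- S["pi", "g2"] <- c_2pi
  S["g1", "z"] <- S["z", "g1"] <- c_1z
  S["g2", "z"] <- S["z", "g2"] <- c_2z
  S["pi", "z"] <- S["z", "pi"] <- c_piz
  S["g1", "y"] <- S["y", "g1"] <- c_1y
  S["g2", "y"] <- S["y", "g2"] <- c_2y
  S["pi", "y"] <- S["y", "pi"] <- c_piy
  S["z", "y"] <- S["y", "z"] <- c_zy
  mu <- c(g1 = 2 * q1, g2 = 2 * q2, pi = p$mu_pi, z = 0,
          y = p$beta1 * 2 * q1 + p$beta_pi * p$mu_pi)
  structure(list(mean = mu, cov = S, params = p),
            class = "moment_structure")
}

#' Expected large-sample OLS coefficient of a tested variant
#'
#' Solves the population normal equations implied by [model_moments()] for
#' the regression of y on an intercept, the tested variant's genotype, and
#' the requested covariates, and returns the genotype coefficient. This is
#' the large-sample limit of the per-variant OLS estimate from
#' [marginal_gwas()] under the generative model, so deviations from the true
#' effect (\eqn{\beta_1} at variant 1, 0 at variant 2) quantify confounding
#' and collider bias exactly.
#'
#' @param moments A `moment_structure` from [model_moments()].
#' @param covariates Character subset of `c("pi", "z")` naming the
#'   adjustment variables (empty vector = unadjusted model).
#' @param test_variant 1 (causal) or 2 (unlinked neutral).
#' @return Expected coefficient (numeric scalar).
#' @examples
#' m <- model_moments(theory_params(0.8, 0.0145, .9, .1, .9, .1, beta1 = 2))
#' expected_coefficient(m, "pi", 1) # unbiased: 2
#' expected_coefficient(m, c("pi", "z"), 2) # collider bias: nonzero
#' @export
expected_coefficient <- function(moments, covariates = character(),
                                 test_variant = 1) {
  stopifnot(inherits(moments, "moment_structure"),
            test_variant %in% c(1, 2),
            all(covariates %in% c("pi", "z")))
  g <- paste0("g", test_variant)
  # constant covariates (e.g., pi in a homogeneous population) carry no
  # information beyond the intercept and are dropped, as OLS would.
  covariates <- covariates[diag(moments$cov)[covariates] > 1e-14]
  vars <- c(g, covariates)
  S <- moments$cov[vars, vars, drop = FALSE]
  rhs <- moments$cov[vars, "y"]
  cn <- tryCatch(solve(S, rhs), error = function(e) NULL)
  if (is.null(cn) || rcond(S) < 1e-12) {
    pair <- which(abs(cov2cor_safe(S)) > 1 - 1e-9 & row(S) < col(S),
                  arr.ind = TRUE)
    nm <- if (nrow(pair)) {
      paste(vars[pair[1, 1]], "and", vars[pair[1, 2]])
    } else "design variables"
    abort(sprintf("singular regression design: %s are collinear.", nm))
  }
  unname(cn[1])
}

cov2cor_safe <- function(S) {
  d <- sqrt(diag(S))
  d[d == 0] <- 1
  S / tcrossprod(d)
}

#' Expected-coefficient table across adjustment models
#'
#' Tabulates the expected large-sample coefficient at the causal variant
#' (variant 1) and the unlinked neutral variant (variant 2) for the three
#' adjustment models compared throughout: unadjusted, adjusted for true
#' global ancestry \eqn{\pi}, and adjusted for \eqn{(\pi, z)} with z an
#' extraneous covariate capturing the two genotypes. Each row carries the
#' truth (\eqn{\beta_1} or 0), the bias, and flags for the structural
#' conditions under which bias is expected: confounding at the tested
#' variant requires heterogeneity (\eqn{V_\pi > 0}) and differentiated
#' frequencies (plus \eqn{\beta_\pi \neq 0} or a differentiated causal
#' variant), while collider bias at variant 2 requires z to be correlated
#' with both genotypes given \eqn{\pi}.
#'
#' @param params A [theory_params()].
#' @return A tibble of class `bias_table` with columns `model`, `variant`,
#'   `expected`, `truth`, `bias`, `confounding_open`, `collider_open`.
#' @export
bias_table <- function(params) {
  m <- model_moments(params)
  d1 <- params$p11 - params$p10
  d2 <- params$p21 - params$p20
  # conditional-on-pi covariances between z and each genotype
  c1z_pi <- m$cov["g1", "z"] - m$cov["g1", "pi"] * m$cov["pi", "z"] / max(params$v_pi, .Machine$double.eps)
  c2z_pi <- m$cov["g2", "z"] - m$cov["g2", "pi"] * m$cov["pi", "z"] / max(params$v_pi, .Machine$double.eps)
  if (params$v_pi == 0) {
    c1z_pi <- m$cov["g1", "z"]
    c2z_pi <- m$cov["g2", "z"]
  }
  grid <- tidyr::expand_grid(
    model = c("unadjusted", "pi", "pi_z"),
    variant = c(1L, 2L)
  )
  covsets <- list(unadjusted = character(), pi = "pi", pi_z = c("pi", "z"))
  out <- grid |>
    dplyr::mutate(
      expected = purrr::map2_dbl(.data$model, .data$variant,
                                 ~ expected_coefficient(m, covsets[[.x]], .y)),
      truth = ifelse(.data$variant == 1L, params$beta1, 0),
      bias = .data$expected - .data$truth,
      confounding_open = .data$model == "unadjusted" & params$v_pi > 0 &
        ifelse(.data$variant == 1L,
               d1 != 0 & params$beta_pi != 0,
               d2 != 0 & (params$beta_pi != 0 | (params$beta1 != 0 & d1 != 0))),
      collider_open = .data$model == "pi_z" & .data$variant == 2L &
        params$beta1 != 0 & abs(c1z_pi) > 1e-12 & abs(c2z_pi) > 1e-12
    )
  class(out) <- c("bias_table", class(out))
  attr(out, "params") <- params
  out
}

#' Monte-Carlo oracle for the expected-coefficient table
#'
#' Validates [bias_table()] by brute force: simulates `reps` cohorts of `n`
#' individuals carrying just the two focal variants (no features) through
#' the package's own generators, fits each adjustment model by OLS, and
#' averages the per-replicate estimates. Admixture proportions are drawn
#' from the Beta distribution matching (`mu_pi`, `v_pi`) — or a point mass
#' when `v_pi = 0` — so the simulated moments match the closed-form ones.
#'
#' @param params A [theory_params()].
#' @param n Individuals per replicate.
#' @param reps Number of replicates.
#' @param seed Integer seed; output is bit-reproducible given the seed.
#' @return A tibble with one row per (model, variant): `empirical` (mean
#'   estimate), `se` (Monte-Carlo standard error of that mean), `expected`
#'   (closed form), `zscore` ((empirical - expected) / se), `n`, `reps`.
#' @export
monte_carlo_oracle <- function(params, n = 2e4, reps = 50, seed = 1) {
  p <- params
  bt <- bias_table(p)
  panel2 <- variant_panel(chrom = c("1", "2"), pos_bp = c(1e6, 1e6),
                          p1 = c(p$p11, p$p21), p0 = c(p$p10, p$p20))
  model <- if (p$v_pi == 0) {
    admixture_model("point_mass", pi_fixed = p$mu_pi)
  } else {
    ab <- p$mu_pi * (1 - p$mu_pi) / p$v_pi - 1
    admixture_model("beta", a = p$mu_pi * ab, b = (1 - p$mu_pi) * ab)
  }
  cells <- matrix(NA_real_, reps, 6)
  for (r in seq_len(reps)) {
    sr <- child_seed(seed, paste0("oracle-rep-", r))
    pi <- draw_admixture(model, n, child_seed(sr, "pi"))
    A <- draw_local_ancestry(pi, panel2, seed = child_seed(sr, "anc"))
    G <- draw_genotypes(A, panel2, seed = child_seed(sr, "geno"))
    z <- make_collider_covariate(G[, 1], G[, 2], w1 = p$w1, w2 = p$w2,
                                 noise_sd = p$z_noise_sd,
                                 seed = child_seed(sr, "z"))
    y <- with_seed(child_seed(sr, "y"),
                   p$beta1 * G[, 1] + p$beta_pi * pi +
                     rnorm(n, 0, p$trait_noise_sd))
    M <- cbind(1, G[, 1], G[, 2], pi, z, y)
    XtX <- crossprod(M)
    colvar <- diag(XtX) / n - (XtX[1, ] / n)^2
    fit <- function(cols, test_col) {
      cols <- cols[colvar[cols] > 1e-14] # constant covariates drop out
      idx <- c(1L, test_col, cols)
      b <- solve(XtX[idx, idx], XtX[idx, 6])
      b[[2]]
    }
    cells[r, ] <- c(
      fit(integer(0), 2L), fit(integer(0), 3L),
      fit(4L, 2L), fit(4L, 3L),
      fit(c(4L, 5L), 2L), fit(c(4L, 5L), 3L)
    )
  }
  out <- tibble::tibble(
    model = rep(c("unadjusted", "pi", "pi_z"), each = 2),
    variant = rep(c(1L, 2L), 3),
    empirical = colMeans(cells),
    se = apply(cells, 2, sd) / sqrt(reps),
    n = n, reps = reps
  )
  dplyr::left_join(out, dplyr::select(bt, "model", "variant", "expected"),
                   by = c("model", "variant")) |>
    dplyr::mutate(zscore = (.data$empirical - .data$expected) / .data$se)
}

#' Standard validation grid of theory parameter settings
#'
#' A fixed grid of parameter settings spanning the regimes the theory
#' distinguishes: heterogeneous vs nearly homogeneous populations, strongly
#' vs weakly differentiated variants, small to large causal effects, with
#' and without a direct ancestry effect, and different extraneous-covariate
#' constructions. Used to validate the closed-form expected coefficients
#' against the Monte-Carlo oracle cell by cell.
#'
#' @return A named list of [theory_params()] objects (12 settings).
#' @export
theory_validation_grid <- function() {
  base <- function(...) {
    args <- utils::modifyList(
      list(mu_pi = 0.8, v_pi = 0.0145, p11 = 0.9, p10 = 0.1,
           p21 = 0.85, p20 = 0.15, beta1 = 2, beta_pi = 0,
           w1 = 1 / sqrt(2), w2 = 1 / sqrt(2), z_noise_sd = 1),
      list(...))
    do.call(theory_params, args)
  }
  list(
    reference        = base(),
    small_effect     = base(beta1 = 0.25),
    medium_effect    = base(beta1 = 1),
    large_effect     = base(beta1 = 4),
    ancestry_effect  = base(beta_pi = 3),
    high_v_pi        = base(v_pi = 0.03),
    low_v_pi         = base(v_pi = 0.005),
    weak_delta2      = base(p21 = 0.55, p20 = 0.45),
    undifferentiated = base(p11 = 0.5, p10 = 0.5, p21 = 0.5, p20 = 0.5),
    noiseless_z      = base(z_noise_sd = 1e-6),
    unbalanced_z     = base(w1 = 0.9, w2 = 0.3),
    mid_ancestry     = base(mu_pi = 0.5, v_pi = 0.02)
  )
}
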