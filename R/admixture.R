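# Admixture-proportion models for two-way admixed cohorts.

#' Specify the distribution of admixture proportions
#'
#' Describes the population distribution of the global ancestry proportion
#' \eqn{\pi_i}, the genome-wide fraction of each individual's genome inherited
#' from ancestral population 1. Three families are supported:
#'
#' * `"beta"` — \eqn{\pi \sim \mathrm{Beta}(a, b)}. The default, `a = 8`,
#'   `b = 2`, gives mean 0.8 and standard deviation about 0.12, emulating the
#'   wide spread of African ancestry proportions seen in African American
#'   cohorts.
#' * `"point_mass"` — every individual has \eqn{\pi = } `pi_fixed`; this is the
#'   ancestrally homogeneous limit with \eqn{V_\pi = 0}.
#' * `"two_point"` — \eqn{\pi} takes the two values in `levels` with equal
#'   probability; a minimal heterogeneous (\eqn{V_\pi > 0}) population.
#'
#' @param family One of `"beta"`, `"point_mass"`, `"two_point"`.
#' @param a,b Beta shape parameters (used when `family = "beta"`).
#' @param pi_fixed Fixed proportion in \[0, 1\] (`family = "point_mass"`).
#' @param levels Length-two vector of proportions (`family = "two_point"`).
#' @return An object of class `admixture_model` with elements `family` and the
#'   relevant parameters, plus `mean` and `var`, the implied population
#'   moments \eqn{\mu_\pi} and \eqn{V_\pi}.
#' @seealso [draw_admixture()]
#' @examples
#' admixture_model("beta", a = 8, b = 2)
#' admixture_model("point_mass", pi_fixed = 0.8)
#' @export
admixture_model <- function(family = c("beta", "point_mass", "two_point"),
                            a = 8, b = 2, pi_fixed = 0.8,
                            levels = c(0.2, 0.9)) {
  family <- match.arg(family)
  out <- switch(family,
    beta = {
      if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) {
        abort("beta family requires shape parameters a > 0, b > 0.")
      }
      list(family = family, a = a, b = b,
           mean = a / (a + b),
           var = a * b / ((a + b)^2 * (a + b + 1)))
    },
    point_mass = {
      check_prob(pi_fixed, "pi_fixed")
      list(family = family, pi_fixed = pi_fixed, mean = pi_fixed, var = 0)
    },
    two_point = {
      stopifnot(length(levels) == 2L)
      check_prob(levels, "levels")
      list(family = family, levels = levels,
           mean = mean(levels), var = diff(levels)^2 / 4)
    })
  structure(out, class = "admixture_model")
}

#' @export
print.admixture_model <- function(x, ...) {
  cat(sprintf("<admixture_model: %s>  mean = %.4g, var = %.4g\n",
              x$family, x$mean, x$var))
  invisible(x)
}

#' Draw admixture proportions
#'
#' Samples `n` global ancestry proportions \eqn{\pi_i} from an
#' [admixture_model()]. Draws are reproducible given `seed` and always lie in
#' \[0, 1\]; the `point_mass` family returns a constant vector (the
#' \eqn{V_\pi = 0} limit).
#'
#' @param model An [admixture_model()].
#' @param n Number of individuals (>= 1).
#' @param seed Integer seed.
#' @return Numeric vector of length `n` with values in \[0, 1\].
#' @examples
#' pi <- draw_admixture(admixture_model("beta", 8, 2), n = 100, seed = 1)
#' mean(pi)
#' @export
draw_admixture <- function(model, n, seed) {
  stopifnot(inherits(model, "admixture_model"), n >= 1)
  with_seed(seed, switch(model$family,
    beta = rbeta(n, model$a, model$b),
    point_mass = rep(model$pi_fixed, n),
    two_point = sample(model$levels, n, replace = TRUE)
  ))
}
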