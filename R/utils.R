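# Internal helpers shared across modules.

#' Derive a child seed from a parent seed and a stage label
#'
#' Expands one user-supplied integer seed into deterministic per-stage child
#' seeds, so that a single seed reproduces a whole pipeline while each stage
#' (admixture draw, local ancestry, genotypes, trait, ...) consumes an
#' independent stream. The derivation is a Lehmer-style mix of the parent
#' seed with a hash of the stage label, reduced modulo 2^31 - 1.
#'
#' @param seed Integer parent seed.
#' @param stage Character stage label.
#' @return A single integer in \[1, 2^31 - 2\].
#' @examples
#' child_seed(1, "admixture")
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  m <- 2147483647
  x <- (abs(as.numeric(seed)) %% m) + 1
  x <- (x * 48271) %% m
  x <- (x + (h * 2654435) %% m) %% m
  as.integer(x %% (m - 2L) + 1L)
}

# Run `expr` with the RNG seeded at `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  invisible(x)
}

# Column standardization that errors informatively on constant columns.
standardize_cols <- function(M, what = "column") {
  mu <- colMeans(M)
  s <- sqrt(colMeans(M^2) - mu^2)
  bad <- which(s <= 0 | !is.finite(s))
  if (length(bad)) {
    abort(sprintf("cannot standardize zero-variance %s(s): %s",
                  what, paste(head(bad, 5), collapse = ", ")))
  }
  sweep(sweep(M, 2, mu, "-"), 2, s, "/")
}
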