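test_that("a trait equal to the genotype is recovered with slope one", {
  set.seed(1)
  n <- 200
  G <- matrix(rbinom(n * 5, 2, 0.5), n)
  panel <- variant_panel(chrom = "1", pos_bp = (1:5) * 1e4,
                         p1 = rep(.5, 5), p0 = rep(.5, 5))
  res <- marginal_gwas(as.numeric(G[, 2]), G, panel)
  expect_equal(res$beta[2], 1, tolerance = 1e-10)
  expect_lt(res$p[2], 1e-100)
})

test_that("marginal scans match per-variant lm fits exactly", {
  set.seed(2)
  n <- 120
  G <- matrix(rbinom(n * 8, 2, 0.4), n)
  panel <- variant_panel(chrom = "1", pos_bp = (1:8) * 1e4,
                         p1 = rep(.5, 8), p0 = rep(.5, 8))
  covs <- cbind(w = rnorm(n))
  y <- rnorm(n) + 0.5 * G[, 4] + covs[, 1]
  res <- marginal_gwas(y, G, panel, covariates = covs)
  for (j in c(1, 4, 8)) {
    fit <- summary(lm(y ~ G[, j] + covs))
    expect_equal(res$beta[j], fit$coefficients[2, 1], tolerance = 1e-10)
    expect_equal(res$se[j], fit$coefficients[2, 2], tolerance = 1e-10)
    nuis <- attr(res, "nuisance")[, j]
    expect_equal(unname(nuis), unname(coef(lm(y ~ G[, j] + covs))[c(1, 3)]),
                 tolerance = 1e-10)
  }
})

test_that("null scans in a homogeneous population are calibrated", {
  set.seed(3)
  n <- 400
  m <- 1000
  G <- matrix(rbinom(n * m, 2, 0.3), n)
  panel <- variant_panel(chrom = rep(c("1", "2"), each = m / 2),
                         pos_bp = rep(seq_len(m / 2) * 1e4, 2),
                         p1 = rep(.5, m), p0 = rep(.5, m))
  y <- rnorm(n)
  res <- marginal_gwas(y, G, panel)
  rate <- mean(res$p < 0.05, na.rm = TRUE)
  band <- 3 * sqrt(0.05 * 0.95 / m) # wider than the binomial 95% band
  expect_lt(abs(rate - 0.05), band + 0.01)
})

test_that("consistent permutation of individuals leaves statistics unchanged", {
  set.seed(4)
  n <- 150
  G <- matrix(rbinom(n * 6, 2, 0.4), n)
  panel <- variant_panel(chrom = "1", pos_bp = (1:6) * 1e4,
                         p1 = rep(.5, 6), p0 = rep(.5, 6))
  covs <- cbind(rnorm(n))
  y <- rnorm(n)
  perm <- sample(n)
  a <- marginal_gwas(y, G, panel, covs)
  b <- marginal_gwas(y[perm], G[perm, ], panel, covs[perm, , drop = FALSE])
  expect_equal(a$beta, b$beta, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("genotypes collinear with covariates are flagged missing", {
  set.seed(5)
  n <- 100
  G <- matrix(rbinom(n * 3, 2, 0.4), n)
  panel <- variant_panel(chrom = "1", pos_bp = (1:3) * 1e4,
                         p1 = rep(.5, 3), p0 = rep(.5, 3))
  res <- marginal_gwas(rnorm(n), G, panel, covariates = cbind(G[, 2]))
  expect_true(res$collinear[2])
  expect_true(is.na(res$p[2]))
  expect_false(any(res$collinear[c(1, 3)]))
  expect_error(marginal_gwas(rnorm(n), G, panel, cbind(rep(1, n))),
               "constant")
})

test_that("spurious chromosomes are counted off the causal chromosome only", {
  tab <- tibble::tibble(
    variant = 1:8,
    chrom = c("1", "1", "4", "4", "7", "7", "9", "9"),
    pos_bp = rep(c(1e5, 2e5), 4),
    beta = 0, se = 1,
    wald = 0,
    p = c(1e-9, .5, 1e-20, 1e-12, .2, 4e-8, .9, .7),
    collinear = FALSE)
  class(tab) <- c("assoc_result", class(tab))
  expect_identical(count_spurious_chromosomes(tab, "4", 5e-8), 2L)
  expect_identical(count_spurious_chromosomes(tab, "4", 1e-30), 0L)
  allp1 <- dplyr::mutate(tab, p = 1)
  expect_identical(count_spurious_chromosomes(allp1, "4", 5e-8), 0L)
  only_causal <- dplyr::mutate(tab, p = ifelse(chrom == "4", 1e-12, 1))
  expect_identical(count_spurious_chromosomes(only_causal, "4", 5e-8), 0L)
  missing_p <- dplyr::mutate(tab, p = ifelse(chrom == "1", NA, p))
  expect_identical(count_spurious_chromosomes(missing_p, "4", 5e-8), 1L)
})

test_that("genomic inflation equals the chi-square median ratio", {
  mk <- function(w) {
    tab <- tibble::tibble(variant = seq_along(w), chrom = "1",
                          pos_bp = seq_along(w), beta = 0, se = 1,
                          wald = w, p = 2 * pnorm(-abs(w)),
                          collinear = FALSE)
    class(tab) <- c("assoc_result", class(tab))
    tab
  }
  expect_identical(genomic_inflation(mk(rep(0, 10))), 0)
  set.seed(6)
  lam <- genomic_inflation(mk(rnorm(1e5)))
  expect_lt(abs(lam - 1), 0.03)
  expect_error(genomic_inflation(mk(NA_real_)), "non-missing")
})

test_that("scan writers emit the documented columns", {
  set.seed(7)
  n <- 80
  G <- matrix(rbinom(n * 4, 2, 0.4), n)
  panel <- variant_panel(chrom = "1", pos_bp = (1:4) * 1e4,
                         p1 = rep(.5, 4), p0 = rep(.5, 4))
  res <- marginal_gwas(rnorm(n), G, panel)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_assoc_tsv(res, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_named(back, c("chrom", "pos", "beta", "se", "wald", "p"))
  write_assoc_summary_json(res, causal_chrom = "1", path = js)
  smry <- jsonlite::read_json(js)
  expect_named(smry, c("lambda", "n_spurious_chroms", "alpha"))
  gl <- glance(res)
  expect_identical(nrow(gl), 1L)
  expect_true(is.finite(gl$lambda))
})

test_that("dropping the extraneous covariate restores nominal type-I error at the partner variant", {
  panel2 <- variant_panel(c("1", "2"), c(1e6, 1e6),
                          p1 = c(.9, .85), p0 = c(.1, .15))
  adm <- admixture_model("beta", 8, 2)
  n <- 2000
  reps <- 150
  p_with_z <- p_without_z <- numeric(reps)
  for (r in seq_len(reps)) {
    sr <- child_seed(300, paste0("rep", r))
    pi <- draw_admixture(adm, n, child_seed(sr, "pi"))
    A <- draw_local_ancestry(pi, panel2, seed = child_seed(sr, "a"))
    G <- draw_genotypes(A, panel2, seed = child_seed(sr, "g"))
    z <- make_collider_covariate(G[, 1], G[, 2], noise_sd = 1,
                                 seed = child_seed(sr, "z"))
    set.seed(child_seed(sr, "y"))
    y <- 2 * G[, 1] + rnorm(n) # beta1 = 2, no direct ancestry effect
    p_with_z[r] <- marginal_gwas(y, G, panel2, cbind(pi = pi, z = z))$p[2]
    p_without_z[r] <- marginal_gwas(y, G, panel2, cbind(pi = pi))$p[2]
  }
  # the collider covariate makes the neutral variant reject almost always;
  # removing it restores the nominal level within the binomial band
  expect_gt(mean(p_with_z < 0.05), 0.5)
  rate <- mean(p_without_z < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})
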