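test_that("local ancestry respects degenerate admixture proportions", {
  panel <- synthetic_panel(1, 20, seed = 1)
  A <- draw_local_ancestry(c(0, 1, 0.5), panel, seed = 2)
  expect_true(all(A[1, ] == 0))
  expect_true(all(A[2, ] == 2))
  expect_true(all(A %in% 0:2))
})

test_that("independent-mode ancestry has binomial mean", {
  panel <- synthetic_panel(1, 1e4, spacing_bp = 1e3, seed = 1)
  A <- draw_local_ancestry(rep(0.5, 2), panel, seed = 3)
  # mean of a_ij / 2 over m variants: Var(a/2) = 2 * 0.25 / 4 per variant
  se <- sqrt(0.125 / ncol(A))
  expect_lt(abs(mean(A[1, ] / 2) - 0.5), 3 * se)
})

test_that("markov-mode ancestry keeps its stationary mean and is tract-correlated", {
  panel <- synthetic_panel(1, 2000, spacing_bp = 1e4, seed = 1)
  pi <- rep(0.7, 20)
  A <- draw_local_ancestry(pi, panel, mode = "markov",
                           switch_rate_per_mb = 0.5, seed = 4)
  expect_true(all(A %in% 0:2))
  expect_lt(abs(mean(A) / 2 - 0.7), 0.05)
  # adjacent variants share ancestry far more than distant ones
  adj <- cor(as.vector(A[, -1]), as.vector(A[, -ncol(A)]))
  expect_gt(adj, 0.5)
})

test_that("genotype law reduces to the binomial admixture mixture", {
  panel <- variant_panel(chrom = "1", pos_bp = 1e5, p1 = 0.9, p0 = 0.1)
  n <- 1e4
  A <- draw_local_ancestry(rep(0.5, n), panel, seed = 5)
  G <- draw_genotypes(A, panel, seed = 6)
  # q(0.5) = 0.5; allele-frequency SE = sqrt(q (1 - q) / (2 n))
  expect_lt(abs(mean(G) / 2 - 0.5), 3 * sqrt(0.25 / (2 * n)))
  fixed <- variant_panel(chrom = "1", pos_bp = 1e5, p1 = 1, p0 = 1)
  expect_true(all(draw_genotypes(A, fixed, seed = 7) == 2))
})

test_that("feature variants correlate with the latent indicator as the two-group oracle predicts", {
  # brute-force oracle: enumerate P(g, f) for carriers (q + s) and
  # non-carriers (q - s) and compute the point-biserial correlation
  q <- 0.5; s <- 0.4; cf <- 0.5
  pg <- function(qq) dbinom(0:2, 2, qq)
  joint <- rbind(pg(q - s) * (1 - cf), pg(q + s) * cf) # rows f = 0, 1
  Eg <- sum(t(joint) * (0:2))
  Ef <- cf
  Egf <- sum(joint[2, ] * (0:2))
  vg <- sum(t(joint) * (0:2)^2) - Eg^2
  oracle_corr <- (Egf - Eg * Ef) / sqrt(vg * cf * (1 - cf))
  expect_gt(oracle_corr, 0.3)

  n <- 2000
  panel <- variant_panel(chrom = "1", pos_bp = c(1e5, 2e5),
                         p1 = c(q, q), p0 = c(q, q))
  ft <- feature_spec(data.frame(chrom = "1", start_bp = 1, end_bp = 3e5),
                     carrier_freq = cf, strength = s)
  f <- matrix(rbinom(n, 1, cf), ncol = 1)
  A <- draw_local_ancestry(rep(0.5, n), panel, seed = 8)
  G <- draw_genotypes(A, panel, features = list(ft), f = f, seed = 9)
  emp <- cor(G[, 1], f[, 1])
  expect_gt(emp, 0.3)
  expect_lt(abs(emp - oracle_corr), 0.1)
})

test_that("out-of-panel feature regions warn and are ignored", {
  panel <- synthetic_panel(1, 10, seed = 1)
  ft <- feature_spec(data.frame(chrom = "9", start_bp = 1, end_bp = 2),
                     strength = 0.3)
  A <- draw_local_ancestry(rep(0.5, 10), panel, seed = 1)
  expect_warning(draw_genotypes(A, panel, features = list(ft),
                                f = matrix(0, 10, 1), seed = 1),
                 "no panel variants")
})

test_that("trait model is the causal-variant linear model", {
  ch <- small_cohort(n = 1e4, m_per = 5, seed = 10)
  y0 <- simulate_trait(ch, 1, beta1 = 0, beta_pi = 0, noise_sd = 1e-8,
                       seed = 11)
  expect_lt(max(abs(y0)), 1e-6)
  y <- simulate_trait(ch, 3, beta1 = 2, seed = 12)
  g <- ch$G[, 3]
  contrast <- mean(y[g == 2]) - mean(y[g == 0])
  expect_lt(abs(contrast - 4), 4 * sqrt(1 / sum(g == 2) + 1 / sum(g == 0)))
  # the conventional effect-size grid is accepted
  for (b in c(0, 0.25, 0.5, 1, 2, 4, 8)) {
    expect_length(simulate_trait(ch, 1, beta1 = b, seed = 13), nrow(ch$G))
  }
  expect_error(simulate_trait(ch, 1, beta1 = 1, noise_sd = 0), "noise_sd")
})

test_that("collider covariate has the advertised correlation structure", {
  set.seed(20)
  g1 <- rbinom(5000, 2, 0.5)
  g2 <- rbinom(5000, 2, 0.5)
  z <- make_collider_covariate(g1, g2, w1 = 1, w2 = 0)
  expect_equal(cor(z, g1), 1)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  # equal weights on independent equal-variance inputs: corr = 1/sqrt(2)
  z2 <- make_collider_covariate(g1, g2)
  expect_lt(abs(cor(z2, g1) - 1 / sqrt(2)), 0.03)
  expect_warning(make_collider_covariate(g1, g2, chrom = c("3", "3")),
                 "same chromosome")
  expect_error(make_collider_covariate(rep(1, 10), rbinom(10, 2, .5)),
               "zero-variance")
  expect_error(make_collider_covariate(g1, g2, w1 = 0, w2 = 0), "both")
})

test_that("genome-wide average local ancestry is the exact column-mean identity", {
  expect_identical(estimate_admixture(matrix(2, 1, 4)), 1)
  expect_identical(estimate_admixture(matrix(c(0, 1, 2, 1), 1)), 0.5)
  A <- matrix(rbinom(120, 2, 0.3), 6)
  expect_identical(estimate_admixture(A), rowSums(A) / (2 * ncol(A)))
  expect_error(estimate_admixture(matrix(integer(0), 2, 0)), "zero variants")
  expect_error(estimate_admixture(matrix(3, 1, 1)), "0, 1, 2")
})

test_that("pi-hat from a dense independent simulation recovers the truth", {
  panel <- synthetic_panel(1, 1e4, spacing_bp = 1e3, seed = 30)
  pi <- draw_admixture(admixture_model("beta", 8, 2), 50, seed = 31)
  A <- draw_local_ancestry(pi, panel, seed = 32)
  expect_gt(cor(estimate_admixture(A), pi), 0.99)
})

test_that("model-implied moment identities hold empirically", {
  # single draw at n = 1e5, 4 SE tolerance; SE via the delta method on
  # empirical moments of products
  n <- 1e5
  panel <- two_variant_panel()
  pi <- draw_admixture(admixture_model("beta", 8, 2), n, seed = 40)
  A <- draw_local_ancestry(pi, panel, seed = 41)
  G <- draw_genotypes(A, panel, seed = 42)
  v <- 8 * 2 / (100 * 11)
  d1 <- 0.8; d2 <- 0.7
  cse <- function(x, y) sd((x - mean(x)) * (y - mean(y))) / sqrt(n)
  expect_lt(abs(cov(G[, 1], pi) - 2 * d1 * v), 4 * cse(G[, 1], pi))
  expect_lt(abs(cov(G[, 1], G[, 2]) - 4 * d1 * d2 * v),
            4 * cse(G[, 1], G[, 2]))
  # homogeneous population: unlinked variants are uncorrelated
  pih <- draw_admixture(admixture_model("point_mass", pi_fixed = 0.8), n,
                        seed = 43)
  Ah <- draw_local_ancestry(pih, panel, seed = 44)
  Gh <- draw_genotypes(Ah, panel, seed = 45)
  expect_lt(abs(cov(Gh[, 1], Gh[, 2])), 4 * cse(Gh[, 1], Gh[, 2]))
})

test_that("the whole cohort is reproducible from one seed", {
  fx1 <- feature_cohort(n = 60, variants_per_chrom = 40, seed = 5)
  fx2 <- feature_cohort(n = 60, variants_per_chrom = 40, seed = 5)
  expect_identical(fx1$cohort$G, fx2$cohort$G)
  expect_identical(fx1$cohort$A, fx2$cohort$A)
  expect_identical(fx1$cohort$pi_true, fx2$cohort$pi_true)
  expect_identical(fx1$cohort$f, fx2$cohort$f)
  fx3 <- feature_cohort(n = 60, variants_per_chrom = 40, seed = 6)
  expect_false(identical(fx1$cohort$G, fx3$cohort$G))
})
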