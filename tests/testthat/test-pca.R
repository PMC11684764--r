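test_that("MAF filter keeps and drops the right columns", {
  set.seed(11)
  n <- 1000
  G <- cbind(rep(0L, n),                       # monomorphic
             c(1L, rep(0L, n - 1)),            # one heterozygote: MAF 5e-4
             rbinom(n, 2, 0.5))
  panel <- variant_panel(chrom = "1", pos_bp = c(1, 2, 3) * 1e5,
                         p1 = rep(.5, 3), p0 = rep(.5, 3))
  expect_identical(maf_filter(G, panel, 0.01), 3L)
  expect_identical(maf_filter(G, panel, 0), 1:3)
  expect_false(1L %in% maf_filter(G, panel, 1e-6))
})

test_that("region exclusion uses inclusive boundaries", {
  regions <- high_ld_regions()
  panel <- variant_panel(chrom = c("6", "6", "6", "1"),
                         pos_bp = c(23691793, 30000000, 38924247, 100),
                         p1 = rep(.5, 4), p0 = rep(.5, 4))
  keep <- exclude_regions(panel, regions)
  expect_false(1L %in% keep)  # exact start boundary: excluded
  expect_false(2L %in% keep)  # interior of the chr6 high-LD region
  expect_true(3L %in% keep)   # one bp past the end
  expect_true(4L %in% keep)
  empty <- region_list(character(0), numeric(0), numeric(0))
  expect_identical(exclude_regions(panel, empty), seq_len(nrow(panel)))
})

test_that("greedy pruning keeps the leftmost of conflicting variants", {
  set.seed(1)
  n <- 300
  base <- rbinom(n, 2, 0.5)
  G <- cbind(base, base, base, rbinom(n, 2, 0.5))
  panel <- variant_panel(chrom = "1", pos_bp = c(1, 2, 3, 4) * 1e4,
                         p1 = rep(.5, 4), p0 = rep(.5, 4))
  kept <- ld_prune(G, panel, r2_max = 0.1, window_bp = 5e5)
  expect_identical(kept, c(1L, 4L))  # one of three identical kept; the left one
  # independent columns: everything kept
  Gi <- matrix(rbinom(n * 6, 2, 0.5), n)
  paneli <- variant_panel(chrom = "1", pos_bp = (1:6) * 1e4,
                          p1 = rep(.5, 6), p0 = rep(.5, 6))
  expect_identical(ld_prune(Gi, paneli, 0.5, 5e5), 1:6)
})

test_that("pruning postcondition holds by brute force on an LD-structured panel", {
  set.seed(2)
  n <- 250
  blocks <- lapply(1:8, function(b) {
    anchor <- rbinom(n, 2, runif(1, 0.2, 0.8))
    copies <- sapply(1:4, function(i) {
      flip <- rbinom(n, 1, 0.12)
      pmin(pmax(anchor + flip * sample(c(-1L, 1L), n, TRUE), 0L), 2L)
    })
    cbind(anchor, copies)
  })
  G <- do.call(cbind, blocks)
  m <- ncol(G)
  panel <- variant_panel(chrom = rep(c("1", "2"), each = m / 2),
                         pos_bp = rep(seq_len(m / 2) * 3e4, 2),
                         p1 = rep(.5, m), p0 = rep(.5, m))
  kept <- ld_prune(G, panel, r2_max = 0.1, window_bp = 5e5)
  expect_lt(max_kept_r2_within_window(G, panel, kept, 5e5), 0.1)
  expect_gt(length(kept), 0)
})

test_that("PCA matches a direct SVD of the standardized matrix", {
  set.seed(3)
  for (dims in list(c(40, 60), c(60, 40), c(50, 50))) {
    G <- matrix(rbinom(prod(dims), 2, 0.4), dims[1])
    G <- G[, apply(G, 2, sd) > 0, drop = FALSE]
    p <- colMeans(G) / 2
    X <- sweep(sweep(G, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
    sv <- svd(X)
    res <- run_pca(G, k = 5)
    expect_equal(res$singular_values, sv$d[1:5], tolerance = 1e-6)
    for (j in 1:5) {
      expect_equal(abs(sum(res$scores[, j] * sv$u[, j])), 1,
                   tolerance = 1e-6)
    }
    # scores orthonormal, singular values non-increasing
    expect_equal(crossprod(res$scores), diag(5), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_true(all(diff(res$singular_values) <= 1e-8))
    # sign convention: dominant loading entry positive
    for (j in 1:5) {
      expect_gt(res$loadings[which.max(abs(res$loadings[, j])), j], 0)
    }
  }
})

test_that("a rank-one genotype matrix is fully explained by one component", {
  u <- rep(c(0L, 2L), each = 10)
  G <- cbind(u, u, 2L - u)
  res <- run_pca(G, k = 1)
  p <- colMeans(G) / 2
  X <- sweep(sweep(G, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
  expect_equal(res$singular_values[1]^2, sum(X^2), tolerance = 1e-8)
})

test_that("PCA errors on monomorphic kept columns", {
  G <- cbind(rep(1L, 20), rbinom(20, 2, .5))
  expect_error(run_pca(G, k = 1), "zero-variance")
})

test_that("PCA is invariant to variant order up to sign", {
  set.seed(4)
  G <- matrix(rbinom(80 * 50, 2, 0.4), 80)
  G <- G[, apply(G, 2, sd) > 0]
  perm <- sample(ncol(G))
  a <- run_pca(G, k = 3)
  b <- run_pca(G[, perm], k = 3)
  for (j in 1:3) {
    expect_equal(abs(cor(a$scores[, j], b$scores[, j])), 1,
                 tolerance = 1e-8)
  }
})

test_that("exclusion and MAF filtering commute", {
  fx <- feature_cohort(n = 150, variants_per_chrom = 80, seed = 9)
  G <- fx$cohort$G
  panel <- fx$panel
  regions <- region_list("1", 1e5, 4e5)
  a <- intersect(maf_filter(G, panel, 0.05), exclude_regions(panel, regions))
  b <- intersect(exclude_regions(panel, regions), maf_filter(G, panel, 0.05))
  expect_identical(sort(a), sort(b))
})

test_that("PC-genotype correlations are bounded and flag degenerate columns", {
  set.seed(5)
  G <- matrix(rbinom(60 * 30, 2, 0.4), 60)
  G[, 7] <- 1L # zero variance
  ok <- which(apply(G, 2, sd) > 0)
  panel <- variant_panel(chrom = "1", pos_bp = seq_len(30) * 1e4,
                         p1 = rep(.5, 30), p0 = rep(.5, 30))
  res <- run_pca(G, keep = ok, k = 4)
  cc <- pc_genotype_correlation(res, G, panel)
  expect_true(all(abs(cc$corr) <= 1 + 1e-12))
  expect_true(all(cc$corr[cc$variant == 7] == 0))
  expect_true(all(cc$zero_variance[cc$variant == 7]))
  # a PC equal to a standardized genotype column correlates 1 at it
  g <- G[, 1]
  fake <- res
  fake$scores[, 1] <- (g - mean(g)) / sd(g) / sqrt(59)
  cc1 <- pc_genotype_correlation(fake, G, panel)
  expect_equal(cc1$corr[cc1$variant == 1 & cc1$pc == 1], 1,
               tolerance = 1e-10)
})

test_that("peak detection recovers planted runs and nothing from flat tables", {
  flat <- tibble::tibble(variant = 1:100, chrom = "1",
                         pos_bp = (1:100) * 1e4, pc = 1L,
                         corr = 0.25, zero_variance = FALSE)
  class(flat) <- c("pc_corr", class(flat))
  expect_identical(nrow(detect_loading_peaks(flat, abs_corr_min = 0.3)), 0L)
  planted <- flat
  planted$corr[c(40:45, 80:83)] <- 0.8
  pk <- detect_loading_peaks(planted, window_bp = 1e5, abs_corr_min = 0.3)
  expect_identical(nrow(pk), 2L)
  expect_equal(pk$start_bp, c(40e4, 80e4))
  expect_equal(pk$end_bp, c(45e4, 83e4))
})
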