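test_that("correlation-matrix PCA has the right algebraic structure", {
  set.seed(31)
  m <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, paste0("i", 1:6)))
  pca <- run_pca(m)
  # trace identity: eigenvalues sum to the number of indices
  expect_equal(sum(pca$eigenvalues), 6, tolerance = 1e-10)
  # per component, sum of squared loadings equals the eigenvalue
  for (j in 1:6) {
    expect_equal(sum(pca$loadings[, j]^2), unname(pca$eigenvalues[j]),
                 tolerance = 1e-6)
  }
  # scores reproduce z-scored data correlations with loadings
  expect_equal(unname(cor(m[, 1], pca$scores[, 1])),
               unname(pca$loadings[1, 1]), tolerance = 1e-10)
  # orientation: largest-|loading| entry positive per component
  for (j in 1:6) {
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
  }
})

test_that("two perfectly correlated columns give eigenvalues (2, 0)", {
  x <- c(1, 2, 3, 5, 8)
  pca <- run_pca(cbind(a = x, b = 2 * x + 1))
  expect_equal(unname(pca$eigenvalues), c(2, 0), tolerance = 1e-10)
})

test_that("PCA rejects degenerate inputs", {
  expect_error(run_pca(cbind(a = c(1, 2, 3), b = c(5, 5, 5))), "zero-variance.*b")
  expect_error(run_pca(matrix(1:4, 2, 2)), ">= 3 accessions")
  expect_warning(run_pca(matrix(rnorm(12), 3, 4)), "more indices")
})

test_that("component retention uses the eigenvalue > 1 rule with a floor of one", {
  expect_equal(retain_components(c(7.601, 2.536, 1.596, 0.71, 0.3)), 3)
  expect_equal(retain_components(c(0.9, 0.6)), 1)
  expect_equal(retain_components(13.0), 1)
  expect_equal(retain_components(c(2, 1.0, 0.5)), 1)  # strict inequality
  expect_error(retain_components(numeric(0)), "empty")
  expect_error(retain_components(c(1, 2)), "descending")
})

test_that("membership is min-max on scores", {
  expect_equal(membership(c(3, 5)), c(0, 1))
  u <- membership(c(2, 8, 5))
  expect_equal(u, c(0, 1, 0.5))
  expect_error(membership(c(1, 1, 1)), "degenerate")
})

test_that("weights are normalized contribution rates", {
  expect_equal(round(pc_weights(c(58.471, 19.509, 12.273)), 3),
               c(0.648, 0.216, 0.136))
  expect_equal(pc_weights(42), 1)
  expect_equal(pc_weights(c(50, 25, 25)), c(0.5, 0.25, 0.25))
  expect_error(pc_weights(c(10, -1)), "positive")
})

test_that("D value is the weighted membership sum with sane guards", {
  w <- pc_weights(c(58.471, 19.509, 12.273))
  expect_equal(round(d_value(c(1.000, 0.589, 0.381), w), 3), 0.827)
  expect_equal(round(d_value(c(0.000, 0.696, 0.000), w), 3), 0.150)
  expect_equal(round(d_value(c(0.088, 1.000, 1.000), w), 3), 0.409)
  expect_error(d_value(c(0.5, 0.5), w), "length")
  # affine consistency: constant memberships give that constant
  for (cc in c(0, 0.3, 1)) {
    expect_equal(d_value(rep(cc, 3), w), cc, tolerance = 1e-12)
  }
})

test_that("ranking is descending with lexicographic tie-break", {
  rs <- rank_and_select(c(b = 0.2, a = 0.8))
  expect_equal(rs$rank, c(b = 2L, a = 1L))
  expect_equal(rs$top, "a")
  ties <- rank_and_select(c(z = 0.5, m = 0.5, a = 0.5))
  expect_equal(ties$order, c("a", "m", "z"))
  expect_true(ties$ties)
})

test_that("reference loading table is consistent with its printed eigenvalues", {
  ref <- reference_panel()
  for (j in 1:3) {
    expect_equal(sum(ref$loadings[[paste0("PC", j)]]^2),
                 ref$pca_summary$eigenvalue[j], tolerance = 0.01)
  }
})

test_that("reference membership table reproduces printed D values and ranking", {
  ref <- reference_panel()
  w <- pc_weights(ref$pca_summary$proportion)
  u <- as.matrix(ref$membership[, c("u_PC1", "u_PC2", "u_PC3")])
  d <- apply(u, 1, d_value, weights = w)
  expect_true(all(abs(d - ref$membership$D) <= 0.001))
  rs <- rank_and_select(setNames(d, ref$membership$name))
  expect_equal(unname(rs$rank[ref$membership$name]), ref$membership$rank)
  expect_equal(rs$top, "Huangluo")
  expect_equal(rs$bottom, "Shanfuliya")
  # extreme memberships: the PC1 maximum and minimum accessions
  expect_equal(ref$membership$u_PC1[ref$membership$name == "Huangluo"], 1)
  expect_equal(ref$membership$u_PC1[ref$membership$name == "Shanfuliya"], 0)
})

test_that("evaluate_panel wires PCA, membership, weights and ranking together", {
  p <- generate_panel(panel_config(seed = 8))
  m <- build_index_matrix(p$observations, "SST", 6)
  ev <- suppressWarnings(evaluate_panel(m))
  k <- ev$pca$n_retained
  expect_equal(sum(ev$weights), 1, tolerance = 1e-9)
  u <- as.matrix(ev$membership[, paste0("u_PC", seq_len(k)), drop = FALSE])
  # each membership column attains 0 and 1
  expect_equal(unname(apply(u, 2, min)), rep(0, k))
  expect_equal(unname(apply(u, 2, max)), rep(1, k))
  expect_true(all(ev$membership$D >= 0 & ev$membership$D <= 1))
  expect_equal(sort(ev$membership$rank), 1:12)
})
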