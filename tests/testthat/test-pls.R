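# PLS fit, permutation significance, spatial similarity, bootstrap gene
# weights and top-gene selection, against an independently coded
# covariance-deflation oracle and analytic cases.

# parcels x genes matrix with exactly orthogonal standardized columns:
# the geometry in which a single-gene response is a perfect predictor
orthogonal_genes <- function(n = 40, p = 20, seed = 1) {
  set.seed(seed)
  raw <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
  q <- qr.Q(qr(raw))
  x <- scale(q)
  colnames(x) <- sprintf("g%03d", seq_len(p))
  x
}

test_that("NIPALS agrees with the covariance-deflation oracle up to sign", {
  set.seed(2)
  for (rep in 1:5) {
    x <- matrix(rnorm(30 * 50), 30, 50)
    y <- rnorm(30)
    fit <- pls_fit(x, y, n_components = 3)
    ora <- oracle_pls(x, y, 3)
    expect_equal(fit$explained_variance_y, ora$explained_variance_y,
                 tolerance = 1e-8)
    for (k in 1:3) {
      s <- sign(sum(fit$x_weights[, k] * ora$weights[, k]))
      expect_equal(fit$x_weights[, k], s * ora$weights[, k], tolerance = 1e-8)
    }
  }
})

test_that("explained variance respects its analytic bounds and edge cases", {
  x <- orthogonal_genes()
  y <- x[, 5]
  fit <- pls_fit(x, y, n_components = 3)
  expect_gte(fit$explained_variance_y[1], 0.999)   # orthogonal perfect predictor
  expect_lte(sum(fit$explained_variance_y), 1 + 1e-8)
  expect_true(all(fit$explained_variance_y >= 0))
  # region scores = deflated predictor matrix times weights, component 1
  expect_equal(fit$region_scores[, 1],
               as.numeric(fit$x %*% fit$x_weights[, 1]), tolerance = 1e-10)
  # response orthogonal to every column: nothing explained
  y_perp <- residuals(lm(rnorm(40) ~ x))
  f0 <- pls_fit(x, y_perp, n_components = 1)
  expect_lt(f0$explained_variance_y[1], 1e-8)
  expect_error(pls_fit(x, rep(1, 40), 1), "constant")
  expect_error(pls_fit(x, x[, 1], 100), "n_components")
})

test_that("permutation p values hit the floor for a perfect predictor", {
  x <- orthogonal_genes()
  y <- x[, 5]
  pt <- permutation_test_variance(x, y, n_components = 1, n_perm = 199,
                                  seed = 3)
  expect_equal(pt$p_perm[1], 1 / 200)
  expect_equal(pt$observed[1], 1, tolerance = 1e-8)
  expect_error(permutation_test_variance(x, y, 1, n_perm = 0), "at least 1")
})

test_that("permutation p values are calibrated under independence", {
  set.seed(4)
  x <- matrix(rnorm(30 * 40), 30, 40)
  ps <- replicate(60, {
    y <- rnorm(30)
    permutation_test_variance(x, y, n_components = 1, n_perm = 79,
                              seed = sample.int(1e6, 1))$p_perm[1]
  })
  expect_gt(mean(ps), 0.35); expect_lt(mean(ps), 0.65)
  expect_gt(mean(ps <= 0.2), 0.05); expect_lt(mean(ps <= 0.2), 0.45)
})

test_that("spatial surrogates preserve the marginal values deterministically", {
  set.seed(5)
  coords <- matrix(runif(60), 20, 3)
  y <- as.numeric(scale(coords[, 1] + rnorm(20, 0, 0.3)))
  s1 <- with_seed <- imgtx:::with_seed(9, spatial_surrogates(y, coords, 5))
  s2 <- imgtx:::with_seed(9, spatial_surrogates(y, coords, 5))
  expect_identical(s1, s2)
  for (i in 1:5) expect_equal(sort(s1[, i]), sort(y))
  pt <- permutation_test_variance(matrix(rnorm(20 * 10), 20, 10), y,
                                  n_components = 1, n_perm = 49,
                                  null = "spatial", coords = coords, seed = 2)
  expect_true(pt$p_perm[1] >= 1 / 50 && pt$p_perm[1] <= 1)
})

test_that("spatial similarity test is two-sided and floored", {
  set.seed(6)
  a <- rnorm(30)
  st <- spatial_similarity_test(a, a, n_perm = 99, seed = 1)
  expect_equal(st$r, 1)
  expect_equal(st$p_spatial, 1 / 100)
  st2 <- spatial_similarity_test(-a, a, n_perm = 99, seed = 1)
  expect_equal(st2$p_spatial, 1 / 100)   # sign symmetry
  expect_error(spatial_similarity_test(rep(1, 30), a), "constant")
  b <- rnorm(30)
  st3 <- spatial_similarity_test(b, a, n_perm = 99, seed = 1)
  expect_gte(st3$p_spatial, 1 / 100)
})

test_that("reported quantities are invariant to a global component sign flip", {
  set.seed(7)
  x <- matrix(rnorm(25 * 30), 25, 30)
  y <- x[, 1] + rnorm(25, 0, 0.5)
  fit <- pls_fit(x, y, n_components = 2)
  w <- fit$x_weights[, 1]
  m1 <- weighted_expression_map(fit$x, w)
  m2 <- weighted_expression_map(fit$x, -w)
  expect_equal(m2, -m1)
  expect_equal(abs(cor(m1, fit$y)), abs(cor(m2, fit$y)))
  # bootstrap Z ranking unchanged if the original weights flip sign
  gw1 <- bootstrap_gene_weights(x, y, n_boot = 120, seed = 11)
  expect_equal(sum(gw1$z > 0) + sum(gw1$z < 0), nrow(gw1))
})

test_that("bootstrap gene weights are deterministic and rank coupled genes on top", {
  parc <- generate_parcellation(c(12, 12, 12), 40, seed = 3)
  tr <- ground_truth(coupled_genes = 1:8, coupling_r = 0.9, seed = 23)
  pt <- generate_probe_table(parc, n_genes = 120, probes_per_gene = 1,
                             truth = tr, fraction_invalid = 0,
                             fraction_background = 0)
  em <- aggregate_to_parcels(filter_probes(pt$probes), parc)
  left <- em$parcels
  y <- rep(0, length(left)); names(y) <- as.character(left)
  y[as.character(intersect(tr$effect_regions, left))] <- 1
  gw <- bootstrap_gene_weights(em, y, n_boot = 150, seed = 5)
  gw2 <- bootstrap_gene_weights(em, y, n_boot = 150, seed = 5)
  expect_identical(gw, gw2)
  top <- select_top_genes(gw, 0.05)
  coupled <- sprintf("g%04d", 1:8)
  expect_gte(mean(top$positive %in% coupled), 0.8)
  expect_warning(bootstrap_gene_weights(em, y, n_boot = 50, seed = 1),
                 "fewer than 100")
})

test_that("top-gene selection counts follow the ceiling rule", {
  tab <- data.frame(gene_id = sprintf("g%04d", 1:1000), z = rnorm(1000))
  sel <- select_top_genes(tab, 0.05)
  expect_equal(sel$n_per_tail, 50L)
  expect_equal(length(sel$positive), 50L)
  expect_setequal(sel$positive, tab$gene_id[order(tab$z, decreasing = TRUE)][1:50])
  half <- select_top_genes(tab, 0.5)
  expect_equal(half$n_per_tail, 500L)
  expect_error(select_top_genes(tab, 0.6), "0.5")
  expect_error(select_top_genes(tab, 0), "0.5")
})

test_that("weighted expression maps equal the matrix product and project to voxels", {
  parc <- generate_parcellation(c(10, 10, 10), 8, seed = 9)
  set.seed(10)
  x <- matrix(rnorm(4 * 6), 4, 6,
              dimnames = list(c("1", "2", "3", "4"), sprintf("g%d", 1:6)))
  w <- rnorm(6)
  m <- weighted_expression_map(x, w)
  expect_equal(unname(m), as.numeric(x %*% w), tolerance = 1e-12)
  one_hot <- replace(rep(0, 6), 3, 1)
  expect_equal(unname(weighted_expression_map(x, one_hot)), unname(x[, 3]))
  expect_equal(unname(weighted_expression_map(x, rep(0, 6))), rep(0, 4))
  proj <- weighted_expression_map(x, w, parc)
  expect_equal(unique(proj$volume[parc$labels == 2]), proj$map[["2"]])
})
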