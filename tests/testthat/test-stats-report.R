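test_that("one-sample test matches closed forms and rejects degeneracy", {
  sym <- one_sample_test(c(-1, 0, 1))
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)

  tight <- one_sample_test(c(0.9, 1.0, 1.1))
  expect_equal(tight$t, 1 / (0.1 / sqrt(3)), tolerance = 1e-10)  # ~17.32
  expect_lt(tight$p, 0.01)

  expect_error(one_sample_test(c(1, 1, 1)), "zero variance")
  expect_error(one_sample_test(1), "at least two")
})

test_that("paired test handles identity, separation and shifts", {
  ident <- paired_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)

  withr::with_seed(5, {
    x <- runif(7, 0.3, 0.6)
    y <- x - 0.1 + rnorm(7, sd = 0.001)
  })
  shifted <- paired_test(x, y)
  expect_lt(shifted$p, 0.001)
  expect_equal(shifted$mean_difference, 0.1, tolerance = 0.01)
})

test_that("statistical wrappers agree with textbook formulas to 1e-10", {
  withr::with_seed(99, {
    for (i in 1:20) {
      x <- rnorm(sample(4:9, 1))
      y <- rnorm(length(x))
      o1 <- oracle_one_sample_t(x)
      g1 <- one_sample_test(x)
      expect_equal(g1$t, o1$t, tolerance = 1e-10)
      expect_equal(g1$p, o1$p, tolerance = 1e-10)

      o2 <- oracle_paired_t(x, y)
      g2 <- paired_test(x, y)
      expect_equal(g2$t, o2$t, tolerance = 1e-10)
      expect_equal(g2$p, o2$p, tolerance = 1e-10)

      op <- oracle_pearson(x, y)
      expr <- data.frame(caf_id = paste0("C", seq_along(x)), gene = "G",
                         log2fc = x)
      areas <- data.frame(caf_id = paste0("C", seq_along(x)),
                          area_fraction = 2^y)
      gp <- expression_area_correlation(expr, areas)
      expect_equal(gp$r, op$r, tolerance = 1e-10)
      expect_equal(gp$p, op$p, tolerance = 1e-10)
    }
  })
})

test_that("expression-area correlation hits the exact-proportionality poles", {
  areas <- data.frame(caf_id = paste0("C", 1:5),
                      area_fraction = c(0.05, 0.1, 0.2, 0.4, 0.8))
  log_area <- log2(areas$area_fraction)
  prop <- data.frame(caf_id = areas$caf_id, gene = "UP",
                     log2fc = 2 * log_area + 1)
  flip <- data.frame(caf_id = areas$caf_id, gene = "DOWN",
                     log2fc = -0.5 * log_area)
  out <- expression_area_correlation(rbind(prop, flip), areas)
  expect_equal(out$r[out$gene == "UP"], 1, tolerance = 1e-12)
  expect_equal(out$r[out$gene == "DOWN"], -1, tolerance = 1e-12)

  # correlation is invariant to positive affine rescaling
  rescaled <- prop
  rescaled$log2fc <- 3 * prop$log2fc + 7
  out2 <- expression_area_correlation(rescaled, areas)
  expect_equal(out2$r, out$r[out$gene == "UP"], tolerance = 1e-12)

  expect_error(expression_area_correlation(
    data.frame(caf_id = "X", gene = "G", log2fc = 1), areas),
    "no matching CAF ids")
})

test_that("a planted negative expression-area slope is detected directionally", {
  neg <- 0
  for (s in 1:200) {
    withr::with_seed(3000 + s, {
      log_area <- rnorm(7, -2, 0.8)
      lfc <- -0.8 * log_area + rnorm(7, sd = 0.5)
    })
    out <- expression_area_correlation(
      data.frame(caf_id = paste0("C", 1:7), gene = "CCL2like", log2fc = lfc),
      data.frame(caf_id = paste0("C", 1:7), area_fraction = 2^log_area))
    neg <- neg + (out$r < 0)
  }
  expect_gte(neg / 200, 0.95)
})

test_that("two-component PCA matches the eigen-decomposition oracle", {
  withr::with_seed(7, m <- matrix(rnorm(7 * 20), 7, 20))
  got <- pca_two_components(m)
  want <- oracle_pca(m)
  expect_equal(align_signs(unname(got$loadings), want$loadings),
               want$loadings, tolerance = 1e-8)
  expect_equal(align_signs(unname(got$scores), want$scores),
               want$scores, tolerance = 1e-8)
  expect_equal(got$explained_variance, want$explained_variance,
               tolerance = 1e-8)

  # loadings are orthonormal, explained variance non-increasing
  expect_equal(crossprod(got$loadings), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_gte(got$explained_variance[1], got$explained_variance[2])
})

test_that("PCA degenerate geometries behave as expected", {
  v <- rnorm(6)
  collinear <- outer(v, c(1, 2, 3, 4))
  got <- pca_two_components(collinear)
  expect_equal(got$explained_variance[1], 1, tolerance = 1e-12)

  withr::with_seed(11, iso <- matrix(rnorm(4000), 2000, 2))
  ev <- pca_two_components(iso)$explained_variance
  expect_equal(ev[1], ev[2], tolerance = 0.1)
})

test_that("clustering merges duplicates first and recovers planted blocks", {
  withr::with_seed(13, {
    m <- rbind(a = rnorm(6), b = rnorm(6), c = rnorm(6))
    m <- rbind(m, a2 = m["a", ])
  })
  cl <- cluster_heatmap(m)
  merged_first <- cl$row_hclust$merge[1, ]
  expect_setequal(abs(merged_first), which(rownames(m) %in% c("a", "a2")))
  expect_equal(cl$row_hclust$height[1], 0)

  # planted two-block structure is cut perfectly
  withr::with_seed(17, {
    block <- rbind(matrix(rnorm(4 * 6, 0), 4, 6),
                   matrix(rnorm(4 * 6, 10), 4, 6))
    rownames(block) <- paste0("s", 1:8)
  })
  cut <- cluster_cut(cluster_heatmap(block), k = 2)
  expect_equal(length(unique(cut[1:4])), 1)
  expect_equal(length(unique(cut[5:8])), 1)
  expect_false(cut[1] == cut[5])

  # permuting input rows permutes labels, not tree topology
  perm <- withr::with_seed(19, sample(8))
  cut_perm <- cluster_cut(cluster_heatmap(block[perm, ]), k = 2)
  expect_equal(unname(cut_perm[rownames(block)] == cut_perm[["s1"]]),
               unname(cut[rownames(block)] == cut[["s1"]]))
})

test_that("isotype gating recovers planted positivity", {
  withr::with_seed(23, iso <- rlnorm(5000, log(100), 0.4))
  same <- cd90_positivity(iso, iso, gate_quantile = 0.99)
  expect_equal(same$fraction, 0.01, tolerance = 0.003)

  above <- cd90_positivity(rep(max(iso) + 1, 100), iso)
  expect_equal(above$fraction, 1)

  fs <- generate_flow_sample(synthetic_config(seed = 24),
                             positive_fraction = 0.96)
  est <- cd90_positivity(fs$events, fs$isotype_events)
  expect_lt(abs(est$fraction - fs$true_positive_fraction), 0.015)
})

test_that("annotation and flooring helpers follow their stated rules", {
  expect_identical(significance_stars(c(0.2, 0.04, 0.009, 0.0009, NA)),
                   c("", "*", "**", "***", ""))
  fl <- floor_area_fractions(c(0.2, 0, 0.05))
  expect_equal(fl$value, c(0.2, 0.025, 0.05))
  expect_identical(fl$floored, c(FALSE, TRUE, FALSE))
})
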