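test_that("simulated counts have the requested moments", {
  # Poisson limit: variance ~ mean when dispersion -> 0
  cm <- simulate_counts(n_genes = 200, n_per_group = 50, dispersion = 0,
                        base_means = rep(100, 200), seed = 51)
  v <- apply(cm$counts, 1, var)
  m <- rowMeans(cm$counts)
  expect_lt(abs(mean(v / m) - 1), 0.1)

  # fold change 1 everywhere: group means equal in expectation
  cm1 <- simulate_counts(500, 30, dispersion = 0.05,
                         base_means = rep(200, 500), seed = 52)
  ma <- rowMeans(cm1$counts[, cm1$condition == "A"])
  mb <- rowMeans(cm1$counts[, cm1$condition == "B"])
  expect_lt(abs(mean(mb) / mean(ma) - 1), 0.03)

  # a depth factor of 2 doubles that sample's column sum in expectation
  cm2 <- simulate_counts(2000, 2, depth_factors = c(1, 1, 2, 1),
                         base_means = rep(100, 2000), seed = 53)
  cs <- colSums(cm2$counts)
  expect_lt(abs(cs[3] / mean(cs[c(1, 2, 4)]) - 2), 0.1)
})

test_that("median-of-ratios size factors: identities and scale equivariance", {
  m <- matrix(rpois(400, 50), 100, 4)
  m[, 2] <- m[, 1]; m[, 3] <- m[, 1]; m[, 4] <- m[, 1]
  expect_equal(estimate_size_factors(m), rep(1, 4), ignore_attr = TRUE)

  m2 <- cbind(m[, 1], 2 * m[, 1])
  sf <- estimate_size_factors(m2)
  expect_equal(sf[2] / sf[1], 2, tolerance = 1e-12)

  # multiplying one column by c multiplies its factor by c (after the
  # geometric-mean renormalization, the ratio to the others scales by c)
  set.seed(54)
  cm <- simulate_counts(800, 3, seed = 54)
  sf1 <- estimate_size_factors(cm$counts)
  scaled <- cm$counts
  scaled[, 1] <- as.integer(scaled[, 1] * 3)
  sf2 <- estimate_size_factors(scaled)
  expect_equal(unname(sf2[1] / sf2[2] / (sf1[1] / sf1[2])), 3,
               tolerance = 0.02)

  zeros <- matrix(c(0L, 5L, 5L, 0L), 2, 2)
  expect_error(estimate_size_factors(zeros), "pseudocount")
  expect_length(estimate_size_factors(zeros, pseudocount = 0.5), 2)
})

test_that("size factors recover planted depth factors", {
  planted <- c(1, 1.5, 0.7, 1.2, 1, 1.5, 0.7, 1.2)
  cm <- simulate_counts(5000, 4, depth_factors = planted, seed = 55)
  sf <- estimate_size_factors(cm$counts)
  target <- planted / exp(mean(log(planted)))
  expect_lt(max(abs(sf / target - 1)), 0.05)
})

test_that("size factors agree with an established median-of-ratios implementation", {
  skip_if_not_installed("DESeq2")
  cm <- simulate_counts(1000, 3, depth_factors = c(1, 2, 0.5, 1, 1.3, 0.8),
                        seed = 56)
  ours <- estimate_size_factors(cm$counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(cm$counts)
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("NB test: planted signal found, all-zero genes get p = 1", {
  planted <- data.frame(gene = 1:10, fold_change = 4)
  cm <- simulate_counts(300, 5, planted = planted, dispersion = 0.05,
                        base_means = c(rep(500, 10), rlnorm(290, log(100), 1)),
                        seed = 57)
  cm$counts[300, ] <- 0L
  res <- nb_differential_test(cm)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_equal(res$p_value[300], 1)
  expect_equal(res$direction[300], "none")
  expect_true(all(res$p_value[1:10] < 0.01))
  expect_true(all(res$fold_change[1:10] > 2))
  # direction consistent with the sign of the log2 fold change
  nz <- res$base_mean > 0
  expect_true(all((res$log2_fold_change[nz] >= 0) ==
                    (res$direction[nz] == "up")))
})

test_that("NB test is roughly calibrated under the null", {
  cm <- simulate_counts(1500, 5, dispersion = 0.05,
                        base_means = rlnorm(1500, log(200), 0.8), seed = 58)
  res <- nb_differential_test(cm)
  frac <- mean(res$p_value < 0.01)
  # binomial 3-sigma band around 0.01 for 1500 genes, plus MoM-dispersion
  # noise; the acceptance suite tightens this at scale
  expect_lt(frac, 0.01 + 4 * sqrt(0.01 * 0.99 / 1500))
  expect_gt(frac, 0.0005)
})

test_that("DE filters apply the fold-change, p and abundance thresholds", {
  res <- structure(
    data.frame(
      gene = c("up_ok", "p_fail", "down_ok", "low_mean", "small_fc"),
      base_mean = c(50, 50, 45, 10, 50),
      mean_A = c(50, 50, 70, 10, 50),
      mean_B = c(80, 80, 41, 16, 60),
      fold_change = c(1.6, 1.6, 1 / 1.7, 1.6, 1.2),
      log2_fold_change = log2(c(1.6, 1.6, 1 / 1.7, 1.6, 1.2)),
      dispersion = 0.05,
      p_value = c(0.005, 0.02, 0.001, 0.001, 0.001),
      p_adjusted = c(0.05, 0.1, 0.02, 0.02, 0.02),
      direction = c("up", "up", "down", "up", "up"),
      stringsAsFactors = FALSE),
    class = c("de_result", "data.frame"))
  f <- apply_de_filters(res)
  expect_equal(f$up, "up_ok")
  expect_equal(f$down, "down_ok")
  expect_equal(f$selected, c(TRUE, FALSE, TRUE, FALSE, FALSE))

  # monotonicity: relaxing any threshold never drops a selected gene
  f_relaxed <- apply_de_filters(res, fc_threshold = 1.1, p_threshold = 0.05,
                                mean_threshold = 5)
  expect_true(all(f$selected <= f_relaxed$selected))

  vt <- volcano_table(res, f)
  expect_equal(vt$selected, f$selected)
  expect_equal(vt$neg_log10_p[1], -log10(0.005))
})

test_that("top-variance PCA separates planted sample clusters", {
  planted <- data.frame(gene = 1:400, fold_change = 3)
  cm <- simulate_counts(2000, 6, planted = planted, seed = 59)
  pc <- top_variance_pca(cm, n_top = 500)
  lab <- cm$condition
  # PC1 separates the two groups (silhouette-like margin > 0)
  gap <- abs(mean(pc$PC1[lab == "A"]) - mean(pc$PC1[lab == "B"]))
  spread <- max(tapply(pc$PC1, lab, sd))
  expect_gt(gap, spread)
  expect_true(all(diff(attr(pc, "var_explained")) <= 1e-8))

  # identical samples land on identical coordinates
  m <- matrix(rpois(200, 50), 100, 2)
  m <- cbind(m, m[, 1])
  pc2 <- top_variance_pca(m, n_top = 50)
  expect_equal(pc2$PC1[1], pc2$PC1[3], tolerance = 1e-10)
  expect_warning(top_variance_pca(m, n_top = 1e5), "n_top")
})
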