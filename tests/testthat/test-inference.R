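# Log transform, PCA, the penalized mixed model, and the secondary tests.

test_that("analysis table logs values with a floor and counts rows", {
  set.seed(31)
  reps <- lapply(1:3, function(i)
    make_repertoire(runif(20, 30, 150 + i * 10), bird_id = paste0("b", i)))
  m <- pairwise_kl_matrices(reps, parameters = c("mean_fm", "var_am"))
  tab <- build_analysis_table(m)
  expect_equal(nrow(tab), 6)
  # kl of 1.0 -> log of 0; verify against the raw matrix
  raw <- m$matrices$mean_fm[1, 2]
  expect_equal(tab$mean_fm[tab$template_id == "b1" & tab$target_id == "b2"],
               log(max(raw, 1e-8)))
  # below-floor values floored, with the count recorded
  m$matrices$mean_fm[1, 2] <- 1e-12
  expect_message(tab2 <- build_analysis_table(m, floor = 1e-8), "floored")
  expect_equal(attr(tab2, "n_floored"), 1)
  expect_equal(tab2$mean_fm[tab2$template_id == "b1" &
                              tab2$target_id == "b2"], log(1e-8))
})

test_that("PCA: perfectly correlated columns load on a single component", {
  set.seed(32)
  base <- rnorm(60)
  tab <- data.frame(template_id = "a", target_id = "b", population_id = "P")
  tab <- tab[rep(1, 60), ]
  for (p in sap_parameters()) tab[[p]] <- base * runif(1, 0.5, 2)
  pca <- pca_pc1(tab)
  expect_equal(pca$proportions[1], 1.0, tolerance = 1e-9)
  expect_equal(sum(pca$proportions), 1, tolerance = 1e-9)
  expect_gt(sum(pca$loadings[, 1]), 0)  # sign convention
  expect_equal(mean(pca$table$PC1), 0, tolerance = 1e-9)
})

test_that("PCA: independent equal-variance columns split variance evenly", {
  set.seed(33)
  tab <- as.data.frame(matrix(rnorm(5000 * 13), 5000, 13))
  names(tab) <- sap_parameters()
  pca <- pca_pc1(tab)
  expect_true(all(abs(pca$proportions - 1 / 13) < 0.03))
})

test_that("PCA matches a direct eigen decomposition on a toy matrix", {
  X <- matrix(c(1, 2, 4, 2, 1, 3), nrow = 3)
  tab <- data.frame(mean_pitch = X[, 1], mean_fm = X[, 2])
  pca <- pca_pc1(tab)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  e <- eigen(crossprod(Xc) / (nrow(X) - 1))
  expect_equal(pca$proportions, e$values / sum(e$values), tolerance = 1e-12)
  v1 <- e$vectors[, 1] * sign(sum(e$vectors[, 1]))
  expect_equal(abs(as.numeric(pca$loadings[, 1])), abs(v1), tolerance = 1e-12)
  expect_equal(as.numeric(abs(pca$scores[, 1])), abs(as.numeric(Xc %*% v1)),
               tolerance = 1e-12)
  # constant column dropped with warning
  tab$var_am <- 5
  expect_warning(pca2 <- pca_pc1(tab), "constant")
  expect_false("var_am" %in% rownames(pca2$loadings))
})

test_that("mixed model recovers equal means under the null", {
  tab <- simulate_pairwise_table(c(2, 2, 2), n_birds = 8, seed = 41)
  fit <- fit_variability(tab)
  expect_s3_class(fit, "variability_fit")
  for (i in 1:3) {
    expect_gt(fit$means$ci_high[i], 2 - 0.5)
    expect_lt(fit$means$ci_low[i], 2 + 0.5)
  }
  # variances stay strictly positive under the weak penalty
  expect_true(all(fit$variances > 0))
  # methods work
  expect_equal(names(coef(fit)), c("P1", "P2", "P3"))
  expect_equal(unname(predict(fit, data.frame(population_id = "P2"))),
               fit$means$mean[2])
  expect_equal(length(residuals(fit)), nrow(tab))
  expect_output(print(fit), "population means")
})

test_that("mixed model recovers a known population offset", {
  delta <- 1.0
  errs <- vapply(1:8, function(s) {
    tab <- simulate_pairwise_table(c(0, delta), n_birds = 10,
                                   sd_bird = 0.2, sd_resid = 0.5, seed = s)
    fit <- fit_variability(tab)
    diff(coef(fit)) - delta
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.1 * delta)
})

test_that("fitted means approach group means as random variances vanish", {
  tab <- simulate_pairwise_table(c(1, 3), n_birds = 6, sd_bird = 0,
                                 sd_resid = 0.4, seed = 43)
  fit <- fit_variability(tab, barrier_weight = 0)
  gm <- tapply(tab$PC1, tab$population_id, mean)
  expect_equal(unname(coef(fit)), as.numeric(gm), tolerance = 0.02)
})

test_that("likelihood-ratio test: identity, chi-square tail, invariance", {
  tab <- simulate_pairwise_table(c(0, 1.5), n_birds = 8, seed = 44)
  full <- fit_variability(tab)
  null <- fit_variability(tab, fixed = ~ 1)
  cmp <- likelihood_ratio_test(full, null)
  expect_equal(cmp$df, 1)
  expect_gte(cmp$chi_square, 0)
  # identical models: chi-square 0, p 1
  cmp0 <- likelihood_ratio_test(full, full)
  expect_equal(cmp0$chi_square, 0)
  expect_equal(cmp0$p_value, 1)
  # chi-square quantile sanity at the conventional threshold
  expect_equal(stats::pchisq(3.84, 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-3)
  # invariance of the statistic to affine rescaling of the response
  tab2 <- tab; tab2$PC1 <- 10 * tab2$PC1 + 3
  cmp2 <- likelihood_ratio_test(fit_variability(tab2),
                                fit_variability(tab2, fixed = ~ 1))
  expect_equal(cmp2$chi_square, cmp$chi_square, tolerance = 0.02)
  # non-nested rejected
  expect_error(likelihood_ratio_test(null, full), "not nested")
})

test_that("ANOVA on maximum syllable duration matches hand computation", {
  # identical groups: F = 0, p = 1
  out0 <- anova_max_duration(c(5, 6, 7, 5, 6, 7), rep(c("a", "b"), each = 3))
  expect_equal(out0$F, 0)
  expect_equal(out0$p, 1)
  # hand-computed mean squares: groups (10,12,11) vs (20,22,21)
  out <- anova_max_duration(c(10, 12, 11, 20, 22, 21),
                            rep(c("a", "b"), each = 3))
  ssb <- 3 * (11 - 16)^2 + 3 * (21 - 16)^2
  ssw <- sum((c(10, 12, 11) - 11)^2) + sum((c(20, 22, 21) - 21)^2)
  expect_equal(out$F, (ssb / 1) / (ssw / 4))
  expect_equal(out$df_between, 1)
  expect_equal(out$df_within, 4)
  expect_error(anova_max_duration(c(1, 2, 3), c("a", "a", "b")),
               "at least 2 birds")
})

test_that("Mann-Whitney U: separation, ties, exact vs approximate", {
  out <- mann_whitney_directed(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$U, 0)  # no a exceeds any b
  # identical samples: exact p = 1
  out2 <- mann_whitney_directed(c(2, 2, 2), c(2, 2, 2))
  expect_equal(out2$p, 1)
  # U agrees with the standard implementation (complement convention)
  set.seed(45)
  a <- rnorm(7); b <- rnorm(9)
  out3 <- mann_whitney_directed(a, b, exact = FALSE)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(out3$U, unname(ref$statistic))
  expect_equal(out3$p, ref$p.value, tolerance = 1e-9)
  # normal approximation close to exact enumeration at 6 vs 6
  set.seed(46)
  x <- round(rnorm(12), 2)
  pe <- mann_whitney_directed(x[1:6], x[7:12], exact = TRUE)$p
  pn <- mann_whitney_directed(x[1:6], x[7:12], exact = FALSE)$p
  expect_lt(abs(pe - pn), 0.05)
})
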