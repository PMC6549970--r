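# K-L divergence between repertoire density estimates.

test_that("density grids are normalized, floored, duplication-invariant", {
  set.seed(2)
  r <- make_repertoire(runif(40, 30, 200),
                       list(mean_pitch = runif(40, 500, 5000)))
  d <- estimate_density(r, "mean_pitch")
  expect_equal(sum(d$mass), 1, tolerance = 1e-9)
  expect_gte(min(d$mass), 0.9 * density_grid_config()$floor)
  # duplicating every syllable leaves the density unchanged
  r2 <- make_repertoire(rep(r$syllables$duration_ms, 2),
                        list(mean_pitch = rep(r$syllables$mean_pitch, 2)))
  grid <- pooled_grid(r, r2, "mean_pitch")
  expect_equal(estimate_density(r, "mean_pitch", grid)$mass,
               estimate_density(r2, "mean_pitch", grid)$mass,
               tolerance = 1e-12)
})

test_that("unsmoothed histogram matches hand binning on a 4x4 grid", {
  set.seed(6)
  dur <- runif(25, 30, 200)
  val <- runif(25, -4, -0.5)
  r <- make_repertoire(dur, list(mean_entropy = val))
  cfg <- density_grid_config(bins = c(4, 4), smooth_sigma = 0, floor = 1e-9)
  g <- pooled_grid(r, r, "mean_entropy", cfg)
  d <- estimate_density(r, "mean_entropy", g, cfg)
  h <- oracle_hist2d(dur, val, g$x_edges, g$y_edges)
  h <- h / sum(h)
  expect_equal(d$mass, (h + 1e-9) / sum(h + 1e-9), tolerance = 1e-12)
})

test_that("kl is zero iff identical, nonnegative, and matches hand example", {
  # two-cell hand computation
  p <- grid_from_mass(matrix(c(0.5, 0.5), 1, 2))
  q <- grid_from_mass(matrix(c(0.9, 0.1), 1, 2))
  expect_equal(kl(p, q), 0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1),
               tolerance = 1e-12)
  expect_equal(kl(p, q), 0.5108, tolerance = 1e-4)
  expect_equal(kl(q, p), 0.3681, tolerance = 1e-4)
  expect_false(isTRUE(all.equal(kl(p, q), kl(q, p))))  # asymmetric

  set.seed(12)
  for (i in 1:20) {
    m1 <- matrix(runif(64, 0.01, 1), 8, 8)
    m2 <- matrix(runif(64, 0.01, 1), 8, 8)
    expect_equal(kl(grid_from_mass(m1), grid_from_mass(m1)), 0)
    expect_gte(kl(grid_from_mass(m1), grid_from_mass(m2)), 0)
  }
  # mismatched grids rejected
  a <- grid_from_mass(matrix(1, 4, 4))
  b <- grid_from_mass(matrix(1, 5, 5))
  expect_error(kl(a, b), "do not match")
})

test_that("discretized Gaussians reproduce the closed-form divergence", {
  xe <- seq(-12, 14, length.out = 401)
  ye <- seq(-10, 12, length.out = 401)
  p <- gaussian_grid(xe, ye, mux = 0, sx = 1.0, muy = 1, sy = 1.5)
  q <- gaussian_grid(xe, ye, mux = 1, sx = 1.4, muy = 0, sy = 1.2)
  expected <- oracle_gauss_kl_1d(0, 1.0, 1, 1.4) +
    oracle_gauss_kl_1d(1, 1.5, 0, 1.2)
  expect_equal(kl(p, q), expected, tolerance = 0.05 * expected)
})

test_that("grid refinement changes kl by less than 10% on smooth densities", {
  xe1 <- seq(-8, 10, length.out = 33); xe2 <- seq(-8, 10, length.out = 65)
  ye1 <- seq(-8, 10, length.out = 33); ye2 <- seq(-8, 10, length.out = 65)
  k1 <- kl(gaussian_grid(xe1, ye1, 0, 1, 0, 1),
           gaussian_grid(xe1, ye1, 1, 1.3, 0.5, 0.8))
  k2 <- kl(gaussian_grid(xe2, ye2, 0, 1, 0, 1),
           gaussian_grid(xe2, ye2, 1, 1.3, 0.5, 0.8))
  expect_lt(abs(k2 - k1) / k1, 0.10)
})

test_that("pairwise matrices have n(n-1) entries and real asymmetry", {
  set.seed(21)
  reps <- lapply(1:3, function(i)
    make_repertoire(runif(30, 30, 200 + 30 * i),
                    list(mean_fm = runif(30, 5, 20 + 10 * i)),
                    bird_id = paste0("b", i)))
  m <- pairwise_kl_matrices(reps, parameters = c("mean_fm", "mean_pitch"))
  for (p in names(m$matrices)) {
    expect_equal(sum(!is.na(m$matrices[[p]])), 6)  # 3 birds -> n(n-1)
    expect_true(all(m$matrices[[p]] >= 0, na.rm = TRUE))
  }
  mm <- m$matrices$mean_fm
  expect_false(isTRUE(all.equal(mm[1, 2], mm[2, 1])))
  # a bird with < 2 syllables is excluded with a warning
  reps2 <- c(reps, list(make_repertoire(50, bird_id = "tiny")))
  expect_warning(m2 <- pairwise_kl_matrices(reps2,
                                            parameters = "mean_fm"),
                 "fewer than 2")
  expect_equal(length(m2$bird_ids), 3)
})

test_that("symmetrize averages the two directions into a half matrix", {
  set.seed(22)
  reps <- lapply(1:4, function(i)
    make_repertoire(runif(20, 30, 150 + 20 * i), bird_id = paste0("b", i)))
  m <- pairwise_kl_matrices(reps, parameters = "mean_amplitude")
  s <- symmetrize(m)
  expect_equal(nrow(s), 6)  # 4 * 3 / 2
  mm <- m$matrices$mean_amplitude
  for (r in seq_len(nrow(s))) {
    i <- match(s$bird_a[r], m$bird_ids); j <- match(s$bird_b[r], m$bird_ids)
    expect_equal(s$mean_amplitude[r], (mm[i, j] + mm[j, i]) / 2)
  }
  # an already-symmetric matrix is unchanged by averaging
  m$matrices$mean_amplitude[] <- (mm + t(mm)) / 2
  diag(m$matrices$mean_amplitude) <- NA
  s2 <- symmetrize(m)
  expect_equal(s2$mean_amplitude,
               m$matrices$mean_amplitude[cbind(match(s2$bird_a, m$bird_ids),
                                               match(s2$bird_b, m$bird_ids))])
})

test_that("tutor-tutee distances: identical birds give zero, pairs counted", {
  r <- make_repertoire(seq(40, 180, length.out = 25),
                       list(mean_entropy = seq(-3, -1, length.out = 25)))
  same <- tutor_tutee_kl(list(r), r, parameters = "mean_entropy")
  expect_equal(same$mean_entropy, 0)
  # missing tutor: pair skipped with warning
  r2 <- make_repertoire(seq(50, 190, length.out = 25), bird_id = "b2")
  expect_warning(
    out <- tutor_tutee_kl(list(r, r2), list(t1 = r),
                          tutor_map = c("t1", "missing"),
                          parameters = "mean_entropy"),
    "pair skipped")
  expect_equal(nrow(out), 1)
})
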