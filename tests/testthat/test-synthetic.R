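# The synthetic generator: determinism, degenerate limits, monotonicity,
# rendering round trips, and noise injection.

test_that("generation is deterministic and leaves the caller's RNG alone", {
  spec <- population_spec("A", n_birds = 3, syllables_per_bird = 12, seed = 5)
  a <- generate_population(spec)
  set.seed(999)
  before <- runif(1)
  b <- generate_population(spec)
  set.seed(999)
  expect_equal(runif(1), before)  # RNG state restored
  expect_identical(a, b)
})

test_that("zero dispersion and zero rendition noise collapse to identical birds", {
  spec <- population_spec("Z", n_birds = 3, syllables_per_bird = 24,
                          archetypes_per_bird = 6, pool_size = 6,
                          dispersion = 0, rendition_noise = 0, seed = 7)
  reps <- generate_population(spec)
  expect_equal(reps[[1]]$syllables$duration_ms,
               reps[[2]]$syllables$duration_ms)
  m <- pairwise_kl_matrices(reps, parameters = "mean_pitch")
  expect_equal(max(unlist(m$matrices), na.rm = TRUE), 0, tolerance = 1e-9)
})

test_that("between-bird dispersion drives mean pairwise divergence up", {
  mean_kl <- function(disp, seed) {
    reps <- generate_population(population_spec(
      "D", n_birds = 4, syllables_per_bird = 40, dispersion = disp,
      seed = seed))
    m <- pairwise_kl_matrices(reps, parameters = "mean_pitch")
    mean(m$matrices$mean_pitch, na.rm = TRUE)
  }
  for (s in 1:5) {
    expect_lt(mean_kl(1, 100 + s), mean_kl(2, 100 + s))
  }
})

test_that("tutor fidelity: tau = 1 copies, divergence decreases with tau", {
  exact <- generate_tutor_tutee(tutor_spec(fidelity = 1, rendition_noise = 0,
                                           syllables_per_bird = 24),
                                n_tutees = 2, seed = 3)
  d <- tutor_tutee_kl(exact$tutees, exact$tutor,
                      tutor_map = rep(exact$tutor$bird_id, 2),
                      parameters = "mean_pitch")
  expect_equal(max(d$mean_pitch), 0, tolerance = 1e-9)

  mean_d <- function(tau, seed) {
    g <- generate_tutor_tutee(tutor_spec(fidelity = tau,
                                         syllables_per_bird = 40),
                              n_tutees = 4, seed = seed)
    d <- tutor_tutee_kl(g$tutees, g$tutor,
                        tutor_map = rep(g$tutor$bird_id, 4),
                        parameters = "mean_pitch")
    mean(d$mean_pitch)
  }
  for (s in 1:3) {
    lo <- mean_d(1, 200 + s); mid <- mean_d(0.5, 200 + s)
    hi <- mean_d(0, 200 + s)
    expect_lt(lo, mid)
    expect_lt(mid, hi)
  }
})

test_that("rendering round trip recovers counts, boundaries, and pitch", {
  r <- generate_population(population_spec("R", n_birds = 2,
                                           syllables_per_bird = 8,
                                           seed = 17))[[1]]
  rend <- render_waveform(r)
  trk <- compute_features(rend$waveform)
  segs <- segment_syllables(trk, suggest_thresholds(trk))
  expect_equal(nrow(segs), nrow(rend$annotations))
  step <- attr(trk, "step_ms") / 1000
  expect_true(all(abs(segs$onset - rend$annotations$onset) <= step))
  expect_true(all(abs(segs$offset - rend$annotations$offset) <= step))
  tab <- syllable_table(trk, segs, r$bird_id)
  expect_true(all(abs(tab$mean_pitch / r$syllables$mean_pitch - 1) < 0.02))
  # silence renders and segments to nothing
  silent <- compute_features(waveform(rep(0, 22050), 22050))
  thr <- segmentation_thresholds(amplitude_floor = -60)
  expect_equal(nrow(segment_syllables(silent, thr)), 0)
  # pitch above Nyquist rejected
  r_bad <- r
  r_bad$syllables$mean_pitch[1] <- 20000
  expect_error(render_waveform(r_bad), "Nyquist")
})

test_that("injected clicks are removed by the duration filter", {
  r <- generate_population(population_spec("N", n_birds = 2,
                                           syllables_per_bird = 8,
                                           seed = 23))[[1]]
  rend <- render_waveform(r)
  noisy <- inject_noise(rend, noise_spec(click_rate = 1.5), seed = 11)
  n_clicks <- sum(noisy$annotations$type == "click")
  expect_gt(n_clicks, 0)
  trk <- compute_features(noisy$waveform)
  segs <- segment_syllables(trk, suggest_thresholds(trk))
  tab <- syllable_table(trk, segs, r$bird_id)
  kept <- drop_short_syllables(tab)
  expect_equal(nrow(kept), nrow(rend$annotations))
  # rate 0 leaves the waveform untouched
  clean <- inject_noise(rend, noise_spec(click_rate = 0), seed = 11)
  expect_identical(clean$waveform$samples, rend$waveform$samples)
})

test_that("long outlier bouts are caught by trimmed clustering", {
  hits <- 0; total <- 0
  for (s in 1:3) {
    r <- generate_population(population_spec("O", n_birds = 2,
                                             syllables_per_bird = 30,
                                             seed = 400 + s))[[1]]
    rend <- render_waveform(r)
    noisy <- inject_noise(rend, noise_spec(click_rate = 0,
                                           outlier_rate = 0.5),
                          seed = s)
    n_out <- sum(noisy$annotations$type == "outlier")
    if (n_out == 0) next
    trk <- compute_features(noisy$waveform)
    segs <- segment_syllables(trk, suggest_thresholds(trk))
    tab <- syllable_table(trk, segs, r$bird_id)
    tab <- drop_short_syllables(tab)
    alpha <- min(0.45, (n_out + 1) / nrow(tab))
    res <- trimmed_cluster_filter(tab, trim_config(alpha = alpha), seed = s)
    # outliers are 400-800 ms; count how many were trimmed
    hits <- hits + sum(res$discarded$duration_ms > 300)
    total <- total + n_out
  }
  expect_gt(total, 0)
  expect_gte(hits / total, 0.9)
})
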