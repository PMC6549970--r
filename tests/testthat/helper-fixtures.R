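# Small fixtures built in code.

# a feature_track from raw per-frame values (step 1 ms)
make_track <- function(amplitude,
                       pitch = rep(2000, length(amplitude)),
                       mean_frequency = rep(3000, length(amplitude)),
                       fm = rep(10, length(amplitude)),
                       am = rep(0, length(amplitude)),
                       wiener_entropy = rep(-2, length(amplitude)),
                       pitch_goodness = rep(0.8, length(amplitude)),
                       step_ms = 1) {
  n <- length(amplitude)
  structure(data.frame(time = (seq_len(n) - 1) * step_ms / 1000,
                       amplitude = amplitude, pitch = pitch,
                       mean_frequency = mean_frequency, fm = fm, am = am,
                       wiener_entropy = wiener_entropy,
                       pitch_goodness = pitch_goodness,
                       voiced = !is.na(pitch)),
            step_ms = step_ms, window_ms = 9, sample_rate = 22050,
            class = c("feature_track", "data.frame"))
}

# a repertoire from duration and per-parameter values (all 13 parameters
# constant unless supplied)
make_repertoire <- function(duration_ms, values = list(), bird_id = "b1",
                            population_id = "P") {
  n <- length(duration_ms)
  df <- data.frame(bird_id = bird_id, onset = seq_len(n),
                   offset = seq_len(n) + duration_ms / 1000,
                   duration_ms = duration_ms)
  for (p in sap_parameters())
    df[[p]] <- if (!is.null(values[[p]])) values[[p]]
               else seq(0.8, 1.2, length.out = n)
  repertoire(df, bird_id, population_id)
}

# pure tone waveform
tone_wave <- function(freq, dur_s = 0.3, sr = 22050, amp = 0.5) {
  t <- seq(0, dur_s, by = 1 / sr)
  waveform(amp * sin(2 * pi * freq * t), sr)
}

# simulated analysis table (pairwise rows) with bird and population effects;
# used for mixed-model calibration without the audio/K-L front end
simulate_pairwise_table <- function(pop_means, n_birds = 10, sd_bird = 0.3,
                                    sd_resid = 1, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (p in seq_along(pop_means)) {
    ids <- sprintf("P%d_b%02d", p, seq_len(n_birds))
    eff <- stats::setNames(stats::rnorm(n_birds, 0, sd_bird), ids)
    eff_t <- stats::setNames(stats::rnorm(n_birds, 0, sd_bird), ids)
    for (i in ids) for (j in ids) {
      if (i == j) next
      rows[[length(rows) + 1L]] <- data.frame(
        template_id = i, target_id = j,
        population_id = paste0("P", p),
        PC1 = pop_means[p] + eff[i] + eff_t[j] +
          stats::rnorm(1, 0, sd_resid),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
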