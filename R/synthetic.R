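# Synthetic repertoire generator: populations of birds whose syllables are
# Gaussian perturbations around population-level syllable archetypes, with
# optional audio rendering and noise injection so every pipeline stage can
# be validated against known ground truth.

# evaluate expr with a local RNG seed, restoring the caller's RNG state
# (seed is forced first: it may itself be drawn from the caller's RNG)
.with_seed <- function(seed, expr) {
  force(seed)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    else if (exists(".Random.seed", .GlobalEnv))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

# archetype prior ranges and base dispersion scales per parameter;
# plausible zebra-finch magnitudes, chosen for well-conditioned rendering
.param_scales <- function(duration_range = c(30, 250)) {
  data.frame(
    parameter = c("duration_ms", sap_parameters()),
    lo   = c(duration_range[1], 58, 450, 5, 50, -4, 0.3, 1500,
             1e3, 20, 0.01, 0.002, 1e4, 1e2),
    hi   = c(duration_range[2], 72, 5500, 60, 400, -0.5, 0.9, 7000,
             4e4, 400, 0.5, 0.05, 4e5, 1e4),
    sd_pop  = c(8, 2, 150, 4, 30, 0.25, 0.05, 200,
                2e3, 30, 0.04, 0.004, 2e4, 8e2),
    sd_rend = c(3, 0.5, 40, 1.5, 10, 0.08, 0.02, 60,
                6e2, 10, 0.012, 0.0015, 6e3, 2.5e2),
    clamp_lo = c(22, -Inf, 400, 0, 0, -Inf, 0, 300,
                 0, 0, 0, 0, 0, 0),
    clamp_hi = c(Inf, Inf, 6000, 90, Inf, -0.01, 1, 11025,
                 Inf, Inf, Inf, Inf, Inf, Inf),
    stringsAsFactors = FALSE)
}

.draw_archetype <- function(scales) {
  stats::setNames(stats::runif(nrow(scales), scales$lo, scales$hi),
                  scales$parameter)
}

.perturb <- function(arch, scales, sd_col, mult) {
  v <- arch + stats::rnorm(length(arch), 0, scales[[sd_col]] * mult)
  pmin(pmax(v, scales$clamp_lo), scales$clamp_hi)
}

# renditions of a bird's archetypes: round-robin archetype schedule (so a
# zero-noise bird's repertoire is exactly its archetype set) + rendition noise
.emit_syllables <- function(arch_mat, n_syllables, scales, rendition_noise,
                            bird_id, gap_ms = 50, sched = NULL) {
  n_arch <- nrow(arch_mat)
  if (is.null(sched)) sched <- rep(seq_len(n_arch), length.out = n_syllables)
  rows <- t(vapply(sched, function(a)
    .perturb(arch_mat[a, ], scales, "sd_rend", rendition_noise),
    numeric(ncol(arch_mat))))
  df <- as.data.frame(rows)
  names(df) <- colnames(arch_mat)
  df <- cbind(bird_id = bird_id, df, archetype = sched,
              stringsAsFactors = FALSE)
  offs <- cumsum(df$duration_ms + gap_ms) / 1000
  df$onset <- c(0, offs[-length(offs)]) + gap_ms / 1000
  df$offset <- df$onset + df$duration_ms / 1000
  df
}

#' Synthetic population specification
#'
#' Describes one population of birds for [generate_population()]: a pool of
#' population-level syllable archetypes; each bird perturbs a draw of
#' archetypes by between-bird noise and emits renditions with per-rendition
#' noise. `dispersion` scales the between-bird standard deviation of every
#' parameter (the population's song-variability dial); `rendition_noise`
#' scales within-bird rendition noise the same way.
#'
#' @param population_id Identifier.
#' @param n_birds Number of birds (>= 2).
#' @param archetypes_per_bird Archetypes each bird draws from the pool.
#' @param pool_size Number of archetypes in the population pool.
#' @param syllables_per_bird Renditions per bird.
#' @param dispersion Nonnegative multiplier on between-bird dispersion.
#' @param rendition_noise Nonnegative multiplier on rendition noise.
#' @param duration_range Clean syllable duration range, ms (low >= 20 so the
#'   cage-noise duration filter never touches signal).
#' @param seed Integer seed (generation is deterministic given the spec).
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(population_id, n_birds = 10,
                            archetypes_per_bird = 6, pool_size = 12,
                            syllables_per_bird = 100, dispersion = 1,
                            rendition_noise = 1,
                            duration_range = c(30, 250), seed = 1) {
  stopifnot(n_birds >= 2, archetypes_per_bird >= 1,
            pool_size >= archetypes_per_bird,
            syllables_per_bird >= 1, dispersion >= 0, rendition_noise >= 0,
            duration_range[1] >= 20, duration_range[2] > duration_range[1])
  structure(list(population_id = as.character(population_id),
                 n_birds = as.integer(n_birds),
                 archetypes_per_bird = as.integer(archetypes_per_bird),
                 pool_size = as.integer(pool_size),
                 syllables_per_bird = as.integer(syllables_per_bird),
                 dispersion = dispersion, rendition_noise = rendition_noise,
                 duration_range = duration_range, seed = as.integer(seed)),
            class = "population_spec")
}

#' Generate a synthetic population of repertoires
#'
#' @param spec A [population_spec()].
#' @return List of [repertoire()] objects, one per bird; each syllable table
#'   carries its ground-truth `archetype` label.
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  scales <- .param_scales(spec$duration_range)
  .with_seed(spec$seed, {
    pool <- t(vapply(seq_len(spec$pool_size), function(i)
      .draw_archetype(scales), numeric(nrow(scales))))
    colnames(pool) <- scales$parameter
    lapply(seq_len(spec$n_birds), function(b) {
      picks <- sort(sample.int(spec$pool_size, spec$archetypes_per_bird))
      arch <- t(vapply(picks, function(i)
        .perturb(pool[i, ], scales, "sd_pop", spec$dispersion),
        numeric(ncol(pool))))
      colnames(arch) <- scales$parameter
      bird_id <- sprintf("%s_b%02d", spec$population_id, b)
      syl <- .emit_syllables(arch, spec$syllables_per_bird, scales,
                             spec$rendition_noise, bird_id)
      repertoire(syl, bird_id, spec$population_id)
    })
  })
}

#' Tutor specification for the copying-fidelity generator
#'
#' Copying fidelity acts at the rendition level: a fraction `fidelity` of a
#' tutee's syllables are renditions of the tutor's archetypes and the rest
#' are renditions of the tutee's own innovated archetypes, so the tutee's
#' syllable distribution is the mixture
#' `fidelity * tutor + (1 - fidelity) * innovation`. The divergence from
#' the tutor is then monotone decreasing in fidelity (convexity of K-L in
#' its second argument); `fidelity = 1` reproduces the tutor exactly up to
#' rendition noise, `fidelity = 0` is an unrelated bird.
#'
#' @param fidelity Copying fidelity in \[0, 1\].
#' @param innovation_dispersion Multiplier on the innovation noise scale.
#' @param n_archetypes Archetypes per bird.
#' @param syllables_per_bird Renditions per bird.
#' @param rendition_noise Multiplier on rendition noise.
#' @param duration_range Clean duration range, ms.
#' @param tutor_id,population_id Identifiers for the tutor and the tutee
#'   group.
#' @return A list of class `tutor_spec`.
#' @export
tutor_spec <- function(fidelity = 0.7, innovation_dispersion = 1,
                       n_archetypes = 6, syllables_per_bird = 100,
                       rendition_noise = 1, duration_range = c(30, 250),
                       tutor_id = "tutor", population_id = "tutees") {
  stopifnot(fidelity >= 0, fidelity <= 1, innovation_dispersion >= 0)
  structure(list(fidelity = fidelity,
                 innovation_dispersion = innovation_dispersion,
                 n_archetypes = as.integer(n_archetypes),
                 syllables_per_bird = as.integer(syllables_per_bird),
                 rendition_noise = rendition_noise,
                 duration_range = duration_range,
                 tutor_id = tutor_id, population_id = population_id),
            class = "tutor_spec")
}

#' Generate a tutor and its tutees
#'
#' @param tspec A [tutor_spec()].
#' @param n_tutees Number of tutees.
#' @param seed Integer seed.
#' @return List with `tutor` (a [repertoire()]) and `tutees` (list of
#'   repertoires).
#' @export
generate_tutor_tutee <- function(tspec, n_tutees, seed = 1) {
  stopifnot(inherits(tspec, "tutor_spec"), n_tutees >= 1)
  scales <- .param_scales(tspec$duration_range)
  .with_seed(seed, {
    tutor_arch <- t(vapply(seq_len(tspec$n_archetypes), function(i)
      .draw_archetype(scales), numeric(nrow(scales))))
    colnames(tutor_arch) <- scales$parameter
    tutor <- repertoire(
      .emit_syllables(tutor_arch, tspec$syllables_per_bird, scales,
                      tspec$rendition_noise, tspec$tutor_id),
      tspec$tutor_id, "tutors")
    tau <- tspec$fidelity
    k <- tspec$n_archetypes
    tutees <- lapply(seq_len(n_tutees), function(b) {
      # innovated archetypes: fresh prior draws, scattered by the
      # tutee-specific innovation dispersion
      innov <- t(vapply(seq_len(k), function(i)
        .perturb(.draw_archetype(scales), scales, "sd_pop",
                 tspec$innovation_dispersion),
        numeric(nrow(scales))))
      arch <- rbind(tutor_arch, innov)
      colnames(arch) <- scales$parameter
      n_syl <- tspec$syllables_per_bird
      n_copy <- round(tau * n_syl)
      sched <- c(rep(seq_len(k), length.out = n_copy),
                 rep(k + seq_len(k), length.out = n_syl - n_copy))
      bird_id <- sprintf("%s_t%02d", tspec$population_id, b)
      repertoire(
        .emit_syllables(arch, n_syl, scales, tspec$rendition_noise,
                        bird_id, sched = sched),
        bird_id, tspec$population_id)
    })
    list(tutor = tutor, tutees = tutees)
  })
}

#' Waveform rendering configuration
#'
#' @param sample_rate Hz.
#' @param gap_ms Silence between syllables, ms.
#' @param harmonics Number of harmonics in the stack (partials above
#'   Nyquist are dropped).
#' @param ramp_ms Raised-cosine attack/decay, ms.
#' @param level Plateau amplitude of each syllable (linear, < 1). Held
#'   constant across syllables so the per-bird amplitude threshold has a
#'   well-defined half-energy crossing at the true boundary.
#' @return A list of class `render_config`.
#' @export
render_config <- function(sample_rate = 22050, gap_ms = 50, harmonics = 3,
                          ramp_ms = 0.5, level = 0.3) {
  stopifnot(sample_rate > 0, gap_ms >= 0, harmonics >= 1, level > 0,
            level <= 1)
  structure(list(sample_rate = sample_rate, gap_ms = gap_ms,
                 harmonics = as.integer(harmonics), ramp_ms = ramp_ms,
                 level = level),
            class = "render_config")
}

#' Render a repertoire as audio with ground-truth boundaries
#'
#' Each syllable becomes a harmonic stack at its `mean_pitch` (fundamental
#' plus decaying harmonics) under a raised-cosine-edged amplitude envelope;
#' syllables are separated by silent gaps.
#'
#' @param r A [repertoire()].
#' @param cfg A [render_config()].
#' @return List with `waveform` (a [waveform()]) and `annotations` (data
#'   frame `onset`, `offset` in s, `type = "syllable"`, `index`).
#' @export
render_waveform <- function(r, cfg = render_config()) {
  stopifnot(inherits(r, "repertoire"))
  sr <- cfg$sample_rate
  syl <- r$syllables
  if (any(syl$mean_pitch > sr / 2))
    stop("syllable pitch above Nyquist (", sr / 2, " Hz); cannot render")
  gap_n <- round(cfg$gap_ms / 1000 * sr)
  pieces <- list(rep(0, gap_n))
  ann <- data.frame(onset = numeric(0), offset = numeric(0))
  pos <- gap_n
  amps <- 0.5^(seq_len(cfg$harmonics) - 1)
  for (i in seq_len(nrow(syl))) {
    d_n <- round(syl$duration_ms[i] / 1000 * sr)
    t <- seq_len(d_n) / sr
    f0 <- syl$mean_pitch[i]
    keep <- which(f0 * seq_len(cfg$harmonics) < sr / 2)
    a <- amps[keep] / sqrt(sum(amps[keep]^2))  # equal RMS across syllables
    sig <- rep(0, d_n)
    for (h in seq_along(keep))
      sig <- sig + a[h] * sin(2 * pi * f0 * keep[h] * t)
    ramp_n <- max(1L, min(round(cfg$ramp_ms / 1000 * sr), d_n %/% 2))
    env <- rep(1, d_n)
    up <- 0.5 - 0.5 * cos(pi * seq_len(ramp_n) / ramp_n)
    env[seq_len(ramp_n)] <- up
    env[d_n - ramp_n + seq_len(ramp_n)] <- rev(up)
    pieces[[length(pieces) + 1L]] <- cfg$level * env * sig
    ann <- rbind(ann, data.frame(onset = pos / sr, offset = (pos + d_n) / sr))
    pos <- pos + d_n + gap_n
    pieces[[length(pieces) + 1L]] <- rep(0, gap_n)
  }
  ann$type <- rep("syllable", nrow(ann))
  ann$index <- seq_len(nrow(ann))
  list(waveform = waveform(unlist(pieces), sr), annotations = ann)
}

#' Noise-injection specification
#'
#' Clicks are broadband bursts strictly shorter than 20 ms (so the duration
#' filter removes them by construction); outlier bouts are long noise
#' segments emulating non-song sounds that survive segmentation and must be
#' caught by trimmed clustering.
#'
#' @param click_rate Clicks per second of audio.
#' @param click_ms Click duration range, ms (max < 20).
#' @param outlier_rate Outlier bouts per second of audio.
#' @param outlier_ms Outlier duration range, ms.
#' @param level Linear amplitude of injected noise.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(click_rate = 0.5, click_ms = c(2, 8),
                       outlier_rate = 0, outlier_ms = c(400, 800),
                       level = 0.3) {
  stopifnot(click_rate >= 0, outlier_rate >= 0, max(click_ms) < 20,
            min(click_ms) > 0, min(outlier_ms) > 0)
  structure(list(click_rate = click_rate, click_ms = click_ms,
                 outlier_rate = outlier_rate, outlier_ms = outlier_ms,
                 level = level),
            class = "noise_spec")
}

# free slots (gaps between annotated events, with margins) that can host an
# event of dur_s; returns start time or NA
.place_in_gap <- function(occupied, total_s, dur_s, margin_s) {
  occ <- occupied[order(occupied$onset), , drop = FALSE]
  gaps_start <- c(0, occ$offset + margin_s)
  gaps_end <- c(occ$onset - margin_s, total_s)
  ok <- which(gaps_end - gaps_start >= dur_s)
  if (length(ok) == 0) return(NA_real_)
  g <- ok[sample.int(length(ok), 1)]
  stats::runif(1, gaps_start[g], gaps_end[g] - dur_s)
}

#' Inject cage noise into a rendered song
#'
#' @param rendered List with `waveform` and `annotations` (from
#'   [render_waveform()]).
#' @param nspec A [noise_spec()].
#' @param seed Integer seed.
#' @param margin_ms Minimum clearance between injected noise and existing
#'   events, ms.
#' @return List with `waveform` and updated `annotations` (`type` one of
#'   `"syllable"`, `"click"`, `"outlier"`).
#' @export
inject_noise <- function(rendered, nspec, seed = 1, margin_ms = 15) {
  stopifnot(inherits(nspec, "noise_spec"))
  w <- rendered$waveform
  ann <- rendered$annotations
  sr <- w$sample_rate
  total_s <- length(w$samples) / sr
  .with_seed(seed, {
    events <- data.frame(dur_ms = numeric(0), type = character(0))
    n_clicks <- stats::rpois(1, nspec$click_rate * total_s)
    n_out <- stats::rpois(1, nspec$outlier_rate * total_s)
    if (n_clicks > 0)
      events <- rbind(events, data.frame(
        dur_ms = stats::runif(n_clicks, nspec$click_ms[1], nspec$click_ms[2]),
        type = "click"))
    if (n_out > 0)
      events <- rbind(events, data.frame(
        dur_ms = stats::runif(n_out, nspec$outlier_ms[1], nspec$outlier_ms[2]),
        type = "outlier"))
    x <- w$samples
    for (i in seq_len(nrow(events))) {
      dur_s <- events$dur_ms[i] / 1000
      margin_s <- margin_ms / 1000
      start <- .place_in_gap(ann, total_s, dur_s, margin_s)
      if (is.na(start)) {
        # no interior gap is long enough: append after the recording
        start <- total_s + margin_s
        x <- c(x, rep(0, round((dur_s + 2 * margin_s) * sr)))
        total_s <- length(x) / sr
      }
      n <- max(4L, round(dur_s * sr))
      i0 <- round(start * sr) + 1L
      if (i0 + n - 1L > length(x)) next
      burst <- stats::rnorm(n)
      # match the RMS of rendered syllables (level / sqrt(2)) so injected
      # noise clears the same segmentation threshold
      burst <- burst / stats::sd(burst) * nspec$level / sqrt(2)
      burst <- pmin(1, pmax(-1, burst))
      ramp_n <- max(1L, n %/% 8)
      env <- rep(1, n)
      up <- 0.5 - 0.5 * cos(pi * seq_len(ramp_n) / ramp_n)
      env[seq_len(ramp_n)] <- up
      env[n - ramp_n + seq_len(ramp_n)] <- rev(up)
      x[i0:(i0 + n - 1L)] <- x[i0:(i0 + n - 1L)] + burst * env
      ann <- rbind(ann, data.frame(onset = start, offset = start + dur_s,
                                   type = events$type[i],
                                   index = nrow(ann) + 1L))
    }
    ann <- ann[order(ann$onset), ]
    rownames(ann) <- NULL
    list(waveform = waveform(x, sr), annotations = ann)
  })
}
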