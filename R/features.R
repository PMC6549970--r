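#' Feature-extraction configuration
#'
#' Settings for [compute_features()]. The analysis band restricts all
#' spectral summaries; the pitch band restricts the autocorrelation search.
#' Frames whose normalized autocorrelation peak (pitch goodness) falls below
#' `goodness_floor` are marked unvoiced: their pitch is `NA` and they are
#' excluded from syllable pitch means/variances.
#'
#' @param band Analysis band in Hz, `c(low, high)`. `high = NULL` uses
#'   `min(11025, Nyquist)`.
#' @param pitch_band Pitch search band in Hz (default 400-6000).
#' @param goodness_floor Minimum pitch goodness for a frame to count as
#'   voiced (normalized autocorrelation units, \[0, 1\]).
#' @param amp_floor_db Amplitude floor in dB for silent frames.
#' @param entropy_smooth Width (bins) of the boxcar spectral smoother applied
#'   before Wiener entropy, reducing single-periodogram variance so a flat
#'   (white-noise) spectrum yields entropy near 0.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(band = c(300, NULL), pitch_band = c(400, 6000),
                           goodness_floor = 0.3, amp_floor_db = -120,
                           entropy_smooth = 8) {
  stopifnot(pitch_band[1] > 0, pitch_band[2] > pitch_band[1],
            entropy_smooth >= 1)
  structure(list(band = band, pitch_band = pitch_band,
                 goodness_floor = goodness_floor,
                 amp_floor_db = amp_floor_db,
                 entropy_smooth = as.integer(entropy_smooth)),
            class = "feature_config")
}

#' Compute frame-wise acoustic features
#'
#' Short-time analysis of a mono waveform into the frame-wise features used
#' for syllable segmentation and summary: amplitude (dB, log total in-band
#' power), Wiener entropy (log ratio of geometric to arithmetic mean of the
#' in-band power spectrum, always <= 0), power-weighted mean frequency,
#' frequency modulation (angle, in degrees in \[0, 90\], of the time- versus
#' frequency-derivative energy of the log spectrogram), amplitude modulation
#' (time derivative of log power, 1/s, signed), and pitch with pitch
#' goodness from the window-corrected autocorrelation peak (parabolic
#' interpolation; goodness in \[0, 1\]).
#'
#' @param w A [waveform()].
#' @param window_ms Analysis window length in ms (> `step_ms`).
#' @param step_ms Frame step in ms (> 0).
#' @param cfg A [feature_config()].
#' @return A `feature_track`: data frame with one row per frame and columns
#'   `time` (s, window centre), `amplitude`, `pitch`, `mean_frequency`,
#'   `fm`, `am`, `wiener_entropy`, `pitch_goodness`, `voiced`; attributes
#'   `step_ms`, `window_ms`, `sample_rate`.
#' @export
compute_features <- function(w, window_ms = 9, step_ms = 1,
                             cfg = feature_config()) {
  stopifnot(inherits(w, "waveform"), window_ms > step_ms, step_ms > 0)
  sr <- w$sample_rate
  band_hi <- if (length(cfg$band) >= 2 && !is.null(cfg$band[2]))
    cfg$band[2] else min(11025, sr / 2)
  band_lo <- cfg$band[1]
  if (sr < 2 * band_hi)
    stop("sample rate ", sr, " Hz is below twice the band ceiling (",
         band_hi, " Hz)")
  wlen <- max(4L, round(window_ms * sr / 1000))
  step <- max(1L, round(step_ms * sr / 1000))
  x <- w$samples
  if (length(x) < wlen)
    stop("waveform shorter than one analysis window")

  starts <- seq.int(1L, length(x) - wlen + 1L, by = step)
  nf <- length(starts)
  idx <- outer(seq_len(wlen) - 1L, starts, `+`)
  frames <- matrix(x[idx], nrow = wlen)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(wlen) / (wlen + 1))  # Hann

  lmax <- min(ceiling(sr / cfg$pitch_band[1]), wlen - 2L)
  lmin <- max(2L, floor(sr / cfg$pitch_band[2]))
  nfft <- 2^ceiling(log2(wlen + lmax + 1))
  pad <- matrix(0, nrow = nfft - wlen, ncol = nf)
  S <- stats::mvfft(rbind(frames * win, pad))
  Pfull <- Mod(S)^2
  nb <- nfft %/% 2 + 1
  P <- Pfull[seq_len(nb), , drop = FALSE]
  freqs <- (seq_len(nb) - 1) * sr / nfft
  ib <- which(freqs >= band_lo & freqs <= band_hi)
  if (length(ib) < 3) stop("analysis band contains too few frequency bins")
  Pb <- P[ib, , drop = FALSE]

  tiny <- 1e-300
  total <- colSums(Pb)
  amplitude <- 10 * log10(total + tiny)
  amplitude <- pmax(amplitude, cfg$amp_floor_db)
  silent <- total <= 0

  # Wiener entropy on a frequency-smoothed spectrum
  ksm <- min(cfg$entropy_smooth, length(ib))
  Ps <- if (ksm > 1) {
    kern <- rep(1 / ksm, ksm)
    apply(Pb, 2, function(col) as.numeric(stats::filter(col, kern, sides = 2)))
  } else Pb
  we <- vapply(seq_len(nf), function(j) {
    v <- Ps[, j]; v <- v[is.finite(v) & v > 0]
    if (length(v) < 2) return(0)
    min(0, mean(log(v)) - log(mean(v)))
  }, numeric(1))

  mean_frequency <- ifelse(total > 0, colSums(Pb * freqs[ib]) / total,
                           mean(freqs[ib]))

  # FM/AM from the log-power spectrogram
  L <- log(Pb + 1e-12)
  jm <- c(1L, seq_len(nf - 1L)); jp <- c(seq.int(2L, length.out = nf - 1L), nf)
  dT <- (L[, jp, drop = FALSE] - L[, jm, drop = FALSE]) / 2
  dF <- apply(L, 2, function(col) c(diff(col), 0))
  fm_t <- sqrt(colMeans(dT^2))
  fm_f <- sqrt(colMeans(dF^2))
  fm <- atan2(fm_t, fm_f) * 180 / pi
  fm[silent] <- 0

  step_s <- step / sr
  lp <- log(total + tiny)
  am <- (lp[jp] - lp[jm]) / (2 * step_s)
  am[silent] <- 0

  # pitch: normalized autocorrelation evaluated on a fine fractional-lag
  # grid (cosine transform of the one-sided power spectrum), corrected for
  # the window's own autocorrelation; integer-lag sampling would miss the
  # short periods of high-pitched frames
  # grid extends below the pitch-ceiling lag so short-lag plateaus (the ACF
  # of a low-pitched frame stays near 1 at small lags) are not mistaken for
  # peaks: acceptable peaks must be interior local maxima in the pitch band
  lag_fine <- seq(2, min(sr / cfg$pitch_band[1], wlen - 2), by = 0.25)
  lag_ok <- lag_fine >= sr / cfg$pitch_band[2] - 0.5
  wts <- c(1, rep(2, nb - 2), 1)
  r0 <- colSums(P * wts)
  Cmat <- cos(2 * pi * outer(lag_fine, freqs) / sr)
  wacf <- as.numeric(Cmat %*% (Mod(stats::fft(
    c(win, rep(0, nfft - wlen))))[seq_len(nb)]^2 * wts))
  w0 <- sum(Mod(stats::fft(c(win, rep(0, nfft - wlen))))[seq_len(nb)]^2 * wts)
  wn <- pmax(wacf / w0, 0.05)
  G <- (Cmat %*% (P * wts)) / (rep(pmax(r0, tiny), each = length(lag_fine)) * wn)
  nl <- length(lag_fine)
  # among in-band interior local maxima, take the first within 90% of the
  # tallest: the ACF of a periodic frame peaks at every multiple of the
  # period (avoids octave-down errors)
  best <- vapply(seq_len(nf), function(j) {
    gv <- G[, j]
    loc <- which(c(FALSE, gv[-c(1, nl)] >= gv[-c(nl - 1, nl)] &
                     gv[-c(1, nl)] >= gv[-c(1, 2)], FALSE) & lag_ok)
    if (length(loc) == 0) return(which.max(ifelse(lag_ok, gv, -Inf)))
    loc <- loc[gv[loc] >= 0.9 * max(gv[loc])]
    loc[1]
  }, integer(1))
  g0 <- G[cbind(best, seq_len(nf))]
  gm1 <- G[cbind(pmax(best - 1L, 1L), seq_len(nf))]
  gp1 <- G[cbind(pmin(best + 1L, nl), seq_len(nf))]
  denom <- gm1 - 2 * g0 + gp1
  delta <- ifelse(abs(denom) > 1e-12, 0.5 * (gm1 - gp1) / denom, 0)
  delta <- pmin(0.5, pmax(-0.5, delta))
  lag_star <- lag_fine[best] + delta * 0.25
  pitch <- sr / lag_star
  pitch <- pmin(cfg$pitch_band[2], pmax(cfg$pitch_band[1], pitch))
  goodness <- pmin(1, pmax(0, g0))
  goodness[silent] <- 0
  voiced_frame <- !silent & goodness >= cfg$goodness_floor
  pitch[!voiced_frame] <- NA_real_

  times <- (starts - 1 + (wlen - 1) / 2) / sr
  out <- data.frame(time = times, amplitude = amplitude, pitch = pitch,
                    mean_frequency = mean_frequency, fm = fm, am = am,
                    wiener_entropy = we, pitch_goodness = goodness,
                    voiced = voiced_frame)
  structure(out, step_ms = step_s * 1000, window_ms = wlen / sr * 1000,
            sample_rate = sr, class = c("feature_track", "data.frame"))
}

#' Segmentation thresholds
#'
#' A frame is voiced when its amplitude is at least `amplitude_floor` and
#' its mean frequency lies inside `mean_freq_band`. Maximal voiced runs are
#' merged across gaps shorter than `min_gap_ms`; a merged run is kept as a
#' syllable when its voiced-frame fraction is at least `continuity_min`.
#' Thresholds are intended to be set once per bird (per-recording levels
#' differ between setups); see [suggest_thresholds()].
#'
#' @param amplitude_floor dB threshold.
#' @param mean_freq_band Hz band, `c(low, high)`.
#' @param continuity_min Minimum voiced fraction in \[0, 1\].
#' @param min_gap_ms Gaps shorter than this (ms) are merged.
#' @return A list of class `segmentation_thresholds`.
#' @export
segmentation_thresholds <- function(amplitude_floor,
                                    mean_freq_band = c(300, 11025),
                                    continuity_min = 0.9, min_gap_ms = 5) {
  stopifnot(mean_freq_band[1] < mean_freq_band[2],
            continuity_min >= 0, continuity_min <= 1, min_gap_ms >= 0)
  structure(list(amplitude_floor = amplitude_floor,
                 mean_freq_band = mean_freq_band,
                 continuity_min = continuity_min,
                 min_gap_ms = min_gap_ms),
            class = "segmentation_thresholds")
}

#' Suggest per-bird segmentation thresholds from a feature track
#'
#' Places the amplitude floor a fixed drop below the loud-frame plateau
#' (upper amplitude quantile). A 3.01 dB drop marks the half-energy point of
#' a symmetric analysis window, so threshold crossings land on syllable
#' boundaries.
#'
#' @param track A `feature_track`.
#' @param drop_db Drop below the plateau in dB.
#' @param plateau_quantile Quantile of frame amplitudes taken as the plateau.
#' @param ... Passed to [segmentation_thresholds()].
#' @return A [segmentation_thresholds()].
#' @export
suggest_thresholds <- function(track, drop_db = 3.01, plateau_quantile = 0.9,
                               ...) {
  plateau <- as.numeric(stats::quantile(track$amplitude, plateau_quantile))
  segmentation_thresholds(amplitude_floor = plateau - drop_db, ...)
}

#' Segment a feature track into syllables
#'
#' @param track A `feature_track` from [compute_features()].
#' @param thr A [segmentation_thresholds()].
#' @return Data frame with columns `onset`, `offset` (s, frame centres of the
#'   first and last voiced frame), disjoint and ordered; zero rows when no
#'   frame is voiced.
#' @export
segment_syllables <- function(track, thr) {
  stopifnot(inherits(thr, "segmentation_thresholds"))
  step_ms <- attr(track, "step_ms")
  voiced <- track$amplitude >= thr$amplitude_floor &
    track$mean_frequency >= thr$mean_freq_band[1] &
    track$mean_frequency <= thr$mean_freq_band[2]
  if (!any(voiced))
    return(data.frame(onset = numeric(0), offset = numeric(0)))
  r <- rle(voiced)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by gaps shorter than min_gap
  if (nrow(runs) > 1) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap_ms <- (runs$start[i] - merged$end[nrow(merged)] - 1L) * step_ms
      if (gap_ms < thr$min_gap_ms) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  frac <- vapply(seq_len(nrow(runs)), function(i)
    mean(voiced[runs$start[i]:runs$end[i]]), numeric(1))
  runs <- runs[frac >= thr$continuity_min, , drop = FALSE]
  n <- nrow(track)
  # refine boundaries to the sub-frame amplitude crossing of the floor
  onset <- vapply(runs$start, function(i) {
    if (i <= 1 || track$amplitude[i - 1] >= thr$amplitude_floor)
      return(track$time[i])
    a0 <- track$amplitude[i - 1]; a1 <- track$amplitude[i]
    track$time[i - 1] + (thr$amplitude_floor - a0) / (a1 - a0) *
      (track$time[i] - track$time[i - 1])
  }, numeric(1))
  offset <- vapply(runs$end, function(i) {
    if (i >= n || track$amplitude[i + 1] >= thr$amplitude_floor)
      return(track$time[i])
    a0 <- track$amplitude[i]; a1 <- track$amplitude[i + 1]
    track$time[i] + (a0 - thr$amplitude_floor) / (a0 - a1) *
      (track$time[i + 1] - track$time[i])
  }, numeric(1))
  data.frame(onset = onset, offset = offset)
}

#' Summarize one syllable into duration plus the 13 parameters
#'
#' Frame-wise means and sample variances over the syllable's frames. Pitch
#' statistics use voiced frames only; if none are voiced the power-weighted
#' mean frequency is substituted and the pitch variance set to 0.
#'
#' @param track A `feature_track`.
#' @param onset,offset Interval in seconds (within the track, >= 2 frames).
#' @param bird_id Identifier carried into the record.
#' @return One-row data frame: `bird_id`, `onset`, `offset`, `duration_ms`,
#'   and the columns of [sap_parameters()].
#' @export
summarize_syllable <- function(track, onset, offset, bird_id = NA_character_) {
  stopifnot(offset > onset)
  eps <- 1e-9
  sel <- track$time >= onset - eps & track$time <= offset + eps
  n <- sum(sel)
  if (n < 2) stop("syllable interval covers fewer than 2 frames")
  tr <- track[sel, ]
  pv <- tr$pitch[!is.na(tr$pitch)]
  if (length(pv) == 0) {
    mean_pitch <- mean(tr$mean_frequency); var_pitch <- 0
  } else {
    mean_pitch <- mean(pv)
    var_pitch <- if (length(pv) >= 2) stats::var(pv) else 0
  }
  data.frame(
    bird_id = bird_id, onset = onset, offset = offset,
    duration_ms = 1000 * (offset - onset),
    mean_amplitude = mean(tr$amplitude),
    mean_pitch = mean_pitch,
    mean_fm = mean(tr$fm),
    mean_am2 = mean(tr$am^2),
    mean_entropy = mean(tr$wiener_entropy),
    mean_goodness = mean(tr$pitch_goodness),
    mean_meanfreq = mean(tr$mean_frequency),
    var_pitch = var_pitch,
    var_fm = stats::var(tr$fm),
    var_entropy = stats::var(tr$wiener_entropy),
    var_goodness = stats::var(tr$pitch_goodness),
    var_meanfreq = stats::var(tr$mean_frequency),
    var_am = stats::var(tr$am),
    stringsAsFactors = FALSE)
}

#' Build a per-bird syllable table from a track and segment list
#'
#' Intervals covering fewer than 2 frames are skipped with a warning.
#'
#' @param track A `feature_track`.
#' @param segments Data frame with `onset`, `offset` (from
#'   [segment_syllables()]).
#' @param bird_id Identifier for all rows.
#' @return Data frame of syllable records (possibly zero rows).
#' @export
syllable_table <- function(track, segments, bird_id = NA_character_) {
  rows <- list()
  for (i in seq_len(nrow(segments))) {
    rec <- tryCatch(
      summarize_syllable(track, segments$onset[i], segments$offset[i], bird_id),
      error = function(e) NULL)
    if (is.null(rec)) {
      warning("skipping interval ", i, " for ", bird_id,
              ": fewer than 2 frames")
    } else rows[[length(rows) + 1L]] <- rec
  }
  if (length(rows) == 0) {
    out <- summarize_empty_table()
  } else {
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  out
}

summarize_empty_table <- function() {
  cols <- c("bird_id", .syllable_columns())
  out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  out$bird_id <- character(0)
  out
}
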