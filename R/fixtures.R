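# Synthetic-signal generators standing in for hardware inputs. All are pure
# functions of (spec, seed): the same arguments always produce the same
# signal and the same ground truth.

#' Randomly triggered pulse train
#'
#' Exactly `n_events` rectangular 0-to-`amplitude` pulses at seeded-random
#' times: inter-event gaps are a minimum gap plus a uniform share of the
#' remaining slack (uniform jitter around the mean interval). The default
#' width reproduces a 50% duty square waveform at the mean event rate:
#' width = half the nominal period.
#'
#' @param duration Seconds.
#' @param n_events Number of pulses.
#' @param width Pulse width, seconds (default `duration / n_events / 2`).
#' @param amplitude Pulse level, volts (5 Vpp from a 0 V baseline).
#' @param min_gap Minimum silence between pulses, seconds.
#' @param seed Integer seed.
#' @return List: `signal` (vectorized function of time, volts), `onsets`
#'   (rising-edge times), `width`, `amplitude`.
#' @export
make_pulse_train <- function(duration, n_events,
                             width = duration / max(n_events, 1) / 2,
                             amplitude = 5,
                             min_gap = duration / max(n_events, 1) / 10,
                             seed = 1L) {
  if (n_events < 0) stop("n_events must be >= 0")
  if (n_events * (width + min_gap) > duration)
    stop("infeasible packing: n_events * (width + min_gap) > duration")
  onsets <- numeric(0)
  if (n_events > 0) {
    slack <- duration - n_events * (width + min_gap)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    u <- stats::runif(n_events + 1L)
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
    extra <- u / sum(u) * slack
    onsets <- cumsum(extra[seq_len(n_events)] + c(0, rep(width + min_gap, n_events - 1L)))
  }
  sig <- function(t) {
    if (!length(onsets)) return(numeric(length(t)))
    i <- findInterval(t, onsets)
    high <- i > 0L & (t - onsets[pmax(i, 1L)]) < width
    amplitude * as.numeric(high)
  }
  list(signal = sig, onsets = onsets, width = width, amplitude = amplitude)
}

# --- synthetic birdsong -----------------------------------------------------

#' Default syllable inventory
#'
#' Three spectrally distinct syllables at the given rate: a 2 kHz harmonic
#' stack (60 ms), a 3-to-5 kHz sweep (50 ms) and a 4 kHz stack (40 ms), each
#' with a Hann amplitude envelope. The first (`A`) is the conventional
#' target.
#'
#' @param rate Sample rate, Hz.
#' @return Named list of waveforms.
#' @export
syllable_inventory <- function(rate = 30000) {
  env <- function(n) hann_window(n)
  stack <- function(f0, dur, nh = 3) {
    n <- round(dur * rate); t <- (seq_len(n) - 1) / rate
    w <- numeric(n)
    for (k in seq_len(nh)) w <- w + sin(2 * pi * k * f0 * t) / k
    w / max(abs(w)) * env(n)
  }
  sweep <- function(f1, f2, dur) {
    n <- round(dur * rate); t <- (seq_len(n) - 1) / rate
    phase <- 2 * pi * (f1 * t + (f2 - f1) / (2 * dur) * t^2)
    sin(phase) * env(n)
  }
  list(A = stack(2000, 0.060), B = sweep(3000, 5000, 0.050),
       C = stack(4000, 0.040))
}

#' Synthesize a song: repeated motifs of syllables with silent gaps
#'
#' Each motif concatenates the inventory syllables in order, separated by
#' gaps of `gap_mean` seconds with seeded Gaussian jitter (truncated at
#' `min_gap`). The returned table is the ground truth for scoring
#' downstream detection.
#'
#' @param n_motifs Number of motif repetitions.
#' @param rate Sample rate, Hz.
#' @param syllables Named list of waveforms (default [syllable_inventory()]).
#' @param target Name of the target syllable.
#' @param gap_mean,gap_jitter_sd Inter-syllable gap mean and jitter, seconds.
#' @param min_gap Smallest allowed gap, seconds.
#' @param noise Background noise floor amplitude (0 = silence outside
#'   syllables).
#' @param lead Leading silence, seconds.
#' @param seed Integer seed.
#' @return List: `wave`, `rate`, `table` (data.frame: onset, offset, label),
#'   `target`, `target_onsets`.
#' @export
make_song <- function(n_motifs = 10, rate = 30000,
                      syllables = syllable_inventory(rate), target = "A",
                      gap_mean = 0.08, gap_jitter_sd = 0.01, min_gap = 0.02,
                      noise = 0, lead = 0.1, seed = 1L) {
  stopifnot(target %in% names(syllables))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  labels <- rep(names(syllables), n_motifs)
  gaps <- pmax(min_gap, stats::rnorm(length(labels), gap_mean, gap_jitter_sd))
  pieces <- list()
  onset <- numeric(length(labels)); offset <- numeric(length(labels))
  t_cursor <- lead
  for (i in seq_along(labels)) {
    syl <- syllables[[labels[i]]]
    onset[i] <- t_cursor
    offset[i] <- t_cursor + length(syl) / rate
    t_cursor <- offset[i] + gaps[i]
  }
  n <- ceiling((t_cursor + lead) * rate)
  wave <- if (noise > 0) stats::rnorm(n, 0, noise) else numeric(n)
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  for (i in seq_along(labels)) {
    s0 <- round(onset[i] * rate) + 1L
    syl <- syllables[[labels[i]]]
    wave[s0:(s0 + length(syl) - 1L)] <- wave[s0:(s0 + length(syl) - 1L)] + syl
  }
  tab <- data.frame(onset = onset, offset = offset, label = labels)
  list(wave = wave, rate = rate, table = tab, target = target,
       target_onsets = onset[labels == target])
}

# --- synthetic EEG ----------------------------------------------------------

#' Seeded pink (1/f) noise
#'
#' Spectral shaping of white Gaussian noise: amplitude scaled by
#' `f^(-1/2)` (power ~ 1/f), then rescaled to the requested standard
#' deviation.
#'
#' @param n Samples. @param rate Sample rate, Hz. @param sd Target standard
#'   deviation. @param seed Integer seed (uses the current RNG stream when
#'   NULL).
#' @return Numeric vector.
#' @export
pink_noise <- function(n, rate, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1)) * rate / n
  f <- pmin(f, rate - f + rate / n)        # mirror for the negative bins
  W <- W * f^(-0.5)
  x <- Re(stats::fft(W, inverse = TRUE) / n)
  x / stats::sd(x) * sd
}

#' Synthetic EEG with a scheduled alpha amplitude
#'
#' Pink-noise background plus a 10 Hz sinusoid whose amplitude follows an
#' eyes-open / eyes-closed segment schedule; optionally a 40 Hz artifact can
#' be added later where stimulation is on. The per-segment truth is
#' returned for scoring the gating downstream.
#'
#' @param duration Seconds.
#' @param rate Sample rate, Hz.
#' @param segment_len Seconds per eye-state segment (alternation period).
#' @param states Repeating state sequence (default EO/EC alternation;
#'   use `"EO"` for a single-state recording).
#' @param segments Optional explicit schedule: data.frame with `start`,
#'   `end`, `state` covering the full duration (overrides `segment_len` and
#'   `states`); see [eeg_session_segments()] for the standard session
#'   layouts.
#' @param alpha_eo,alpha_ec Alpha amplitude (volts) in each state.
#' @param alpha_freq Alpha frequency, Hz.
#' @param noise_sd Pink-noise background level.
#' @param seed Integer seed.
#' @return List: `x`, `rate`, `segments` (data.frame: start, end, state,
#'   alpha_amplitude).
#' @export
make_eeg <- function(duration, rate = 2000, segment_len = 30,
                     states = c("EO", "EC"), segments = NULL,
                     alpha_eo = 1, alpha_ec = 3,
                     alpha_freq = 10, noise_sd = 1, seed = 1L) {
  if (any(c(alpha_eo, alpha_ec) < 0)) stop("alpha amplitudes must be >= 0")
  n <- round(duration * rate)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  bg <- pink_noise(n, rate, sd = noise_sd, seed = seed)
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  if (is.null(segments)) {
    starts <- seq(0, duration - 1e-9, by = segment_len)
    seg <- data.frame(start = starts,
                      end = pmin(starts + segment_len, duration),
                      state = rep(states, length.out = length(starts)))
  } else {
    seg <- segments
    if (abs(max(seg$end) - duration) > 1e-9 || min(seg$start) > 1e-9)
      stop("segment schedule must cover the full duration")
  }
  seg$alpha_amplitude <- ifelse(seg$state == "EC", alpha_ec, alpha_eo)
  t <- (seq_len(n) - 1) / rate
  amp <- seg$alpha_amplitude[pmin(findInterval(t, seg$start), nrow(seg))]
  x <- bg + amp * sin(2 * pi * alpha_freq * t)
  list(x = x, rate = rate, segments = seg)
}

#' Eye-state schedule for a standard stimulation session
#'
#' Two calibration phases first (eyes open, then eyes closed, `calib_phase`
#' seconds each), followed by the protocol proper: `"EO"` keeps the eyes
#' open throughout; `"EOEC"` alternates every `segment_len` seconds.
#'
#' @param duration Total session seconds (the standard session is 12 min).
#' @param protocol `"EO"` or `"EOEC"`.
#' @param calib_phase Seconds per calibration phase.
#' @param segment_len Alternation period for `"EOEC"`, seconds.
#' @return data.frame with `start`, `end`, `state` for [make_eeg()].
#' @export
eeg_session_segments <- function(duration, protocol = c("EO", "EOEC"),
                                 calib_phase = 60, segment_len = 30) {
  protocol <- match.arg(protocol)
  if (duration <= 2 * calib_phase) stop("duration must exceed the calibration")
  seg <- data.frame(start = c(0, calib_phase), end = c(calib_phase, 2 * calib_phase),
                    state = c("EO", "EC"))
  t0 <- 2 * calib_phase
  if (protocol == "EO") {
    seg <- rbind(seg, data.frame(start = t0, end = duration, state = "EO"))
  } else {
    starts <- seq(t0, duration - 1e-9, by = segment_len)
    seg <- rbind(seg, data.frame(start = starts,
                                 end = pmin(starts + segment_len, duration),
                                 state = rep(c("EO", "EC"),
                                             length.out = length(starts))))
  }
  seg
}
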