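# Distorted-auditory-feedback pipeline: circular buffer, idle-mode RMS gate
# evaluated at 1 kHz over the trailing 10 ms, triggered-mode spectrogram
# correlation of the most recent 20 ms against a template, detection events
# with refractory, and feedback playback.

#' DAF detector configuration
#'
#' Defaults: 30 kHz audio rate; RMS over the trailing 10 ms evaluated at
#' 1 kHz; 20 ms analysis segment; Hann STFT with a 128-sample window and
#' 64-sample hop restricted to 0.5-10 kHz; detection when the Pearson
#' correlation of the live spectrogram with the template exceeds
#' `corr_threshold`. The refractory period defaults to the feedback clip
#' duration so a detection cannot retrigger on its own feedback.
#'
#' @param rate Sample rate, Hz.
#' @param rms_window RMS window, seconds.
#' @param rms_eval_rate RMS/correlation evaluation cadence, Hz.
#' @param rms_threshold Idle-to-triggered gate, volts RMS.
#' @param segment Analysis segment length, seconds.
#' @param stft_window,stft_hop STFT window and hop, samples.
#' @param band `c(f_lo, f_hi)` Hz kept in the spectrogram.
#' @param corr_threshold Detection threshold in (0, 1).
#' @param feedback Feedback waveform samples (at `rate`), possibly empty.
#' @param refractory Seconds between detections (default: feedback length,
#'   or 50 ms when no feedback clip is configured).
#' @return An `ll_daf_config` list with derived sample counts.
#' @export
daf_config <- function(rate = 30000, rms_window = 0.010, rms_eval_rate = 1000,
                       rms_threshold = 0.05, segment = 0.020,
                       stft_window = 128L, stft_hop = 64L,
                       band = c(500, 10000), corr_threshold = 0.75,
                       feedback = numeric(), refractory = NULL) {
  if (round(rate * rms_window) < 1) stop("rms window shorter than one sample")
  if (corr_threshold >= 1 || corr_threshold <= 0)
    stop("corr_threshold must be in (0, 1)")
  if (band[1] >= band[2] || band[2] > rate / 2)
    stop("band must be inside (0, rate/2)")
  if (is.null(refractory))
    refractory <- if (length(feedback)) length(feedback) / rate else 0.05
  cfg <- list(rate = rate, rms_window = rms_window, rms_eval_rate = rms_eval_rate,
              rms_threshold = rms_threshold, segment = segment,
              stft_window = as.integer(stft_window), stft_hop = as.integer(stft_hop),
              band = band, corr_threshold = corr_threshold,
              feedback = as.numeric(feedback), refractory = refractory,
              rms_n = as.integer(round(rate * rms_window)),
              seg_n = as.integer(round(rate * segment)),
              eval_every = as.integer(round(rate / rms_eval_rate)))
  class(cfg) <- "ll_daf_config"
  cfg
}

#' Root mean square of a buffer segment
#'
#' `sqrt(mean(x^2))`; invariant to sign flips of the signal.
#'
#' @param x Segment spanning exactly the configured RMS window (checked when
#'   `config` is given).
#' @param config Optional [daf_config()] to enforce the window length.
#' @return Volts.
#' @export
rms_level <- function(x, config = NULL) {
  if (!is.null(config) && length(x) != config$rms_n)
    stop("segment length ", length(x), " != rms window of ", config$rms_n,
         " samples")
  if (!length(x)) stop("empty segment")
  sqrt(mean(x^2))
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

#' Magnitude spectrogram of a 20 ms analysis segment
#'
#' Short-time Fourier transform with a Hann window, magnitude only,
#' frequency rows restricted to the configured band.
#'
#' @param x Segment of exactly `config$seg_n` samples.
#' @param config [daf_config()].
#' @return Matrix (frequency bins x frames); row names give bin centre
#'   frequencies in Hz.
#' @export
spectrogram_20ms <- function(x, config) {
  if (length(x) != config$seg_n)
    stop("segment length ", length(x), " != ", config$seg_n, " samples")
  win <- config$stft_window; hop <- config$stft_hop
  starts <- seq(1L, length(x) - win + 1L, by = hop)
  w <- hann_window(win)
  frames <- vapply(starts, function(s) x[s:(s + win - 1L)] * w, numeric(win))
  spec <- Mod(stats::mvfft(frames))
  freqs <- (seq_len(win) - 1L) * config$rate / win
  keep <- which(freqs >= config$band[1] & freqs <= config$band[2] &
                  freqs <= config$rate / 2)
  out <- spec[keep, , drop = FALSE]
  rownames(out) <- format(freqs[keep])
  out
}

#' Build a template spectrogram from a template clip
#'
#' The clip is trimmed (or zero-padded at the front) to the analysis
#' segment length, then transformed with the same STFT settings the live
#' detector uses, so correlation compares like with like.
#'
#' @param clip Template waveform at the configured rate.
#' @param config [daf_config()].
#' @return Template spectrogram matrix.
#' @export
make_template <- function(clip, config) {
  n <- config$seg_n
  x <- if (length(clip) >= n) clip[(length(clip) - n + 1L):length(clip)]
       else c(numeric(n - length(clip)), clip)
  spectrogram_20ms(x, config)
}

#' Pearson correlation between two spectrograms
#'
#' Computed over the flattened entries. A zero-variance operand (e.g. a
#' silent segment) is defined to correlate 0 with anything: silence cannot
#' match a template.
#'
#' @param spec,template Matrices of identical shape.
#' @return r in [-1, 1].
#' @export
template_corr <- function(spec, template) {
  if (!all(dim(spec) == dim(template)))
    stop("spectrogram shapes differ: ", paste(dim(spec), collapse = "x"),
         " vs ", paste(dim(template), collapse = "x"))
  a <- as.vector(spec); b <- as.vector(template)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Create a streaming DAF detector state
#'
#' @param config [daf_config()]. @param template From [make_template()].
#' @return An `ll_daf_state` environment (mode idle, empty ring buffer).
#' @export
new_daf_state <- function(config, template) {
  st <- new.env(parent = emptyenv())
  class(st) <- "ll_daf_state"
  st$config <- config
  st$template <- template
  st$buf_n <- max(config$rms_n, config$seg_n)
  st$buf <- numeric(st$buf_n)
  st$count <- 0L              # samples consumed
  st$mode <- "idle"
  st$last_detection <- -Inf
  st$fb_cursor <- 0L          # 0 = not playing
  st$detections <- numeric()
  st
}

ring_tail <- function(st, n) {
  # last n samples in arrival order (count >= n guaranteed by callers)
  pos <- ((st$count - n):(st$count - 1L)) %% st$buf_n + 1L
  st$buf[pos]
}

# shared per-evaluation-instant decision logic; t = i / rate of the sample
# just consumed. Returns TRUE on detection.
daf_evaluate <- function(st, t) {
  cfg <- st$config
  if (st$count < cfg$rms_n) return(FALSE)
  r <- sqrt(mean(ring_tail(st, cfg$rms_n)^2))
  detected <- FALSE
  if (st$mode == "idle") {
    if (r > cfg$rms_threshold) st$mode <- "triggered"
  } else {
    if (r < cfg$rms_threshold && st$fb_cursor == 0L) {
      st$mode <- "idle"
    } else if (st$count >= cfg$seg_n &&
               t - st$last_detection >= cfg$refractory) {
      spec <- spectrogram_20ms(ring_tail(st, cfg$seg_n), cfg)
      if (template_corr(spec, st$template) > cfg$corr_threshold) {
        detected <- TRUE
        st$last_detection <- t
        st$detections <- c(st$detections, t)
        if (length(cfg$feedback)) st$fb_cursor <- 1L
      }
    }
  }
  detected
}

#' Stream one audio sample through the DAF detector
#'
#' Pushes the sample into the ring buffer; at each RMS evaluation instant
#' (every `rate / rms_eval_rate` samples) the idle/triggered state machine
#' runs: the RMS gate switches idle to triggered, the spectrogram
#' correlation fires detections (subject to the refractory), and triggered
#' falls back to idle when the gate closes and no feedback is playing.
#'
#' @param sample Audio sample, volts.
#' @param st State from [new_daf_state()].
#' @return List: `detected` (logical), `feedback` (output sample, 0 when
#'   not playing).
#' @export
daf_step <- function(sample, st) {
  cfg <- st$config
  st$count <- st$count + 1L
  st$buf[(st$count - 1L) %% st$buf_n + 1L] <- sample
  detected <- if (st$count %% cfg$eval_every == 0L)
    daf_evaluate(st, st$count / cfg$rate) else FALSE
  fb <- 0
  if (st$fb_cursor > 0L) {
    fb <- cfg$feedback[st$fb_cursor]
    st$fb_cursor <- if (st$fb_cursor >= length(cfg$feedback)) 0L
                    else st$fb_cursor + 1L
  }
  list(detected = detected, feedback = fb)
}

#' Run the DAF detector over a full recording
#'
#' Chunk-efficient equivalent of streaming every sample through
#' [daf_step()]: RMS values for all evaluation instants are computed
#' vectorized, and the identical state machine is advanced instant by
#' instant. Produces exactly the same detections as the sample-by-sample
#' path.
#'
#' @param x Waveform at `config$rate`.
#' @param config [daf_config()]. @param template From [make_template()].
#' @return List: `detections` (times, s), `feedback` (output waveform, same
#'   length as `x`), `n_evaluations`.
#' @export
daf_run <- function(x, config, template) {
  cfg <- config
  n <- length(x)
  ev <- seq(cfg$eval_every, n, by = cfg$eval_every)   # sample index of instants
  cs <- cumsum(c(0, x^2))
  rms_at <- function(i) sqrt((cs[i + 1L] - cs[i + 1L - cfg$rms_n]) / cfg$rms_n)
  mode <- "idle"; last_det <- -Inf; fb_until <- 0L
  detections <- numeric()
  fb_starts <- integer()
  for (i in ev) {
    if (i < cfg$rms_n) next
    r <- rms_at(i)
    t <- i / cfg$rate
    playing <- fb_until >= i
    if (mode == "idle") {
      if (r > cfg$rms_threshold) mode <- "triggered"
    } else {
      if (r < cfg$rms_threshold && !playing) {
        mode <- "idle"
      } else if (i >= cfg$seg_n && t - last_det >= cfg$refractory) {
        spec <- spectrogram_20ms(x[(i - cfg$seg_n + 1L):i], cfg)
        if (template_corr(spec, template) > cfg$corr_threshold) {
          last_det <- t
          detections <- c(detections, t)
          if (length(cfg$feedback)) {
            # playback cursor starts on the detection sample itself
            fb_starts <- c(fb_starts, i)
            fb_until <- i + length(cfg$feedback) - 1L
          }
        }
      }
    }
  }
  feedback <- numeric(n)
  for (s in fb_starts) {
    idx <- s:min(n, s + length(cfg$feedback) - 1L)
    feedback[idx] <- cfg$feedback[seq_along(idx)]
  }
  list(detections = detections, feedback = feedback, n_evaluations = length(ev))
}

#' Score online detections against ground-truth onsets
#'
#' Greedy one-to-one matching in time order: each truth onset is matched to
#' the earliest unused detection within `[onset, onset + tolerance]`.
#'
#' @param detections Detection times, seconds.
#' @param truth Ground-truth syllable onset times, seconds.
#' @param tolerance Seconds a detection may trail its onset (> 0).
#' @return List: `hit_rate` (matched / truth; 0 for empty truth handled as
#'   NA), `hits`, `false_positives`, `misses`.
#' @export
score_detections <- function(detections, truth, tolerance) {
  if (tolerance <= 0) stop("tolerance must be > 0")
  detections <- sort(detections); truth <- sort(truth)
  used <- logical(length(detections))
  hits <- 0L
  for (tt in truth) {
    i <- which(!used & detections >= tt & detections <= tt + tolerance)
    if (length(i)) { used[i[1]] <- TRUE; hits <- hits + 1L }
  }
  list(hit_rate = if (length(truth)) hits / length(truth) else NA_real_,
       hits = hits,
       false_positives = sum(!used),
       misses = length(truth) - hits)
}
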