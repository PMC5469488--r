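# EEG alpha-power feedback stimulation control: causal 6th-order Butterworth
# 8-12 Hz band-pass, trailing 1 s mean-square alpha power, two-phase
# eyes-open / eyes-closed calibration with a 1.05x threshold, and a 0.25 Hz
# epoch controller gating 40 Hz stimulation for the first 2 s of each
# stim-on epoch.

#' Alpha-feedback controller configuration
#'
#' @param rate EEG sample rate, Hz.
#' @param order Butterworth band-pass order (even; 6 = three biquads'
#'   worth of poles on each skirt).
#' @param band Pass band `c(lo, hi)` in Hz, inside `(0, rate/2)`.
#' @param power_window Power averaging window, seconds; must not exceed the
#'   epoch length `1/decision_rate`.
#' @param decision_rate Epoch controller cadence, Hz (0.25 = 4 s epochs).
#' @param threshold_factor Calibration multiplier for the stimulation
#'   threshold.
#' @param stim_frequency Stimulation frequency, Hz.
#' @param stim_duration Seconds of stimulation at the start of a stim-on
#'   epoch.
#' @param stim_amplitude Stimulation amplitude, volts.
#' @param calib_phase Seconds per calibration phase (eyes-open then
#'   eyes-closed).
#' @param power_method `"mean_square"` (mean of squared filtered samples) or
#'   `"hilbert"` (half the mean squared analytic envelope; equal for a
#'   narrowband signal).
#' @return An `ll_alpha_config` list including the designed filter
#'   coefficients.
#' @export
alpha_config <- function(rate = 2000, order = 6, band = c(8, 12),
                         power_window = 1, decision_rate = 0.25,
                         threshold_factor = 1.05, stim_frequency = 40,
                         stim_duration = 2, stim_amplitude = 1,
                         calib_phase = 60,
                         power_method = c("mean_square", "hilbert")) {
  power_method <- match.arg(power_method)
  epoch <- 1 / decision_rate
  if (power_window > epoch)
    stop("power window must not exceed the epoch length 1/decision_rate")
  if (band[1] <= 0 || band[2] >= rate / 2 || band[1] >= band[2])
    stop("band must be inside (0, rate/2)")
  if (stim_duration > epoch) stop("stim duration cannot exceed the epoch")
  cfg <- list(rate = rate, order = as.integer(order), band = band,
              power_window = power_window, decision_rate = decision_rate,
              epoch = epoch, threshold_factor = threshold_factor,
              stim_frequency = stim_frequency, stim_duration = stim_duration,
              stim_amplitude = stim_amplitude, calib_phase = calib_phase,
              power_method = power_method,
              win_n = as.integer(round(rate * power_window)))
  cfg$filter <- design_alpha_filter(cfg)
  class(cfg) <- "ll_alpha_config"
  cfg
}

#' Design the causal alpha band-pass filter
#'
#' Butterworth band-pass of the configured order (bilinear transform via
#' \pkg{signal}); the design is rejected at configuration time if any pole
#' lies on or outside the unit circle.
#'
#' @param config [alpha_config()] fields (used before the class is set).
#' @return List with `b`, `a` coefficient vectors.
#' @export
design_alpha_filter <- function(config) {
  if (config$order %% 2L != 0L) stop("band-pass order must be even")
  bt <- signal::butter(config$order / 2L, config$band / (config$rate / 2),
                       type = "pass")
  poles <- polyroot(rev(bt$a))
  if (any(Mod(poles) >= 1))
    stop("unstable band-pass design at rate ", config$rate,
         " Hz (pole radius ", format(max(Mod(poles))), ")")
  list(b = as.numeric(bt$b), a = as.numeric(bt$a))
}

#' Causal streaming band-pass: one sample
#'
#' Direct-form I update `y_t = sum b_i x_(t-i) - sum a_j y_(t-j)`; no output
#' sample depends on future inputs. State is created on first use.
#'
#' @param sample Input sample.
#' @param state Filter state from a previous call, or `NULL` to start.
#' @param config [alpha_config()].
#' @return List: `y` (filtered sample), `state`.
#' @export
bandpass_alpha <- function(sample, state = NULL, config) {
  b <- config$filter$b; a <- config$filter$a
  m <- length(b)
  if (is.null(state)) state <- list(x = numeric(m), y = numeric(m - 1L))
  xh <- c(sample, state$x[seq_len(m - 1L)])
  y <- sum(b * xh) - sum(a[-1] * state$y)
  list(y = y, state = list(x = xh, y = c(y, state$y[seq_len(m - 2L)])))
}

# chunk filter, exactly equal to repeated bandpass_alpha up to float
# associativity; st holds the trailing (order) inputs/outputs, recent last
filter_chunk <- function(x, st, config) {
  b <- config$filter$b; a <- config$filter$a
  m <- length(b) - 1L
  if (is.null(st))
    y <- as.numeric(signal::filter(b, a, x))
  else
    y <- as.numeric(signal::filter(b, a, x, init.x = st$x, init.y = st$y))
  k <- length(x)
  take <- function(v, prev) if (k >= m) v[(k - m + 1L):k] else
    c(prev[(length(prev) - (m - k) + 1L):length(prev)], v)
  newst <- list(x = take(x, if (is.null(st)) numeric(m) else st$x),
                y = take(y, if (is.null(st)) numeric(m) else st$y))
  list(y = y, state = newst)
}

#' Mean alpha power of a filtered window
#'
#' Mean oscillation power over one power window: the mean of the squared
#' filtered samples (or, with the Hilbert flag, half the mean squared
#' analytic envelope).
#'
#' @param xf Filtered samples spanning exactly one power window.
#' @param config [alpha_config()].
#' @return Power, V^2.
#' @export
alpha_power <- function(xf, config) {
  if (length(xf) != config$win_n)
    stop("window of ", length(xf), " samples; expected ", config$win_n)
  if (config$power_method == "hilbert") {
    n <- length(xf)
    H <- stats::fft(xf)
    h <- numeric(n); h[1] <- 1
    if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
    else h[2:((n + 1) / 2)] <- 2
    env <- Mod(stats::fft(H * h, inverse = TRUE) / n)
    mean(env^2) / 2
  } else mean(xf^2)
}

#' Calibration threshold from the two mean alpha powers
#'
#' `theta = factor * (mean(P_EO) + mean(P_EC)) / 2`: the threshold is set to
#' 1.05 of the average of the eyes-open and eyes-closed mean alpha power
#' values.
#'
#' @param p_eo,p_ec Non-empty per-second power series from the two
#'   calibration phases, V^2.
#' @param factor Threshold multiplier.
#' @return theta, V^2.
#' @export
calibrate_threshold <- function(p_eo, p_ec, factor = 1.05) {
  if (!length(p_eo) || !length(p_ec))
    stop("both calibration power series must be non-empty")
  factor * (mean(p_eo) + mean(p_ec)) / 2
}

#' Create a streaming alpha-feedback controller
#'
#' The controller consumes one EEG sample per call to [controller_step()].
#' It runs the eyes-open calibration phase first, then eyes-closed, then
#' computes the threshold and enters the run phase, where it evaluates the
#' trailing power window at every epoch boundary and gates the next epoch's
#' stimulation (strictly greater than theta turns it on).
#'
#' @param config [alpha_config()].
#' @param theta Pre-computed threshold to skip calibration (the controller
#'   then starts directly in the run phase; entering the run phase without a
#'   threshold is an error).
#' @return An `ll_alpha_controller` environment.
#' @export
new_alpha_controller <- function(config, theta = NULL) {
  ctrl <- new.env(parent = emptyenv())
  class(ctrl) <- "ll_alpha_controller"
  ctrl$config <- config
  ctrl$fstate <- NULL
  ctrl$win <- numeric(config$win_n)   # ring of filtered samples
  ctrl$count <- 0L
  ctrl$p_eo <- numeric(); ctrl$p_ec <- numeric()
  ctrl$theta <- theta
  ctrl$phase <- if (is.null(theta)) "calib_EO" else "run"
  ctrl$run_start <- if (is.null(theta)) 2 * config$calib_phase else 0
  ctrl$stim_on <- FALSE
  ctrl$epoch_start <- ctrl$run_start
  ctrl$stim_epochs <- integer()
  ctrl
}

#' Step the alpha controller with one EEG sample
#'
#' @param ctrl Controller from [new_alpha_controller()].
#' @param sample Raw EEG sample, volts.
#' @return Stimulation output sample, volts (0 outside stim windows).
#' @export
controller_step <- function(ctrl, sample) {
  cfg <- ctrl$config
  fs <- bandpass_alpha(sample, ctrl$fstate, cfg)
  ctrl$fstate <- fs$state
  ctrl$count <- ctrl$count + 1L
  i <- (ctrl$count - 1L) %% cfg$win_n + 1L
  ctrl$win[i] <- fs$y
  t <- ctrl$count / cfg$rate          # time just completed
  win_full <- ctrl$count >= cfg$win_n
  # powers are needed only at second/epoch boundaries, so the window is
  # evaluated exactly there instead of tracking a drifting running sum
  power <- function() {
    ord <- ((ctrl$count - cfg$win_n):(ctrl$count - 1L)) %% cfg$win_n + 1L
    alpha_power(ctrl$win[ord], cfg)
  }
  if (ctrl$phase != "run") {
    # one power value per second of each calibration phase
    if (win_full && ctrl$count %% cfg$rate == 0L) {
      if (ctrl$phase == "calib_EO") ctrl$p_eo <- c(ctrl$p_eo, power())
      else ctrl$p_ec <- c(ctrl$p_ec, power())
    }
    if (ctrl$phase == "calib_EO" && t >= cfg$calib_phase) ctrl$phase <- "calib_EC"
    if (ctrl$phase == "calib_EC" && t >= 2 * cfg$calib_phase) {
      ctrl$theta <- calibrate_threshold(ctrl$p_eo, ctrl$p_ec, cfg$threshold_factor)
      ctrl$phase <- "run"
      ctrl$stim_on <- power() > ctrl$theta     # gate the first epoch
      ctrl$epoch_start <- t
    }
    return(0)
  }
  if (is.null(ctrl$theta)) stop("run phase entered before calibration")
  if (t - ctrl$epoch_start >= cfg$epoch - 1e-12) {   # epoch boundary
    ctrl$epoch_start <- ctrl$epoch_start + cfg$epoch
    ctrl$stim_on <- win_full && power() > ctrl$theta
    if (ctrl$stim_on)
      ctrl$stim_epochs <- c(ctrl$stim_epochs,
                            as.integer(round((ctrl$epoch_start - ctrl$run_start) /
                                               cfg$epoch)) + 1L)
  }
  tin <- t - ctrl$epoch_start
  if (ctrl$stim_on && tin < cfg$stim_duration)
    cfg$stim_amplitude * sin(2 * pi * cfg$stim_frequency * tin)
  else 0
}

#' Run a full feedback (or dose-matched random) stimulation session
#'
#' Vectorized equivalent of streaming the whole recording through
#' [controller_step()]: two calibration phases, threshold, then 4 s epochs
#' whose stimulation is gated by the trailing power window evaluated at each
#' epoch boundary (the decision gates the epoch that begins at that
#' boundary, i.e. one epoch after the activity that produced it). The
#' dose-matched random arm delivers the same number of stimulation epochs at
#' seeded uniformly random epoch positions, independent of measured power.
#'
#' @param eeg EEG samples at `config$rate`, at least calibration + 1 epoch
#'   long.
#' @param config [alpha_config()].
#' @param protocol `"feedback"` or `"dose_matched_random"`.
#' @param seed Seed for the random arm's epoch draw.
#' @return List: `theta`, `p_eo`, `p_ec`, `epochs` (data.frame with start
#'   time, boundary power, `gate` = power decision, `stim_on` = stimulation
#'   actually delivered), `stim` (output waveform, same length as `eeg`),
#'   `filtered` (band-passed EEG), `n_stim_epochs`.
#' @export
run_alpha_session <- function(eeg, config, protocol = c("feedback",
                                                        "dose_matched_random"),
                              seed = 1L) {
  protocol <- match.arg(protocol)
  cfg <- config
  n <- length(eeg)
  calib_n <- as.integer(2 * cfg$calib_phase * cfg$rate)
  epoch_n <- as.integer(cfg$epoch * cfg$rate)
  if (n < calib_n + epoch_n)
    stop("EEG source shorter than calibration plus one epoch")
  y <- filter_chunk(eeg, NULL, cfg)$y
  csq <- cumsum(y^2)
  win_power <- function(end_sample)   # trailing window ending at end_sample
    (csq[end_sample] - if (end_sample > cfg$win_n) csq[end_sample - cfg$win_n] else 0) /
      cfg$win_n
  power_at <- function(end_sample) {
    if (cfg$power_method == "hilbert")
      alpha_power(y[(end_sample - cfg$win_n + 1L):end_sample], cfg)
    else win_power(end_sample)
  }
  sec <- as.integer(cfg$calib_phase)
  p_eo <- vapply(seq_len(sec), function(s) power_at(s * cfg$rate), numeric(1))
  p_ec <- vapply(seq_len(sec), function(s) power_at((sec + s) * cfg$rate), numeric(1))
  # drop sub-window-length seconds at the very start (window not yet full)
  full <- seq_len(sec) * cfg$rate >= cfg$win_n
  p_eo <- p_eo[full]
  theta <- calibrate_threshold(p_eo, p_ec, cfg$threshold_factor)
  n_epochs <- (n - calib_n) %/% epoch_n
  starts <- calib_n + (seq_len(n_epochs) - 1L) * epoch_n   # sample offsets
  bpow <- vapply(starts, function(s) power_at(s), numeric(1))
  gate <- bpow > theta
  stim_on <- gate
  if (protocol == "dose_matched_random") {
    k <- sum(gate)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    pick <- sort(sample.int(n_epochs, k))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    stim_on <- seq_len(n_epochs) %in% pick
  }
  stim <- numeric(n)
  stim_len <- as.integer(cfg$stim_duration * cfg$rate)
  for (e in which(stim_on)) {
    # the boundary sample itself emits the phase-0 (zero-crossing) sample
    idx <- starts[e]:(starts[e] + stim_len - 1L)
    tin <- (idx - starts[e]) / cfg$rate
    stim[idx] <- cfg$stim_amplitude * sin(2 * pi * cfg$stim_frequency * tin)
  }
  list(theta = theta, p_eo = p_eo, p_ec = p_ec,
       epochs = data.frame(start = starts / cfg$rate, power = bpow,
                           gate = gate, stim_on = stim_on),
       stim = stim, filtered = y, n_stim_epochs = sum(stim_on),
       protocol = protocol)
}
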