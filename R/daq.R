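# Virtual data-acquisition device: per-channel scaling, plus an external
# high-rate sampler harness for input/output latency measurement.

#' Scale an analog-input sample
#'
#' Applies the channel's gain and offset, then clips to the measurement
#' range: `clip(gain * raw + offset, lo, hi)`. Vectorized over `raw`.
#' Monotone non-decreasing in `raw` for `gain >= 0`.
#'
#' @param raw Raw sample(s), volts.
#' @param config Channel config (an entry of `ws$channels`), direction AI.
#' @return Scaled volts.
#' @export
scale_ai <- function(raw, config) {
  if (!config$enabled) stop("read from disabled channel AI", config$index)
  if (config$direction != "AI") stop("scale_ai on non-AI channel")
  clip_range(config$gain * raw + config$offset, config$range)
}

#' Emit an analog-output value
#'
#' Clips to the channel range. NaN is propagated untouched (flagged upstream,
#' never clamped). Vectorized.
#'
#' @param value Volts. @param config Channel config, direction AO.
#' @return Emitted volts.
#' @export
emit_ao <- function(value, config) {
  if (!config$enabled) stop("write to disabled channel AO", config$index)
  if (config$direction != "AO") stop("emit_ao on non-AO channel")
  out <- value
  ok <- !is.nan(value)
  out[ok] <- clip_range(value[ok], config$range)
  out
}

#' Sample an engine-rate trace on an external sampler grid
#'
#' Zero-order hold: the sampler (default 250 kHz) sees, at each of its grid
#' times `j/rate`, the most recent engine sample at or before that time
#' (0 before the first sample).
#'
#' @param times Engine sample times (sorted, seconds).
#' @param values Engine samples.
#' @param rate Sampler rate in Hz.
#' @param duration Seconds of grid to produce.
#' @return List with `time` and `value` vectors.
#' @export
sample_zoh <- function(times, values, rate = 250000, duration = max(times)) {
  grid <- seq(0, duration, by = 1 / rate)
  idx <- findInterval(grid, times)
  v <- c(0, values)[idx + 1L]
  list(time = grid, value = v)
}

#' Detect rising edges by half-amplitude crossing
#'
#' An edge is a sample at or above the threshold whose predecessor was below
#' it. The threshold defaults to 50% of the maximum absolute level.
#'
#' @param values Sampled trace.
#' @param threshold Crossing level in volts.
#' @param prev Value preceding `values[1]` (for chunked scans).
#' @return Integer indices of edge samples.
#' @export
detect_edges <- function(values, threshold = max(abs(values)) / 2, prev = 0) {
  above <- values >= threshold
  lagged <- c(prev >= threshold, above[-length(above)])
  which(above & !lagged)
}

#' Match input edges to output edges and measure per-event latency
#'
#' Greedy in time order: each input edge is matched to the earliest unused
#' output edge at or after it; inputs with no output edge within
#' `max_latency` are counted as missed events. Latency is also reported in
#' engine periods (ceiling), the unit in which the hard real-time bound
#' (at most twice the period; a delay of no more than one sample in
#' loopback) is stated.
#'
#' @param input_edges,output_edges Edge times in seconds (sampler time base).
#' @param period Engine period, seconds.
#' @param max_latency Matching window, seconds (default 10 periods).
#' @return List: `latency` data.frame (`input_time`, `output_time`,
#'   `latency_s`, `latency_periods`), `missed` count, `unmatched_outputs`
#'   count.
#' @export
measure_latency <- function(input_edges, output_edges, period,
                            max_latency = 10 * period) {
  n_in <- length(input_edges)
  out_t <- rep(NA_real_, n_in)
  j <- 1L
  n_out <- length(output_edges)
  for (i in seq_len(n_in)) {
    while (j <= n_out && output_edges[j] < input_edges[i]) j <- j + 1L
    if (j <= n_out && output_edges[j] - input_edges[i] <= max_latency) {
      out_t[i] <- output_edges[j]
      j <- j + 1L
    }
  }
  ok <- !is.na(out_t)
  lat <- out_t[ok] - input_edges[ok]
  list(latency = data.frame(input_time = input_edges[ok], output_time = out_t[ok],
                            latency_s = lat,
                            latency_periods = ceiling(lat / period - 1e-9)),
       missed = sum(!ok),
       unmatched_outputs = n_out - sum(ok))
}

#' External-sampler latency analysis of a loopback run
#'
#' Reproduces the bench harness in which a separate acquisition system
#' samples the physical input and the engine's analog output at a high rate
#' (default 250 kHz) and measures, for every rising input edge, the delay to
#' the corresponding output edge. The input is the continuous-time source
#' signal; the output is the engine-rate AO trace held zero-order. Both are
#' evaluated on the sampler grid in chunks, so half-hour runs are analyzed
#' without materializing the full grid.
#'
#' @param signal_fn Continuous-time input signal (vectorized over t).
#' @param ao_values Engine-rate AO samples (cycle k emitted at `k/frequency`).
#' @param frequency Engine rate, Hz.
#' @param duration Seconds analyzed.
#' @param sampler_rate External sampler rate, Hz (must be >= `frequency`).
#' @param threshold Edge threshold, volts (default half the max AO level).
#' @param chunk Grid samples per chunk.
#' @return As [measure_latency()].
#' @export
measure_loopback_latency <- function(signal_fn, ao_values, frequency,
                                     duration, sampler_rate = 250000,
                                     threshold = NULL, chunk = 5000000L) {
  if (sampler_rate < frequency)
    stop("sampler rate must be at least the engine frequency")
  if (is.null(threshold)) threshold <- max(abs(ao_values)) / 2
  n_grid <- floor(duration * sampler_rate)
  in_edges <- numeric(0); out_edges <- numeric(0)
  prev_in <- 0; prev_out <- 0
  j0 <- 0L
  while (j0 < n_grid) {
    j1 <- min(j0 + chunk, n_grid)
    j <- j0:(j1 - 1L)
    grid <- j / sampler_rate
    vin <- signal_fn(grid)
    # ZOH of the engine trace: sample k covers [k/f, (k+1)/f). The cycle
    # index is computed as floor(j * f / R) in exact double-integer
    # arithmetic so boundary-aligned grid points never round down a cycle.
    idx <- pmin(floor((j * frequency) / sampler_rate) + 1, length(ao_values))
    vout <- ao_values[idx]
    ei <- detect_edges(vin, threshold, prev = prev_in)
    eo <- detect_edges(vout, threshold, prev = prev_out)
    in_edges <- c(in_edges, grid[ei])
    out_edges <- c(out_edges, grid[eo])
    prev_in <- vin[length(vin)]
    prev_out <- vout[length(vout)]
    j0 <- j1
  }
  measure_latency(in_edges, out_edges, period = 1 / frequency)
}

#' Export sampler traces to CSV
#'
#' Writes `time,channel,value` rows for one or more sampled traces.
#'
#' @param traces Named list of `list(time=, value=)` traces.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_sampler_csv <- function(traces, path) {
  df <- do.call(rbind, lapply(names(traces), function(nm)
    data.frame(time = traces[[nm]]$time, channel = nm,
               value = traces[[nm]]$value)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
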