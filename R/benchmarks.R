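# Real-time benchmark statistics: per-cycle period, jitter (signed deviation
# from nominal), and computation time, with the hard real-time pass rule
# (the realized period must never exceed twice the nominal period).

#' Create a benchmark statistics collector
#'
#' Collects cycle start timestamps and computation times. The realized
#' period `p_k = t_start(k) - t_start(k-1)`, the jitter `j_k = p_k - nominal`
#' and the computation time `c_k = t_end - t_start` are derived. In
#' simulated mode the engine stamps cycles with simulated time, so `p_k`
#' equals the nominal period identically and jitter is zero; computation
#' times are wall-clock and informational only. Raw samples are retained up
#' to `keep` cycles; beyond that only running summaries (count, mean, sd,
#' min, max, first hard-RT violation) are updated, so arbitrarily long runs
#' stay in constant memory.
#'
#' @param nominal_period Nominal engine period, seconds.
#' @param keep Maximum number of raw per-cycle samples to retain.
#' @return An `ll_benchmarks` environment.
#' @export
new_benchmark_stats <- function(nominal_period, keep = 1000000L) {
  stopifnot(is.numeric(nominal_period), nominal_period > 0)
  bm <- new.env(parent = emptyenv())
  class(bm) <- "ll_benchmarks"
  bm$nominal <- nominal_period
  bm$keep <- as.integer(keep)
  bm$t_start <- new_trace()
  bm$comp <- new_trace()
  bm$n <- 0L            # number of cycles recorded
  bm$np <- 0L           # number of periods observed (n - 1, plus bulk)
  bm$p_min <- Inf; bm$p_max <- -Inf
  bm$p_mean <- 0; bm$p_m2 <- 0     # Welford accumulators
  bm$first_violation <- NA_integer_
  bm$prev_t <- NA_real_
  bm
}

#' @export
print.ll_benchmarks <- function(x, ...) {
  cat("<ll_benchmarks> ", x$n, " cycles, nominal period ",
      format(x$nominal * 1e6), " us\n", sep = "")
  if (x$np > 0)
    cat("  period: mean ", format(x$p_mean * 1e6), " us, max ",
        format(x$p_max * 1e6), " us, hard-RT ",
        if (isTRUE(check_hard_rt(x)$pass)) "PASS" else "FAIL", "\n", sep = "")
  invisible(x)
}

bm_add_period <- function(bm, p) {
  bm$np <- bm$np + 1L
  if (p < bm$p_min) bm$p_min <- p
  if (p > bm$p_max) {
    bm$p_max <- p
    if (is.na(bm$first_violation) && p > 2 * bm$nominal + 1e-15)
      bm$first_violation <- bm$n   # period ending at the current cycle
  }
  d <- p - bm$p_mean
  bm$p_mean <- bm$p_mean + d / bm$np
  bm$p_m2 <- bm$p_m2 + d * (p - bm$p_mean)
}

#' Record the timing of one cycle
#'
#' @param bm Collector from [new_benchmark_stats()].
#' @param t_start,t_end Cycle start and end timestamps, seconds
#'   (`t_end >= t_start`; starts must be non-decreasing across calls).
#' @return The collector, invisibly.
#' @export
record_cycle_timing <- function(bm, t_start, t_end) {
  stopifnot(inherits(bm, "ll_benchmarks"))
  if (t_end < t_start) stop("non-monotone timestamps: t_end < t_start")
  if (!is.na(bm$prev_t) && t_start < bm$prev_t)
    stop("non-monotone timestamps: cycle starts must not decrease")
  bm$n <- bm$n + 1L
  if (bm$n <= bm$keep) {
    trace_push(bm$t_start, t_start)
    trace_push(bm$comp, t_end - t_start)
  }
  if (!is.na(bm$prev_t)) bm_add_period(bm, t_start - bm$prev_t)
  bm$prev_t <- t_start
  bm
}

# bulk path for chunked simulated runs: n cycles at exactly the nominal
# period with zero recorded computation cost
record_timing_bulk <- function(bm, n) {
  if (is.null(bm) || n < 1L) return(invisible(bm))
  p <- bm$nominal
  # the first ever cycle contributes no period; afterwards every cycle does
  n_new_periods <- if (is.na(bm$prev_t)) n - 1L else n
  start0 <- if (is.na(bm$prev_t)) 0 else bm$prev_t + p
  if (n_new_periods > 0) {
    if (p < bm$p_min) bm$p_min <- p
    if (p > bm$p_max) bm$p_max <- p
    tot <- bm$np + n_new_periods
    d <- p - bm$p_mean
    bm$p_mean <- bm$p_mean + d * n_new_periods / tot
    bm$p_m2 <- bm$p_m2 + d * d * bm$np * n_new_periods / tot
    bm$np <- as.integer(tot)
  }
  bm$n <- bm$n + as.integer(n)
  bm$prev_t <- start0 + (n - 1) * p
  invisible(bm)
}

#' Hard real-time check
#'
#' Passes iff no realized period exceeded twice the nominal period (the
#' boundary case of exactly twice passes). Adding cycles can keep or flip a
#' pass to fail, never the reverse.
#'
#' @param bm Collector with at least 2 recorded cycles.
#' @return List: `pass` (logical), `first_violation` (cycle index of the
#'   first violating period, NA if none), `max_period` (seconds).
#' @export
check_hard_rt <- function(bm) {
  stopifnot(inherits(bm, "ll_benchmarks"))
  if (bm$n < 2L) stop("need at least 2 recorded cycles")
  list(pass = bm$p_max <= 2 * bm$nominal + 1e-15,
       first_violation = bm$first_violation,
       max_period = bm$p_max)
}

#' Summarize benchmark statistics
#'
#' Mean/sd/min/max for the realized period, the signed jitter, and the
#' computation time, plus a period histogram.
#'
#' @param bm Collector with at least 1 cycle.
#' @param breaks Histogram breaks (passed to [graphics::hist()] semantics
#'   over retained raw periods), or NULL for automatic.
#' @return List with `summary` (data.frame: statistic rows for period,
#'   jitter, comp), `abs_jitter_max`, and `histogram` (list of `mids` and
#'   `counts`, NULL if no raw samples were retained).
#' @export
summarize_benchmarks <- function(bm, breaks = NULL) {
  stopifnot(inherits(bm, "ll_benchmarks"))
  if (bm$n < 1L) stop("no cycles recorded")
  p_sd <- if (bm$np > 1) sqrt(bm$p_m2 / (bm$np - 1)) else 0
  have_p <- bm$np > 0
  s <- data.frame(
    quantity = c("period", "jitter", "comp_time"),
    mean = c(if (have_p) bm$p_mean else NA_real_,
             if (have_p) bm$p_mean - bm$nominal else NA_real_,
             mean(trace_values(bm$comp))),
    sd = c(if (have_p) p_sd else NA_real_, if (have_p) p_sd else NA_real_,
           stats::sd(trace_values(bm$comp))),
    min = c(if (have_p) bm$p_min else NA_real_,
            if (have_p) bm$p_min - bm$nominal else NA_real_,
            suppressWarnings(min(trace_values(bm$comp)))),
    max = c(if (have_p) bm$p_max else NA_real_,
            if (have_p) bm$p_max - bm$nominal else NA_real_,
            suppressWarnings(max(trace_values(bm$comp)))))
  hist <- NULL
  ts <- trace_values(bm$t_start)
  if (length(ts) > 1) {
    periods <- diff(ts)
    h <- if (is.null(breaks)) graphics::hist(periods, plot = FALSE)
         else graphics::hist(periods, breaks = breaks, plot = FALSE)
    hist <- list(mids = h$mids, counts = h$counts)
  }
  if (length(ts) == 1 && bm$np == 0) {      # singleton: sd of one value is 0
    s$sd[3] <- 0
  }
  list(summary = s,
       abs_jitter_max = if (have_p) max(abs(c(bm$p_min, bm$p_max) - bm$nominal))
                        else NA_real_,
       histogram = hist)
}
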