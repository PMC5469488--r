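# Standard experiment modules: signal generator, Hodgkin-Huxley point
# neuron, threshold-crossing spike detector with TTL output, and
# dynamic-clamp leak-conductance injection.

# --- signal generator -------------------------------------------------------

#' Evaluate a standard stimulus waveform
#'
#' Deterministic function of time; vectorized over `t`.
#'
#' Kinds and their parameters:
#' * `dc`: `value` (volts)
#' * `sine`: `amplitude`, `frequency` (Hz), `phase` (rad), `offset`
#' * `square`: `vpp` (peak-to-peak volts, levels at offset +/- vpp/2),
#'   `frequency`, `duty` (fraction of the period spent high), `offset`
#' * `pulse_train`: `onsets` (sorted seconds), `width` (s), `level` (volts)
#' * `file_waveform`: `samples` (volts), `rate` (Hz); zero outside the clip
#'
#' @param kind Waveform kind.
#' @param params Named list of parameters for the kind.
#' @param t Time(s), seconds.
#' @return Volts, same length as `t`.
#' @export
signal_generator <- function(kind, params, t) {
  p <- function(name, default = NULL) {
    v <- params[[name]]
    if (is.null(v)) {
      if (is.null(default)) stop("signal_generator('", kind, "') needs parameter '",
                                 name, "'")
      default
    } else v
  }
  switch(kind,
    dc = rep(p("value"), length(t)),
    sine = p("amplitude") * sin(2 * pi * p("frequency") * t + p("phase", 0)) +
      p("offset", 0),
    square = {
      frac <- (t * p("frequency")) %% 1
      p("offset", 0) + ifelse(frac < p("duty", 0.5), p("vpp") / 2, -p("vpp") / 2)
    },
    pulse_train = {
      onsets <- p("onsets"); width <- p("width")
      i <- findInterval(t, onsets)
      high <- i > 0L & (t - onsets[pmax(i, 1L)]) < width
      ifelse(high, p("level", 5), 0)
    },
    file_waveform = {
      samples <- p("samples"); rate <- p("rate")
      i <- floor(t * rate) + 1L
      ok <- i >= 1L & i <= length(samples) & t >= 0
      out <- numeric(length(t))
      out[ok] <- samples[i[ok]]
      out
    },
    stop("unknown signal kind: ", kind))
}

#' Read a one-column ASCII waveform file
#'
#' One sample per line; the waveform-maker analogue for `file_waveform`.
#'
#' @param path Text file. @return Numeric vector.
#' @export
read_waveform_ascii <- function(path) as.numeric(readLines(path))

# --- Hodgkin-Huxley ---------------------------------------------------------

#' Hodgkin-Huxley parameters (classic squid-axon constants)
#'
#' `Cm` in uF/cm^2; conductances in mS/cm^2; reversal potentials in mV;
#' `stim_scale` maps the input port's volts to injected current density in
#' (uA/cm^2)/V. Resting potential of this parameterization is about -65 mV.
#'
#' @param ... Overrides of any constant.
#' @return Named list of parameters.
#' @export
hh_params <- function(...) {
  p <- list(Cm = 1, gNa = 120, gK = 36, gL = 0.3,
            ENa = 50, EK = -77, EL = -54.4, stim_scale = 10, V0 = -65)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown HH parameter(s): ", paste(bad, collapse = ", "))
  if (any(unlist(over[intersect(names(over), c("gNa", "gK", "gL"))]) < 0))
    stop("conductances must be >= 0")
  if (!is.null(over$Cm) && over$Cm <= 0) stop("Cm must be > 0")
  p[names(over)] <- over
  p
}

# voltage-dependent rate constants, 1/ms; singularities at V = -40 and -55
# are removed by their analytic limits
hh_rates <- function(V) {
  xm <- V + 40
  am <- ifelse(abs(xm) < 1e-7, 1, 0.1 * xm / (1 - exp(-xm / 10)))
  bm <- 4 * exp(-(V + 65) / 18)
  ah <- 0.07 * exp(-(V + 65) / 20)
  bh <- 1 / (1 + exp(-(V + 35) / 10))
  xn <- V + 55
  an <- ifelse(abs(xn) < 1e-7, 0.1, 0.01 * xn / (1 - exp(-xn / 10)))
  bn <- 0.125 * exp(-(V + 65) / 80)
  list(am = am, bm = bm, ah = ah, bh = bh, an = an, bn = bn)
}

#' Gating-variable steady state at a holding potential
#' @param V Membrane potential, mV. @param params From [hh_params()].
#' @return Named state vector `c(V, m, h, n)`.
#' @export
hh_steady_state <- function(V, params = hh_params()) {
  r <- hh_rates(V)
  c(V = V, m = r$am / (r$am + r$bm), h = r$ah / (r$ah + r$bh),
    n = r$an / (r$an + r$bn))
}

hh_derivs <- function(y, I, p) {
  V <- y[1]; m <- y[2]; h <- y[3]; n <- y[4]
  r <- hh_rates(V)
  c((I - p$gNa * m^3 * h * (V - p$ENa) - p$gK * n^4 * (V - p$EK) -
       p$gL * (V - p$EL)) / p$Cm,
    r$am * (1 - m) - r$bm * m,
    r$ah * (1 - h) - r$bh * h,
    r$an * (1 - n) - r$bn * n)
}

#' Advance the Hodgkin-Huxley state by one engine period
#'
#' Classical RK4 on the four-dimensional HH system
#' `C dV/dt = I - gNa m^3 h (V - ENa) - gK n^4 (V - EK) - gL (V - EL)`
#' with the standard rate functions (time constants in ms internally). The
#' step is automatically divided into substeps no longer than `max_substep`
#' so integration stays stable at periods above the stiffness bound without
#' changing engine semantics; gates are clamped to [0, 1] after every
#' substep.
#'
#' @param state Named vector `c(V, m, h, n)` (mV, unitless).
#' @param I Injected current density, uA/cm^2, held constant over the step.
#' @param dt Step, seconds.
#' @param params From [hh_params()].
#' @param max_substep Maximum internal substep, seconds (default 25 us).
#' @return The advanced state vector.
#' @export
hh_step <- function(state, I, dt, params = hh_params(), max_substep = 25e-6) {
  if (!all(is.finite(state))) stop("non-finite HH state")
  if (dt <= 0) stop("dt must be > 0")
  nsub <- max(1L, ceiling(dt / max_substep))
  hms <- dt * 1000 / nsub        # substep in ms
  y <- unname(state)
  for (i in seq_len(nsub)) {
    k1 <- hh_derivs(y, I, params)
    k2 <- hh_derivs(y + hms / 2 * k1, I, params)
    k3 <- hh_derivs(y + hms / 2 * k2, I, params)
    k4 <- hh_derivs(y + hms * k3, I, params)
    y <- y + hms / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    y[2:4] <- pmin(pmax(y[2:4], 0), 1)
  }
  c(V = y[1], m = y[2], h = y[3], n = y[4])
}

# --- spike detector ---------------------------------------------------------

#' Create a threshold-crossing spike detector
#'
#' Fires on an upward crossing of the threshold while armed: the TTL output
#' is held at `pulse_level` for `pulse_width` seconds, then the detector
#' stays disarmed until the refractory time has elapsed *and* the input has
#' fallen back below threshold (hysteresis re-arm).
#'
#' @param threshold mV. @param refractory Seconds >= 0.
#' @param pulse_width Seconds (at least one engine period to be visible).
#' @param pulse_level TTL level, volts.
#' @return An `ll_spike_detector` state environment.
#' @export
new_spike_detector <- function(threshold = -10, refractory = 0.002,
                               pulse_width = 0.001, pulse_level = 5) {
  if (refractory < 0) stop("refractory must be >= 0")
  st <- new.env(parent = emptyenv())
  class(st) <- "ll_spike_detector"
  st$threshold <- threshold
  st$refractory <- refractory
  st$pulse_width <- pulse_width
  st$pulse_level <- pulse_level
  st$armed <- TRUE
  st$pulse_until <- -Inf
  st$refr_until <- -Inf
  st$n_spikes <- 0L
  st
}

#' Step the spike detector with one membrane-potential sample
#'
#' @param V Sample, mV. @param st Detector from [new_spike_detector()].
#' @param t Current time, seconds.
#' @return TTL output for this cycle, volts.
#' @export
spike_detect <- function(V, st, t) {
  if (!st$armed && t >= st$refr_until && V < st$threshold) st$armed <- TRUE
  if (st$armed && V >= st$threshold) {
    st$armed <- FALSE
    st$pulse_until <- t + st$pulse_width
    st$refr_until <- t + st$refractory
    st$n_spikes <- st$n_spikes + 1L
  }
  if (t < st$pulse_until) st$pulse_level else 0
}

# --- dynamic clamp ----------------------------------------------------------

#' Dynamic-clamp leak current
#'
#' The current a dynamic clamp injects to add a virtual leak conductance:
#' `I = -G_leak * (V - E_leak)` in pA (nS x mV). Positive output is
#' depolarizing, so a negative `G_leak` depolarizes the cell above
#' `E_leak` -- subtracting leak and increasing excitability, the classic
#' excitability-enhancement configuration.
#'
#' @param V Membrane potential, mV (vectorized).
#' @param G_leak Virtual conductance, nS (sign free).
#' @param E_leak Reversal potential, mV.
#' @return Current in pA.
#' @export
dynamic_clamp_current <- function(V, G_leak, E_leak) -G_leak * (V - E_leak)

# --- built-in module types --------------------------------------------------

register_builtin_modules <- function() {
  define_module_type("signal_generator",
    outputs = "out",
    params = list(kind = "dc", value = 0, amplitude = 1, frequency = 1,
                  phase = 0, offset = 0, vpp = 5, duty = 0.5,
                  onsets = numeric(), width = 0.001, level = 5,
                  samples = numeric(), rate = 1),
    execute = function(mod, inputs, t, dt, engine)
      list(out = signal_generator(mod$params$kind, mod$params, t)),
    overwrite = TRUE)

  define_module_type("hh_neuron",
    inputs = "input", outputs = "Vm",
    params = hh_params(),
    init = function(mod, engine) {
      mod$hh <- hh_steady_state(mod$params$V0, mod$params)
      engine$ports[[paste0(mod$id, ".Vm")]] <- mod$params$V0
    },
    execute = function(mod, inputs, t, dt, engine) {
      I <- mod$params$stim_scale * inputs$input
      mod$hh <- hh_step(mod$hh, I, dt, mod$params)
      list(Vm = unname(mod$hh["V"]))
    },
    # parameter changes (MODIFY) take effect at the next step automatically;
    # the integrated state is deliberately kept
    overwrite = TRUE)

  define_module_type("spike_detector",
    inputs = "Vm", outputs = "TTL",
    params = list(threshold = -10, refractory = 0.002, pulse_width = 0.001,
                  pulse_level = 5),
    init = function(mod, engine) {
      mod$det <- new_spike_detector(mod$params$threshold, mod$params$refractory,
                                    mod$params$pulse_width, mod$params$pulse_level)
    },
    execute = function(mod, inputs, t, dt, engine)
      list(TTL = spike_detect(inputs$Vm, mod$det, t)),
    update = function(mod, flag, event, engine) {
      if (flag == "MODIFY") {
        mod$det$threshold <- mod$params$threshold
        mod$det$refractory <- mod$params$refractory
        mod$det$pulse_width <- mod$params$pulse_width
        mod$det$pulse_level <- mod$params$pulse_level
      }
    },
    overwrite = TRUE)

  define_module_type("dynamic_clamp",
    inputs = "Vm", outputs = "command",
    params = list(G_leak = 0, E_leak = -65, current_scale = 1000),
    execute = function(mod, inputs, t, dt, engine)
      list(command = dynamic_clamp_current(inputs$Vm, mod$params$G_leak,
                                           mod$params$E_leak) /
             mod$params$current_scale),
    overwrite = TRUE)
}

# --- closed-loop excitability probe ----------------------------------------

#' Minimal DC drive that elicits a spike under dynamic clamp
#'
#' Runs the closed loop (DC source -> HH neuron <- dynamic clamp reading the
#' neuron's own membrane potential; spike detector on Vm) and bisects the DC
#' input amplitude for the smallest drive producing at least one spike. With
#' the default scales a G_leak of -60 nS subtracts 0.6 mS/cm^2 of leak
#' density, so the threshold drive drops relative to G_leak = 0 -- the
#' directional excitability claim this function exists to demonstrate.
#'
#' @param G_leak Clamp conductance, nS.
#' @param E_leak Clamp reversal, mV (default: the neuron's resting potential).
#' @param frequency Engine rate, Hz.
#' @param duration Probe length per bisection step, seconds.
#' @param drive_range Bracketing DC input range, volts.
#' @param tol Bisection tolerance, volts.
#' @param current_scale Clamp command scale, pA per volt; with the neuron's
#'   default 10 (uA/cm^2)/V input scale, the virtual conductance density is
#'   `G_leak * 10 / current_scale` mS/cm^2 (the default maps -60 nS to
#'   -0.06 mS/cm^2, a fifth of the model's own leak).
#' @return List: `rheobase_volts` (input units),
#'   `rheobase_current` (uA/cm^2 at the neuron, using its stim scale),
#'   `iterations`.
#' @export
measure_rheobase <- function(G_leak = 0, E_leak = -65, frequency = 20000,
                             duration = 0.2, drive_range = c(0, 2),
                             tol = 0.005, current_scale = 10000) {
  spikes_at <- function(drive) {
    ws <- new_workspace(frequency = frequency)
    ws <- add_channel(ws, 0, "AO")
    ws <- add_module(ws, "signal_generator", id = "stim",
                     params = list(kind = "dc", value = drive))
    ws <- add_module(ws, "hh_neuron", id = "neuron")
    ws <- add_module(ws, "dynamic_clamp", id = "clamp",
                     params = list(G_leak = G_leak, E_leak = E_leak,
                                   current_scale = current_scale))
    ws <- add_module(ws, "spike_detector", id = "det")
    ws <- connect(ws, "stim.out", "neuron.input")
    ws <- connect(ws, "clamp.command", "neuron.input")
    ws <- connect(ws, "neuron.Vm", "clamp.Vm")
    ws <- connect(ws, "neuron.Vm", "det.Vm")
    ws <- connect(ws, "det.TTL", "AO0")
    res <- run(ws, duration, benchmarks = FALSE)
    length(detect_edges(res$ao$AO0, threshold = 2.5)) > 0
  }
  lo <- drive_range[1]; hi <- drive_range[2]
  if (spikes_at(lo)) stop("lower bracket already spikes; widen drive_range")
  if (!spikes_at(hi)) stop("upper bracket never spikes; widen drive_range")
  it <- 0L
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (spikes_at(mid)) hi <- mid else lo <- mid
    it <- it + 1L
  }
  list(rheobase_volts = hi, rheobase_current = hi * hh_params()$stim_scale,
       iterations = it)
}
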