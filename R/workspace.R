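# Workspace: engine config + channel configs + module instances + connections.
# Value-semantics S3 object; the running engine (engine.R) holds the mutable
# runtime state.

#' Create an empty workspace
#'
#' A workspace bundles the engine configuration (acquisition frequency, time
#' mode, seed), the virtual DAQ channel configurations, the ordered list of
#' loaded module instances, and the connection list. It is a plain value
#' object: build it up with [add_channel()], [add_module()] and [connect()],
#' persist it with [save_workspace()], and execute it with [run()].
#'
#' @param frequency Acquisition/computation rate in Hz. The cycle period is
#'   `1/frequency` seconds; at the default 20 kHz each cycle has a 50 microsecond
#'   budget.
#' @param mode `"simulated"` (default; simulated time, fully deterministic) or
#'   `"wallclock"` (sleeps to each cycle deadline; no hard real-time guarantee).
#' @param seed Integer seed for all engine-owned randomness.
#' @return An object of class `ll_workspace`.
#' @examples
#' ws <- new_workspace(frequency = 20000)
#' ws <- add_channel(ws, 0, "AI")
#' ws <- add_channel(ws, 0, "AO")
#' ws <- connect(ws, "AI0", "AO0")
#' @export
new_workspace <- function(frequency = 20000, mode = c("simulated", "wallclock"),
                          seed = 1L) {
  mode <- match.arg(mode)
  if (!is.numeric(frequency) || length(frequency) != 1L || !is.finite(frequency) ||
      frequency <= 0)
    stop("frequency must be a positive finite number")
  ws <- list(engine = list(frequency = as.numeric(frequency),
                           period = 1 / as.numeric(frequency),
                           mode = mode, seed = as.integer(seed)),
             channels = list(), modules = list(), connections = list(),
             next_connection_id = 1L)
  class(ws) <- "ll_workspace"
  ws
}

#' @export
print.ll_workspace <- function(x, ...) {
  cat("<ll_workspace> ", x$engine$frequency, " Hz (period ",
      format(x$engine$period * 1e6), " us), mode=", x$engine$mode,
      ", seed=", x$engine$seed, "\n", sep = "")
  cat("  channels:    ", length(x$channels), "\n")
  cat("  modules:     ", length(x$modules),
      if (length(x$modules)) paste0(" (", paste(vapply(x$modules, `[[`, "", "id"),
                                                collapse = ", "), ")") else "", "\n", sep = "")
  cat("  connections: ", length(x$connections), "\n")
  invisible(x)
}

# --- channels ---------------------------------------------------------------

#' Add a virtual DAQ channel
#'
#' Channel semantics follow a system control panel: analog-input samples are
#' scaled as `clip(gain * raw + offset, range)`; analog-output values are
#' clipped to the range. Digital I/O channels are modelled as 0/5 V analog
#' levels. Disabled channels publish nothing and reject reads/writes.
#'
#' @param ws Workspace.
#' @param index Non-negative channel index within its direction.
#' @param direction `"AI"`, `"AO"` or `"DIO"`.
#' @param mode Measurement mode label (`"ground_referenced"` or `"differential"`).
#' @param range Length-2 numeric `c(lo, hi)` in volts, `lo < hi`.
#' @param gain Dimensionless scale applied to AI samples.
#' @param offset Volts added after the gain.
#' @param enabled Logical.
#' @return The updated workspace.
#' @export
add_channel <- function(ws, index, direction = c("AI", "AO", "DIO"),
                        mode = c("ground_referenced", "differential"),
                        range = c(-10, 10), gain = 1, offset = 0,
                        enabled = TRUE) {
  stopifnot(inherits(ws, "ll_workspace"))
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  index <- as.integer(index)
  if (index < 0L) stop("channel index must be >= 0")
  if (length(range) != 2L || !all(is.finite(range)) || range[1] >= range[2])
    stop("range must be c(lo, hi) with lo < hi")
  key <- paste0(direction, index)
  if (!is.null(ws$channels[[key]]))
    stop("channel already exists: ", key)
  ws$channels[[key]] <- list(index = index, direction = direction, mode = mode,
                             range = as.numeric(range), gain = as.numeric(gain),
                             offset = as.numeric(offset),
                             enabled = isTRUE(enabled))
  ws
}

# --- modules ----------------------------------------------------------------

#' Add a module instance to a workspace
#'
#' The instance is appended to the load order, which is also the per-cycle
#' execution order. Parameters not given keep the type's defaults; invalid
#' parameter names are rejected before anything is modified.
#'
#' @param ws Workspace.
#' @param type Registered module type name (see [define_module_type()]).
#' @param id Unique instance id; defaults to the type name (with a numeric
#'   suffix if needed).
#' @param params Named list of parameter overrides.
#' @param states Named list of initial state overrides.
#' @return The updated workspace.
#' @export
add_module <- function(ws, type, id = NULL, params = list(), states = list()) {
  stopifnot(inherits(ws, "ll_workspace"))
  if (is.null(id)) {
    id <- type
    n <- 1L
    while (!is.null(ws$modules[[id]])) { n <- n + 1L; id <- paste0(type, n) }
  }
  if (grepl("[. ]", id)) stop("module ids may not contain '.' or spaces: ", id)
  if (!is.null(ws$modules[[id]])) stop("module id already in use: ", id)
  ws$modules[[id]] <- new_module_instance(type, id, params, states)
  ws
}

#' Remove a module instance from a workspace
#'
#' Connections touching the module are removed with it, so a dangling
#' connection cannot exist by construction.
#'
#' @param ws Workspace. @param id Module id.
#' @return The updated workspace.
#' @export
remove_module <- function(ws, id) {
  stopifnot(inherits(ws, "ll_workspace"))
  if (is.null(ws$modules[[id]])) stop("no such module: ", id)
  ws$modules[[id]] <- NULL
  keep <- vapply(ws$connections, function(cn) {
    endpoint_owner(cn$src) != id && endpoint_owner(cn$dst) != id
  }, logical(1))
  ws$connections <- ws$connections[keep]
  ws
}

# --- endpoints & connections ------------------------------------------------

# An endpoint is "AI0"/"AO0"/"DIO0" (a DAQ channel) or "module.port".
endpoint_owner <- function(ep) {
  if (grepl("\\.", ep)) sub("\\..*$", "", ep) else ".daq"
}

is_daq_endpoint <- function(ep) grepl("^(AI|AO|DIO)[0-9]+$", ep)

# Resolve an endpoint and report its dataflow direction:
# sources ("output" side): AI channels, module output ports
# sinks   ("input" side):  AO channels, module input ports; DIO may be either.
resolve_endpoint <- function(ws, ep) {
  if (is_daq_endpoint(ep)) {
    ch <- ws$channels[[ep]]
    if (is.null(ch)) stop("unknown DAQ channel endpoint: ", ep)
    side <- switch(ch$direction, AI = "output", AO = "input", DIO = "both")
    return(list(kind = "daq", key = ep, side = side))
  }
  if (!grepl("^[^.]+\\.[^.]+$", ep))
    stop("malformed endpoint '", ep, "' (expected 'module.port' or e.g. 'AI0')")
  id <- sub("\\..*$", "", ep); port <- sub("^[^.]*\\.", "", ep)
  m <- ws$modules[[id]]
  if (is.null(m)) stop("unknown module in endpoint: ", ep)
  def <- module_type(m$type)
  if (port %in% def$outputs) return(list(kind = "module", key = ep, side = "output"))
  if (port %in% def$inputs)  return(list(kind = "module", key = ep, side = "input"))
  stop("module '", id, "' has no port named '", port, "'")
}

#' Connect an output endpoint to an input endpoint
#'
#' Endpoints are `"module.port"` strings or DAQ channel names (`"AI0"`,
#' `"AO1"`, `"DIO0"`). Many-to-one fan-in is allowed: all sources feeding one
#' input are summed at gather time. Duplicate and direction-mismatched
#' connections are rejected.
#'
#' @param ws Workspace.
#' @param src Source endpoint (an output port or AI channel).
#' @param dst Destination endpoint (an input port or AO channel).
#' @return The updated workspace; the new connection id is in
#'   `attr(, "connection_id")`.
#' @export
connect <- function(ws, src, dst) {
  stopifnot(inherits(ws, "ll_workspace"))
  s <- resolve_endpoint(ws, src); d <- resolve_endpoint(ws, dst)
  if (!(s$side %in% c("output", "both")))
    stop("source endpoint is not an output: ", src)
  if (!(d$side %in% c("input", "both")))
    stop("destination endpoint is not an input: ", dst)
  for (cn in ws$connections)
    if (cn$src == src && cn$dst == dst)
      stop("duplicate connection: ", src, " -> ", dst)
  cid <- ws$next_connection_id
  ws$connections[[length(ws$connections) + 1L]] <-
    list(id = cid, src = src, dst = dst)
  ws$next_connection_id <- cid + 1L
  attr(ws, "connection_id") <- cid
  ws
}

#' Remove a connection by id
#' @param ws Workspace. @param id Connection id as returned by [connect()].
#' @return The updated workspace.
#' @export
disconnect <- function(ws, id) {
  stopifnot(inherits(ws, "ll_workspace"))
  ids <- vapply(ws$connections, `[[`, integer(1), "id")
  hit <- which(ids == id)
  if (!length(hit)) stop("no such connection id: ", id)
  ws$connections <- ws$connections[-hit]
  ws
}

#' Validate a workspace
#'
#' Checks that every connection endpoint resolves with the correct direction,
#' channel ranges are ordered, and module types/parameters are consistent.
#'
#' @param ws Workspace.
#' @return `TRUE` invisibly, or an error naming the offending element.
#' @export
validate_workspace <- function(ws) {
  stopifnot(inherits(ws, "ll_workspace"))
  if (ws$engine$frequency <= 0) stop("engine frequency must be > 0")
  if (abs(ws$engine$period * ws$engine$frequency - 1) > 1e-9)
    stop("engine period is inconsistent with the frequency")
  for (m in ws$modules) module_type(m$type)   # errors on unknown types
  for (cn in ws$connections) {
    s <- resolve_endpoint(ws, cn$src); d <- resolve_endpoint(ws, cn$dst)
    if (!(s$side %in% c("output", "both")))
      stop("connection ", cn$id, ": source is not an output: ", cn$src)
    if (!(d$side %in% c("input", "both")))
      stop("connection ", cn$id, ": destination is not an input: ", cn$dst)
  }
  invisible(TRUE)
}

# Sources feeding each input endpoint, ordered by ascending connection id
# (the fixed summation order).
incoming_map <- function(ws) {
  if (!length(ws$connections)) return(list())
  ids <- vapply(ws$connections, `[[`, integer(1), "id")
  out <- list()
  for (cn in ws$connections[order(ids)])
    out[[cn$dst]] <- c(out[[cn$dst]], cn$src)
  out
}

#' Gather rule: summed fan-in for one input endpoint
#'
#' Returns the sum of the current values of all source ports connected to
#' `dst`, in ascending connection-id order; an unconnected input reads 0.
#' This is the dataflow rule the engine applies before every module execute
#' and analog-output emit.
#'
#' @param values Named list/environment of current port values keyed by
#'   endpoint string.
#' @param sources Character vector of source endpoints (from the connection
#'   table), possibly empty.
#' @return Scalar sum (0 for an unconnected input).
#' @export
gather_input <- function(values, sources) {
  if (!length(sources)) return(0)
  tot <- 0
  for (s in sources) {
    v <- values[[s]]
    tot <- tot + (if (is.null(v)) 0 else v)
  }
  tot
}
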