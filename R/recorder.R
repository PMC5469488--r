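# HDF5 trial recorder.
#
# Layout (versioned dialect; plain HDF5, no custom filters, readable by any
# standard HDF5 tool):
#   /Trial N                        group; attrs: Period, Start Time,
#                                   Stop Time, Downsample, Column Names
#     /Synchronous Data             rows x signals float64 matrix
#                                   (omitted when a trial stored no rows)
#     /Parameters/<module>.<name>   per-parameter change table (time, value),
#                                   attr "Initial Value" = snapshot at start;
#                                   a scalar 0 placeholder when no changes
#     /System Settings/Channels     enabled AI channel configs (numeric
#                                   matrix; names/modes/fields as attrs)
#     /Tags/Times, /Tags/Text       experiment tags (when any)
# Times are float64 seconds of simulated time, so identical runs produce
# byte-identical files.

h5_with_fid <- function(path, fun) {
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  fun(fid)
}

h5_set_attr <- function(path, obj, name, value) {
  h5_with_fid(path, function(fid) {
    oid <- rhdf5::H5Oopen(fid, obj)
    on.exit(rhdf5::H5Oclose(oid), add = TRUE)
    rhdf5::h5writeAttribute(value, oid, name)
  })
  invisible()
}

#' Open or create an HDF5 recording file
#'
#' A recording file holds numbered trial groups (`/Trial 1`, `/Trial 2`,
#' ...). When the file already exists the caller must choose: append new
#' trials after the existing ones, or overwrite (truncate) the file;
#' otherwise an error is raised, mirroring the choice an operator is given.
#'
#' @param path HDF5 file path.
#' @param append Add trials to an existing file.
#' @param overwrite Truncate an existing file.
#' @return An `ll_recording` handle.
#' @export
create_recording <- function(path, append = FALSE, overwrite = FALSE) {
  if (file.exists(path)) {
    if (overwrite) {
      file.remove(path)
      rhdf5::h5createFile(path)
    } else if (!append) {
      stop("file exists: ", path,
           " -- choose append = TRUE (next trial number) or overwrite = TRUE")
    }
  } else {
    rhdf5::h5createFile(path)
  }
  rec <- new.env(parent = emptyenv())
  class(rec) <- "ll_recording"
  rec$path <- path
  rec$active <- FALSE
  rec
}

#' Number of trials stored in a recording file
#' @param path HDF5 file path (or an `ll_recording` handle).
#' @return Integer count.
#' @export
count_trials <- function(path) {
  if (inherits(path, "ll_recording")) path <- path$path
  if (!file.exists(path)) return(0L)
  ls <- rhdf5::h5ls(path, recursive = FALSE)
  if (is.null(ls) || !nrow(ls)) return(0L)
  sum(grepl("^Trial [0-9]+$", ls$name))
}

snapshot_params <- function(modules) {
  snap <- list()
  for (m in modules) {
    p <- if (is.environment(m)) m$params else m$params
    id <- if (is.environment(m)) m$id else m$id
    for (nm in names(p)) snap[[paste0(id, ".", nm)]] <- p[[nm]]
  }
  snap
}

#' Start a recording trial
#'
#' Creates the next `/Trial N` group, snapshots every module parameter, and
#' stores the enabled AI channel configurations ("System Settings"). Rows
#' are then buffered by [record_cycle()] and flushed by [stop_trial()].
#'
#' @param rec Recording handle from [create_recording()].
#' @param ws Workspace (or running `ll_engine`) providing the period, module
#'   parameters and channel configs.
#' @param signals Character vector of port endpoints to record, in column
#'   order.
#' @param downsample Positive integer k: cycles with index divisible by k
#'   are stored (decimation, no anti-alias filter), so a trial of n cycles
#'   stores `ceiling(n / k)` rows.
#' @param start_time Simulated time of the trial start, seconds.
#' @return An `ll_trial` handle.
#' @export
start_trial <- function(rec, ws, signals, downsample = 1L, start_time = 0) {
  stopifnot(inherits(rec, "ll_recording"))
  if (isTRUE(rec$active)) stop("a trial is already active on this file")
  downsample <- as.integer(downsample)
  if (is.na(downsample) || downsample < 1L)
    stop("downsample factor must be a positive integer")
  signals <- as.character(signals)
  is_engine <- inherits(ws, "ll_engine")
  channels <- if (is_engine) ws$channels else ws$channels
  modules <- if (is_engine) ws$modules else ws$modules
  period <- if (is_engine) ws$period else ws$engine$period
  # signals must resolve to channels or module ports
  for (s in signals) {
    if (!is.null(channels[[s]])) next
    if (grepl("^[^.]+\\.[^.]+$", s)) {
      id <- sub("\\..*$", "", s); port <- sub("^[^.]*\\.", "", s)
      m <- modules[[id]]
      if (!is.null(m)) {
        def <- module_type(if (is.environment(m)) m$type else m$type)
        if (port %in% c(def$inputs, def$outputs)) next
      }
    }
    stop("recorded signal does not resolve to a port or channel: ", s)
  }
  n_prev <- count_trials(rec$path)
  trial_name <- paste0("Trial ", n_prev + 1L)
  rhdf5::h5createGroup(rec$path, trial_name)
  rhdf5::h5createGroup(rec$path, paste0(trial_name, "/Parameters"))
  rhdf5::h5createGroup(rec$path, paste0(trial_name, "/System Settings"))

  h <- new.env(parent = emptyenv())
  class(h) <- "ll_trial"
  h$rec <- rec
  h$path <- rec$path
  h$trial <- n_prev + 1L
  h$name <- trial_name
  h$signals <- signals
  h$k <- downsample
  h$period <- period
  h$start_time <- start_time
  h$snapshot <- snapshot_params(modules)
  h$changes <- list()          # per-param list of c(time, value) rows
  h$tags <- list()
  h$buf <- matrix(0, nrow = 256L, ncol = length(signals))
  h$rows <- 0L
  h$n_cycles <- 0L
  h$active <- TRUE
  # System Settings: enabled AI channels
  ai <- channels[vapply(channels, function(ch) ch$enabled && ch$direction == "AI",
                        logical(1))]
  h$sysset <- ai
  rec$active <- TRUE
  rec$trial <- h
  h
}

buf_push_rows <- function(h, rows) {
  need <- h$rows + nrow(rows)
  if (need > nrow(h$buf)) {
    grow <- matrix(0, nrow = max(nrow(h$buf), need), ncol = ncol(h$buf))
    h$buf <- rbind(h$buf, grow)
  }
  h$buf[(h$rows + 1L):need, ] <- rows
  h$rows <- need
}

#' Buffer one cycle of recorded values
#'
#' Stores the row iff `cycle_index` is divisible by the trial's downsample
#' factor; every offered cycle counts toward the trial length either way.
#'
#' @param h Trial handle. @param cycle_index Cycle index (0-based).
#' @param values Numeric vector, one value per registered signal.
#' @return Logical: was the row stored?
#' @export
record_cycle <- function(h, cycle_index, values) {
  stopifnot(inherits(h, "ll_trial"))
  if (!isTRUE(h$active)) stop("trial is not active")
  if (length(values) != length(h$signals))
    stop("value count mismatch: got ", length(values), ", expected ",
         length(h$signals))
  h$n_cycles <- max(h$n_cycles, as.integer(cycle_index) + 1L)
  if (cycle_index %% h$k != 0L) return(invisible(FALSE))
  buf_push_rows(h, matrix(as.numeric(values), nrow = 1L))
  invisible(TRUE)
}

# engine hook: pull registered signal values out of the port table
record_engine_cycle <- function(h, cycle_index, ports) {
  if (cycle_index %% h$k == 0L) {
    vals <- vapply(h$signals, function(s) {
      v <- ports[[s]]
      if (is.null(v)) 0 else v
    }, numeric(1))
    buf_push_rows(h, matrix(vals, nrow = 1L))
  }
  h$n_cycles <- max(h$n_cycles, as.integer(cycle_index) + 1L)
  invisible()
}

# chunked-run hook: vals is a named list of per-cycle vectors for cycles
# k0 .. k0+len-1
record_chunk <- function(h, k0, vals, len) {
  idx <- which((k0 + seq_len(len) - 1L) %% h$k == 0L)
  if (length(idx)) {
    rows <- vapply(h$signals, function(s) {
      v <- vals[[s]]
      if (is.null(v)) numeric(length(idx)) else v[idx]
    }, numeric(length(idx)))
    if (length(idx) == 1L) rows <- matrix(rows, nrow = 1L)
    buf_push_rows(h, rows)
  }
  h$n_cycles <- max(h$n_cycles, as.integer(k0 + len))
  invisible()
}

#' Tag a time point in the active trial
#' @param h Trial handle. @param time Seconds (simulated). @param text Label.
#' @return The handle, invisibly.
#' @export
add_tag <- function(h, time, text) {
  stopifnot(inherits(h, "ll_trial"))
  if (!isTRUE(h$active)) stop("trial is not active")
  h$tags[[length(h$tags) + 1L]] <- list(time = as.numeric(time),
                                        text = as.character(text))
  invisible(h)
}

#' Log a timestamped parameter change
#'
#' Appends `(time, value)` to the parameter's change table. The recorder
#' only logs; applying the value to the live module is the engine's job
#' (see [set_param()], which does both when a trial is active).
#'
#' @param h Trial handle. @param time Seconds. @param module Module id.
#' @param name Parameter name. @param value New value (scalar numeric).
#' @return The handle, invisibly.
#' @export
log_param_change <- function(h, time, module, name, value) {
  stopifnot(inherits(h, "ll_trial"))
  if (!isTRUE(h$active)) stop("trial is not active")
  key <- paste0(module, ".", name)
  if (!key %in% names(h$snapshot))
    stop("unknown parameter: ", key)
  if (!is.numeric(value) || length(value) != 1L)
    stop("change logging requires scalar numeric values")
  h$changes[[key]] <- rbind(h$changes[[key]], c(as.numeric(time), as.numeric(value)))
  invisible(h)
}

#' Stop the active trial and flush it to the HDF5 file
#'
#' Writes the synchronous data matrix, parameter snapshot and change tables,
#' channel settings, and tags; the trial group's attributes record the
#' period, start/stop simulated times and the downsample factor.
#'
#' @param h Trial handle.
#' @return List: `trial` (number), `rows`, `n_cycles`, `duration` (s).
#' @export
stop_trial <- function(h) {
  stopifnot(inherits(h, "ll_trial"))
  if (!isTRUE(h$active)) stop("trial already stopped")
  h$active <- FALSE
  h$rec$active <- FALSE
  path <- h$path
  stop_time <- h$start_time + h$n_cycles * h$period
  if (h$rows > 0L)
    rhdf5::h5write(h$buf[seq_len(h$rows), , drop = FALSE], path,
                   paste0(h$name, "/Synchronous Data"))
  h5_set_attr(path, h$name, "Period", h$period)
  h5_set_attr(path, h$name, "Start Time", h$start_time)
  h5_set_attr(path, h$name, "Stop Time", stop_time)
  h5_set_attr(path, h$name, "Downsample", as.integer(h$k))
  h5_set_attr(path, h$name, "Column Names",
              if (length(h$signals)) h$signals else "")
  for (key in names(h$snapshot)) {
    dpath <- paste0(h$name, "/Parameters/", key)
    ch <- h$changes[[key]]
    if (is.null(ch)) rhdf5::h5write(0, path, dpath)
    else rhdf5::h5write(ch, path, dpath)
    v <- h$snapshot[[key]]
    h5_set_attr(path, dpath, "Initial Value",
                if (is.character(v)) v else as.numeric(v))
    h5_set_attr(path, dpath, "Has Changes", as.integer(!is.null(ch)))
  }
  if (length(h$sysset)) {
    m <- t(vapply(h$sysset, function(ch)
      c(ch$index, ch$range[1], ch$range[2], ch$gain, ch$offset,
        as.numeric(ch$enabled)), numeric(6)))
    dpath <- paste0(h$name, "/System Settings/Channels")
    rhdf5::h5write(m, path, dpath)
    h5_set_attr(path, dpath, "Channel Names", names(h$sysset))
    h5_set_attr(path, dpath, "Fields",
                c("index", "range_lo", "range_hi", "gain", "offset", "enabled"))
    h5_set_attr(path, dpath, "Modes",
                vapply(h$sysset, `[[`, "", "mode"))
  }
  if (length(h$tags)) {
    rhdf5::h5createGroup(path, paste0(h$name, "/Tags"))
    rhdf5::h5write(vapply(h$tags, `[[`, numeric(1), "time"), path,
                   paste0(h$name, "/Tags/Times"))
    rhdf5::h5write(vapply(h$tags, `[[`, "", "text"), path,
                   paste0(h$name, "/Tags/Text"))
  }
  list(trial = h$trial, rows = h$rows, n_cycles = h$n_cycles,
       duration = h$n_cycles * h$period)
}

#' Read a trial back from a recording file
#'
#' @param path HDF5 file. @param trial Trial number.
#' @return List: `data` (matrix with signal column names; 0 rows if none
#'   were stored), `period`, `start_time`, `stop_time`, `downsample`,
#'   `parameters` (list with `initial` values and `changes` tables),
#'   `system_settings`, and `tags` (data.frame).
#' @export
read_trial <- function(path, trial = 1L) {
  name <- paste0("Trial ", trial)
  ls <- rhdf5::h5ls(path)
  here <- ls[ls$group == paste0("/", name) | startsWith(ls$group, paste0("/", name, "/")), ]
  if (!nrow(ls[ls$name == name & ls$group == "/", ]))
    stop("no such trial in ", path, ": ", name)
  at <- rhdf5::h5readAttributes(path, name)
  signals <- as.character(at[["Column Names"]])
  if (identical(signals, "")) signals <- character()
  data <- if (any(here$name == "Synchronous Data")) {
    d <- rhdf5::h5read(path, paste0(name, "/Synchronous Data"))
    colnames(d) <- signals
    d
  } else matrix(numeric(0), 0, length(signals), dimnames = list(NULL, signals))
  pgrp <- paste0("/", name, "/Parameters")
  pnames <- here$name[here$group == pgrp]
  initial <- list(); changes <- list()
  for (pn in pnames) {
    dpath <- paste0(name, "/Parameters/", pn)
    pat <- rhdf5::h5readAttributes(path, dpath)
    initial[[pn]] <- as.vector(pat[["Initial Value"]])
    if (isTRUE(pat[["Has Changes"]] == 1L)) {
      ch <- rhdf5::h5read(path, dpath)
      colnames(ch) <- c("time", "value")
      changes[[pn]] <- ch
    }
  }
  sys <- NULL
  if (any(here$name == "Channels")) {
    dpath <- paste0(name, "/System Settings/Channels")
    m <- rhdf5::h5read(path, dpath)
    sat <- rhdf5::h5readAttributes(path, dpath)
    colnames(m) <- as.character(sat[["Fields"]])
    rownames(m) <- as.character(sat[["Channel Names"]])
    sys <- list(channels = m, modes = as.character(sat[["Modes"]]))
  }
  tags <- data.frame(time = numeric(0), text = character(0))
  if (any(here$name == "Times"))
    tags <- data.frame(time = as.vector(rhdf5::h5read(path, paste0(name, "/Tags/Times"))),
                       text = as.character(rhdf5::h5read(path, paste0(name, "/Tags/Text"))))
  list(data = data, period = as.vector(at[["Period"]]),
       start_time = as.vector(at[["Start Time"]]),
       stop_time = as.vector(at[["Stop Time"]]),
       downsample = as.vector(at[["Downsample"]]),
       parameters = list(initial = initial, changes = changes),
       system_settings = sys, tags = tags)
}

#' Export recorded signals to CSV (and optionally a PNG quick-look)
#'
#' Offline stand-in for an interactive oscilloscope: renders selected
#' columns of a trial to a CSV table (time + one column per signal) and,
#' optionally, a line plot.
#'
#' @param path HDF5 recording. @param trial Trial number.
#' @param signals Signals to export (default: all recorded).
#' @param csv,png Optional output paths.
#' @return The exported data.frame, invisibly.
#' @export
export_trace <- function(path, trial = 1L, signals = NULL, csv = NULL, png = NULL) {
  tr <- read_trial(path, trial)
  if (is.null(signals)) signals <- colnames(tr$data)
  missing <- setdiff(signals, colnames(tr$data))
  if (length(missing)) stop("signal(s) not in trial: ", paste(missing, collapse = ", "))
  t <- tr$start_time + (seq_len(nrow(tr$data)) - 1L) * tr$period * tr$downsample
  df <- data.frame(time = t, tr$data[, signals, drop = FALSE], check.names = FALSE)
  if (!is.null(csv)) utils::write.csv(df, csv, row.names = FALSE)
  if (!is.null(png)) {
    grDevices::png(png, width = 900, height = 300 * length(signals))
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::par(mfrow = c(length(signals), 1), mar = c(3, 4, 1, 1))
    for (s in signals)
      graphics::plot(t, tr$data[, s], type = "l", xlab = "time (s)", ylab = s)
  }
  invisible(df)
}
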