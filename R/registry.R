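# Module type registry ------------------------------------------------------
#
# A module type declares its port surface (inputs/outputs), default parameter
# and state values, and up to three hooks:
#   init(mod, engine)                 -- run once when the module is loaded
#   execute(mod, inputs, t, dt, engine) -> named list/vector of output values
#   update(mod, flag, event, engine)  -- lifecycle notifications (MODIFY,
#                                        PERIOD, PAUSED, UNPAUSED, EVENT)
# `mod` is the per-instance runtime environment (fields: id, type, params,
# states, plus anything the hooks store).

.ll_registry <- new.env(parent = emptyenv())

#' Register a module type
#'
#' Declares a reusable module type: its input/output ports, default
#' parameters and states, and its `init`/`execute`/`update` hooks. Loaded
#' module instances of the type can then be added to a workspace with
#' [add_module()] or loaded into a running engine with [load_module()].
#'
#' @param type Character scalar, unique type name.
#' @param inputs,outputs Character vectors of port names.
#' @param params Named list of default parameter values (numeric or string).
#' @param states Named list of default state values (numeric).
#' @param init,execute,update Hook functions (may be `NULL`). `execute`
#'   receives `(mod, inputs, t, dt, engine)` where `inputs` is a named list
#'   of gathered (summed) input samples, and must return a named list or
#'   vector with one value per output port it wishes to write. `update`
#'   receives `(mod, flag, event, engine)` with `flag` one of
#'   `"MODIFY"`, `"PERIOD"`, `"PAUSED"`, `"UNPAUSED"`, `"EVENT"`.
#' @param subscribes Character vector of additional event kinds for which the
#'   module's `update` hook is invoked (with flag `"EVENT"`).
#' @param overwrite Replace an existing registration of the same name.
#' @return The type name, invisibly.
#' @export
define_module_type <- function(type, inputs = character(), outputs = character(),
                               params = list(), states = list(),
                               init = NULL, execute = NULL, update = NULL,
                               subscribes = character(), overwrite = FALSE) {
  stopifnot(is.character(type), length(type) == 1L, nzchar(type))
  if (!overwrite && exists(type, envir = .ll_registry, inherits = FALSE))
    stop("module type already registered: ", type)
  if (grepl("[. ]", type))
    stop("module type names may not contain '.' or spaces: ", type)
  if (anyDuplicated(c(inputs, outputs)))
    stop("duplicate port name in module type ", type)
  if (length(params) && is.null(names(params)))
    stop("params must be named")
  if (length(states) && is.null(names(states)))
    stop("states must be named")
  assign(type, list(type = type,
                    inputs = as.character(inputs),
                    outputs = as.character(outputs),
                    params = params, states = states,
                    init = init, execute = execute, update = update,
                    subscribes = as.character(subscribes)),
         envir = .ll_registry)
  invisible(type)
}

#' List registered module types
#' @return Character vector of type names.
#' @export
module_types <- function() sort(ls(.ll_registry))

#' Look up a module type definition
#' @param type Type name.
#' @return The registration record (a list).
#' @export
module_type <- function(type) {
  if (!exists(type, envir = .ll_registry, inherits = FALSE))
    stop("unknown module type '", type, "'; registered types: ",
         paste(module_types(), collapse = ", "))
  get(type, envir = .ll_registry)
}

# instantiate a module record for a workspace (pure data; runtime env is
# created by the engine)
new_module_instance <- function(type, id, params = list(), states = list()) {
  def <- module_type(type)
  if (length(params)) {
    bad <- setdiff(names(params), names(def$params))
    if (length(bad))
      stop("invalid parameter name(s) for type '", type, "': ",
           paste(bad, collapse = ", "))
  }
  if (length(states)) {
    bad <- setdiff(names(states), names(def$states))
    if (length(bad))
      stop("invalid state name(s) for type '", type, "': ",
           paste(bad, collapse = ", "))
  }
  p <- def$params; p[names(params)] <- params
  s <- def$states; s[names(states)] <- states
  list(id = id, type = type, params = p, states = s)
}
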