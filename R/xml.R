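# XML workspace persistence. Self-defined, versioned dialect:
#
# <workspace version="1">
#   <engine frequency=".." period=".." mode=".." seed=".."/>
#   <daq><channel index direction mode range_lo range_hi gain offset enabled/></daq>
#   <modules><module id type><param name value type/><state name value type/></module></modules>
#   <connections><connection src="a.b" dst="c.d"/></connections>
# </workspace>
#
# Numeric values are serialized with "%.17g" so that load(save(ws)) is the
# identity on doubles. Parameter values may be numeric vectors
# (space-separated) or character scalars (type="string").

fmt_num <- function(x) paste(sprintf("%.17g", as.numeric(x)), collapse = " ")

serialize_value <- function(v) {
  if (is.character(v)) {
    if (length(v) != 1L) stop("character parameters must be scalars")
    c(value = v, type = "string")
  } else if (is.numeric(v) || is.logical(v)) {
    c(value = fmt_num(v), type = "numeric")
  } else stop("unsupported parameter value class: ", class(v)[1])
}

deserialize_value <- function(value, type) {
  if (identical(type, "string")) value
  else if (!nzchar(value)) numeric(0)
  else as.numeric(strsplit(value, " ", fixed = TRUE)[[1]])
}

#' Save a workspace to an XML settings file
#'
#' Writes the complete workspace -- engine configuration, channel
#' configurations, module instances with parameter and state values, and the
#' connection list -- to a versioned XML dialect. [load_workspace()] of the
#' result reproduces the workspace exactly, so settings files can be shared
#' and used to restore a protocol on another machine.
#'
#' @param ws Workspace (validated before writing).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_workspace <- function(ws, path) {
  validate_workspace(ws)
  doc <- xml2::xml_new_root("workspace", version = "1")
  e <- ws$engine
  xml2::xml_add_child(doc, "engine", frequency = fmt_num(e$frequency),
                      period = fmt_num(e$period), mode = e$mode,
                      seed = as.character(e$seed))
  daq <- xml2::xml_add_child(doc, "daq")
  for (ch in ws$channels)
    xml2::xml_add_child(daq, "channel", index = as.character(ch$index),
                        direction = ch$direction, mode = ch$mode,
                        range_lo = fmt_num(ch$range[1]), range_hi = fmt_num(ch$range[2]),
                        gain = fmt_num(ch$gain), offset = fmt_num(ch$offset),
                        enabled = if (ch$enabled) "true" else "false")
  mods <- xml2::xml_add_child(doc, "modules")
  for (m in ws$modules) {
    mn <- xml2::xml_add_child(mods, "module", id = m$id, type = m$type)
    for (nm in names(m$params)) {
      sv <- serialize_value(m$params[[nm]])
      xml2::xml_add_child(mn, "param", name = nm, value = sv[["value"]],
                          type = sv[["type"]])
    }
    for (nm in names(m$states)) {
      sv <- serialize_value(m$states[[nm]])
      xml2::xml_add_child(mn, "state", name = nm, value = sv[["value"]],
                          type = sv[["type"]])
    }
  }
  cons <- xml2::xml_add_child(doc, "connections")
  ids <- vapply(ws$connections, `[[`, integer(1), "id")
  for (cn in ws$connections[order(ids)])
    xml2::xml_add_child(cons, "connection", src = cn$src, dst = cn$dst)
  xml2::write_xml(doc, path)
  invisible(path)
}

xml_attr1 <- function(node, name, what) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) stop("workspace XML: element <", xml2::xml_name(node),
                     "> is missing attribute '", name, "' (", what, ")")
  v
}

#' Load a workspace from an XML settings file
#'
#' Inverse of [save_workspace()]. The whole document is parsed and validated
#' before a workspace is returned, so a malformed file or an unregistered
#' module type yields an error and no partial workspace.
#'
#' @param path XML file written by [save_workspace()].
#' @return An `ll_workspace`.
#' @export
load_workspace <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "workspace")
    stop("workspace XML: root element must be <workspace>, found <",
         xml2::xml_name(doc), ">")
  ver <- xml2::xml_attr(doc, "version")
  if (!identical(ver, "1"))
    stop("workspace XML: unsupported version '", ver, "'")
  en <- xml2::xml_find_first(doc, "./engine")
  if (inherits(en, "xml_missing")) stop("workspace XML: missing <engine>")
  ws <- new_workspace(frequency = as.numeric(xml_attr1(en, "frequency", "Hz")),
                      mode = xml_attr1(en, "mode", "simulated|wallclock"),
                      seed = as.integer(xml_attr1(en, "seed", "integer")))
  for (ch in xml2::xml_find_all(doc, "./daq/channel"))
    ws <- add_channel(ws,
                      index = as.integer(xml_attr1(ch, "index", "channel index")),
                      direction = xml_attr1(ch, "direction", "AI|AO|DIO"),
                      mode = xml_attr1(ch, "mode", "measurement mode"),
                      range = c(as.numeric(xml_attr1(ch, "range_lo", "volts")),
                                as.numeric(xml_attr1(ch, "range_hi", "volts"))),
                      gain = as.numeric(xml_attr1(ch, "gain", "gain")),
                      offset = as.numeric(xml_attr1(ch, "offset", "volts")),
                      enabled = identical(xml_attr1(ch, "enabled", "flag"), "true"))
  for (mn in xml2::xml_find_all(doc, "./modules/module")) {
    params <- list(); states <- list()
    for (p in xml2::xml_find_all(mn, "./param"))
      params[[xml_attr1(p, "name", "param name")]] <-
        deserialize_value(xml_attr1(p, "value", "param value"),
                          xml2::xml_attr(p, "type"))
    for (s in xml2::xml_find_all(mn, "./state"))
      states[[xml_attr1(s, "name", "state name")]] <-
        deserialize_value(xml_attr1(s, "value", "state value"),
                          xml2::xml_attr(s, "type"))
    ws <- add_module(ws, type = xml_attr1(mn, "type", "module type"),
                     id = xml_attr1(mn, "id", "module id"),
                     params = params, states = states)
  }
  for (cn in xml2::xml_find_all(doc, "./connections/connection"))
    ws <- connect(ws, xml_attr1(cn, "src", "endpoint"),
                  xml_attr1(cn, "dst", "endpoint"))
  attr(ws, "connection_id") <- NULL
  validate_workspace(ws)
  ws
}
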