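# Scenario config serialization (YAML).
#
# Schema (all rates in initiations/kb/sec, lengths kb, times sec):
#   initiation:
#     background: <number >= 0>
#     zones:                       # optional list
#       - shape: gaussian | rounded_box
#         center: <kb>
#         width: <kb>              # sigma (gaussian) or full width (rounded_box)
#         amplitude: <rate >= 0>
#         edge_scale: <kb>         # optional, rounded_box only (default 2)
#         t_on: <sec>              # optional (default 0)
#         t_off: <sec|.inf>        # optional (default .inf)
#   velocity:
#     v_plus: <kb/sec > 0>
#     v_minus: <kb/sec > 0>        # optional (default v_plus)
#     segments:                    # optional list of {from, to, v_plus, v_minus}
#   boundary:
#     mode: periodic | isolated | injection
#     I_left, I_right: <rate>      # injection only
#     v_out: <kb/sec>              # injection only, optional
#   defects:                       # optional
#     d: <kb > 0>
#     tau: <sec > 0 | .inf>

schema_err <- function(path, msg) {
  stop("scenario config error at '", path, "': ", msg, call. = FALSE)
}

check_keys <- function(node, path, required, optional = character()) {
  if (!is.list(node)) schema_err(path, "expected a mapping")
  unknown <- setdiff(names(node), c(required, optional))
  if (length(unknown))
    schema_err(paste0(path, "/", unknown[1]), "unknown key")
  missing <- setdiff(required, names(node))
  if (length(missing))
    schema_err(paste0(path, "/", missing[1]), "missing required key")
}

num1 <- function(node, path) {
  if (is.character(node) && node %in% c(".inf", "inf", "Inf")) return(Inf)
  if (is.character(node) && length(node) == 1L) {
    # YAML 1.1 parses exponent forms like "1e-07" as strings; coerce
    node <- suppressWarnings(as.numeric(node))
  }
  if (!is.numeric(node) || length(node) != 1L || is.na(node))
    schema_err(path, "expected a single number")
  as.numeric(node)
}

#' Read a replication-scenario config
#'
#' Parses the documented YAML schema into an [scenario()] object, validating
#' types, ranges and key names; errors name the offending config path.
#'
#' @param path file path, or `text =` a YAML string.
#' @param text YAML text (alternative to `path`).
#' @return An `"rk_scenario"`.
#' @seealso [save_scenario()]
#' @export
load_scenario <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  cfg <- yaml::yaml.load(text)
  check_keys(cfg, "", required = c("initiation", "velocity", "boundary"),
             optional = "defects")

  ini <- cfg$initiation
  check_keys(ini, "initiation", required = "background", optional = "zones")
  bg <- num1(ini$background, "initiation/background")
  if (bg < 0) schema_err("initiation/background", "rate must be >= 0")
  zones <- list()
  for (i in seq_along(ini$zones)) {
    zp <- paste0("initiation/zones[", i, "]")
    zn <- ini$zones[[i]]
    check_keys(zn, zp, required = c("shape", "center", "width", "amplitude"),
               optional = c("edge_scale", "t_on", "t_off"))
    if (!zn$shape %in% c("gaussian", "rounded_box"))
      schema_err(paste0(zp, "/shape"), "must be 'gaussian' or 'rounded_box'")
    amp <- num1(zn$amplitude, paste0(zp, "/amplitude"))
    if (amp < 0) schema_err(paste0(zp, "/amplitude"), "rate must be >= 0")
    wid <- num1(zn$width, paste0(zp, "/width"))
    if (wid <= 0) schema_err(paste0(zp, "/width"), "must be > 0")
    zones[[i]] <- initiation_zone(
      center = num1(zn$center, paste0(zp, "/center")),
      width = wid, amplitude = amp, shape = zn$shape,
      edge_scale = if (is.null(zn$edge_scale)) 2
                   else num1(zn$edge_scale, paste0(zp, "/edge_scale")),
      t_on = if (is.null(zn$t_on)) 0 else num1(zn$t_on, paste0(zp, "/t_on")),
      t_off = if (is.null(zn$t_off)) Inf else num1(zn$t_off, paste0(zp, "/t_off"))
    )
  }

  vel <- cfg$velocity
  check_keys(vel, "velocity", required = "v_plus",
             optional = c("v_minus", "segments"))
  vp <- num1(vel$v_plus, "velocity/v_plus")
  vm <- if (is.null(vel$v_minus)) vp else num1(vel$v_minus, "velocity/v_minus")
  if (vp <= 0 || vm <= 0) schema_err("velocity", "fork speeds must be > 0")
  seg <- NULL
  if (!is.null(vel$segments)) {
    seg <- do.call(rbind, lapply(seq_along(vel$segments), function(i) {
      sp <- paste0("velocity/segments[", i, "]")
      s <- vel$segments[[i]]
      check_keys(s, sp, required = c("from", "to", "v_plus", "v_minus"))
      data.frame(from = num1(s$from, sp), to = num1(s$to, sp),
                 v_plus = num1(s$v_plus, sp), v_minus = num1(s$v_minus, sp))
    }))
  }

  bnd <- cfg$boundary
  check_keys(bnd, "boundary", required = "mode",
             optional = c("I_left", "I_right", "v_out"))
  if (!bnd$mode %in% c("periodic", "isolated", "injection"))
    schema_err("boundary/mode", "must be periodic, isolated or injection")
  bc <- boundary_condition(
    mode = bnd$mode,
    I_left = if (is.null(bnd$I_left)) 0 else num1(bnd$I_left, "boundary/I_left"),
    I_right = if (is.null(bnd$I_right)) 0 else num1(bnd$I_right, "boundary/I_right"),
    v_out = if (is.null(bnd$v_out)) NA_real_ else num1(bnd$v_out, "boundary/v_out")
  )

  dm <- NULL
  if (!is.null(cfg$defects)) {
    check_keys(cfg$defects, "defects", required = "d", optional = "tau")
    dm <- defect_model(
      d = num1(cfg$defects$d, "defects/d"),
      tau = if (is.null(cfg$defects$tau)) Inf
            else num1(cfg$defects$tau, "defects/tau")
    )
  }

  scenario(initiation_profile(zones, background = bg),
           velocity_profile(vp, vm, segments = seg), bc, dm)
}

fmt_num <- function(x) {
  if (is.infinite(x)) return(".inf")
  trimws(formatC(x, format = "g", digits = 15))
}

#' Write a replication-scenario config
#'
#' Serializes a scenario to canonical YAML text: fixed key order and a fixed
#' number format, so that save -> load -> save is byte-identical.
#'
#' @param sc an [scenario()].
#' @param path optional file to write to.
#' @return The YAML text, invisibly if `path` is given.
#' @export
save_scenario <- function(sc, path = NULL) {
  stopifnot(inherits(sc, "rk_scenario"))
  out <- c("initiation:",
           paste0("  background: ", fmt_num(sc$initiation$background)))
  if (length(sc$initiation$zones)) {
    out <- c(out, "  zones:")
    for (z in sc$initiation$zones) {
      out <- c(out,
        paste0("  - shape: ", z$shape),
        paste0("    center: ", fmt_num(z$center)),
        paste0("    width: ", fmt_num(z$width)),
        paste0("    amplitude: ", fmt_num(z$amplitude)),
        paste0("    edge_scale: ", fmt_num(z$edge_scale)),
        paste0("    t_on: ", fmt_num(z$t_on)),
        paste0("    t_off: ", fmt_num(z$t_off)))
    }
  }
  out <- c(out, "velocity:",
           paste0("  v_plus: ", fmt_num(sc$velocity$v_plus)),
           paste0("  v_minus: ", fmt_num(sc$velocity$v_minus)))
  if (!is.null(sc$velocity$segments)) {
    out <- c(out, "  segments:")
    for (i in seq_len(nrow(sc$velocity$segments))) {
      s <- sc$velocity$segments[i, ]
      out <- c(out,
        paste0("  - from: ", fmt_num(s$from)),
        paste0("    to: ", fmt_num(s$to)),
        paste0("    v_plus: ", fmt_num(s$v_plus)),
        paste0("    v_minus: ", fmt_num(s$v_minus)))
    }
  }
  out <- c(out, "boundary:", paste0("  mode: ", sc$boundary$mode))
  if (sc$boundary$mode == "injection") {
    out <- c(out,
      paste0("  I_left: ", fmt_num(sc$boundary$I_left)),
      paste0("  I_right: ", fmt_num(sc$boundary$I_right)))
    if (!is.na(sc$boundary$v_out))
      out <- c(out, paste0("  v_out: ", fmt_num(sc$boundary$v_out)))
  }
  if (!is.null(sc$defects)) {
    out <- c(out, "defects:",
             paste0("  d: ", fmt_num(sc$defects$d)),
             paste0("  tau: ", fmt_num(sc$defects$tau)))
  }
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}
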