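#' Initiation zone
#'
#' An extended genomic region over which origin-firing probability is spread.
#' Two shapes are supported: a Gaussian,
#' `amplitude * exp(-(x - center)^2 / (2 * width^2))` (so `width` is the
#' Gaussian sigma), and a rounded box of full width `width` whose edges are
#' logistic sigmoids of length scale `edge_scale`:
#' `amplitude * plogis((x - (center - width/2))/edge_scale) *
#'  plogis(((center + width/2) - x)/edge_scale)`.
#' A zone may be gated in time: outside `[t_on, t_off]` it contributes exactly
#' zero (hard on/off switching, as for a late-firing zone that only becomes
#' active part-way through S phase).
#'
#' @param center zone center in kb.
#' @param width kb; sigma for `"gaussian"`, full width for `"rounded_box"`.
#' @param amplitude peak initiation rate, initiations/kb/sec; must be >= 0.
#' @param shape `"gaussian"` or `"rounded_box"`.
#' @param edge_scale logistic edge length scale in kb (rounded box only).
#' @param t_on,t_off activation window in seconds (default: always active).
#' @return An object of class `"rk_zone"`.
#' @examples
#' late <- initiation_zone(800, 25, 2e-4, t_on = 5000)
#' @export
initiation_zone <- function(center, width, amplitude,
                            shape = c("gaussian", "rounded_box"),
                            edge_scale = 2, t_on = 0, t_off = Inf) {
  shape <- match.arg(shape)
  if (!is.numeric(width) || width <= 0) stop("zone width must be > 0")
  if (!is.numeric(amplitude) || amplitude < 0) stop("zone amplitude must be >= 0")
  if (edge_scale <= 0) stop("edge_scale must be > 0")
  if (t_off < t_on) stop("t_off must be >= t_on")
  z <- list(shape = shape, center = center, width = width,
            amplitude = amplitude, edge_scale = edge_scale,
            t_on = t_on, t_off = t_off)
  class(z) <- "rk_zone"
  z
}

#' Spatial shape of a zone, normalized to peak 1
#' @noRd
zone_shape <- function(zone, x) {
  if (zone$shape == "gaussian") {
    exp(-(x - zone$center)^2 / (2 * zone$width^2))
  } else {
    stats::plogis((x - (zone$center - zone$width / 2)) / zone$edge_scale) *
      stats::plogis(((zone$center + zone$width / 2) - x) / zone$edge_scale)
  }
}

#' Initiation-rate profile I(x, t)
#'
#' The local rate of origin firing per kb of *unreplicated* DNA per second,
#' composed of a constant background plus a sum of (possibly time-gated)
#' initiation zones.
#'
#' @param zones a list of [initiation_zone()] objects (may be empty).
#' @param background constant rate in initiations/kb/sec; must be >= 0.
#' @return An object of class `"rk_initiation"`.
#' @seealso [evaluate_initiation()]
#' @export
initiation_profile <- function(zones = list(), background = 0) {
  if (inherits(zones, "rk_zone")) zones <- list(zones)
  if (!all(vapply(zones, inherits, logical(1), "rk_zone")))
    stop("zones must be a list of initiation_zone() objects")
  if (!is.numeric(background) || background < 0)
    stop("background rate must be >= 0")
  p <- list(zones = zones, background = background)
  class(p) <- "rk_initiation"
  p
}

#' Evaluate an initiation profile
#'
#' Returns `I(x, t)` = background + the sum of gated zone contributions, in
#' initiations/kb/sec. Vectorized over `x`; `t` must be a scalar.
#'
#' @param profile an [initiation_profile()].
#' @param x positions in kb.
#' @param t time in seconds (scalar, >= 0).
#' @return numeric vector of rates, same length as `x`.
#' @export
evaluate_initiation <- function(profile, x, t) {
  stopifnot(inherits(profile, "rk_initiation"), length(t) == 1L, t >= 0)
  out <- rep(profile$background, length(x))
  for (z in profile$zones) {
    if (t >= z$t_on && t <= z$t_off)
      out <- out + z$amplitude * zone_shape(z, x)
  }
  out
}

#' Fork-velocity profile v(x)
#'
#' Strictly positive speeds (kb/sec) for right-moving (`plus`) and left-moving
#' (`minus`) forks, either constant or piecewise constant in space. A
#' piecewise profile is a base speed plus segments `[from, to)` carrying their
#' own speed.
#'
#' @param v_plus,v_minus base speeds in kb/sec (> 0). `v_minus` defaults to
#'   `v_plus`.
#' @param segments optional data.frame with columns `from`, `to` (kb) and
#'   `v_plus`, `v_minus` (kb/sec) overriding the base speed on `[from, to)`.
#' @return An object of class `"rk_velocity"`.
#' @examples
#' velocity_profile(0.04)
#' velocity_profile(0.04, segments = data.frame(from = 100, to = 150,
#'                                              v_plus = 0.01, v_minus = 0.01))
#' @export
velocity_profile <- function(v_plus, v_minus = v_plus, segments = NULL) {
  if (!is.numeric(v_plus) || v_plus <= 0 || !is.numeric(v_minus) || v_minus <= 0)
    stop("fork speeds must be strictly positive")
  if (!is.null(segments)) {
    segments <- as.data.frame(segments)
    need <- c("from", "to", "v_plus", "v_minus")
    if (!all(need %in% names(segments)))
      stop("segments needs columns from, to, v_plus, v_minus")
    if (any(segments$v_plus <= 0) || any(segments$v_minus <= 0))
      stop("segment fork speeds must be strictly positive")
    if (any(segments$to <= segments$from))
      stop("segment 'to' must exceed 'from'")
  }
  v <- list(v_plus = v_plus, v_minus = v_minus, segments = segments)
  class(v) <- "rk_velocity"
  v
}

#' Evaluate a velocity profile
#'
#' @param profile a [velocity_profile()].
#' @param x positions in kb (vectorized).
#' @param t time in seconds (accepted for interface symmetry; profiles are
#'   time-invariant).
#' @param direction `"plus"` (right-moving) or `"minus"` (left-moving).
#' @return numeric vector of speeds (kb/sec), strictly positive.
#' @export
evaluate_velocity <- function(profile, x, t = 0, direction = c("plus", "minus")) {
  stopifnot(inherits(profile, "rk_velocity"))
  direction <- match.arg(direction)
  base <- if (direction == "plus") profile$v_plus else profile$v_minus
  out <- rep(base, length(x))
  if (!is.null(profile$segments)) {
    seg <- profile$segments
    for (i in seq_len(nrow(seg))) {
      idx <- x >= seg$from[i] & x < seg$to[i]
      out[idx] <- if (direction == "plus") seg$v_plus[i] else seg$v_minus[i]
    }
  }
  out
}

#' Boundary condition for the modeled region
#'
#' * `"periodic"`: the molecule is a circle; forks leaving one end re-enter
#'   the other (the standard choice for a self-contained test system).
#' * `"isolated"`: a linear molecule with no fork inflow; forks exit freely.
#' * `"injection"`: the region is a fragment of a much longer genome. Forks
#'   created outside enter across the ends; the inflow fork density is the
#'   closed form for a semi-infinite homogeneous flank with constant
#'   initiation rate `I_left`/`I_right` and fork speed `v_out`
#'   (see [boundary_fork_density()]).
#'
#' @param mode `"periodic"`, `"isolated"` or `"injection"`.
#' @param I_left,I_right constant initiation rates of the outside regions
#'   (initiations/kb/sec), injection mode only.
#' @param v_out fork speed in the outside regions (kb/sec), injection mode only;
#'   defaults to the inside speed at solve time when `NA`.
#' @return An object of class `"rk_boundary"`.
#' @export
boundary_condition <- function(mode = c("periodic", "isolated", "injection"),
                               I_left = 0, I_right = 0, v_out = NA_real_) {
  mode <- match.arg(mode)
  if (mode != "injection" && (I_left != 0 || I_right != 0))
    stop("injection rates are only allowed in injection mode")
  if (I_left < 0 || I_right < 0) stop("injection rates must be >= 0")
  if (!is.na(v_out) && v_out <= 0) stop("v_out must be > 0")
  b <- list(mode = mode, I_left = I_left, I_right = I_right, v_out = v_out)
  class(b) <- "rk_boundary"
  b
}

#' Fork-stalling defect model
#'
#' DNA lesions at which replication forks stall. Defects are spaced with mean
#' spacing `d` kb; a stalled fork resumes after an exponentially distributed
#' repair time with mean `tau` seconds (`tau = Inf`: never repaired during
#' this S phase — the blocked DNA must be replicated by the opposing fork).
#'
#' @param d mean spacing between defects (kb, > 0).
#' @param tau mean repair time (seconds, > 0 or `Inf`).
#' @return An object of class `"rk_defects"`.
#' @export
defect_model <- function(d, tau = Inf) {
  if (!is.numeric(d) || d <= 0) stop("defect spacing d must be > 0")
  if (!is.numeric(tau) || tau <= 0) stop("repair time tau must be > 0 (or Inf)")
  dm <- list(d = d, tau = tau)
  class(dm) <- "rk_defects"
  dm
}

#' Replication scenario
#'
#' Bundles everything that defines the replication kinetics of a region:
#' the initiation-rate profile `I(x,t)`, the fork-velocity profile `v(x)`,
#' the boundary condition, and optionally a fork-stalling defect model.
#'
#' @param initiation an [initiation_profile()].
#' @param velocity a [velocity_profile()].
#' @param boundary a [boundary_condition()] (default periodic).
#' @param defects optional [defect_model()].
#' @return An object of class `"rk_scenario"`.
#' @examples
#' sc <- scenario(
#'   initiation_profile(list(initiation_zone(200, 25, 2e-5)), background = 0),
#'   velocity_profile(0.04)
#' )
#' @export
scenario <- function(initiation, velocity, boundary = boundary_condition(),
                     defects = NULL) {
  stopifnot(inherits(initiation, "rk_initiation"),
            inherits(velocity, "rk_velocity"),
            inherits(boundary, "rk_boundary"))
  if (!is.null(defects) && !inherits(defects, "rk_defects"))
    stop("defects must be a defect_model() or NULL")
  s <- list(initiation = initiation, velocity = velocity,
            boundary = boundary, defects = defects)
  class(s) <- "rk_scenario"
  s
}

#' @export
print.rk_scenario <- function(x, ...) {
  nz <- length(x$initiation$zones)
  cat("Replication scenario:\n")
  cat("  initiation: ", nz, " zone(s), background ",
      format(x$initiation$background), " /kb/s\n", sep = "")
  for (z in x$initiation$zones) {
    gate <- if (is.finite(z$t_off) || z$t_on > 0)
      paste0(", gate [", z$t_on, ", ", z$t_off, "] s") else ""
    cat("    - ", z$shape, " at ", z$center, " kb, width ", z$width,
        " kb, peak ", format(z$amplitude), " /kb/s", gate, "\n", sep = "")
  }
  cat("  velocity:   v+ = ", x$velocity$v_plus, ", v- = ", x$velocity$v_minus,
      " kb/s", if (!is.null(x$velocity$segments)) " (piecewise)" else "",
      "\n", sep = "")
  cat("  boundary:   ", x$boundary$mode, "\n", sep = "")
  if (x$boundary$mode == "injection")
    cat("    I_left = ", format(x$boundary$I_left), ", I_right = ",
        format(x$boundary$I_right), " /kb/s\n", sep = "")
  if (!is.null(x$defects))
    cat("  defects:    mean spacing ", x$defects$d, " kb, mean repair ",
        x$defects$tau, " s\n", sep = "")
  invisible(x)
}

#' The two-zone demonstration scenario
#'
#' The package's standard test system: a 1000 kb periodic genome with two
#' Gaussian initiation zones of 50 kb size (sigma 25 kb) centered at 200 kb
#' ("early", active at all times) and 800 kb ("late", switched on at 5000 s,
#' with a peak rate 10 times the early zone's), and a constant fork velocity
#' of 0.04 kb/sec — parameter magnitudes typical of somatic mammalian cells.
#' The early-zone peak amplitude defaults to 2e-5 initiations/kb/sec.
#'
#' @param early_amplitude peak rate of the early zone (initiations/kb/sec).
#' @param v fork speed (kb/sec).
#' @return An `"rk_scenario"` with periodic boundaries.
#' @examples
#' sc <- two_zone_scenario()
#' @export
two_zone_scenario <- function(early_amplitude = 2e-5, v = 0.04) {
  scenario(
    initiation_profile(list(
      initiation_zone(center = 200, width = 25, amplitude = early_amplitude),
      initiation_zone(center = 800, width = 25,
                      amplitude = 10 * early_amplitude, t_on = 5000)
    ), background = 0),
    velocity_profile(v),
    boundary_condition("periodic")
  )
}

#' Default grid for the two-zone demonstration scenario
#' @param dx,dt,t_max grid steps and horizon; see [replication_grid()].
#' @return An `"rk_grid"` for the 1000 kb system.
#' @export
two_zone_grid <- function(dx = 0.5, dt = 10, t_max = 25000) {
  replication_grid(L = 1000, dx = dx, dt = dt, t_max = t_max, x0 = 0)
}
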