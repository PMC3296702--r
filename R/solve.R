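#' Fork density entering a fragment from a homogeneous flank
#'
#' For an injection boundary, the modeled fragment is embedded in a much
#' longer genome. If the outside region has a constant initiation rate
#' `I_out` and fork speed `v_out`, the density of inward-moving forks
#' arriving at the boundary is
#' \deqn{\rho_b(t) = I_{out}\, t\, e^{-I_{out} v_{out} t^2 / 2}.}
#' The exponential is the probability that the boundary point is still
#' unreplicated: its coverage cone spans only the flank side, hence half the
#' usual KJMA exponent. The density rises linearly at early times, peaks at
#' \eqn{t^* = 1/\sqrt{I_{out} v_{out}}} and decays as the flank finishes
#' replicating; its time integral times `v_out` is exactly 1 — the boundary
#' point is crossed by exactly one inward-moving fork per cycle. The form is
#' validated against explicit Monte Carlo simulation of long homogeneous
#' flanks.
#'
#' @param I_out outside initiation rate (initiations/kb/sec, >= 0).
#' @param v_out outside fork speed (kb/sec, > 0).
#' @param t time(s) since S-phase entry (seconds, >= 0); vectorized.
#' @return fork density in forks/kb, same length as `t`.
#' @examples
#' boundary_fork_density(0.001, 0.04, c(0, 100, 500))
#' @export
boundary_fork_density <- function(I_out, v_out, t) {
  stopifnot(I_out >= 0, v_out > 0, all(t >= 0))
  I_out * t * exp(-I_out * v_out * t^2 / 2)
}

#' Solve the mean-field replication rate equations
#'
#' Integrates the coupled equations for the replication fraction `f(x,t)` and
#' the right-/left-moving fork densities `rho±(x,t)`:
#' \deqn{\partial f/\partial t = v_+\rho_+ + v_-\rho_-}
#' \deqn{\partial \rho_\pm/\partial t \pm \partial(v_\pm \rho_\pm)/\partial x
#'   = I(x,t)(1-f) - \frac{(v_+ + v_-)\,\rho_+ \rho_-}{1-f}.}
#' New fork pairs are created at the initiation rate `I` rescaled by the
#' probability `1 - f` that the site is not yet replicated (passive
#' replication); forks annihilate pairwise at a rate proportional to the two
#' local fork populations and their relative speed, normalized by `1 - f`.
#'
#' If the scenario carries a [defect_model()], two additional densities of
#' stalled forks are integrated: moving forks stall at rate `v±ρ±/d`, stalled
#' forks are repaired at rate `ρˢ±/τ` (dropped when `tau = Inf`) and are
#' removed by collisions with opposing moving forks at rate `v∓ρ∓ρˢ±/(1-f)`;
#' stalled forks do not advect.
#'
#' The scheme is explicit first-order upwind for the advection terms with a
#' forward-Euler source/sink update, under the CFL condition
#' `max(v) * dt <= dx` (checked). Boundary handling follows the scenario:
#' periodic wrap, zero inflow (isolated), or a ghost-cell inflow density given
#' by [boundary_fork_density()] (injection). Initial conditions are `f = 0`,
#' `rho± = 0` everywhere. Integration stops early once replication is
#' complete (all `f` at 1 and negligible fork mass).
#'
#' @param sc an [scenario()].
#' @param grid an [replication_grid()] satisfying `max(v) * dt <= dx`.
#' @param early_stop stop once replication is complete (default `TRUE`).
#' @return An object of class `"rk_fields"`: matrices `f`, `rho_plus`,
#'   `rho_minus`, `f_plus`, `f_minus` (and `rho_stall_plus`/`rho_stall_minus`
#'   when defects are modeled) of dimension `n_x` x `length(t)`; the time
#'   points `t` actually integrated; the expected per-cycle initiation and
#'   coalescence counts `N_init`, `N_coal` accumulated by quadrature of the
#'   source and sink terms; `residual_fork_mass` and the completion flag
#'   `complete`.
#' @examples
#' sol <- solve_replication(two_zone_scenario(), two_zone_grid(dx = 2, dt = 25))
#' sol$N_init
#' @export
solve_replication <- function(sc, grid, early_stop = TRUE) {
  stopifnot(inherits(sc, "rk_scenario"), inherits(grid, "rk_grid"))
  n <- grid$n_x
  dx <- grid$dx
  dt <- grid$dt
  x <- grid$x

  v_p <- evaluate_velocity(sc$velocity, x, direction = "plus")
  v_m <- evaluate_velocity(sc$velocity, x, direction = "minus")
  if (max(v_p, v_m) * dt > dx + 1e-12)
    stop("CFL condition violated: max(v)*dt = ", max(v_p, v_m) * dt,
         " exceeds dx = ", dx, "; decrease dt or increase dx")

  bc <- sc$boundary
  v_out <- if (bc$mode == "injection" && !is.na(bc$v_out)) bc$v_out
           else max(v_p[1], v_m[n])

  has_stall <- !is.null(sc$defects)
  d_def <- if (has_stall) sc$defects$d else Inf
  tau <- if (has_stall) sc$defects$tau else Inf

  # zone shapes precomputed; time dependence enters through the gates only
  zs <- sc$initiation$zones
  shapes <- if (length(zs))
    vapply(zs, zone_shape, numeric(n), x = x) else NULL
  amps <- vapply(zs, `[[`, numeric(1), "amplitude")
  t_on <- vapply(zs, `[[`, numeric(1), "t_on")
  t_off <- vapply(zs, `[[`, numeric(1), "t_off")
  bg <- sc$initiation$background

  n_t <- grid$n_t
  res <- solver_kernel(
    n, dx, dt, n_t,
    if (is.null(shapes)) matrix(0, n, 0) else shapes,
    amps, t_on, t_off, bg,
    v_p, v_m,
    switch(bc$mode, periodic = 0L, isolated = 1L, injection = 2L),
    bc$I_left, bc$I_right, v_out,
    has_stall, d_def, tau, early_stop)
  if (isTRUE(res$bad_f))
    stop("numerical instability: f exceeds 1 at cell ", res$bad_cell,
         ", t = ", res$bad_t, " s")
  k_last <- res$k_last
  f <- res$f; rp <- res$rho_plus; rm <- res$rho_minus
  fp <- res$f_plus; fm <- res$f_minus
  sp <- if (has_stall) res$rho_stall_plus else NULL
  sm <- if (has_stall) res$rho_stall_minus else NULL
  N_init <- res$N_init
  N_coal <- res$N_coal
  idx <- seq_len(k_last)
  residual <- (sum(rp[, k_last]) + sum(rm[, k_last]) +
               (if (has_stall) sum(sp[, k_last]) + sum(sm[, k_last]) else 0)) * dx
  out <- list(
    grid = grid, scenario = sc,
    t = grid$t[idx],
    f = f[, idx, drop = FALSE],
    rho_plus = rp[, idx, drop = FALSE],
    rho_minus = rm[, idx, drop = FALSE],
    f_plus = fp[, idx, drop = FALSE],
    f_minus = fm[, idx, drop = FALSE],
    rho_stall_plus = if (has_stall) sp[, idx, drop = FALSE] else NULL,
    rho_stall_minus = if (has_stall) sm[, idx, drop = FALSE] else NULL,
    N_init = N_init, N_coal = N_coal,
    residual_fork_mass = residual,
    complete = min(f[, k_last]) > 1 - 1e-2
  )
  class(out) <- "rk_fields"
  out
}

#' @export
print.rk_fields <- function(x, ...) {
  cat("Mean-field replication solution on", x$grid$n_x, "cells x",
      length(x$t), "time points\n")
  cat("  N_init =", format(x$N_init, digits = 6),
      " N_coal =", format(x$N_coal, digits = 6),
      " (rel. diff ", format(abs(x$N_init - x$N_coal) / x$N_init * 100,
                             digits = 3), "% )\n")
  cat("  replication", if (x$complete) "complete" else
      paste0("INCOMPLETE (residual fork mass ",
             format(x$residual_fork_mass, digits = 3), ")"), "\n")
  invisible(x)
}

#' @export
plot.rk_fields <- function(x, what = c("f", "rho_plus", "rho_minus"), ...) {
  what <- match.arg(what)
  z <- x[[what]]
  graphics::image(x$grid$x, x$t, z, xlab = "position (kb)",
                  ylab = "time (s)", main = what,
                  col = grDevices::hcl.colors(64, "YlGnBu", rev = TRUE), ...)
  invisible(x)
}

#' Initiation- and coalescence-event densities
#'
#' From a solved field, computes the space-time probability densities of
#' initiation and coalescence events, `D_init ∝ I(x,t)(1-f)` and
#' `D_coal ∝ (v_+ + v_-) ρ_+ ρ_- / (1-f)`, each normalized to unit space-time
#' integral, along with the expected numbers of initiations and coalescences
#' per replication cycle, `N_init` and `N_coal` (the unnormalized space-time
#' integrals, accumulated during the solve). Under periodic boundary
#' conditions every initiation is eventually balanced by a coalescence, so
#' `N_init = N_coal` up to round-off; on a linear molecule forks can exit at
#' the ends and `N_init > N_coal`.
#'
#' @param sol an `"rk_fields"` from [solve_replication()].
#' @param completeness_tol warn if `max(1 - f)` at the final time exceeds
#'   this. The first-order scheme can leave a small frozen unreplicated
#'   residue at termination points (it vanishes linearly with the grid step),
#'   so the default tolerance is 1e-2.
#' @return An object of class `"rk_events"`: matrices `D_init`, `D_coal`
#'   (1/kb/sec) and counts `N_init`, `N_coal`.
#' @export
event_densities <- function(sol, completeness_tol = 1e-2) {
  stopifnot(inherits(sol, "rk_fields"))
  g <- sol$grid
  resid <- max(1 - sol$f[, ncol(sol$f)])
  if (resid > completeness_tol)
    warning("integration horizon too short: residual unreplicated mass ",
            format(resid, digits = 3), "; densities are truncated")
  sc <- sol$scenario
  x <- g$x
  v_p <- evaluate_velocity(sc$velocity, x, direction = "plus")
  v_m <- evaluate_velocity(sc$velocity, x, direction = "minus")
  n_t <- length(sol$t)
  D_i <- matrix(0, g$n_x, n_t)
  D_c <- matrix(0, g$n_x, n_t)
  for (k in seq_len(n_t)) {
    one_mf <- pmax(1 - sol$f[, k], 0)
    D_i[, k] <- evaluate_initiation(sc$initiation, x, sol$t[k]) * one_mf
    D_c[, k] <- (v_p + v_m) * sol$rho_plus[, k] * sol$rho_minus[, k] /
      pmax(one_mf, 1e-12)
  }
  Zi <- sum(D_i) * g$dx * g$dt
  Zc <- sum(D_c) * g$dx * g$dt
  out <- list(D_init = D_i / Zi, D_coal = D_c / Zc,
              N_init = sol$N_init, N_coal = sol$N_coal,
              x = x, t = sol$t, dx = g$dx, dt = g$dt)
  class(out) <- "rk_events"
  out
}

#' @export
print.rk_events <- function(x, ...) {
  cat("Replication event densities:\n")
  cat("  N_init =", format(x$N_init, digits = 6),
      " N_coal =", format(x$N_coal, digits = 6), "\n")
  invisible(x)
}
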