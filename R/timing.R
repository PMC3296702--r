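# Replication start- and end-time probabilities.
#
# The start of replication (first initiation) is Poisson-exact: the expected
# number of initiations by time t, ignoring passive replication, is
# N_e(t) = int_0^t int I(x,t') dx dt', and P_s(t) = 1 - exp(-N_e(t)).
# The end of replication (last coalescence) has no closed form for
# inhomogeneous scenarios; it is estimated by assuming the number of forks
# remaining at time t is Poisson, giving P_e(t) = exp(-int q(x,t) dx) with q
# a normalized fork density. The approximation is good early and late in
# S phase and degrades mid-S phase where fork numbers are largest.

#' Probability that replication has started
#'
#' For a whole molecule, `P_s(t) = 1 - exp(-N_e(t))` where `N_e(t)` is the
#' expected number of initiations up to `t` over the molecule (no passive-
#' replication factor: the first initiation cannot be preceded by another).
#' For a fragment `[x_minus, x_plus]` of a larger genome, replication can
#' also start by a fork crossing a boundary, so
#' `P_s(t) = 1 - exp(-N_e_frag(t)) * (1 - f_plus(x_minus, t)) *
#' (1 - f_minus(x_plus, t))`: no internal initiation and no right-moving
#' fork across the left end and no left-moving fork across the right end.
#'
#' @param sol an `"rk_fields"` from [solve_replication()].
#' @param region `"whole"` or `c(x_minus, x_plus)` in kb for a fragment.
#' @return data.frame with columns `t` and `P_start`.
#' @export
start_probability <- function(sol, region = "whole") {
  stopifnot(inherits(sol, "rk_fields"))
  g <- sol$grid
  sc <- sol$scenario
  if (identical(region, "whole")) {
    idx <- seq_len(g$n_x)
    crossing <- 1
  } else {
    stopifnot(is.numeric(region), length(region) == 2L, region[1] < region[2])
    if (region[1] < g$x0 - 1e-9 || region[2] > g$x0 + g$L + 1e-9)
      stop("fragment bounds outside the solved domain")
    idx <- which(g$x >= region[1] & g$x <= region[2])
    i_lo <- idx[1]; i_hi <- idx[length(idx)]
    crossing <- (1 - sol$f_plus[i_lo, ]) * (1 - sol$f_minus[i_hi, ])
  }
  # N_e(t): cumulative space-time integral of I over the region. Zones are
  # separable (static shape x gate), so the spatial sums are precomputed.
  n_t <- length(sol$t)
  zs <- sc$initiation$zones
  rate <- rep(sc$initiation$background * length(idx) * g$dx, n_t)
  for (z in zs) {
    zsum <- sum(zone_shape(z, g$x[idx])) * g$dx * z$amplitude
    rate <- rate + zsum * (sol$t >= z$t_on & sol$t <= z$t_off)
  }
  Ne <- cumsum(c(0, (rate[-n_t] + rate[-1]) / 2 * g$dt))
  data.frame(t = sol$t, P_start = 1 - exp(-Ne) * crossing)
}

#' Probability that replication has ended
#'
#' Estimates the probability that a molecule has finished replicating by
#' time `t`, assuming the number of forks still present is Poisson
#' distributed. For a periodic molecule the estimate is
#' `P_e(t) = exp(-int_0^L q_+(x,t) dx)` using right-moving forks (left-moving
#' gives an equivalent estimate under periodic boundaries, where the two
#' counts are equal). For a fragment, the absence of right-moving forks does
#' not imply the left part is replicated, so
#' `P_e(t) = f(x_minus, t) * exp(-int_{x_minus}^{x_plus} q_+ dx)`
#' (or mirrored with `f(x_plus, t)` and `q_-`).
#'
#' The fork density is normalized by the probability of being replicated:
#' `q_± = rho_± / max(f, eps)` (`normalize = "f"`, the default), which makes
#' the estimate exact in the t -> 0 limit; `normalize = "none"` uses the raw
#' density. Stalled forks, when present, are included in the density (a
#' molecule with a stalled fork has not finished). The result is clipped to
#' not exceed the start probability.
#'
#' @param sol an `"rk_fields"`.
#' @param region `"whole"` (requires periodic boundaries) or
#'   `c(x_minus, x_plus)` in kb.
#' @param side `"plus"` or `"minus"`: which fork direction to integrate.
#' @param normalize `"f"` or `"none"`.
#' @return data.frame with columns `t` and `P_end`.
#' @export
end_probability <- function(sol, region = "whole",
                            side = c("plus", "minus"),
                            normalize = c("f", "none")) {
  stopifnot(inherits(sol, "rk_fields"))
  side <- match.arg(side)
  normalize <- match.arg(normalize)
  g <- sol$grid
  rho <- if (side == "plus") sol$rho_plus else sol$rho_minus
  if (!is.null(sol$rho_stall_plus))
    rho <- rho + if (side == "plus") sol$rho_stall_plus else sol$rho_stall_minus

  if (identical(region, "whole")) {
    if (sol$scenario$boundary$mode != "periodic")
      stop("whole-molecule end probability requires periodic boundaries; ",
           "use a fragment region instead")
    idx <- seq_len(g$n_x)
    prefac <- rep(1, length(sol$t))
  } else {
    stopifnot(is.numeric(region), length(region) == 2L, region[1] < region[2])
    idx <- which(g$x >= region[1] & g$x <= region[2])
    if (!length(idx)) stop("fragment bounds outside the solved domain")
    bnd <- if (side == "plus") idx[1] else idx[length(idx)]
    prefac <- sol$f[bnd, ]
  }
  q <- rho[idx, , drop = FALSE]
  if (normalize == "f")
    q <- q / pmax(sol$f[idx, , drop = FALSE], 1e-12)
  P_e <- prefac * exp(-colSums(q) * g$dx)
  # cannot have ended before having started
  Ps <- start_probability(sol, region)$P_start
  data.frame(t = sol$t, P_end = pmin(P_e, Ps))
}

#' Differentiate timing curves into densities
#'
#' Central finite differences (one-sided at the ends) of a non-decreasing
#' probability curve; negative round-off is clipped at zero.
#'
#' @param curve data.frame with a time column `t` and one probability column.
#' @param tol tolerance for non-monotonicity before erroring.
#' @return data.frame with columns `t` and `density` (1/sec).
#' @export
timing_density <- function(curve, tol = 1e-8) {
  stopifnot(is.data.frame(curve), ncol(curve) >= 2)
  t <- curve[[1]]
  p <- curve[[2]]
  if (any(diff(p) < -tol))
    stop("input curve is not non-decreasing (beyond tolerance)")
  n <- length(t)
  d <- numeric(n)
  d[1] <- (p[2] - p[1]) / (t[2] - t[1])
  d[n] <- (p[n] - p[n - 1]) / (t[n] - t[n - 1])
  if (n > 2)
    d[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  data.frame(t = t, density = pmax(d, 0))
}
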