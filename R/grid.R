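#' Space-time discretization for replication kinetics
#'
#' Defines the lattice on which the mean-field rate equations are integrated:
#' a genomic segment of length `L` kb split into cells of `dx` kb, and a time
#' axis from 0 to `t_max` seconds in steps of `dt`. Cell centers are at
#' `x0 + (i - 1/2) * dx`; cells are half-open bins `[x, x + dx)`.
#'
#' @param L genome or fragment length in kb; must be a positive multiple of `dx`.
#' @param dx spatial step in kb.
#' @param dt time step in seconds.
#' @param t_max integration horizon in seconds; must be a positive multiple of `dt`.
#' @param x0 coordinate of the left end of the domain (kb). Defaults to 0.
#'
#' @return An object of class `"rk_grid"`: a list with elements `L`, `dx`,
#'   `dt`, `t_max`, `x0`, the cell-center coordinates `x` (length `n_x`) and
#'   time points `t` (length `n_t`, including t = 0).
#' @examples
#' g <- replication_grid(L = 1000, dx = 0.5, dt = 10, t_max = 20000)
#' g$n_x
#' @export
replication_grid <- function(L, dx, dt, t_max, x0 = 0) {
  stopifnot(is.numeric(L), is.numeric(dx), is.numeric(dt), is.numeric(t_max))
  if (L <= 0) stop("L must be positive")
  if (dx <= 0) stop("dx must be positive")
  if (dt <= 0) stop("dt must be positive")
  if (t_max <= 0) stop("t_max must be positive")
  n_x <- L / dx
  if (abs(n_x - round(n_x)) > 1e-8)
    stop("L/dx must be a positive integer (got ", n_x, ")")
  n_x <- as.integer(round(n_x))
  n_t <- t_max / dt
  if (abs(n_t - round(n_t)) > 1e-8)
    stop("t_max/dt must be a positive integer (got ", n_t, ")")
  n_t <- as.integer(round(n_t)) + 1L
  g <- list(
    L = L, dx = dx, dt = dt, t_max = t_max, x0 = x0,
    n_x = n_x, n_t = n_t,
    x = x0 + (seq_len(n_x) - 0.5) * dx,
    t = seq(0, t_max, by = dt)
  )
  class(g) <- "rk_grid"
  g
}

#' @export
print.rk_grid <- function(x, ...) {
  cat("Replication grid: [", x$x0, ",", x$x0 + x$L, ") kb, dx =", x$dx,
      "kb (", x$n_x, "cells ), dt =", x$dt, "s, t_max =", x$t_max, "s\n")
  invisible(x)
}
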