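# Stochastic (Monte Carlo) simulation of single replication cycles.
# The per-cycle kernel lives in src/mc_kernel.cpp; these wrappers build its
# inputs from a scenario, aggregate ensembles, and extract timing CDFs.

#' Lattice and rate tables for the MC kernel
#' @noRd
mc_inputs <- function(sc, t_max, delta_x = 0.1, x0 = 0, L = NULL) {
  stopifnot(inherits(sc, "rk_scenario"))
  if (is.null(L))
    stop("mc_inputs needs the domain length L")
  bc <- sc$boundary
  v_p_base <- sc$velocity$v_plus
  v_m_base <- sc$velocity$v_minus
  v_max <- max(v_p_base, v_m_base,
               if (!is.null(sc$velocity$segments))
                 c(sc$velocity$segments$v_plus, sc$velocity$segments$v_minus)
               else numeric(0))
  v_out <- if (bc$mode == "injection" && !is.na(bc$v_out)) bc$v_out else v_max
  delta_t <- delta_x / max(v_max, v_out)

  pbc <- bc$mode == "periodic"
  flank <- 0
  if (bc$mode == "injection") {
    # explicit homogeneous flanks long enough that no fork from beyond them
    # could reach the fragment within the horizon
    flank <- ceiling(v_out * t_max / delta_x) * delta_x
  }
  x_lo <- x0 - flank
  x_hi <- x0 + L + flank
  n <- round((x_hi - x_lo) / delta_x)
  site_x <- x_lo + (seq_len(n) - 0.5) * delta_x
  core <- site_x >= x0 & site_x < x0 + L

  bg_site <- rep(sc$initiation$background, n)
  if (bc$mode == "injection") {
    bg_site[site_x < x0] <- bc$I_left
    bg_site[site_x >= x0 + L] <- bc$I_right
  }
  zs <- sc$initiation$zones
  shapes <- if (length(zs)) vapply(zs, zone_shape, numeric(n), x = site_x)
            else matrix(0, n, 0)
  # zones describe the modeled region only; the flanks carry the constant rate
  if (flank > 0 && length(zs)) shapes[!core, ] <- 0

  v_p <- evaluate_velocity(sc$velocity, site_x, direction = "plus")
  v_m <- evaluate_velocity(sc$velocity, site_x, direction = "minus")
  if (flank > 0) {
    v_p[!core] <- v_out
    v_m[!core] <- v_out
  }

  list(site_x = site_x, bg_site = bg_site,
       shapes = shapes,
       amps = vapply(zs, `[[`, numeric(1), "amplitude"),
       gate_on = vapply(zs, `[[`, numeric(1), "t_on"),
       gate_off = vapply(zs, `[[`, numeric(1), "t_off"),
       v_p = v_p, v_m = v_m,
       delta_x = delta_x, delta_t = delta_t,
       n_steps = as.integer(ceiling(t_max / delta_t)),
       pbc = pbc, x_lo = x_lo, x_hi = x_hi, core = core,
       defect_d = if (is.null(sc$defects)) Inf else sc$defects$d,
       defect_tau = if (is.null(sc$defects)) Inf else sc$defects$tau)
}

mc_run_cycle <- function(mi) {
  mc_cycle_kernel(mi$site_x, mi$bg_site, mi$shapes,
                  mi$amps, mi$gate_on, mi$gate_off,
                  mi$v_p, mi$v_m,
                  mi$delta_x, mi$delta_t, mi$n_steps,
                  mi$pbc, mi$x_lo, mi$x_hi,
                  mi$defect_d, mi$defect_tau)
}

#' Simulate one stochastic replication cycle
#'
#' Runs a single cycle of the lattice Monte Carlo: unreplicated sites fire
#' with probability `I(x,t) * delta_x * delta_t` per step, forks advance at
#' `v±`, converging forks coalesce, and (with a [defect_model()]) forks stall
#' at Poisson-placed defects until an exponential repair time elapses.
#' Periodic boundaries wrap forks around; an injection boundary is realized
#' exactly, by simulating explicit homogeneous flanks of length
#' `v_out * t_max` on either side of the modeled region.
#'
#' @param sc an [scenario()].
#' @param L modeled region length in kb.
#' @param t_max simulation horizon in seconds.
#' @param seed optional integer seed (`set.seed`).
#' @param delta_x MC lattice spacing in kb (default 0.1); the time step is
#'   `delta_x / max(v)`.
#' @param x0 left end of the modeled region (kb).
#' @return An object of class `"rk_cycle"`: data frames `initiations` and
#'   `coalescences` (columns `x`, `t`), per-core-site vectors `x`, `t_rep`
#'   (NA where never replicated) and `dir` (+1 right-moving fork, -1
#'   left-moving, 0 origin site), and scalars `t_first_init`, `t_last_coal`.
#' @examples
#' cyc <- simulate_cycle(two_zone_scenario(), L = 1000, t_max = 30000, seed = 1)
#' nrow(cyc$initiations)
#' @export
simulate_cycle <- function(sc, L, t_max, seed = NULL, delta_x = 0.1, x0 = 0) {
  if (!is.null(seed)) set.seed(seed)
  mi <- mc_inputs(sc, t_max, delta_x, x0 = x0, L = L)
  res <- mc_run_cycle(mi)
  core <- mi$core
  coal_core <- res$coal_x >= x0 & res$coal_x < x0 + L
  init_core <- res$init_x >= x0 & res$init_x < x0 + L
  out <- list(
    x = mi$site_x[core],
    t_rep = res$t_rep[core],
    dir = res$dir[core],
    initiations = data.frame(x = res$init_x[init_core],
                             t = res$init_t[init_core]),
    coalescences = data.frame(x = res$coal_x[coal_core],
                              t = res$coal_t[coal_core]),
    all_initiations = data.frame(x = res$init_x, t = res$init_t),
    all_coalescences = data.frame(x = res$coal_x, t = res$coal_t),
    t_first_init = if (length(res$init_t)) min(res$init_t) else NA_real_,
    t_last_coal = if (length(res$coal_t)) max(res$coal_t) else NA_real_,
    delta_x = delta_x, delta_t = mi$delta_t,
    complete = res$complete, boundary = sc$boundary$mode
  )
  class(out) <- "rk_cycle"
  out
}

#' @export
print.rk_cycle <- function(x, ...) {
  cat("Replication cycle:", nrow(x$initiations), "initiation(s),",
      nrow(x$coalescences), "coalescence(s)\n")
  cat("  first initiation at", format(x$t_first_init),
      "s; last coalescence at", format(x$t_last_coal), "s\n")
  invisible(x)
}

#' Ensemble of stochastic replication cycles
#'
#' Repeats [simulate_cycle()] `n_cycles` times and aggregates, on a
#' space-time comparison binning, the ensemble mean replication fraction,
#' the moving-fork densities (estimated from the per-site replication flux),
#' and the initiation/coalescence event histograms, together with per-bin
#' standard errors (standard deviation over cycles / sqrt(n_cycles)).
#'
#' @param sc an [scenario()].
#' @param L region length (kb); `t_max` horizon (s).
#' @param n_cycles number of cycles (>= 1).
#' @param seed integer master seed; all cycles consume the same R RNG stream.
#' @param bin_x,bin_t comparison bin sizes (kb, s).
#' @param delta_x MC lattice spacing (kb).
#' @param t_max simulation horizon in seconds.
#' @param x0 left end of the modeled region (kb).
#' @return An object of class `"rk_ensemble"` with matrices `mean_f`,
#'   `se_f`, `rho_plus`, `se_rho_plus`, `rho_minus`, `se_rho_minus`,
#'   `D_init`, `se_D_init`, `D_coal`, `se_D_coal` (densities per kb per sec
#'   per cycle), bin centers `x`, `t`, per-cycle vectors `n_init`,
#'   `t_first_init`, `t_last_coal`, and `n_cycles`. The density matrices are
#'   within-bin averages (times `t`); `mean_f` is cumulative, i.e. the
#'   replication fraction at the bin right edges `t_edge`.
#' @export
run_ensemble <- function(sc, L, t_max, n_cycles, seed = NULL,
                         bin_x = 10, bin_t = 250, delta_x = 0.1, x0 = 0) {
  stopifnot(n_cycles >= 1)
  if (!is.null(seed)) set.seed(seed)
  mi <- mc_inputs(sc, t_max, delta_x, x0 = x0, L = L)
  core <- mi$core
  cx_site <- pmin(floor((mi$site_x[core] - x0) / bin_x) + 1L,
                  as.integer(ceiling(L / bin_x)))
  n_bx <- as.integer(ceiling(L / bin_x))
  n_bt <- as.integer(ceiling(t_max / bin_t))
  sites_per_bin <- tabulate(cx_site, n_bx)
  v_p_bin <- evaluate_velocity(sc$velocity, x0 + (seq_len(n_bx) - 0.5) * bin_x,
                               direction = "plus")
  v_m_bin <- evaluate_velocity(sc$velocity, x0 + (seq_len(n_bx) - 0.5) * bin_x,
                               direction = "minus")

  zero <- matrix(0, n_bx, n_bt)
  acc <- list(f = zero, f2 = zero, rp = zero, rp2 = zero,
              rm = zero, rm2 = zero, di = zero, di2 = zero,
              dc = zero, dc2 = zero)
  n_init <- t_first <- t_last <- numeric(n_cycles)

  bin_counts <- function(keep, t_vals) {
    bt <- floor(t_vals / bin_t) + 1L
    ok <- keep & !is.na(bt) & bt >= 1L & bt <= n_bt
    m <- tabulate(cx_site[ok] + (bt[ok] - 1L) * n_bx, n_bx * n_bt)
    matrix(m, n_bx, n_bt)
  }

  for (cyc in seq_len(n_cycles)) {
    res <- mc_run_cycle(mi)
    t_rep <- res$t_rep[core]
    dir <- res$dir[core]

    C_all <- bin_counts(rep(TRUE, length(t_rep)), t_rep)
    f_cyc <- t(apply(C_all, 1, cumsum)) / pmax(sites_per_bin, 1L)
    C_p <- bin_counts(!is.na(dir) & dir == 1L, t_rep)
    C_m <- bin_counts(!is.na(dir) & dir == -1L, t_rep)
    # a fork at density rho sweeps v*bin_t/delta_x sites per time bin
    rp_cyc <- C_p * delta_x / (bin_x * bin_t) / v_p_bin
    rm_cyc <- C_m * delta_x / (bin_x * bin_t) / v_m_bin

    ix <- res$init_x; it <- res$init_t
    ok <- ix >= x0 & ix < x0 + L & it < t_max
    bi <- floor((ix[ok] - x0) / bin_x) + 1L + floor(it[ok] / bin_t) * n_bx
    di_cyc <- matrix(tabulate(bi, n_bx * n_bt), n_bx, n_bt) / (bin_x * bin_t)
    cxv <- res$coal_x; ctv <- res$coal_t
    ok <- cxv >= x0 & cxv < x0 + L & ctv < t_max
    bi <- floor((cxv[ok] - x0) / bin_x) + 1L + floor(ctv[ok] / bin_t) * n_bx
    dc_cyc <- matrix(tabulate(bi, n_bx * n_bt), n_bx, n_bt) / (bin_x * bin_t)

    acc$f <- acc$f + f_cyc;   acc$f2 <- acc$f2 + f_cyc^2
    acc$rp <- acc$rp + rp_cyc; acc$rp2 <- acc$rp2 + rp_cyc^2
    acc$rm <- acc$rm + rm_cyc; acc$rm2 <- acc$rm2 + rm_cyc^2
    acc$di <- acc$di + di_cyc; acc$di2 <- acc$di2 + di_cyc^2
    acc$dc <- acc$dc + dc_cyc; acc$dc2 <- acc$dc2 + dc_cyc^2

    n_init[cyc] <- sum(res$init_x >= x0 & res$init_x < x0 + L)
    t_first[cyc] <- if (length(res$init_t)) min(res$init_t) else NA_real_
    t_last[cyc] <- if (length(res$coal_t)) max(res$coal_t) else NA_real_
  }

  mean_se <- function(s1, s2) {
    m <- s1 / n_cycles
    v <- pmax(s2 / n_cycles - m^2, 0)
    list(mean = m, se = sqrt(v / n_cycles))
  }
  f_ms <- mean_se(acc$f, acc$f2)
  rp_ms <- mean_se(acc$rp, acc$rp2)
  rm_ms <- mean_se(acc$rm, acc$rm2)
  di_ms <- mean_se(acc$di, acc$di2)
  dc_ms <- mean_se(acc$dc, acc$dc2)

  out <- list(
    x = x0 + (seq_len(n_bx) - 0.5) * bin_x,
    t = (seq_len(n_bt) - 0.5) * bin_t,
    t_edge = seq_len(n_bt) * bin_t,  # mean_f is cumulative: f(x, t_edge)
    bin_x = bin_x, bin_t = bin_t,
    mean_f = f_ms$mean, se_f = f_ms$se,
    rho_plus = rp_ms$mean, se_rho_plus = rp_ms$se,
    rho_minus = rm_ms$mean, se_rho_minus = rm_ms$se,
    D_init = di_ms$mean, se_D_init = di_ms$se,
    D_coal = dc_ms$mean, se_D_coal = dc_ms$se,
    n_init = n_init, t_first_init = t_first, t_last_coal = t_last,
    n_cycles = n_cycles
  )
  class(out) <- "rk_ensemble"
  out
}

#' @export
print.rk_ensemble <- function(x, ...) {
  cat("MC ensemble of", x$n_cycles, "replication cycles\n")
  cat("  mean initiations/cycle:", format(mean(x$n_init), digits = 4), "\n")
  cat("  mean start / end time:", format(mean(x$t_first_init, na.rm = TRUE),
      digits = 5), "/", format(mean(x$t_last_coal, na.rm = TRUE),
      digits = 5), "s\n")
  invisible(x)
}

#' Empirical replication start-/end-time distributions
#'
#' Step CDFs of the first-initiation and last-coalescence times over an
#' ensemble of cycles. Cycles without any event are excluded with a warning.
#'
#' @param ens an `"rk_ensemble"` from [run_ensemble()], or a list of
#'   `"rk_cycle"` objects.
#' @return list with `start` and `end` (empirical CDF functions, see
#'   [stats::ecdf()]), and `n_excluded`.
#' @export
empirical_timing <- function(ens) {
  if (inherits(ens, "rk_ensemble")) {
    tf <- ens$t_first_init
    tl <- ens$t_last_coal
  } else {
    tf <- vapply(ens, `[[`, numeric(1), "t_first_init")
    tl <- vapply(ens, `[[`, numeric(1), "t_last_coal")
  }
  bad <- is.na(tf) | is.na(tl)
  if (any(bad))
    warning(sum(bad), " cycle(s) without events excluded")
  list(start = stats::ecdf(tf[!bad]), end = stats::ecdf(tl[!bad]),
       n_excluded = sum(bad))
}
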