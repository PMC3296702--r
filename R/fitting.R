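# Inference of replication scenarios from SMARD profiles by iterative
# decorrelated least squares.
#
# SMARD profile bins are strongly correlated along the genome (a molecule
# that is red at x tends to be red at x + 5 kb too), so an ordinary
# chi-square over bins is invalid. The procedure: simulate replicate
# experiments under the current scenario, estimate their covariance, fit a
# positive-definite parametric surrogate (per-block variance profile times
# an exponential-decay correlation), Cholesky-factorize it, decorrelate data
# and model with the inverse factor, minimize the evenly weighted sum of
# squares, and iterate with the refreshed scenario until convergence.

#' Sample covariance of replicate profile vectors
#'
#' @param replicates matrix with one replicate per row (>= 2 rows), or a
#'   list of equal-length vectors.
#' @return the unbiased sample covariance matrix.
#' @export
estimate_covariance <- function(replicates) {
  if (is.list(replicates)) replicates <- do.call(rbind, replicates)
  stopifnot(is.matrix(replicates), nrow(replicates) >= 2)
  stats::cov(replicates)
}

#' Positive-definite parametric covariance surrogate
#'
#' An empirical covariance estimated from few replicates is typically
#' rank-deficient, hence not usable for Cholesky decorrelation. This builds
#' a certified positive-definite surrogate: within each data block (e.g. the
#' red-green content bins of one fragment), the variance profile is the
#' (lightly smoothed) empirical diagonal and the correlation decays
#' exponentially, `exp(-|x_i - x_j| / lambda)`, with the decay length fitted
#' to the empirical within-block correlations; across blocks the covariance
#' is zero. A small diagonal ridge is escalated until the Cholesky
#' factorization succeeds.
#'
#' @param C empirical covariance matrix.
#' @param blocks list of blocks, each a list with `idx` (column indices into
#'   the data vector) and `x` (bin positions, kb).
#' @param var_floor relative floor for the variance profile (guards zero
#'   variance bins; default 1e-3 of the block mean variance).
#' @return An object of class `"rk_covmodel"`: `C_par`, lower-triangular
#'   `L_chol`, fitted `lambda` per block, and the ridge used.
#' @export
parametrize_covariance <- function(C, blocks, var_floor = 1e-3) {
  n <- nrow(C)
  C_par <- matrix(0, n, n)
  lambda <- numeric(length(blocks))
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]$idx
    x <- blocks[[b]]$x
    stopifnot(length(idx) == length(x))
    v <- diag(C)[idx]
    vbar <- mean(v)
    if (vbar <= 0) vbar <- 1e-12
    # smooth the variance profile (running mean, window 3)
    if (length(v) >= 3)
      v <- stats::filter(v, rep(1 / 3, 3), sides = 2) |>
        (\(z) { z[is.na(z)] <- v[is.na(z)]; as.numeric(z) })()
    v <- pmax(v, var_floor * vbar)
    # empirical mean correlation per lag; nugget + exponential decay model:
    # R(0) = 1, R(d) = a * exp(-d / lambda) for d > 0 (positive definite for
    # 0 <= a <= 1 as a nugget plus exponential mixture)
    Cb <- C[idx, idx, drop = FALSE]
    R <- Cb / sqrt(outer(v, v))
    dmat <- abs(outer(x, x, "-"))
    off <- upper.tri(R)
    lags <- dmat[off]
    cors <- R[off]
    a_b <- 0
    if (length(lags) && any(cors > 0.05)) {
      lag_m <- tapply(cors, lags, mean)
      lag_d <- as.numeric(names(lag_m))
      w <- as.numeric(tapply(cors, lags, length))
      span <- max(lag_d)
      sse <- function(p) {
        a <- stats::plogis(p[1]); lam <- exp(p[2])
        sum(w * (lag_m - a * exp(-lag_d / lam))^2)
      }
      op <- stats::optim(c(stats::qlogis(0.8), log(span / 4)), sse,
                         method = "Nelder-Mead")
      a_b <- stats::plogis(op$par[1])
      lambda[b] <- exp(op$par[2])
      lambda[b] <- min(max(lambda[b], span * 1e-4), span * 10)
    } else {
      lambda[b] <- min(diff(sort(unique(x))), 1) * 1e-6  # ~ diagonal
    }
    Rpar <- a_b * exp(-dmat / lambda[b])
    diag(Rpar) <- 1
    C_par[idx, idx] <- sqrt(outer(v, v)) * Rpar
  }
  ridge <- 0
  Lc <- NULL
  scale <- mean(diag(C_par))
  for (r in c(0, 10^(-8:0) * scale)) {
    Lc <- tryCatch(t(chol(C_par + diag(r, n))), error = function(e) NULL)
    if (!is.null(Lc)) { ridge <- r; break }
  }
  if (is.null(Lc))
    stop("covariance parametrization could not be made positive definite")
  out <- list(C_par = C_par + diag(ridge, n), L_chol = Lc,
              lambda = lambda, ridge = ridge, blocks = blocks)
  class(out) <- "rk_covmodel"
  out
}

#' @export
print.rk_covmodel <- function(x, ...) {
  cat("Parametrized covariance model:", nrow(x$C_par), "bins,",
      length(x$blocks), "block(s); decay lengths",
      paste(signif(x$lambda, 3), collapse = ", "), "kb",
      if (x$ridge > 0) paste0("; ridge ", signif(x$ridge, 2)) else "", "\n")
  invisible(x)
}

#' Covariance model from a positive-definite matrix
#'
#' Wraps an already positive-definite covariance (e.g. the empirical sample
#' covariance of sufficiently many replicates) into the same object
#' [decorrelate()] uses, by direct Cholesky factorization — no parametric
#' surrogate. Use [parametrize_covariance()] instead when the replicate
#' count is below (or near) the data dimension.
#'
#' @param C symmetric positive-definite covariance matrix.
#' @return An `"rk_covmodel"`.
#' @export
covariance_model <- function(C) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (max(abs(C - t(C))) > 1e-8 * max(abs(C)))
    stop("C must be symmetric")
  Lc <- tryCatch(t(chol(C)), error = function(e)
    stop("C is not positive definite; use parametrize_covariance()"))
  out <- list(C_par = C, L_chol = Lc, lambda = NA_real_, ridge = 0,
              blocks = list(list(idx = seq_len(nrow(C)), x = seq_len(nrow(C)))))
  class(out) <- "rk_covmodel"
  out
}

#' Decorrelate a profile vector
#'
#' Solves `L z = vec` with the lower-triangular Cholesky factor, so that
#' replicate vectors transformed this way have (approximately) identity
#' covariance and can be fitted with unit weights.
#'
#' @param cm an `"rk_covmodel"`.
#' @param vec numeric vector matching the model dimension.
#' @return the decorrelated vector.
#' @export
decorrelate <- function(cm, vec) {
  stopifnot(inherits(cm, "rk_covmodel"))
  if (length(vec) != nrow(cm$L_chol))
    stop("dimension mismatch: vector has ", length(vec), " entries, model ",
         nrow(cm$L_chol))
  as.numeric(forwardsolve(cm$L_chol, vec))
}

# ---------------------------------------------------------------------------
# Scenario families for fitting

#' Parametric scenario family with two initiation zones
#'
#' The parametrization used for fitting fragment data: two rounded-box
#' initiation zones (center, width, peak rate each), a constant initiation
#' background, fork injection rates at the left and right ends of the
#' modeled region, and a constant fork velocity. With
#' `deletion = c(start, length)` the family describes a *pair* of
#' conditions — a normal allele and a rearranged allele carrying a genomic
#' deletion: the deleted scenario loses the second zone (assumed to lie in
#' the deleted region), its domain is shorter by the deletion length, and
#' coordinates beyond the deletion shift left; the two conditions share all
#' initiation parameters but may have distinct fork velocities (one extra
#' parameter), for a total of 11.
#'
#' @param L modeled region length (kb).
#' @param deletion optional `c(start_kb, length_kb)` enabling the paired
#'   (normal + deleted) variant.
#' @param x0 left end coordinate (kb).
#' @param zone_shape `"rounded_box"` (default) or `"gaussian"`.
#' @return An object of class `"rk_family"` with `par_names`, `lower`,
#'   `upper` bounds and a `build(theta)` closure returning the scenario(s).
#' @export
two_zone_family <- function(L, deletion = NULL, x0 = 0,
                            zone_shape = "rounded_box") {
  paired <- !is.null(deletion)
  par_names <- c("center1", "width1", "rate1",
                 "center2", "width2", "rate2",
                 "background", "I_left", "I_right", "v")
  if (paired) par_names <- c(par_names, "v_deleted")
  # velocity bounds span the range reported for metazoan replication forks
  lower <- c(x0, 5, 0, x0, 5, 0, 0, 0, 0, 0.005)
  upper <- c(x0 + L, L / 2, 1e-2, x0 + L, L / 2, 1e-2, 1e-3, 1e-2, 1e-2, 0.1)
  if (paired) { lower <- c(lower, 0.005); upper <- c(upper, 0.1) }

  build_one <- function(th, drop_zone2 = FALSE, Lc = L, shift_from = Inf,
                        shift_by = 0) {
    mkz <- function(ctr, w, r) {
      if (ctr > shift_from) ctr <- ctr - shift_by
      initiation_zone(ctr, w, r, shape = zone_shape)
    }
    zones <- list(mkz(th[1], th[2], th[3]))
    if (!drop_zone2) zones <- c(zones, list(mkz(th[4], th[5], th[6])))
    v <- if (drop_zone2 && paired) th[11] else th[10]
    scenario(
      initiation_profile(zones, background = th[7]),
      velocity_profile(v),
      boundary_condition("injection", I_left = th[8], I_right = th[9])
    )
  }
  build <- function(theta) {
    stopifnot(length(theta) == length(par_names))
    if (!paired) return(list(normal = build_one(theta)))
    list(normal = build_one(theta),
         deleted = build_one(theta, drop_zone2 = TRUE,
                             Lc = L - deletion[2],
                             shift_from = deletion[1] + deletion[2],
                             shift_by = deletion[2]))
  }
  fam <- list(name = if (paired) "two_zone_pair" else "two_zone",
              L = L, x0 = x0, deletion = deletion,
              condition_L = if (paired) c(normal = L,
                                          deleted = L - deletion[2])
                            else c(normal = L),
              par_names = par_names, n_par = length(par_names),
              lower = lower, upper = upper, build = build)
  class(fam) <- "rk_family"
  fam
}

#' Build scenario(s) from a fit parameter vector
#'
#' @param theta numeric parameter vector (length `family$n_par`).
#' @param family an `"rk_family"` from [two_zone_family()].
#' @return named list of `"rk_scenario"` objects, one per condition.
#' @export
scenario_from_params <- function(theta, family) {
  stopifnot(inherits(family, "rk_family"))
  if (length(theta) != family$n_par)
    stop("theta length ", length(theta), " does not match family ",
         family$name, " (", family$n_par, " parameters)")
  if (any(theta < family$lower - 1e-12) || any(theta > family$upper + 1e-12))
    stop("theta out of bounds for family ", family$name)
  family$build(theta)
}

# ---------------------------------------------------------------------------
# Forward model and fit

#' Grid used by the fit's forward solves
#' @noRd
fit_grid <- function(L, v_max, dx = 2, t_max = 6e4, x0 = 0) {
  dx <- L / round(L / dx)
  dt <- 0.8 * dx / v_max
  replication_grid(L, dx, dt, ceiling(t_max / dt) * dt, x0 = x0)
}

#' Bin a fine profile to comparison bins
#' @noRd
bin_profile <- function(x, y, x0, L, bin) {
  b <- pmin(floor((x - x0) / bin) + 1L, ceiling(L / bin))
  as.numeric(tapply(y, b, mean))
}

#' Predicted SMARD profile vector for one condition
#'
#' Besides the binned red-green content and fork-density profiles, the
#' vector may carry the expected fraction of two-color molecules among
#' fully labeled ones, `int (P_s - P_e) dt / t_window`. The time-integrated
#' profiles alone are invariant under jointly rescaling all rates and the
#' velocity, so this collection-fraction component is what anchors the
#' absolute timescale (experimentally it comes from the counts of fully
#' red/green molecules, the same counts the fork-speed estimator uses).
#' @noRd
predict_vector <- function(sol, fragments, x0, L, bin_content, bin_fork,
                           t_window = NA_real_) {
  out <- list()
  for (fr in fragments) {
    parts <- smard_denominator(sol, fr)
    rg <- predict_red_green(sol, fr, .parts = parts)
    fd <- predict_fork_density(sol, fr, .parts = parts)
    sel <- rg$x >= fr[1] & rg$x < fr[2]
    Lf <- fr[2] - fr[1]
    v <- c(
      bin_profile(rg$x[sel], rg$r[sel], fr[1], Lf, bin_content),
      bin_profile(fd$x[sel], fd$rho_plus[sel], fr[1], Lf, bin_fork),
      bin_profile(fd$x[sel], fd$rho_minus[sel], fr[1], Lf, bin_fork))
    if (!is.na(t_window))
      v <- c(v, min(parts$den / t_window, 1))
    out[[length(out) + 1L]] <- v
  }
  unlist(out)
}

#' Observed profile vector from a molecule set
#' @noRd
observed_vector <- function(ms, bin_content, bin_fork,
                            with_acceptance = FALSE) {
  pf <- smard_profiles(ms, bin_content = bin_content, bin_fork = bin_fork)
  v <- c(pf$content$r, pf$forks$rho_plus, pf$forks$rho_minus)
  if (with_acceptance) {
    n_rg <- nrow(ms$labels)
    v <- c(v, n_rg / (ms$n_full_red + ms$n_full_green + n_rg))
  }
  v
}

#' Block structure (content / fork+ / fork- / acceptance) of the vector
#' @noRd
vector_blocks <- function(fragments, bin_content, bin_fork,
                          with_acceptance = FALSE) {
  blocks <- list()
  off <- 0L
  for (fr in fragments) {
    Lf <- fr[2] - fr[1]
    n_c <- ceiling(Lf / bin_content)
    n_f <- ceiling(Lf / bin_fork)
    xc <- fr[1] + (seq_len(n_c) - 0.5) * bin_content
    xf <- fr[1] + (seq_len(n_f) - 0.5) * bin_fork
    blocks <- c(blocks, list(
      list(idx = off + seq_len(n_c), x = xc),
      list(idx = off + n_c + seq_len(n_f), x = xf),
      list(idx = off + n_c + n_f + seq_len(n_f), x = xf)))
    off <- off + n_c + 2L * n_f
    if (with_acceptance) {
      blocks <- c(blocks, list(list(idx = off + 1L, x = fr[1])))
      off <- off + 1L
    }
  }
  blocks
}

#' Data-driven starting values for the two-zone family
#'
#' Zone centers are placed at the two most prominent local maxima of the
#' pooled red-green content, widths at a fraction of the region, amplitudes
#' at a rate scale set by the homogeneous closed form, the injection rates
#' at a matching scale, and the velocity at the experimental estimator
#' `v = l / (n_f * t_rep)` with `t_rep = t_window * n_rg / (n_r + n_rg)`
#' when the molecule sets carry full-red/full-green counts (falling back to
#' 0.04 kb/s otherwise).
#'
#' @param mol_sets list of `"rk_molecules"`.
#' @param fragments list of `c(from, to)` per set (kb).
#' @param family an `"rk_family"`.
#' @param bin_content content bin (kb) for peak finding.
#' @return numeric vector of starting values.
#' @export
init_two_zone <- function(mol_sets, fragments, family, bin_content = 10) {
  # pooled content profile across fragments of the normal condition
  xs <- c(); rs <- c()
  for (i in seq_along(mol_sets)) {
    pf <- smard_profiles(mol_sets[[i]], bin_content = bin_content,
                         bin_fork = fragments[[i]][2] - fragments[[i]][1])
    xs <- c(xs, pf$content$x)
    rs <- c(rs, pf$content$r)
  }
  o <- order(xs)
  xs <- xs[o]; rs <- rs[o]
  sm <- stats::filter(rs, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- rs[is.na(sm)]
  loc <- which(diff(sign(diff(sm))) < 0) + 1L
  if (length(loc) < 2) loc <- order(sm, decreasing = TRUE)[1:2]
  loc <- loc[order(sm[loc], decreasing = TRUE)][1:2]
  ctrs <- sort(xs[loc])

  # fork-speed estimator from the experiment's own counts
  v0 <- 0.04
  vs <- c()
  for (i in seq_along(mol_sets)) {
    ms <- mol_sets[[i]]
    if (is.na(ms$n_full_red) || is.null(ms$t_window)) next
    n_rg <- nrow(ms$labels)
    n_f <- mean(vapply(ms$fork_marks, nrow, integer(1)))
    t_rep <- ms$t_window * n_rg / (ms$n_full_red + ms$n_full_green + n_rg)
    if (n_f > 0 && t_rep > 0) vs <- c(vs, ms$L / (n_f * t_rep))
  }
  if (length(vs)) v0 <- stats::median(vs)
  v0 <- min(max(v0, family$lower[10] * 1.5), family$upper[10] / 1.5)

  # rate scale from the homogeneous closed form: S phase ~ 1/sqrt(I v)
  span <- sum(vapply(fragments, function(f) f[2] - f[1], numeric(1)))
  t_rep_all <- if (length(vs)) stats::median(vapply(mol_sets, function(ms) {
    n_rg <- nrow(ms$labels)
    ms$t_window * n_rg / (ms$n_full_red + ms$n_full_green + n_rg)
  }, numeric(1))) else 1e4
  I0 <- 1 / (v0 * t_rep_all^2)
  width0 <- max(family$lower[2] * 1.2, span / 12)
  amp0 <- min(max(I0 * span / (2 * width0), 1e-7), family$upper[3] / 10)
  th <- c(ctrs[1], width0, amp0, ctrs[2], width0, amp0,
          amp0 / 50, amp0 * width0 / 2, amp0 * width0 / 2, v0)
  if (family$n_par == 11) th <- c(th, v0)
  pmin(pmax(th, family$lower * 1.0000001), family$upper * 0.9999999)
}

#' Fit a replication scenario to SMARD molecule data
#'
#' The package's central model-fitting function. Implements the iterative
#' decorrelated least-squares procedure: (1) start from `theta0` (or a
#' data-driven initialization); (2) solve the mean-field rate equations for
#' the current scenario and predict the concatenated profile vector; (3)
#' simulate `n_sim` replicate SMARD experiments at the current scenario with
#' the observed molecule counts; (4) estimate and parametrize their
#' covariance; (5) Cholesky-decorrelate data and model; (6) minimize the
#' unit-weight sum of squared decorrelated residuals over the family's
#' parameters (Nelder-Mead on a log scale for rates); (7) repeat from (2)
#' with the refreshed scenario until the relative parameter change drops
#' below `tol` or `max_outer` iterations.
#'
#' @param mol_sets list of `"rk_molecules"` (one per fragment per condition).
#' @param fragments list of `c(from, to)` kb intervals, one per molecule set,
#'   in the coordinates of the modeled region.
#' @param family an `"rk_family"` (see [two_zone_family()]).
#' @param condition character vector naming each set's condition
#'   (`"normal"`/`"deleted"`); defaults to all `"normal"`.
#' @param theta0 optional starting parameter vector.
#' @param n_sim simulated replicate experiments per outer iteration.
#' @param bin_content,bin_fork comparison bin sizes (kb).
#' @param max_outer,tol outer-loop controls.
#' @param seed integer seed for the simulation replicates.
#' @param solver_dx forward-solver spatial step (kb).
#' @param mc_delta_x MC lattice step for replicate simulation (kb).
#' @param optim_control passed to [stats::optim()] (Nelder-Mead).
#' @param verbose print per-iteration progress.
#' @return An object of class `"rk_fit"` with components `theta` (named),
#'   `objective`, `chisq_red`, `df`, `converged`, `n_outer`, `history`,
#'   `vcov` (Gauss-Newton, from the decorrelated Jacobian), `se`, the final
#'   covariance model `cov_model`, observed vector `y`, fitted vector
#'   `fitted`, and the call ingredients needed by its methods.
#' @examples
#' \donttest{
#' fam <- two_zone_family(L = 500)
#' sc <- scenario_from_params(
#'   c(150, 40, 2e-5, 350, 40, 4e-5, 1e-7, 5e-4, 5e-4, 0.04), fam)$normal
#' ms1 <- sample_smard(sc, L = 500, n_keep = 30, fragment = c(0, 250),
#'                     seed = 1, delta_x = 0.5)
#' ms2 <- sample_smard(sc, L = 500, n_keep = 30, fragment = c(250, 500),
#'                     seed = 2, delta_x = 0.5)
#' fit <- fit_smard(list(ms1, ms2), list(c(0, 250), c(250, 500)), fam,
#'                  n_sim = 20, max_outer = 2, seed = 3)
#' coef(fit)
#' }
#' @export
fit_smard <- function(mol_sets, fragments, family,
                      condition = NULL, theta0 = NULL,
                      n_sim = 200, bin_content = 10, bin_fork = 50,
                      max_outer = 10, tol = 1e-2, seed = NULL,
                      solver_dx = 1, mc_delta_x = 0.5,
                      optim_control = list(maxit = 300), verbose = FALSE) {
  stopifnot(inherits(family, "rk_family"),
            length(mol_sets) == length(fragments))
  if (is.null(condition)) condition <- rep("normal", length(mol_sets))
  stopifnot(all(condition %in% names(family$condition_L)))
  if (!is.null(seed)) set.seed(seed)
  n_mol <- vapply(mol_sets, function(m) nrow(m$labels), integer(1))
  t_windows <- vapply(mol_sets, function(m)
    if (is.null(m$t_window)) NA_real_ else m$t_window, numeric(1))
  # the collection-fraction component (absolute-timescale anchor) needs the
  # full-red/green counts and the asynchrony window for every set
  with_acc <- all(!is.na(t_windows)) &&
    all(vapply(mol_sets, function(m)
      !is.na(m$n_full_red) && !is.na(m$n_full_green), logical(1)))

  y <- unlist(lapply(seq_along(mol_sets), function(i)
    observed_vector(mol_sets[[i]], bin_content, bin_fork,
                    with_acceptance = with_acc)))
  blocks <- vector_blocks(fragments, bin_content, bin_fork,
                          with_acceptance = with_acc)

  conds <- unique(condition)
  grids <- lapply(conds, function(cd)
    fit_grid(family$condition_L[[cd]], family$upper[10], dx = solver_dx,
             x0 = family$x0))
  names(grids) <- conds

  # forward model: theta -> concatenated predicted vector; one solve per
  # condition, reused across that condition's fragments
  forward_cached <- function(theta) {
    scs <- family$build(theta)
    sols <- lapply(conds, function(cd)
      solve_replication(scs[[cd]], grids[[cd]]))
    names(sols) <- conds
    suppressWarnings(unlist(lapply(seq_along(mol_sets), function(i)
      predict_vector(sols[[condition[i]]], list(fragments[[i]]), family$x0,
                     family$condition_L[[condition[i]]],
                     bin_content, bin_fork,
                     t_window = if (with_acc) t_windows[i] else NA_real_))))
  }

  if (is.null(theta0)) theta0 <- init_two_zone(mol_sets, fragments, family,
                                               bin_content = bin_content)
  theta <- pmin(pmax(theta0, family$lower), family$upper)

  # log-scale transform for rate parameters
  is_rate <- grepl("rate|background|I_", family$par_names)
  rate_floor <- 1e-10
  to_z <- function(th) ifelse(is_rate, log(pmax(th, rate_floor)), th)
  to_th <- function(z) ifelse(is_rate, exp(z), z)

  history <- data.frame(outer = integer(0), objective = numeric(0))
  cm <- NULL
  converged <- FALSE
  n_outer_done <- 0L

  for (outer in seq_len(max_outer)) {
    n_outer_done <- outer
    scs <- family$build(theta)
    # (3) replicate experiments at the current scenario
    reps <- matrix(NA_real_, n_sim, length(y))
    for (s in seq_len(n_sim)) {
      v <- c()
      for (i in seq_along(mol_sets)) {
        ms <- sample_smard(scs[[condition[i]]],
                           L = family$condition_L[[condition[i]]],
                           n_keep = n_mol[i],
                           fragment = fragments[[i]],
                           t_window = if (is.na(t_windows[i])) NULL
                                      else t_windows[i],
                           delta_x = mc_delta_x, x0 = family$x0)
        v <- c(v, observed_vector(ms, bin_content, bin_fork,
                                  with_acceptance = with_acc))
      }
      reps[s, ] <- v
    }
    C_emp <- estimate_covariance(reps)
    cm <- parametrize_covariance(C_emp, blocks)
    yd <- decorrelate(cm, y)

    obj <- function(z) {
      th <- to_th(z)
      if (any(th < family$lower) || any(th > family$upper))
        return(1e8 + sum(pmax(th - family$upper, 0, family$lower - th)^2))
      md <- tryCatch(decorrelate(cm, forward_cached(th)),
                     error = function(e) NULL)
      if (is.null(md)) return(1e8)
      sum((yd - md)^2)
    }
    opt <- stats::optim(to_z(theta), obj, method = "Nelder-Mead",
                        control = optim_control)
    theta_new <- to_th(opt$par)
    history <- rbind(history,
                     data.frame(outer = outer, objective = opt$value))
    if (verbose)
      message("outer ", outer, ": objective ", signif(opt$value, 6))
    rel <- max(abs(theta_new - theta) /
                 pmax(abs(theta), 1e-3 * (family$upper - family$lower)))
    theta <- theta_new
    if (rel < tol) { converged <- TRUE; break }
  }

  fitted_vec <- forward_cached(theta)
  resid_d <- decorrelate(cm, y) - decorrelate(cm, fitted_vec)
  df <- length(y) - family$n_par
  chisq_red <- sum(resid_d^2) / df

  # Gauss-Newton uncertainties from the decorrelated Jacobian
  J <- matrix(NA_real_, length(y), family$n_par)
  f0 <- decorrelate(cm, fitted_vec)
  for (j in seq_len(family$n_par)) {
    h <- pmax(1e-4 * abs(theta[j]), 1e-6 * (family$upper[j] - family$lower[j]))
    tp <- theta; tp[j] <- min(theta[j] + h, family$upper[j])
    J[, j] <- (decorrelate(cm, forward_cached(tp)) - f0) /
      (tp[j] - theta[j])
  }
  vcov_th <- tryCatch(solve(crossprod(J)) * max(chisq_red, 1),
                      error = function(e)
                        matrix(NA_real_, family$n_par, family$n_par))
  se <- sqrt(pmax(diag(vcov_th), 0))
  names(theta) <- names(se) <- family$par_names
  dimnames(vcov_th) <- list(family$par_names, family$par_names)

  out <- list(theta = theta, objective = sum(resid_d^2),
              chisq_red = chisq_red, df = df,
              converged = converged, n_outer = n_outer_done,
              history = history, vcov = vcov_th, se = se,
              cov_model = cm, y = y, fitted = fitted_vec,
              blocks = blocks, family = family, condition = condition,
              fragments = fragments, bin_content = bin_content,
              bin_fork = bin_fork, n_mol = n_mol, grids = grids,
              t_windows = t_windows, with_acceptance = with_acc)
  class(out) <- "rk_fit"
  out
}

#' @export
print.rk_fit <- function(x, ...) {
  cat("Replication-scenario fit (", x$family$name, " family )\n", sep = "")
  cat("  reduced chi-square:", signif(x$chisq_red, 4), "on", x$df,
      "degrees of freedom\n")
  cat("  outer iterations:", x$n_outer,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  parameters:\n")
  print(signif(x$theta, 4))
  invisible(x)
}

#' @export
coef.rk_fit <- function(object, ...) object$theta

#' @export
vcov.rk_fit <- function(object, ...) object$vcov

#' @export
summary.rk_fit <- function(object, ...) {
  tab <- data.frame(estimate = object$theta, std_error = object$se)
  out <- list(coefficients = tab, chisq_red = object$chisq_red,
              df = object$df, converged = object$converged,
              lambda = object$cov_model$lambda)
  class(out) <- "summary.rk_fit"
  out
}

#' @export
print.summary.rk_fit <- function(x, ...) {
  cat("Coefficients:\n")
  print(signif(as.matrix(x$coefficients), 4))
  cat("\nReduced chi-square:", signif(x$chisq_red, 4), "on", x$df,
      "df;", if (x$converged) "converged" else "not converged", "\n")
  cat("Correlation decay lengths (kb):",
      paste(signif(x$lambda, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.rk_fit <- function(object, theta = NULL, ...) {
  th <- if (is.null(theta)) object$theta else theta
  scs <- object$family$build(th)
  out <- list()
  for (i in seq_along(object$fragments)) {
    cd <- object$condition[i]
    sol <- solve_replication(scs[[cd]], object$grids[[cd]])
    out[[i]] <- list(
      red_green = predict_red_green(sol, object$fragments[[i]]),
      forks = predict_fork_density(sol, object$fragments[[i]]))
  }
  out
}

#' @export
residuals.rk_fit <- function(object, type = c("decorrelated", "raw"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted
  if (type == "decorrelated") r <- decorrelate(object$cov_model, r)
  r
}

#' @export
plot.rk_fit <- function(x, ...) {
  n_b <- length(x$blocks)
  graphics::plot(x$y, pch = 1, xlab = "data-vector index",
                 ylab = "profile value",
                 main = "observed (circles) vs fitted (line)")
  graphics::lines(x$fitted, col = 2, lwd = 2)
  for (b in x$blocks)
    graphics::abline(v = min(b$idx) - 0.5, lty = 3, col = "grey")
  invisible(x)
}

#' Simulate replicate molecule sets from a fitted scenario
#'
#' @param object an `"rk_fit"`.
#' @param nsim number of replicate experiments.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of length `nsim`; each element is a list of
#'   `"rk_molecules"` matching the fitted data sets.
#' @export
simulate.rk_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  scs <- object$family$build(object$theta)
  lapply(seq_len(nsim), function(s)
    lapply(seq_along(object$fragments), function(i)
      sample_smard(scs[[object$condition[i]]],
                   L = object$family$condition_L[[object$condition[i]]],
                   n_keep = object$n_mol[i],
                   fragment = object$fragments[[i]],
                   t_window = if (is.na(object$t_windows[i])) NULL
                              else object$t_windows[i],
                   delta_x = 0.25, x0 = object$family$x0)))
}
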