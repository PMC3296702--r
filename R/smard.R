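# SMARD (single-molecule analysis of replicated DNA) simulation and
# mean-field prediction of its summary profiles.
#
# In a SMARD experiment an asynchronous cell population is pulse-labeled
# with a first ("red") and then a second ("green") nucleotide analog. On a
# molecule caught mid-replication, DNA replicated before the label switch is
# red, DNA replicated after is green, and red->green transition points mark
# the replication forks at the switch time (forks move from red into green).

#' Label a simulated replication cycle
#'
#' Applies the dual-label protocol to one [simulate_cycle()] result: a
#' position is red (1) if it replicated before `t_switch`, green (0)
#' otherwise. Fork marks are read off the label transitions, with direction
#' from the red side to the green side.
#'
#' @param cyc an `"rk_cycle"`.
#' @param t_switch label-switch time in seconds (>= 0).
#' @return An object of class `"rk_molecule"`: `x` (site centers, kb),
#'   `label` (1 red / 0 green), `fork_marks` (data.frame `x`, `dir`),
#'   `t_switch`, and `two_color`.
#' @export
label_cycle <- function(cyc, t_switch) {
  stopifnot(inherits(cyc, "rk_cycle"))
  if (t_switch < 0) stop("t_switch must be >= 0")
  if (anyNA(cyc$t_rep))
    stop("cycle did not fully replicate the molecule; labels undefined")
  label <- as.integer(cyc$t_rep < t_switch)
  fm <- fork_marks_from_labels(cyc$x, label, pbc = cyc$boundary == "periodic")
  m <- list(x = cyc$x, label = label, fork_marks = fm, t_switch = t_switch,
            two_color = any(label == 1L) && any(label == 0L))
  class(m) <- "rk_molecule"
  m
}

#' Fork positions and directions from a label vector
#' @noRd
fork_marks_from_labels <- function(x, label, pbc = FALSE) {
  n <- length(label)
  dx <- if (n > 1) x[2] - x[1] else 0
  i <- which(label[-n] != label[-1])
  pos <- (x[i] + x[i + 1]) / 2
  dir <- ifelse(label[i] == 1L, 1L, -1L)  # red -> green reads as + fork
  if (pbc && n > 1 && label[n] != label[1]) {
    pos <- c(pos, x[n] + dx / 2)
    dir <- c(dir, if (label[n] == 1L) 1L else -1L)
  }
  data.frame(x = pos, dir = dir)
}

#' Collect a synthetic SMARD molecule set
#'
#' Repeats the full experimental protocol on simulated cycles: each cell's
#' label-switch time is uniform on `[0, t_window]` (a perfectly asynchronous
#' population), the cycle is labeled, and molecules are kept according to
#' `keep`: `"two_color"` keeps only molecules carrying both labels (the set
#' analyzed for profiles; a molecule is two-color iff the switch falls
#' between its first initiation and last coalescence), `"all_fully_labeled"`
#' also keeps fully red and fully green molecules (needed e.g. for the
#' experimental fork-speed estimator). Counts of fully red/green molecules
#' encountered are recorded either way.
#'
#' @param sc an [scenario()].
#' @param L molecule length (kb).
#' @param n_keep number of molecules to collect.
#' @param t_window asynchrony window (s). Default: smallest time with
#'   whole-molecule end probability > 0.999, found from a mean-field
#'   pre-solve on `window_grid`.
#' @param keep `"two_color"` or `"all_fully_labeled"`.
#' @param seed optional integer seed.
#' @param delta_x MC lattice spacing (kb).
#' @param window_grid optional `"rk_grid"` for the pre-solve.
#' @param max_attempts abort guard (default `200 * n_keep`, and an error is
#'   raised if the acceptance probability appears to be below 1e-3).
#' @param x0 left end of the region (kb).
#' @param fragment optional `c(from, to)` kb: collect molecules covering only
#'   this sub-interval of the modeled region (a restriction fragment of a
#'   larger genome). Labels, fork marks and the two-color criterion are then
#'   evaluated on the fragment alone.
#' @return An object of class `"rk_molecules"`: `labels` (matrix, molecules
#'   in rows), `x` (site centers), `t_switch` per molecule, `fork_marks`
#'   (list of data.frames), counts `n_attempted`, `n_full_red`,
#'   `n_full_green`, and `t_window`.
#' @export
sample_smard <- function(sc, L, n_keep, t_window = NULL,
                         keep = c("two_color", "all_fully_labeled"),
                         seed = NULL, delta_x = 0.1, window_grid = NULL,
                         max_attempts = 200 * n_keep, x0 = 0,
                         fragment = NULL) {
  keep <- match.arg(keep)
  stopifnot(n_keep >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(fragment)) {
    stopifnot(length(fragment) == 2L, fragment[1] < fragment[2],
              fragment[1] >= x0 - 1e-9, fragment[2] <= x0 + L + 1e-9)
  }
  if (is.null(t_window)) {
    if (is.null(window_grid)) {
      v_max <- max(sc$velocity$v_plus, sc$velocity$v_minus)
      dx <- L / max(200L, min(1000L, round(L)))
      dtt <- 0.8 * dx / v_max  # Courant < 1: numerical diffusion lets
                               # residual opposing fork packets annihilate
      # generous horizon; the solve stops early once replication completes
      window_grid <- replication_grid(L, dx, dtt, ceiling(1.2e5 / dtt) * dtt,
                                      x0 = x0)
    }
    pre <- solve_replication(sc, window_grid)
    region <- if (!is.null(fragment)) fragment
              else if (sc$boundary$mode == "periodic") "whole"
              else c(x0, x0 + L)
    Pe <- end_probability(pre, region)
    hit <- which(Pe$P_end > 0.999)
    if (!length(hit))
      stop("could not determine t_window: end probability never exceeds ",
           "0.999 on the pre-solve grid; pass t_window explicitly")
    t_window <- Pe$t[hit[1]]
  }
  t_max <- 1.3 * t_window

  mi <- mc_inputs(sc, t_max, delta_x, x0 = x0, L = L)
  core <- mi$core
  if (!is.null(fragment))
    core <- core & mi$site_x >= fragment[1] & mi$site_x < fragment[2]
  labels <- matrix(NA_integer_, n_keep, sum(core))
  fork_marks <- vector("list", n_keep)
  t_sw <- numeric(n_keep)
  got <- 0L; attempted <- 0L; n_red <- 0L; n_green <- 0L
  x_core <- mi$site_x[core]
  pbc <- is.null(fragment) && sc$boundary$mode == "periodic"

  while (got < n_keep) {
    if (attempted >= max_attempts)
      stop("sample_smard: acceptance probability too low (",
           got, "/", attempted, " kept); is t_window far too wide?")
    attempted <- attempted + 1L
    res <- mc_run_cycle(mi)
    trep <- res$t_rep[core]
    if (anyNA(trep)) next  # horizon guard; extremely rare
    ts <- stats::runif(1, 0, t_window)
    red <- trep < ts
    if (all(red)) { n_red <- n_red + 1L; two <- FALSE }
    else if (all(!red)) { n_green <- n_green + 1L; two <- FALSE }
    else two <- TRUE
    ok <- if (keep == "two_color") two else TRUE
    if (!ok) next
    if (attempted > 1000L && got / attempted < 1e-3)
      stop("sample_smard: acceptance probability below 1e-3")
    got <- got + 1L
    labels[got, ] <- as.integer(red)
    t_sw[got] <- ts
    fork_marks[[got]] <- fork_marks_from_labels(x_core, as.integer(red), pbc)
  }

  out_x0 <- if (is.null(fragment)) x0 else fragment[1]
  out_L <- if (is.null(fragment)) L else fragment[2] - fragment[1]
  out <- list(labels = labels, x = x_core, t_switch = t_sw,
              fork_marks = fork_marks,
              n_attempted = attempted, n_full_red = n_red,
              n_full_green = n_green, t_window = t_window,
              pbc = pbc, L = out_L, x0 = out_x0)
  class(out) <- "rk_molecules"
  out
}

#' @export
print.rk_molecules <- function(x, ...) {
  cat("SMARD molecule set:", nrow(x$labels), "molecule(s) on [",
      x$x0, ",", x$x0 + x$L, ") kb\n")
  cat("  collected from", x$n_attempted, "cycles (",
      x$n_full_red, "fully red,", x$n_full_green, "fully green seen )\n")
  invisible(x)
}

#' SMARD summary profiles of a molecule set
#'
#' Computes the experiment's three per-position summaries:
#' the red-green content `r(x)` (fraction of molecules red at `x`, averaged
#' over `bin_content`-kb bins), the right- and left-moving fork densities
#' (fork marks per molecule per kb in `bin_fork`-kb bins), and the spatial
#' autocorrelation `A(dx)` of the red-green indicator, averaged over
#' molecules (biased estimator, normalized by the lag-0 pair count, with
#' wraparound on periodic molecules where the maximum displacement is L/2).
#'
#' @param ms an `"rk_molecules"` set (or anything with `labels`, `x`,
#'   `fork_marks`).
#' @param bin_content content bin size in kb (default 5).
#' @param bin_fork fork-density bin size in kb (default 50).
#' @return An object of class `"rk_profiles"`: data.frames `content`
#'   (`x`, `r`, `se`), `forks` (`x`, `rho_plus`, `rho_minus`, `se_plus`,
#'   `se_minus`), and `autocorr` (`lag`, `A`); `n_molecules`.
#' @export
smard_profiles <- function(ms, bin_content = 5, bin_fork = 50) {
  n_mol <- nrow(ms$labels)
  if (is.null(n_mol) || n_mol == 0) stop("empty molecule set")
  dx <- ms$x[2] - ms$x[1]
  rel <- ms$x - ms$x0

  # red-green content per bin
  cb <- pmin(floor(rel / bin_content) + 1L, ceiling(ms$L / bin_content))
  n_cb <- max(cb)
  lab_bin <- t(apply(ms$labels, 1, function(l) {
    vapply(split(l, cb), mean, numeric(1))
  }))
  r <- colMeans(lab_bin)
  se_r <- apply(lab_bin, 2, stats::sd) / sqrt(n_mol)

  # fork densities per bin
  n_fb <- ceiling(ms$L / bin_fork)
  cnt_p <- matrix(0, n_mol, n_fb)
  cnt_m <- matrix(0, n_mol, n_fb)
  for (i in seq_len(n_mol)) {
    fm <- ms$fork_marks[[i]]
    if (!nrow(fm)) next
    b <- pmin(floor(((fm$x - ms$x0) %% ms$L) / bin_fork) + 1L, n_fb)
    cnt_p[i, ] <- tabulate(b[fm$dir == 1L], n_fb)
    cnt_m[i, ] <- tabulate(b[fm$dir == -1L], n_fb)
  }
  rho_p <- colMeans(cnt_p) / bin_fork
  rho_m <- colMeans(cnt_m) / bin_fork
  se_p <- apply(cnt_p, 2, stats::sd) / sqrt(n_mol) / bin_fork
  se_m <- apply(cnt_m, 2, stats::sd) / sqrt(n_mol) / bin_fork

  # autocorrelation of the centered red-green indicator (on content bins)
  D <- sweep(lab_bin, 2, r)
  if (isTRUE(ms$pbc)) {
    ft <- stats::mvfft(t(D))
    ac <- Re(stats::mvfft(ft * Conj(ft), inverse = TRUE)) / n_cb
    A <- rowMeans(ac) / n_cb
    n_lag <- floor(n_cb / 2) + 1L
    A <- A[seq_len(n_lag)]
  } else {
    n_lag <- floor(n_cb / 2) + 1L
    A <- vapply(seq_len(n_lag) - 1L, function(lag) {
      if (lag == 0) return(mean(D^2))
      m <- n_cb - lag
      sum(D[, 1:m, drop = FALSE] * D[, (1 + lag):n_cb, drop = FALSE]) /
        (n_mol * n_cb)
    }, numeric(1))
  }

  out <- list(
    content = data.frame(x = ms$x0 + (seq_len(n_cb) - 0.5) * bin_content,
                         r = r, se = se_r),
    forks = data.frame(x = ms$x0 + (seq_len(n_fb) - 0.5) * bin_fork,
                       rho_plus = rho_p, rho_minus = rho_m,
                       se_plus = se_p, se_minus = se_m),
    autocorr = data.frame(lag = (seq_len(n_lag) - 1L) * bin_content, A = A),
    n_molecules = n_mol, bin_content = bin_content, bin_fork = bin_fork
  )
  class(out) <- "rk_profiles"
  out
}

#' @export
print.rk_profiles <- function(x, ...) {
  cat("SMARD profiles from", x$n_molecules, "molecules (",
      x$bin_content, "kb content bins,", x$bin_fork, "kb fork bins )\n")
  invisible(x)
}

#' @export
plot.rk_profiles <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$content$x, x$content$r, type = "p", pch = 1, ylim = c(0, 1),
       xlab = "position (kb)", ylab = "red-green content r(x)", ...)
  plot(x$forks$x, x$forks$rho_plus, type = "b", pch = 2,
       ylim = range(0, x$forks$rho_plus, x$forks$rho_minus),
       xlab = "position (kb)", ylab = "fork density (forks/kb)")
  graphics::points(x$forks$x, x$forks$rho_minus, type = "b", pch = 6)
  graphics::legend("topright", legend = c("right-moving", "left-moving"),
                   pch = c(2, 6), bty = "n")
  invisible(x)
}

smard_denominator <- function(sol, region) {
  Ps <- start_probability(sol, region)$P_start
  Pe <- end_probability(sol, region)$P_end
  if (Pe[length(Pe)] < 0.99)
    warning("end probability only reaches ", round(Pe[length(Pe)], 4),
            " at the horizon; SMARD estimates are truncated")
  dt <- sol$t[2] - sol$t[1]
  den <- sum(Ps - Pe) * dt
  list(Ps = Ps, Pe = Pe, den = den, dt = dt)
}

#' Predict the SMARD red-green content from the mean-field solution
#'
#' The expected red-green content of two-color molecules is
#' \deqn{\tilde r(x) = \frac{\int_0^\infty [f(x,t) - P_e(t)]\,dt}
#'                          {\int_0^\infty [P_s(t) - P_e(t)]\,dt}.}
#' The numerator subtracts `P_e` because fully replicated molecules (which
#' contribute to `f` but are not collected as two-color) must be corrected
#' for; fully unreplicated molecules contribute zero and need no correction.
#' The denominator is the collection probability density integral: a
#' molecule is collectable while replication has started but not ended.
#'
#' @param sol a solved `"rk_fields"` whose horizon covers the full S phase.
#' @param region `"whole"` or `c(x_minus, x_plus)`, passed to the timing
#'   curves.
#' @param .parts precomputed timing curves (internal; avoids recomputation
#'   when several estimators share one region).
#' @return data.frame with columns `x` and `r`.
#' @export
predict_red_green <- function(sol, region = "whole", .parts = NULL) {
  stopifnot(inherits(sol, "rk_fields"))
  parts <- if (is.null(.parts)) smard_denominator(sol, region) else .parts
  if (parts$den <= 1e-9)
    stop("degenerate scenario: collection window has vanishing probability")
  num <- (sol$f %*% rep(parts$dt, ncol(sol$f))) -
    sum(parts$Pe) * parts$dt
  r <- pmin(pmax(as.numeric(num) / parts$den, 0), 1)
  data.frame(x = sol$grid$x, r = r)
}

#' Predict the SMARD fork densities from the mean-field solution
#'
#' \deqn{\tilde\rho_\pm(x) = \frac{\int_0^\infty \rho_\pm(x,t)\,dt}
#'                                {\int_0^\infty [P_s(t) - P_e(t)]\,dt}.}
#' No fully-replicated-molecule correction is needed: finished molecules
#' carry no forks.
#'
#' @inheritParams predict_red_green
#' @return data.frame with columns `x`, `rho_plus`, `rho_minus` (forks/kb).
#' @export
predict_fork_density <- function(sol, region = "whole", .parts = NULL) {
  stopifnot(inherits(sol, "rk_fields"))
  parts <- if (is.null(.parts)) smard_denominator(sol, region) else .parts
  if (parts$den <= 1e-9)
    stop("degenerate scenario: collection window has vanishing probability")
  data.frame(
    x = sol$grid$x,
    rho_plus = rowSums(sol$rho_plus) * parts$dt / parts$den,
    rho_minus = rowSums(sol$rho_minus) * parts$dt / parts$den
  )
}
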