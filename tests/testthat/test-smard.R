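test_that("labeling a cycle follows the dual-pulse geometry", {
  sc <- homog_scenario(3e-5, 0.04)
  set.seed(13)
  cyc <- simulate_cycle(sc, L = 200, t_max = 10000)

  all_red <- label_cycle(cyc, max(cyc$t_rep) + 1)
  expect_true(all(all_red$label == 1L))
  expect_equal(nrow(all_red$fork_marks), 0L)
  expect_false(all_red$two_color)

  all_green <- label_cycle(cyc, min(cyc$t_rep) - 1)
  expect_true(all(all_green$label == 0L))
  expect_equal(nrow(all_green$fork_marks), 0L)

  expect_error(label_cycle(cyc, -5), "t_switch")
})

test_that("fork marks read off labels equal the true fork positions", {
  sc <- homog_scenario(3e-5, 0.04)
  set.seed(19)
  for (k in 1:10) {
    cyc <- simulate_cycle(sc, L = 200, t_max = 10000)
    ts <- stats::runif(1, min(cyc$t_rep), max(cyc$t_rep))
    mol <- label_cycle(cyc, ts)
    if (!mol$two_color) next
    # true fork positions at ts: boundaries between replicated (t_rep < ts)
    # and unreplicated sites, with direction red -> green
    red <- cyc$t_rep < ts
    n <- length(red)
    i <- which(red[-n] != red[-1])
    true_pos <- (cyc$x[i] + cyc$x[i + 1]) / 2
    true_dir <- ifelse(red[i], 1L, -1L)
    if (red[n] != red[1]) {
      true_pos <- c(true_pos, cyc$x[n] + cyc$delta_x / 2)
      true_dir <- c(true_dir, if (red[n]) 1L else -1L)
    }
    expect_equal(mol$fork_marks$x, true_pos)
    expect_equal(mol$fork_marks$dir, true_dir)
    # a single-origin-like structure: equal numbers of outward fork pairs
    expect_equal(sum(mol$fork_marks$dir == 1), sum(mol$fork_marks$dir == -1))
  }
})

test_that("a single-origin molecule labels as one red island with outward forks", {
  # one narrow efficient zone; pick a cycle with exactly one initiation
  sc <- scenario(
    initiation_profile(list(initiation_zone(100, 3, 2e-3, t_off = 500))),
    velocity_profile(0.04))
  set.seed(23)
  repeat {
    cyc <- simulate_cycle(sc, L = 200, t_max = 10000)
    if (nrow(cyc$initiations) == 1) break
  }
  t0 <- cyc$initiations$t[1]
  mol <- label_cycle(cyc, t0 + 1000)  # mid-replication switch
  expect_true(mol$two_color)
  expect_equal(nrow(mol$fork_marks), 2L)
  # right-moving fork right of the origin, left-moving fork left of it
  x0 <- cyc$initiations$x[1]
  plus <- mol$fork_marks$x[mol$fork_marks$dir == 1]
  minus <- mol$fork_marks$x[mol$fork_marks$dir == -1]
  d <- function(a, b) { dd <- (a - b) %% 200; min(dd, 200 - dd) }
  expect_equal(d(plus, x0), 1000 * 0.04, tolerance = 0.2)
  expect_equal(d(minus, x0), 1000 * 0.04, tolerance = 0.2)
  # red interval centered on the origin
  red_span <- range(cyc$x[mol$label == 1L])
  expect_true(x0 >= red_span[1] && x0 <= red_span[2])
})

test_that("two-color selection and the acceptance fraction match theory", {
  sc <- two_zone_scenario()
  g <- two_zone_grid()
  sol <- solve_replication(sc, g)
  set.seed(29)
  ms <- sample_smard(sc, L = 1000, n_keep = 200, delta_x = 0.25)
  # every kept molecule carries both labels
  expect_true(all(rowSums(ms$labels) > 0))
  expect_true(all(rowSums(ms$labels) < ncol(ms$labels)))
  # empirical acceptance ~ integral of (P_s - P_e) / t_window
  Ps <- start_probability(sol)$P_start
  Pe <- end_probability(sol)$P_end
  pred <- sum(pmax(Ps - Pe, 0)) * g$dt / ms$t_window
  emp <- 200 / ms$n_attempted
  se <- sqrt(pred * (1 - pred) / ms$n_attempted)
  expect_lt(abs(emp - pred), 4 * se + 0.01)
})

test_that("profiles of degenerate sets behave as defined", {
  fake <- structure(list(
    labels = matrix(1L, 4, 100),
    x = (1:100) - 0.5, t_switch = rep(1, 4),
    fork_marks = replicate(4, data.frame(x = numeric(0), dir = integer(0)),
                           simplify = FALSE),
    pbc = TRUE, L = 100, x0 = 0), class = "rk_molecules")
  pf <- smard_profiles(fake, bin_content = 5, bin_fork = 50)
  expect_true(all(pf$content$r == 1))
  expect_true(all(pf$forks$rho_plus == 0))
  expect_error(smard_profiles(structure(list(labels = NULL),
                                        class = "rk_molecules")), "empty")
})

test_that("mean-field SMARD estimators are symmetric for homogeneous kinetics", {
  sol <- solve_replication(homog_scenario(2e-5, 0.04),
                           replication_grid(200, 0.5, 10, 10000))
  r <- predict_red_green(sol)
  expect_lt(diff(range(r$r)), 1e-9)       # constant in x
  expect_true(all(r$r >= 0 & r$r <= 1))
  fd <- predict_fork_density(sol)
  expect_lt(diff(range(fd$rho_plus)), 1e-12)
  expect_equal(fd$rho_plus, fd$rho_minus, tolerance = 1e-9)
  # f(x,t) dominates P_e(t) pointwise: a finished molecule has f = 1
  Pe <- end_probability(sol)$P_end
  expect_gt(min(sweep(sol$f, 2, Pe)), -1e-6)
})

test_that("sampled profiles converge to the mean-field predictions", {
  sc <- two_zone_scenario()
  sol <- solve_replication(sc, two_zone_grid())
  pr <- predict_red_green(sol)
  r_pred <- tapply(pr$r, rep(1:100, each = 20), mean)  # 10 kb bins
  fd <- predict_fork_density(sol)
  rp_pred <- tapply(fd$rho_plus, rep(1:10, each = 200), mean)  # 100 kb bins
  set.seed(37)
  tw <- NULL
  errs <- matrix(NA_real_, 3, 2)
  for (i in 1:3) {
    n <- c(50, 500, 5000)[i]
    ms <- sample_smard(sc, L = 1000, n_keep = n, delta_x = 0.25,
                       t_window = tw)
    tw <- ms$t_window
    pf <- smard_profiles(ms, bin_content = 10, bin_fork = 100)
    errs[i, 1] <- sqrt(mean((pf$content$r - r_pred)^2))
    errs[i, 2] <- sqrt(mean((pf$forks$rho_plus - rp_pred)^2)) / mean(rp_pred)
  }
  # estimates converge towards the mean-field predictions as n grows
  expect_lt(errs[3, 1], errs[1, 1])
  expect_lt(errs[3, 2], errs[1, 2])
  expect_lt(errs[3, 1], 0.02)   # content within 2 points at n = 5000
  expect_lt(errs[3, 2], 0.10)   # fork densities within 10% RMS
})

test_that("red-green autocorrelation is materially positive at short lags", {
  sc <- two_zone_scenario()
  set.seed(41)
  # experiment-scale set: tens of molecules
  ms <- sample_smard(sc, L = 1000, n_keep = 57, delta_x = 0.25)
  pf <- smard_profiles(ms)
  A <- pf$autocorr
  a5 <- A$A[A$lag == 5]
  floor_sd <- stats::sd(A$A[A$lag > 300])
  expect_gt(a5, 3 * floor_sd)
  expect_gt(a5, 0.05)
  expect_gte(A$A[1], a5)  # lag-0 variance dominates
})
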