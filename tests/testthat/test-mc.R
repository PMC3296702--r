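test_that("a sourceless cycle stays empty", {
  sc <- scenario(initiation_profile(background = 0), velocity_profile(0.04))
  cyc <- simulate_cycle(sc, L = 100, t_max = 1000, seed = 1)
  expect_equal(nrow(cyc$initiations), 0L)
  expect_equal(nrow(cyc$coalescences), 0L)
  expect_true(all(is.na(cyc$t_rep)))
  expect_false(cyc$complete)
})

test_that("initiations equal coalescences in every periodic cycle", {
  sc <- homog_scenario(3e-5, 0.04)
  set.seed(5)
  for (k in 1:30) {
    cyc <- simulate_cycle(sc, L = 200, t_max = 10000)
    expect_true(cyc$complete)
    expect_equal(nrow(cyc$initiations), nrow(cyc$coalescences))
    expect_true(all(diff(sort(cyc$t_rep)) >= 0))  # times well-defined
  }
})

test_that("site replication times equal the nearest-origin arrival times", {
  # with constant v, coverage is the union of independent growth cones, so
  # t_rep(x) = min over initiations of (t_i + circular_dist(x, x_i)/v),
  # up to half a lattice cell of rounding
  sc <- homog_scenario(3e-5, 0.04)
  set.seed(11)
  v <- 0.04; L <- 200
  for (k in 1:5) {
    cyc <- simulate_cycle(sc, L = L, t_max = 10000, delta_x = 0.1)
    ini <- cyc$initiations
    expect_gt(nrow(ini), 0)
    pred <- vapply(cyc$x, function(x) {
      d <- abs(x - ini$x)
      d <- pmin(d, L - d)
      min(ini$t + d / v)
    }, numeric(1))
    tol <- 0.1 / v + cyc$delta_t + 1e-9
    expect_lt(max(abs(cyc$t_rep - pred)), tol)
  }
})

test_that("ensemble means converge to the KJMA closed form", {
  I0 <- 2e-5; v <- 0.04
  sc <- homog_scenario(I0, v)
  set.seed(42)
  ens <- run_ensemble(sc, L = 200, t_max = 8000, n_cycles = 300,
                      bin_x = 20, bin_t = 500)
  # the infinite-line closed form is exact on a ring only until the
  # coverage cone wraps, t < L/(2v) = 2500 s; compare inside that window
  pre <- ens$t_edge <= 2400
  f_exact <- matrix(1 - exp(-I0 * v * ens$t_edge[pre]^2),
                    nrow(ens$mean_f), sum(pre), byrow = TRUE)
  tol <- tol_prob(ens$se_f[, pre], f_exact, 300, quantum = 0.1 / 20 / 300)
  expect_gt(mean(abs(ens$mean_f[, pre] - f_exact) < tol), 0.95)
  # fork density: within-bin average of the closed form, early-to-mid
  # S phase (the lattice flux estimator loses ~half a site per coalescence
  # near the end of S phase)
  prer <- ens$t <= 1500
  rho_avg <- vapply(which(prer), function(k) {
    tt <- seq(ens$t[k] - 250, ens$t[k] + 250, length.out = 26)
    tt <- tt[tt >= 0]
    mean(I0 * tt * exp(-I0 * v * tt^2))
  }, numeric(1))
  z_ok_r <- frac_within(ens$rho_plus[, prer],
                        matrix(rho_avg, nrow(ens$rho_plus),
                               sum(prer), byrow = TRUE),
                        ens$se_rho_plus[, prer],
                        floor = 0.1 / (20 * 500 * v) / 300)
  expect_gt(z_ok_r, 0.9)
})

test_that("ensemble error shrinks roughly like 1/sqrt(n)", {
  I0 <- 2e-5; v <- 0.04
  sc <- homog_scenario(I0, v)
  err_at <- function(n, seed) {
    set.seed(seed)
    ens <- run_ensemble(sc, L = 200, t_max = 8000, n_cycles = n,
                        bin_x = 50, bin_t = 1000)
    f_exact <- 1 - exp(-I0 * v * ens$t_edge^2)
    sqrt(mean(sweep(ens$mean_f, 2, f_exact)^2))
  }
  e100 <- err_at(100, 1)
  e1000 <- err_at(1000, 2)
  expect_lt(e1000, e100)          # monotone improvement
  expect_lt(e1000 / e100, 0.75)   # consistent with ~1/sqrt(10) = 0.32
})

test_that("first-initiation times follow the exponential first-event law", {
  I0 <- 2e-5; L <- 200
  sc <- homog_scenario(I0, 0.04)
  set.seed(17)
  ens <- run_ensemble(sc, L = L, t_max = 8000, n_cycles = 1000,
                      bin_x = 50, bin_t = 1000)
  et <- empirical_timing(ens)
  s <- sort(ens$t_first_init)
  theo <- 1 - exp(-I0 * L * s)
  ks <- max(abs(theo - seq_along(s) / length(s)),
            abs(theo - (seq_along(s) - 1) / length(s)))
  expect_lt(ks, 3 * 1.358 / sqrt(1000))
  # degenerate case: identical logs give a step CDF
  expect_equal(et$start(max(s)), 1)
  expect_equal(et$start(-1), 0)
})

test_that("single-cycle stats equal the log's indicator fields", {
  sc <- homog_scenario(5e-5, 0.04)
  set.seed(3)
  ens <- run_ensemble(sc, L = 100, t_max = 6000, n_cycles = 1,
                      bin_x = 10, bin_t = 500)
  # with one cycle, per-bin means are multiples of 1/(sites per bin)
  expect_true(all(abs(ens$mean_f * 100 - round(ens$mean_f * 100)) < 1e-9))
  expect_true(all(ens$se_f == 0))
  expect_equal(length(ens$n_init), 1L)
})
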