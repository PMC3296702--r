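test_that("no initiation means no replication", {
  sc <- scenario(initiation_profile(background = 0), velocity_profile(0.04))
  g <- replication_grid(100, 0.5, 10, 2000)
  sol <- solve_replication(sc, g)
  expect_true(all(sol$f == 0))
  expect_true(all(sol$rho_plus == 0))
  expect_true(all(sol$rho_minus == 0))
  expect_equal(sol$N_init, 0)
})

test_that("homogeneous kinetics match the KJMA closed form", {
  # drho/dt = I0 exp(-I0 v t^2) - 2 v rho^2 exp(+I0 v t^2) is solved by
  # rho = I0 t exp(-I0 v t^2); f = 1 - exp(-I0 v t^2) (verified analytically)
  I0 <- 2e-5; v <- 0.04
  sc <- homog_scenario(I0, v)
  g <- replication_grid(200, 0.5, 10, 8000)
  sol <- solve_replication(sc, g)
  f_exact <- 1 - exp(-I0 * v * sol$t^2)
  rho_exact <- I0 * sol$t * exp(-I0 * v * sol$t^2)
  err_f <- max(abs(colMeans(sol$f) - f_exact))
  err_rp <- max(abs(colMeans(sol$rho_plus) - rho_exact))
  err_rm <- max(abs(colMeans(sol$rho_minus) - rho_exact))
  expect_lt(err_f, 1e-2)
  expect_lt(err_rp, 1e-3)
  expect_lt(err_rm, 1e-3)
  # spatial homogeneity is preserved exactly
  expect_equal(max(apply(sol$f, 2, stats::sd)), 0)

  # first-order convergence: refining the grid halves the error
  g2 <- replication_grid(200, 0.25, 5, 8000)
  sol2 <- solve_replication(sc, g2)
  err_f2 <- max(abs(colMeans(sol2$f) - (1 - exp(-I0 * v * sol2$t^2))))
  expect_lt(err_f2, 0.65 * err_f)
})

test_that("initiations balance coalescences under periodic boundaries", {
  sol <- solve_replication(two_zone_scenario(), two_zone_grid())
  expect_lt(abs(sol$N_init - sol$N_coal) / sol$N_init, 0.002)
  ev <- event_densities(sol)
  expect_equal(sum(ev$D_init) * ev$dx * ev$dt, 1, tolerance = 1e-6)
  expect_equal(sum(ev$D_coal) * ev$dx * ev$dt, 1, tolerance = 1e-6)
  expect_true(all(ev$D_init >= 0))
  expect_true(all(ev$D_coal >= 0))
})

test_that("fields respect their structural invariants", {
  sol <- solve_replication(two_zone_scenario(), two_zone_grid(dx = 1, dt = 20))
  expect_true(all(sol$f >= 0 & sol$f <= 1 + 1e-9))
  expect_true(all(sol$rho_plus >= 0))
  expect_true(all(sol$rho_minus >= 0))
  # f non-decreasing in time at every position
  expect_true(all(apply(sol$f, 1, function(r) all(diff(r) >= -1e-12))))
  # directional fractions add up to f
  expect_lt(max(abs(sol$f_plus + sol$f_minus - sol$f)), 1e-9)
})

test_that("grid refinement changes N_init by less than 1 percent", {
  sc <- two_zone_scenario()
  n1 <- solve_replication(sc, two_zone_grid(dx = 0.5, dt = 10))$N_init
  n2 <- solve_replication(sc, two_zone_grid(dx = 0.25, dt = 5))$N_init
  expect_lt(abs(n1 - n2) / n1, 0.01)
})

test_that("CFL violations and instabilities are caught", {
  sc <- homog_scenario(1e-5, 0.1)
  expect_error(solve_replication(sc, replication_grid(100, 0.5, 10, 1000)),
               "CFL")
})

test_that("an isolated molecule dominated by one origin has N_init ~ N_coal + 1", {
  # single narrow efficient zone on a linear molecule: nearly every cycle has
  # one replicating domain, whose forks exit at the ends without coalescing
  sc <- scenario(
    initiation_profile(list(initiation_zone(100, 10, 2e-4))),
    velocity_profile(0.04),
    boundary_condition("isolated"))
  g <- replication_grid(200, 0.5, 10, 20000)
  sol <- solve_replication(sc, g)
  expect_gt(sol$N_init, sol$N_coal)
  # on a linear molecule the two outermost forks always exit the ends, so
  # every cycle has exactly one more initiation than coalescence
  expect_equal(sol$N_init - sol$N_coal, 1, tolerance = 0.05)
  # cross-check against MC event counts on the same scenario
  set.seed(7)
  n_i <- n_c <- integer(300)
  for (k in 1:300) {
    cyc <- simulate_cycle(sc, L = 200, t_max = 20000, delta_x = 0.25)
    n_i[k] <- nrow(cyc$initiations)
    n_c[k] <- nrow(cyc$coalescences)
  }
  expect_true(all(n_i - n_c == 1L))
  se <- stats::sd(n_i) / sqrt(300)
  # allowance for the first-order source discretization (Richardson)
  sol2 <- solve_replication(sc, replication_grid(200, 0.25, 5, 20000))
  allow <- 2 * abs(sol$N_init - sol2$N_init)
  expect_lt(abs(sol$N_init - mean(n_i)), 3 * se + allow)
})

test_that("boundary fork density follows the semi-infinite closed form", {
  expect_equal(boundary_fork_density(0, 0.04, c(0, 100, 1e4)), c(0, 0, 0))
  expect_equal(boundary_fork_density(1e-3, 0.04, 0), 0)
  # peak of I t exp(-I v t^2 / 2) is at t* = 1/sqrt(I v), value I t* e^{-1/2};
  # the time integral of v * rho_b is 1: exactly one fork ever crosses
  I0 <- 1e-3; v <- 0.04
  t_star <- 1 / sqrt(I0 * v)
  tt <- seq(0, 2000, by = 0.25)
  bd <- boundary_fork_density(I0, v, tt)
  expect_equal(tt[which.max(bd)], t_star, tolerance = 1e-2)
  expect_equal(max(bd), I0 * t_star * exp(-0.5), tolerance = 1e-6)
  expect_equal(sum(bd) * 0.25 * v, 1, tolerance = 1e-3)
})
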