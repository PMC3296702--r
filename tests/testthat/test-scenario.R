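test_that("initiation profiles evaluate zones, background and gates", {
  # empty profile is identically zero
  empty <- initiation_profile()
  expect_equal(evaluate_initiation(empty, c(0, 100, 999), 0), c(0, 0, 0))
  expect_equal(evaluate_initiation(empty, 500, 1e5), 0)

  # the two-zone test system: late/early peak ratio is 10 once the late
  # zone's gate has opened, and the late zone is silent before 5000 s
  sc <- two_zone_scenario()
  I6000 <- evaluate_initiation(sc$initiation, c(200, 800), 6000)
  expect_equal(I6000[2] / I6000[1], 10, tolerance = 1e-12)
  expect_equal(evaluate_initiation(sc$initiation, 800, 4000), 0)
  expect_gt(evaluate_initiation(sc$initiation, 200, 4000), 0)

  # gaussian zone: sigma parametrization integrates to amp * sigma * sqrt(2pi)
  z <- initiation_zone(500, 30, 1e-4)
  p <- initiation_profile(list(z))
  x <- seq(0, 1000, by = 0.1)
  integ <- sum(evaluate_initiation(p, x, 0)) * 0.1
  expect_equal(integ, 1e-4 * 30 * sqrt(2 * pi), tolerance = 1e-4)

  # rounded box: flat top near center, logistic shoulders, gated zones add up
  rb <- initiation_zone(100, 50, 2e-4, shape = "rounded_box", edge_scale = 2)
  prb <- initiation_profile(list(rb), background = 1e-6)
  expect_equal(evaluate_initiation(prb, 100, 0), 2e-4 + 1e-6, tolerance = 1e-4)
  expect_lt(evaluate_initiation(prb, 125, 0), 0.6 * 2e-4)
  expect_gt(evaluate_initiation(prb, 75.01, 0), 0.4 * 2e-4)
})

test_that("velocity profiles are strictly positive and segment-aware", {
  v <- velocity_profile(0.04)
  expect_equal(evaluate_velocity(v, c(0, 500, 999), direction = "plus"),
               rep(0.04, 3))
  expect_equal(evaluate_velocity(v, 1, direction = "minus"), 0.04)

  vs <- velocity_profile(0.04, segments = data.frame(
    from = 100, to = 150, v_plus = 0.01, v_minus = 0.02))
  expect_equal(evaluate_velocity(vs, c(99, 100, 149, 150), direction = "plus"),
               c(0.04, 0.01, 0.01, 0.04))
  expect_equal(evaluate_velocity(vs, 120, direction = "minus"), 0.02)

  va <- velocity_profile(0.05, 0.03)
  expect_false(evaluate_velocity(va, 10, direction = "plus") ==
                 evaluate_velocity(va, 10, direction = "minus"))

  expect_error(velocity_profile(0), "positive")
  expect_error(velocity_profile(0.04, segments = data.frame(
    from = 0, to = 10, v_plus = -1, v_minus = 0.04)), "positive")
  expect_error(initiation_zone(100, 10, -1), "amplitude")
})

test_that("random valid scenarios satisfy the rate/speed sign invariants", {
  set.seed(42)
  for (rep in 1:20) {
    nz <- sample(0:3, 1)
    zones <- lapply(seq_len(nz), function(i)
      initiation_zone(runif(1, 0, 500), runif(1, 5, 60),
                      10^runif(1, -7, -3),
                      shape = sample(c("gaussian", "rounded_box"), 1),
                      t_on = runif(1, 0, 5000),
                      t_off = runif(1, 5000, 2e4)))
    sc <- scenario(initiation_profile(zones, background = 10^runif(1, -9, -5)),
                   velocity_profile(runif(1, 0.01, 0.1), runif(1, 0.01, 0.1)))
    x <- seq(0, 500, length.out = 101)
    for (t in c(0, 1000, 7000)) {
      expect_true(all(evaluate_initiation(sc$initiation, x, t) >= 0))
      expect_true(all(evaluate_velocity(sc$velocity, x, t, "plus") > 0))
      expect_true(all(evaluate_velocity(sc$velocity, x, t, "minus") > 0))
    }
    # gated zones contribute exactly zero outside their window
    for (z in zones) {
      solo <- initiation_profile(list(z))
      expect_identical(evaluate_initiation(solo, z$center, z$t_off + 1), 0)
      if (z$t_on > 0)
        expect_identical(evaluate_initiation(solo, z$center, z$t_on - 1), 0)
    }
  }
})

test_that("scenario configs round-trip through canonical YAML", {
  sc <- scenario(
    initiation_profile(list(
      initiation_zone(200, 25, 2e-5),
      initiation_zone(800, 25, 2e-4, shape = "rounded_box",
                      edge_scale = 3, t_on = 5000, t_off = Inf)),
      background = 1e-7),
    velocity_profile(0.04, 0.05,
                     segments = data.frame(from = 10, to = 20,
                                           v_plus = 0.01, v_minus = 0.01)),
    boundary_condition("injection", I_left = 1e-4, I_right = 2e-4,
                       v_out = 0.04),
    defect_model(d = 200, tau = Inf))
  txt <- save_scenario(sc)
  sc2 <- load_scenario(text = txt)
  # identical evaluation on a test lattice
  x <- seq(0, 1000, length.out = 37)
  for (t in c(0, 4000, 6000))
    expect_equal(evaluate_initiation(sc2$initiation, x, t),
                 evaluate_initiation(sc$initiation, x, t))
  expect_equal(evaluate_velocity(sc2$velocity, x, direction = "minus"),
               evaluate_velocity(sc$velocity, x, direction = "minus"))
  expect_equal(sc2$boundary, sc$boundary)
  expect_equal(sc2$defects, sc$defects)
  # save -> load -> save is byte-identical
  expect_identical(save_scenario(sc2), txt)
})

test_that("scenario configs reject schema violations with a path", {
  good <- save_scenario(two_zone_scenario())
  expect_s3_class(load_scenario(text = good), "rk_scenario")
  expect_error(load_scenario(text = sub("amplitude: 2e-05", "amplitude: -1",
                                        good)),
               "amplitude")
  expect_error(load_scenario(text = sub("background", "bckground", good)),
               "bckground|unknown|missing")
  expect_error(load_scenario(text = paste0(good, "unknown_top: 1\n")),
               "unknown")
  expect_error(load_scenario(text = sub("v_plus: 0.04", "v_plus: -0.04",
                                        good)),
               "speed")
})

test_that("grids validate their invariants", {
  g <- replication_grid(1000, 0.5, 10, 20000)
  expect_equal(g$n_x, 2000L)
  expect_equal(length(g$t), g$n_t)
  expect_equal(g$x[1], 0.25)
  expect_error(replication_grid(1000, 0.3, 10, 20000), "integer")
  expect_error(replication_grid(1000, 0.5, 10, 20005), "integer")
  expect_error(replication_grid(-1, 0.5, 10, 100), "positive")
  expect_error(replication_grid(100, 0.5, -10, 100), "positive")
})
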