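test_that("covariance estimation behaves on controlled replicates", {
  # identical replicates: zero covariance
  R <- matrix(rep(c(1, 2, 3), 10), 10, 3, byrow = TRUE)
  expect_true(all(estimate_covariance(R) == 0))

  # independent unit-variance replicates: C ~ identity
  set.seed(61)
  Z <- matrix(rnorm(1000 * 6), 1000, 6)
  C <- estimate_covariance(Z)
  expect_lt(max(abs(C - diag(6))), 0.2)
})

test_that("the parametrized covariance recovers a known decay length", {
  set.seed(62)
  x <- seq(5, 300, by = 10)
  n <- length(x)
  lam_true <- 30
  C_true <- exp(-abs(outer(x, x, "-")) / lam_true)
  Lt <- t(chol(C_true))
  reps <- t(apply(matrix(rnorm(1000 * n), 1000, n), 1,
                  function(z) as.numeric(Lt %*% z)))
  cm <- parametrize_covariance(estimate_covariance(reps),
                               list(list(idx = 1:n, x = x)))
  expect_lt(abs(cm$lambda[1] - lam_true) / lam_true, 0.2)
  # positive definiteness certificate: factorization succeeded and
  # reconstructs C_par
  expect_lt(max(abs(cm$L_chol %*% t(cm$L_chol) - cm$C_par)), 1e-8)
})

test_that("degenerate empirical covariances are handled", {
  # diagonal empirical C: near-diagonal surrogate
  set.seed(63)
  Z <- matrix(rnorm(2000 * 5), 2000, 5)
  cm <- parametrize_covariance(estimate_covariance(Z),
                               list(list(idx = 1:5, x = (1:5) * 50)))
  off <- cm$C_par[upper.tri(cm$C_par)]
  expect_lt(max(abs(off)), 0.1)
  # rank-deficient empirical C (fewer replicates than dimension) still
  # yields a factorizable surrogate
  Z2 <- matrix(rnorm(4 * 10), 4, 10)
  cm2 <- parametrize_covariance(estimate_covariance(Z2),
                                list(list(idx = 1:10, x = (1:10) * 5)))
  expect_s3_class(cm2, "rk_covmodel")
})

test_that("decorrelation satisfies its identities", {
  x <- (1:8) * 10
  cmI <- parametrize_covariance(diag(8), list(list(idx = 1:8, x = x)))
  v <- rnorm(8)
  expect_equal(decorrelate(cmI, v), v, tolerance = 1e-9)

  set.seed(64)
  lam <- 25
  C_true <- 2 * exp(-abs(outer(x, x, "-")) / lam)
  Lt <- t(chol(C_true))
  reps <- t(apply(matrix(rnorm(1000 * 8), 1000, 8), 1,
                  function(z) as.numeric(Lt %*% z)))
  cm <- parametrize_covariance(estimate_covariance(reps),
                               list(list(idx = 1:8, x = x)))
  D <- t(apply(reps, 1, function(r) decorrelate(cm, r)))
  CD <- estimate_covariance(D)
  expect_lt(max(abs(diag(CD) - 1)), 0.25)
  expect_lt(max(abs(CD[upper.tri(CD)])), 0.2)
  # triangular solve inverts exactly
  vec <- rnorm(8)
  expect_equal(as.numeric(cm$L_chol %*% decorrelate(cm, vec)), vec,
               tolerance = 1e-10)
  expect_error(decorrelate(cm, rnorm(5)), "dimension")
})

test_that("scenario families build the right scenarios", {
  fam <- two_zone_family(L = 500)
  th <- c(150, 40, 2e-5, 350, 40, 4e-5, 1e-7, 5e-4, 6e-4, 0.04)
  scs <- scenario_from_params(th, fam)
  expect_named(scs, "normal")
  sc <- scs$normal
  x <- seq(0, 500, by = 1)
  I <- evaluate_initiation(sc$initiation, x, 0)
  expect_equal(x[which.max(I)], 150, tolerance = 2)
  expect_equal(sc$boundary$I_left, 5e-4)
  expect_equal(sc$boundary$I_right, 6e-4)

  # zero zone amplitudes: background-only profile
  th0 <- th; th0[c(3, 6)] <- 0
  sc0 <- scenario_from_params(th0, fam)$normal
  expect_equal(evaluate_initiation(sc0$initiation, x, 0), rep(1e-7, length(x)))

  # paired family: deleted allele loses the second zone, domain shrinks
  famp <- two_zone_family(L = 500, deletion = c(330, 65))
  thp <- c(th, 0.03)
  scsp <- scenario_from_params(thp, famp)
  expect_named(scsp, c("normal", "deleted"))
  expect_equal(length(scsp$deleted$initiation$zones), 1L)
  expect_equal(famp$condition_L[["deleted"]], 435)
  expect_equal(scsp$deleted$velocity$v_plus, 0.03)
  # a zone right of the deletion shifts left by its length
  th_shift <- thp; th_shift[1] <- 450
  scd <- scenario_from_params(th_shift, famp)$deleted
  expect_equal(scd$initiation$zones[[1]]$center, 450 - 65)

  expect_error(scenario_from_params(th[-1], fam), "length")
  thbad <- th; thbad[10] <- 5
  expect_error(scenario_from_params(thbad, fam), "bounds")
})

test_that("noise-free model output is a fixed point of the objective", {
  # the decorrelated least-squares objective built on m(theta*) as the data
  # is zero at theta* and positive elsewhere, so a fit initialized at the
  # truth stays there
  fam <- two_zone_family(L = 300)
  th <- c(90, 30, 3e-5, 210, 30, 3e-5, 1e-7, 5e-4, 5e-4, 0.04)
  sc <- scenario_from_params(th, fam)$normal
  g <- repkin:::fit_grid(300, 0.1, dx = 2)
  frag <- c(0, 300)
  m_star <- repkin:::predict_vector(solve_replication(sc, g),
                                    list(frag), 0, 300, 10, 50)
  blocks <- repkin:::vector_blocks(list(frag), 10, 50)
  cm <- parametrize_covariance(diag(1e-4, length(m_star)), blocks)
  obj <- function(theta) {
    if (any(theta < fam$lower) || any(theta > fam$upper)) return(1e8)
    s <- scenario_from_params(theta, fam)$normal
    m <- repkin:::predict_vector(solve_replication(s, g),
                                 list(frag), 0, 300, 10, 50)
    sum((decorrelate(cm, m_star) - decorrelate(cm, m))^2)
  }
  expect_equal(obj(th), 0)
  th_off <- th; th_off[1] <- 120; th_off[10] <- 0.05
  expect_gt(obj(th_off), obj(th))
  op <- stats::optim(th, obj, method = "Nelder-Mead",
                     control = list(maxit = 40))
  expect_lt(op$value, 1e-6)
  expect_equal(op$par[1], th[1], tolerance = 1)
  expect_equal(op$par[10], th[10], tolerance = 0.001)
})

test_that("fit reports are reproducible given data, seed and config", {
  fam <- two_zone_family(L = 300)
  th <- c(90, 30, 3e-5, 210, 30, 3e-5, 1e-7, 5e-4, 5e-4, 0.04)
  sc <- scenario_from_params(th, fam)$normal
  set.seed(67)
  ms <- sample_smard(sc, L = 300, n_keep = 25, fragment = c(0, 300),
                     delta_x = 0.5)
  run <- function() fit_smard(list(ms), list(c(0, 300)), fam, theta0 = th,
                              n_sim = 8, max_outer = 1, seed = 68,
                              optim_control = list(maxit = 25))
  f1 <- run()
  f2 <- run()
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$objective, f2$objective)
  expect_s3_class(summary(f1), "summary.rk_fit")
  expect_equal(unname(coef(f1)), unname(f1$theta))
  expect_equal(length(residuals(f1)), length(f1$y))
})
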