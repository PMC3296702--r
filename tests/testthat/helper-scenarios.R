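# Shared fixtures and comparison helpers for the test suite.

# homogeneous scenario: constant initiation rate, constant velocity, PBC
homog_scenario <- function(I0 = 2e-5, v = 0.04) {
  scenario(initiation_profile(background = I0), velocity_profile(v))
}

# average a field matrix (cells x times) into coarse x-bins at chosen times
bin_rows <- function(M, cells_per_bin, t_idx) {
  n_bin <- nrow(M) / cells_per_bin
  grp <- rep(seq_len(n_bin), each = cells_per_bin)
  t(vapply(split(seq_len(nrow(M)), grp),
           function(ii) colMeans(M[ii, t_idx, drop = FALSE]),
           numeric(length(t_idx))))
}

# time-average a field matrix over MC comparison time bins
bin_cols_time <- function(sol, M, bin_t, t_max) {
  edges <- seq(0, t_max, by = bin_t)
  tb <- findInterval(sol$t, edges, left.open = TRUE, rightmost.closed = TRUE)
  vapply(seq_len(length(edges) - 1L), function(k) {
    sel <- which(tb == k)
    if (!length(sel)) return(rep(NA_real_, nrow(M)))
    rowMeans(M[, sel, drop = FALSE])
  }, numeric(nrow(M)))
}

# fraction of bins where |a - b| < 3*se + floor (+ optional allowance)
frac_within <- function(a, b, se, floor = 0, allow = 0) {
  mean(abs(a - b) < 3 * se + floor + allow, na.rm = TRUE)
}

# per-bin tolerance for comparing an MC probability field (n cycles) with a
# model value m: 3 x the larger of the empirical SE and the model-implied
# binomial SE (which handles saturated bins where the empirical SE is 0),
# plus a one-count quantum and any discretization allowance
tol_prob <- function(se_emp, m, n, quantum = 0, allow = 0) {
  p <- pmin(pmax(m, 0), 1)
  3 * pmax(se_emp, sqrt(p * (1 - p) / n)) + quantum + allow
}

# ditto for a density field with per-site count quantum q (counting SE)
tol_dens <- function(se_emp, m, n, q, allow = 0) {
  3 * pmax(se_emp, sqrt(pmax(m, 0) * q / n)) + q / n + allow
}
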