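test_that("BIC order selection is consistent on simulated processes", {
  ## white noise carries no lag structure: the smallest order wins
  p_white <- vapply(1:100, function(i) {
    set.seed(3000 + i)
    as.integer(select_order_bic(matrix(rnorm(400), 200, 2), p_max = 5))
  }, integer(1))
  expect_gte(mean(p_white == 1L), 0.8)
  ## a strong VAR(2) at 1000 samples is identified
  A <- array(0, dim = c(2, 2, 2))
  A[, , 1] <- matrix(c(0.4, 0.3, 0.2, 0.4), 2, 2)
  A[, , 2] <- matrix(c(-0.5, 0, 0.2, -0.5), 2, 2)
  p_var2 <- vapply(1:100, function(i) {
    x <- simulate_var_local(A, 1000, seed = 4000 + i)
    as.integer(select_order_bic(sweep(x, 2, colMeans(x)), p_max = 6))
  }, integer(1))
  expect_gte(mean(p_var2 == 2L), 0.9)
  expect_equal(as.integer(select_order_bic(matrix(rnorm(100), 50, 2), p_max = 1)), 1L)
})

test_that("least-squares VAR fits recover generating coefficients", {
  A <- array(c(0.5, 0.25, -0.2, 0.6), dim = c(2, 2, 1))
  x <- simulate_var_local(A, 5000, seed = 11)
  x <- sweep(x, 2, colMeans(x))
  m <- fit_var(x, 1)
  expect_lt(max(abs(m$A[, , 1] - A[, , 1])), 0.05)
  expect_lt(max(abs(m$Sigma - diag(2))), 0.1)
  ## determinism and invariants
  m2 <- fit_var(x, 1)
  expect_identical(m$A, m2$A)
  expect_true(isSymmetric(m$Sigma, tol = 1e-12))
  expect_true(all(eigen(m$Sigma, only.values = TRUE)$values > -1e-12))
  expect_lt(m$spectral_radius, 1)
  ## white noise: coefficients near zero, covariance near identity
  set.seed(12)
  wn <- matrix(rnorm(10000), 5000, 2)
  mw <- fit_var(sweep(wn, 2, colMeans(wn)), 1)
  expect_lt(max(abs(mw$A)), 0.1)
  expect_lt(max(abs(mw$Sigma - diag(2))), 0.1)
  ## a constant column makes the regression singular: degenerate window
  bad <- cbind(rnorm(100), rep(1, 100))
  expect_error(fit_var(sweep(bad, 2, colMeans(bad)), 2), "singular|degenerate")
})

test_that("the transfer function matches its closed forms", {
  ## empty coefficient sum: H is the identity everywhere
  null_model <- structure(list(p = 1L, A = array(0, c(2, 2, 1)),
                               Sigma = diag(2)), class = "var_model")
  tf <- transfer_function(null_model, fs = 500)
  for (k in c(1L, 64L, 128L)) {
    expect_equal(tf$H[, , k], diag(2) + 0i, tolerance = 1e-12)
  }
  ## scalar AR(1): |H|^2 = 1 / (1 - 2 a cos w + a^2)
  a <- 0.5
  m1 <- structure(list(p = 1L, A = array(a, c(1, 1, 1)),
                       Sigma = matrix(1)), class = "var_model")
  fs <- 500
  tf1 <- transfer_function(m1, fs = fs)
  w <- 2 * pi * tf1$freq_hz / fs
  expect_equal(as.numeric(Mod(tf1$H[1, 1, ])^2),
               1 / (1 - 2 * a * cos(w) + a^2), tolerance = 1e-10)
  ## conjugate symmetry: H at mirrored frequencies
  tf_lo <- transfer_function(m1, fs = fs, freq_hz = 100)
  tf_hi <- transfer_function(m1, fs = fs, freq_hz = 400)  # 2 pi - w
  expect_equal(Conj(tf_lo$H[1, 1, 1]), tf_hi$H[1, 1, 1], tolerance = 1e-12)
})

test_that("the spectral density matrix obeys its factorization", {
  null_model <- structure(list(p = 1L, A = array(0, c(2, 2, 1)),
                               Sigma = diag(2)), class = "var_model")
  sm <- cpsd(null_model, fs = 500)
  for (k in c(1L, 100L)) expect_equal(sm$S[, , k], diag(2) + 0i, tolerance = 1e-12)
  ## AR(1) with a = 0.9 concentrates power at the lowest frequencies
  m9 <- structure(list(p = 1L, A = array(0.9, c(1, 1, 1)),
                       Sigma = matrix(1)), class = "var_model")
  s9 <- cpsd(m9, fs = 500)
  expect_equal(which.max(Re(s9$S[1, 1, ])), 1L)
  ## the mean of S over the grid approximates the process variance
  A <- array(c(0.5, 0.2, 0.1, 0.4), dim = c(2, 2, 1))
  x <- simulate_var_local(A, 200000, seed = 21)
  m <- fit_var(sweep(x, 2, colMeans(x)), 1)
  sm2 <- cpsd(m, fs = 2 * pi, freq_hz = default_grid(2 * pi, 2048))
  int_var <- rowMeans(Re(apply(sm2$S, 3, diag)))
  expect_lt(max(abs(int_var - apply(x, 2, var)) / apply(x, 2, var)), 0.05)
})

test_that("spectral causality vanishes without cross-terms and matches the time-domain oracle", {
  ## diagonal coefficients and covariance: exactly zero causality
  md <- structure(list(p = 1L, A = array(c(0.5, 0, 0, 0.7), c(2, 2, 1)),
                       Sigma = diag(2)), class = "var_model")
  sg <- spectral_gc_pair(md, fs = 500)
  expect_true(all(sg$f == 0))
  ## canonical coupled pair: full-grid mean equals the restricted/full
  ## log-variance ratio; the reverse direction is at the noise floor
  x <- simulate_var_local(coupled_var1(), 5000, seed = 31)
  x <- sweep(x, 2, colMeans(x))
  m <- fit_var(x, 2)
  sg2 <- spectral_gc_pair(m, fs = 2 * pi, freq_hz = default_grid(2 * pi, 512))
  f_yx <- mean(sg2$f[, 1])               # column 2 -> column 1
  td <- time_domain_gc(x, source = 2, target = 1, p = 2, p_restricted = 6)
  expect_lt(abs(f_yx - td) / td, 0.05)
  expect_lt(mean(sg2$f[, 2]), 0.01)
  ## swapping the pair labels swaps the directional results exactly
  m_sw <- fit_var(x[, 2:1], 2)
  sg_sw <- spectral_gc_pair(m_sw, fs = 2 * pi, freq_hz = default_grid(2 * pi, 512))
  expect_equal(unname(sg_sw$f[, 2]), unname(sg2$f[, 1]), tolerance = 1e-10)
  expect_equal(unname(sg_sw$f[, 1]), unname(sg2$f[, 2]), tolerance = 1e-10)
})

test_that("band averages are means over in-band grid frequencies", {
  sg <- structure(list(freq_hz = default_grid(500, 128),
                       f = matrix(c(rep(0.3, 128), rep(0, 128)), 128, 2)),
                  class = "spectral_gc")
  expect_equal(unname(band_average(sg, "theta")), c(0.3, 0))
  expect_equal(unname(band_average(sg, c(30, 60))), c(0.3, 0))
  expect_error(band_average(sg, c(0.1, 0.5)), "no points")
  ## a theta-tuned driven pair concentrates causality in the theta band
  d <- pair_design2()
  sch <- build_tv_var(d, coupling_scenario(
    coupling("F1", "P1", "theta", 0, 9000, 0.4)))
  tr <- simulate_trial(sch, seed = 41)
  seg <- sweep(t(tr[, 1001:3000]), 2, colMeans(t(tr[, 1001:3000])))
  m <- fit_var(seg, 3)
  sgc <- spectral_gc_pair(m, fs = 500)
  expect_gt(band_average(sgc, "theta")[2], band_average(sgc, "gamma")[2])
})

test_that("time-domain causality is calibrated and degenerates gracefully", {
  set.seed(51)
  wn <- matrix(rnorm(10000), 5000, 2)
  wn <- sweep(wn, 2, colMeans(wn))
  expect_lt(abs(time_domain_gc(wn, 2, 1, p = 2)), 0.02)
  ## a constant-zero source contributes nothing
  x <- cbind(rnorm(500), rep(0, 500))
  expect_equal(time_domain_gc(x, source = 2, target = 1, p = 2), 0)
})

test_that("causality estimates are nonnegative, scale-invariant and conjugate-symmetric", {
  set.seed(61)
  for (i in 1:10) {
    A <- gcnet:::sample_stable_var2()
    x <- simulate_var_local(A, 600)
    x <- sweep(x, 2, colMeans(x))
    m <- fit_var(x, 2)
    sg <- spectral_gc_pair(m, fs = 500)
    expect_true(all(sg$f >= 0))
    ## scale invariance: rescaling either series leaves causality unchanged
    xs <- x %*% diag(c(1000, 0.01))
    ms <- fit_var(xs, 2)
    sgs <- spectral_gc_pair(ms, fs = 500)
    expect_lt(max(abs(sgs$f - sg$f)), 1e-8)
    ## f(w) = f(2 pi - w)
    core_lo <- gcnet:::spectral_gc_core(m$A, m$Sigma, 0.3)
    core_hi <- gcnet:::spectral_gc_core(m$A, m$Sigma, 2 * pi - 0.3)
    expect_equal(core_lo$f21, core_hi$f21, tolerance = 1e-12)
    expect_equal(core_lo$f12, core_hi$f12, tolerance = 1e-12)
  }
})

test_that("the null distribution of short-window causality is stable across batches", {
  ## this percentile anchors the binarization null: its spread across
  ## seeded batches must be modest
  fhz <- default_grid(500, 64)
  omega <- 2 * pi * fhz / 500
  th <- fhz >= 4 & fhz < 8
  q95 <- vapply(1:10, function(b) {
    set.seed(7000 + b)
    x <- matrix(rnorm(2 * 500 * 50), 500 * 50, 2)
    starts <- as.integer(seq(1, 500 * 50 - 49, by = 50))
    res <- gcnet:::gc_pair_windows_cpp(x, starts, 50L, 3L, omega, 0L)
    vals <- rowMeans(res$f21[, th, drop = FALSE])
    stats::quantile(vals, 0.95, na.rm = TRUE)
  }, numeric(1))
  expect_lt(stats::sd(q95) / mean(q95), 0.2)
})

test_that("conditional time-domain causality discounts mediated influence", {
  ## chain 1 -> 2 -> 3: the pairwise 1 -> 3 value is positive, the
  ## conditional value (given node 2) is near zero
  A <- array(0, dim = c(3, 3, 1))
  diag(A[, , 1]) <- 0.4
  A[2, 1, 1] <- 0.5
  A[3, 2, 1] <- 0.5
  set.seed(71)
  x <- matrix(0, 6000, 3)
  e <- matrix(rnorm(18000), 6000, 3)
  for (t in 2:6000) x[t, ] <- A[, , 1] %*% x[t - 1, ] + e[t, ]
  x <- sweep(x[1001:6000, ], 2, colMeans(x[1001:6000, ]))
  pairwise <- time_domain_gc(x, source = 1, target = 3, p = 2)
  conditional <- time_domain_gc(x, source = 1, target = 3, p = 2, conditional = TRUE)
  expect_gt(pairwise, 0.05)
  expect_lt(conditional, 0.01)
})
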