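test_that("delay embedding lays out lagged coordinates with M = N-(m-1)tau", {
  expect_equal(delay_embed(1:5, m = 2, tau = 1),
               matrix(c(1, 2, 3, 4, 2, 3, 4, 5), ncol = 2))
  expect_equal(nrow(delay_embed(rnorm(1024), m = 3, tau = 5)), 1014L)
  u <- rnorm(20)
  expect_equal(delay_embed(u, m = 1, tau = 7), matrix(u, ncol = 1))
  # component k of vector i is u(i + k*tau)
  y <- delay_embed(u, m = 3, tau = 4)
  expect_equal(y[2, 3], u[2 + 2 * 4])
  expect_error(delay_embed(1:5, m = 3, tau = 3), "too short")
})

test_that("mutual-information lag lands near the quarter period of a
          sinusoid and flags white noise", {
  for (s in 1:5) {
    set.seed(s)
    u <- sin(2 * pi * (1:1024) / 100) + rnorm(1024, 0, 0.1)
    lag <- select_lag_mi(u, max_lag = 50)
    expect_true(abs(as.integer(lag) - 25) <= 2)
    expect_false(attr(lag, "fallback"))
  }

  set.seed(6)
  lag_noise <- select_lag_mi(rnorm(1024), max_lag = 50)
  expect_true(attr(lag_noise, "fallback"))
  # flat curve: everything near the independence bias
  expect_lt(max(attr(lag_noise, "mi")), 0.25)

  # a lagged near-copy creates dependence detectable below that lag
  set.seed(7)
  base <- as.numeric(stats::filter(rnorm(1100), rep(1 / 6, 6),
                                   sides = 1))[-(1:10)]
  u <- base[1:1000] + 0.05 * rnorm(1000)
  lag <- select_lag_mi(u, max_lag = 40)
  expect_lte(as.integer(lag), 40L)

  expect_error(select_lag_mi(rep(1, 100), max_lag = 10), "Constant")
})

test_that("false-nearest-neighbour dimension: plane for a sine, small for
          the logistic map, flagged for noise", {
  sine <- sin(2 * pi * (1:1024) / 100)
  m_sine <- select_dim_fnn(sine, tau = 25)
  expect_equal(as.integer(m_sine), 2L)

  x <- logistic_series(2000)
  m_log <- select_dim_fnn(x, tau = 1)
  expect_lte(as.integer(m_log), 3L)

  set.seed(71)
  m_noise <- select_dim_fnn(rnorm(1024), tau = 1, max_m = 6)
  expect_true(attr(m_noise, "fallback") || as.integer(m_noise) == 6L)

  # fractions agree with the brute-force transcription on a tiny series
  set.seed(72)
  u <- rnorm(120)
  f <- attr(select_dim_fnn(u, tau = 2, max_m = 3), "fnn_fraction")
  for (m in 1:3) {
    expect_equal(f[m], fnn_fraction_naive(u, m, 2), tolerance = 1e-12)
  }
})

test_that("largest Lyapunov exponent recovers ln 2 on the logistic map and
          is non-positive for a sinusoid", {
  x <- logistic_series(2000)
  lam <- largest_lyapunov(x, m = 2, tau = 1, follow_steps = 5, dt = 1,
                          mode = "rosenstein_slope")
  expect_lt(abs(lam - log(2)) / log(2), 0.15)

  s <- sin(2 * pi * (1:2000) / 100)
  lam_s <- largest_lyapunov(s, m = 2, tau = 25, follow_steps = 5, dt = 1,
                            mode = "rosenstein_slope")
  expect_lte(lam_s, 0.05)
})

test_that("the two LLE modes agree in sign across dynamical regimes and
          scale inversely with dt", {
  x <- logistic_series(2000)
  s <- sin(2 * pi * (1:2000) / 100)
  set.seed(81)
  nz <- rnorm(2000)
  # regime classification (divergent / neutral / convergent, dead zone at
  # 0.05 per step) agrees between the two modes on all three signals
  classify <- function(lam) sign(lam) * (abs(lam) > 0.05)
  for (u in list(x, s, nz)) {
    tau <- if (identical(u, s)) 25L else 1L
    a <- largest_lyapunov(u, m = 2, tau = tau, follow_steps = 5, dt = 1,
                          mode = "horizon_average")
    b <- largest_lyapunov(u, m = 2, tau = tau, follow_steps = 5, dt = 1,
                          mode = "rosenstein_slope")
    expect_equal(classify(a), classify(b))
  }

  lam1 <- largest_lyapunov(x, m = 2, tau = 1, follow_steps = 5, dt = 1,
                           mode = "rosenstein_slope")
  lam2 <- largest_lyapunov(x, m = 2, tau = 1, follow_steps = 5, dt = 2,
                           mode = "rosenstein_slope")
  expect_equal(lam1 / 2, lam2, tolerance = 1e-12)
})

test_that("the estimator is direction-sensitive on the logistic map", {
  x <- logistic_series(2000)
  fwd <- largest_lyapunov(x, m = 2, tau = 1, follow_steps = 5, dt = 1,
                          mode = "rosenstein_slope")
  rev_ <- largest_lyapunov(rev(x), m = 2, tau = 1, follow_steps = 5, dt = 1,
                           mode = "rosenstein_slope")
  expect_gt(abs(fwd - rev_), 1e-3)
})

test_that("nearby starts in the synthetic latency window diverge
          (positive exponent)", {
  set.seed(91)
  cfg <- synth_config()
  s <- generate_series(cfg, seed = 91)
  lat <- s$velocity[1:128]
  lam <- largest_lyapunov(lat, m = 2, tau = 1, follow_steps = 10, dt = 0.001)
  expect_gt(lam, 0)
})
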