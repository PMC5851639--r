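test_that("infinite-domain density matches its closed form and an
           independent survival-derivative oracle", {
  expect_equal(fpt_density_infinite(1, 1), exp(-0.25) / sqrt(4 * pi),
               tolerance = 1e-12)
  expect_equal(fpt_density_infinite(1, 1), 0.2197, tolerance = 1e-3)
  # oracle: survival of unit-diffusion BM is 2*Phi(a/sqrt(2t)) - 1;
  # density = -dS/dt by central differences
  a <- 1.7
  for (t in c(0.5, 2, 10)) {
    h <- 1e-5 * t
    surv <- function(tt) 2 * pnorm(a / sqrt(2 * tt)) - 1
    oracle <- -(surv(t + h) - surv(t - h)) / (2 * h)
    expect_equal(fpt_density_infinite(a, t), oracle, tolerance = 1e-6)
  }
  expect_error(fpt_density_infinite(0, 1), class = "gridrt_invalid_parameter")
  expect_error(fpt_density_infinite(1, -1), class = "gridrt_invalid_parameter")
})

test_that("densities normalize to certain absorption", {
  z <- integrate(function(t) fpt_density_infinite(1, t), 0, Inf,
                 rel.tol = 1e-9)
  expect_lt(abs(z$value - 1), 1e-6)
  zb <- integrate(function(t) fpt_density_bounded(0.3, 1, -1, t), 0, Inf,
                  rel.tol = 1e-9)
  expect_lt(abs(zb$value - 1), 1e-6)
})

test_that("far reflecting boundary reduces to the infinite domain", {
  # |xR - x0| = 100 |xT - x0|
  t <- c(0.05, 0.2, 1, 5)
  far <- fpt_density_bounded(0, 1, -100, t)
  inf <- fpt_density_infinite(1, t)
  expect_lt(max(abs(far / inf - 1)), 1e-6)
})

test_that("series and image forms agree at the switch point", {
  L <- 2
  ts <- gridrt:::bounded_switch_time(L) * c(0.5, 0.9, 1.1, 2)
  ser <- gridrt:::bounded_series(L, 1.3, ts)
  img <- gridrt:::bounded_images(L, 1.3, ts)
  expect_lt(max(abs(ser - img)), 1e-8)
})

test_that("bounded-domain survival has an exponential tail", {
  # slope of log-survival must be constant (rate (pi/2L)^2) in the tail
  t1 <- seq(3, 9.5, length.out = 30)
  t2 <- seq(9.5, 30, length.out = 30)
  s1 <- tail_log_slope(t1, fpt_survival_bounded(0.3, 1, -1, t1), "semilog")
  s2 <- tail_log_slope(t2, fpt_survival_bounded(0.3, 1, -1, t2), "semilog")
  expect_lt(abs(s1$slope / s2$slope - 1), 0.01)
  expect_equal(s2$slope, -(pi / 4)^2, tolerance = 1e-3)
})

test_that("Levy-Smirnov tails: density slope -3/2, survival slope -1/2", {
  t <- exp(seq(log(100), log(10000), length.out = 50))
  sl <- tail_log_slope(t, fpt_density_infinite(1, t), "loglog")
  expect_lt(abs(sl$slope - (-1.5)), 0.01)
  tt <- exp(seq(log(1e4), log(1e6), length.out = 50))
  surv <- 2 * pnorm(1 / sqrt(2 * tt)) - 1
  ss <- tail_log_slope(tt, surv, "loglog")
  expect_lt(abs(ss$slope - (-0.5)), 0.01)
})

test_that("tail_log_slope recovers an exact exponential rate", {
  tau <- 3.7
  t <- seq(2, 40, length.out = 25)
  fit <- tail_log_slope(t, exp(-t / tau), "semilog")
  expect_equal(fit$slope, -1 / tau, tolerance = 1e-10)
  expect_error(tail_log_slope(t[1:5], exp(-t[1:5])),
               class = "gridrt_invalid_window")
})

test_that("exact_fpt_markov: degenerate and hand-computable chains", {
  p1 <- exact_fpt_markov(build_grid(1, 0, 1))
  expect_equal(p1, 1, ignore_attr = TRUE)
  # corridor: 3-state chain built by hand
  grid <- corridor_grid()
  pmf <- exact_fpt_markov(grid)
  Tm <- matrix(c(3, 1, 0,   # from origin: 3 blocked self-loops, right
                 1, 2, 1,   # from (1,0)
                 0, 1, 2),  # from (2,0): up/down blocked, left open, exit right
               3, 3, byrow = TRUE) / 4
  a <- c(0, 0, 1 / 4)
  p <- c(1, 0, 0)
  hand <- numeric(length(pmf))
  for (k in seq_along(hand)) {
    hand[k] <- sum(p * a)
    p <- as.numeric(p %*% Tm)
  }
  expect_equal(as.numeric(pmf), hand, tolerance = 1e-12)
})

test_that("exact_fpt_markov agrees with brute-force path enumeration", {
  for (s in c(1, 7)) {
    grid <- sample_connected_grid(obstacles_params(2, 0.4, 90), seed = s)
    pmf <- exact_fpt_markov(grid)
    enum <- oracle_enum_pmf(grid, 6)
    expect_equal(as.numeric(pmf[1:6]), enum, tolerance = 1e-12)
  }
})

test_that("markov pmf is a proper distribution starting at ceil(R)", {
  for (s in 1:5) {
    grid <- sample_connected_grid(obstacles_params(3, 0.5, 90), seed = 60 + s)
    pmf <- exact_fpt_markov(grid)
    expect_lt(abs(sum(pmf) - 1), 1e-9)
    expect_gte(which(pmf > 0)[1], 3L)
    # mean of the pmf agrees with the exit-time linear system
    expect_equal(sum(seq_along(pmf) * pmf), exact_mean_exit_steps(grid),
                 tolerance = 1e-6)
  }
  expect_error(exact_fpt_markov(ring_grid()),
               class = "gridrt_connectivity_error")
})
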