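test_that("acceptance cost is the normalized angular cost", {
  expect_equal(acceptance_cost(c(0, 3), c(0, 1)), 0)
  expect_equal(acceptance_cost(c(0, 3), c(0, -1)), 1)
  expect_equal(acceptance_cost(c(0, 3), c(1, 0)), 0.5)
  expect_equal(acceptance_cost(c(2, 2), c(1, 0)), (1 - 1 / sqrt(2)) / 2)
  expect_true(is.na(acceptance_cost(c(0, 0), c(1, 0))))  # origin: caller accepts
  expect_error(acceptance_cost(c(0, 3), c(1, 1)),
               class = "gridrt_invalid_parameter")
})

test_that("R = 1 walks absorb in exactly one step for both models", {
  for (s in 1:20) {
    expect_identical(batch_fpt(obstacles_params(1, 0, 50), 5, s)$steps,
                     rep(1L, 5))
    expect_identical(batch_fpt(ddm_params(1, 0.01, 50), 5, s)$steps,
                     rep(1L, 5))
  }
})

test_that("first-passage times never undercut the radius, any parameters", {
  set.seed(4)
  for (k in 1:25) {
    radius <- sample(2:8, 1)
    if (k %% 2 == 0) {
      par <- obstacles_params(radius, runif(1, 0, 0.6), runif(1, 10, 150))
    } else {
      par <- ddm_params(radius, runif(1, 0.001, 0.25), runif(1, 10, 150))
    }
    s <- batch_fpt(par, 1000, seed = k)
    expect_gte(min(s$steps), radius)
    expect_true(all(s$rt_ms > 0))
  }
})

test_that("batches are reproducible and seed-sensitive", {
  par <- obstacles_params(4, 0.45, 90)
  a <- batch_fpt(par, 500, seed = 11)
  b <- batch_fpt(par, 500, seed = 11)
  expect_identical(a$steps, b$steps)
  expect_false(identical(a$steps, batch_fpt(par, 500, seed = 12)$steps))
  d1 <- batch_fpt(ddm_params(6, 0.1, 60), 500, seed = 11)
  d2 <- batch_fpt(ddm_params(6, 0.1, 60), 500, seed = 11)
  expect_identical(d1$steps, d2$steps)
})

test_that("quenched simulation matches the exact Markov-chain pmf", {
  par <- obstacles_params(3, 0.45, 90)
  grid <- sample_connected_grid(par, seed = 21)
  pmf <- exact_fpt_markov(grid)
  sim <- batch_fpt(par, 30000, seed = 5, grid = grid)
  expect_lt(tv_sample_pmf(sim$steps, pmf), 0.02)
})

test_that("obstacle-free mean exit time matches the discrete linear system", {
  for (radius in c(3, 5)) {
    exact <- exact_mean_exit_steps(build_grid(radius, 0, 1))
    sim <- batch_fpt(obstacles_params(radius, 0, 90), 30000, seed = radius)
    se <- sd(sim$steps) / sqrt(length(sim$steps))
    expect_lt(abs(mean(sim$steps) - exact), 2 * se)
  }
})

test_that("the epsilon -> infinity DDM limit recovers the unbiased walk", {
  n <- 50000
  ddm <- batch_fpt(ddm_params(4, 1e6, 90), n, seed = 31)
  free <- batch_fpt(obstacles_params(4, 0, 90), n, seed = 32)
  ks <- ks_two_sample(ddm$steps, free$steps)
  expect_gt(ks$p_value, 0.01)
})

test_that("a strong outward bias shortens passage at moderate epsilon", {
  fast <- batch_fpt(ddm_params(8, 0.1, 60), 20000, seed = 41)
  slow <- batch_fpt(ddm_params(8, 1000, 60), 20000, seed = 42)
  se <- sqrt(sd(fast$steps)^2 / 20000 + sd(slow$steps)^2 / 20000)
  expect_lt(mean(fast$steps) + 2 * se, mean(slow$steps))
})

test_that("step cap raises a runaway error; absorb cap censors quietly", {
  par <- obstacles_params(8, 0.5, 90)
  expect_error(batch_fpt(par, 50, seed = 1, step_cap = 10),
               class = "gridrt_runaway_error")
  s <- batch_fpt(par, 2000, seed = 1, absorb_cap_steps = 70)
  expect_lte(max(s$steps), 70)
  expect_gt(s$n_censored, 0)
  # censoring must not perturb the uncensored walks (per-walk substreams)
  full <- batch_fpt(par, 2000, seed = 1)
  keep <- full$steps < 70
  expect_identical(s$steps[keep], full$steps[keep])
})

test_that("single-walk wrappers agree with their batch counterparts", {
  par <- obstacles_params(3, 0.3, 90)
  grid <- sample_connected_grid(par, seed = 2)
  expect_identical(walk_fpt_obstacles(par, grid, seed = 9),
                   batch_fpt(par, 1, seed = 9, grid = grid)$steps[[1]])
  dpar <- ddm_params(5, 0.15, 60)
  expect_identical(walk_fpt_ddm(dpar, seed = 9),
                   batch_fpt(dpar, 1, seed = 9)$steps[[1]])
})
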