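# Reduced budgets throughout: recovery at full protocol scale lives in
# test-acceptance.R.

small_space <- function() {
  fit_space(radius_values = 2:4, density_bounds = c(0.2, 0.65),
            dt_bounds = c(40, 120), sims_per_eval = 2000)
}

small_control <- function() fit_control(n_starts = 2, maxit = 20)

test_that("derived evaluation seeds are deterministic and distinct", {
  p <- obstacles_params(4, 0.45, 90)
  s1 <- derive_eval_seed(7, p)
  expect_identical(s1, derive_eval_seed(7, p))
  expect_true(s1 >= 1 && s1 < 2^31)
  expect_false(s1 == derive_eval_seed(8, p))
  expect_false(s1 == derive_eval_seed(7, obstacles_params(4, 0.46, 90)))
  expect_false(s1 == derive_eval_seed(7, ddm_params(4, 0.45, 90)))
})

test_that("objective is exactly zero against its own simulation", {
  p <- obstacles_params(3, 0.4, 80)
  base_seed <- 13
  cap_steps <- ceiling(300 * 1000 / p$dt_ms) + 1
  rts <- gen_rt_sample(p, 3000, derive_eval_seed(base_seed, p),
                       absorb_cap_steps = cap_steps)
  target <- bin_rt(rts)
  expect_identical(objective_jsd(p, target, 3000, base_seed), 0)
})

test_that("objective is deterministic and larger away from the truth", {
  p <- obstacles_params(3, 0.4, 80)
  target <- bin_rt(gen_rt_sample(p, 20000, seed = 500))
  v1 <- objective_jsd(p, target, 2000, 7)
  expect_identical(v1, objective_jsd(p, target, 2000, 7))
  far <- obstacles_params(6, 0.6, 40)
  wins <- sum(vapply(1:20, function(k) {
    objective_jsd(far, target, 2000, 100 + k) >
      objective_jsd(p, target, 2000, 100 + k)
  }, logical(1)))
  expect_gte(wins, 19)
})

test_that("Monte-Carlo JSD bias shrinks with the simulation budget", {
  p <- obstacles_params(3, 0.4, 80)
  target <- bin_rt(gen_rt_sample(p, 40000, seed = 501))
  small <- vapply(1:5, function(k) objective_jsd(p, target, 1000, 200 + k),
                  numeric(1))
  big <- vapply(1:5, function(k) objective_jsd(p, target, 20000, 300 + k),
                numeric(1))
  expect_gt(mean(small), 0)
  expect_lt(mean(big), mean(small))
})

test_that("fit_model recovers a small generating triple", {
  truth <- obstacles_params(3, 0.4, 80)
  target <- bin_rt(gen_rt_sample(truth, 20000, seed = 42))
  fit <- fit_model("obstacles", target, small_space(), base_seed = 43,
                   control = small_control())
  expect_identical(fit$params$radius, 3L)
  expect_lt(abs(fit$params$density - 0.4), 0.1)
  expect_lt(abs(fit$params$dt_ms - 80), 10)
})

test_that("fit results stay inside the space with monotone traces", {
  truth <- obstacles_params(3, 0.35, 70)
  target <- bin_rt(gen_rt_sample(truth, 5000, seed = 44))
  sp <- small_space()
  fit <- fit_model("obstacles", target, sp, base_seed = 45,
                   control = small_control())
  expect_true(fit$params$radius %in% sp$radius_values)
  expect_true(fit$params$density >= sp$density_bounds[1] &&
              fit$params$density <= sp$density_bounds[2])
  expect_true(fit$params$dt_ms >= sp$dt_bounds[1] &&
              fit$params$dt_ms <= sp$dt_bounds[2])
  for (tr in fit$traces) expect_true(all(diff(tr) <= 0))
  expect_equal(sum(fit$per_radius$n_evals), fit$n_evals)
  expect_gte(fit$objective, 0)
})

test_that("degenerate targets are refused", {
  target <- bin_rt(rep(0.25, 50))  # single occupied bin
  expect_error(fit_model("obstacles", target, small_space()),
               class = "gridrt_fit_failure")
})

test_that("fit results serialize to JSON", {
  truth <- obstacles_params(3, 0.35, 70)
  target <- bin_rt(gen_rt_sample(truth, 4000, seed = 46))
  fit <- fit_model("obstacles", target,
                   fit_space(radius_values = 3, sims_per_eval = 1000),
                   base_seed = 47, control = fit_control(n_starts = 1,
                                                         maxit = 10))
  path <- tempfile(fileext = ".json")
  fit_to_json(fit, path)
  obj <- jsonlite::read_json(path)
  expect_equal(obj$model, "obstacles")
  expect_equal(obj$params$radius, 3)
  expect_true(is.numeric(obj$objective))
  unlink(path)
})

test_that("cross-validation treats identical model kinds identically-ish", {
  truth <- obstacles_params(3, 0.4, 80)
  rts <- gen_rt_sample(truth, 600, seed = 48)
  cv <- cross_validate(rts, models = c("obstacles", "obstacles"),
                       split_fraction = 0.8, repeats = 6, base_seed = 49,
                       space = fit_space(radius_values = 3,
                                         sims_per_eval = 800),
                       control = fit_control(n_starts = 1, maxit = 10))
  expect_lt(abs(diff(cv$mean_jsd)), 0.02)
  expect_equal(nrow(cv$per_repeat), 6)
  expect_error(cross_validate(rts[1:50], repeats = 2),
               class = "gridrt_empty_input")
})
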