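tiny_space <- function(radii = 2:5) {
  fit_space(radius_values = radii, dt_bounds = c(40, 120),
            sims_per_eval = 1200)
}

tiny_control <- function() fit_control(n_starts = 1, maxit = 12,
                                       coarse_dt_ms = 20)

test_that("middle-game filter keeps the closed [0.1, 0.9] fraction window", {
  rec <- data.frame(player_id = "a", rating = 1500, game_id = "g",
                    total_time_s = 300,
                    remaining_time_s = c(285, 270, 150, 30, 15),
                    rt_s = 1)
  kept <- filter_middle_game(rec)
  # 300 s budget: window is remaining time in [30, 270]
  expect_equal(kept$remaining_time_s, c(270, 150, 30))
  expect_equal(filter_middle_game(kept), kept)  # idempotent
  expect_equal(nrow(filter_middle_game(rec[rec$remaining_time_s > 280, ])), 0)
  expect_error(filter_middle_game(data.frame(x = 1)),
               class = "gridrt_invalid_parameter")
})

test_that("quintile grouping partitions records with near-equal sizes", {
  set.seed(5)
  rec <- toy_records(runif(6, 1000, 2000),
                     replicate(6, obstacles_params(3, 0.4, 80),
                               simplify = FALSE),
                     n_moves = 53, seed = 2)
  qa <- quintile_analysis(rec, n_groups = 5, space = tiny_space(3),
                          base_seed = 1, control = tiny_control())
  expect_equal(sum(qa$groups$n), nrow(rec))
  expect_lte(diff(range(qa$groups$n)), 1)
  expect_true(all(diff(qa$groups$mean_rating) >= 0))
})

test_that("degenerate ratings give undefined correlations, not errors", {
  rec <- toy_records(rep(1500, 3),
                     replicate(3, obstacles_params(3, 0.4, 80),
                               simplify = FALSE),
                     n_moves = 40, seed = 3)
  qa <- quintile_analysis(rec, n_groups = 3, space = tiny_space(3),
                          base_seed = 1, control = tiny_control())
  expect_true(all(is.na(qa$correlations$estimate)))
})

test_that("similarity ranking: perfect fits give correlation 1,
           random fits average ~0", {
  set.seed(31)
  hists <- lapply(1:6, function(i) make_hist(runif(40)))
  names(hists) <- paste0("p", 1:6)
  r <- similarity_rank_correlation(hists, hists)
  expect_equal(unname(r), rep(1, 6))
  # permutation baseline: random fitted histograms carry no player-specific
  # signal.  The baseline mean is not exactly zero because JSD distances
  # share a "remoteness" component (an outlying player is far from real and
  # random histograms alike), but it must sit far below the perfect-fit
  # ceiling of 1.
  means <- vapply(1:100, function(k) {
    fake <- lapply(1:6, function(i) make_hist(runif(40)))
    mean(similarity_rank_correlation(hists, fake))
  }, numeric(1))
  expect_lt(mean(means), 0.5)
  expect_gt(mean(means), -0.5)
  expect_error(similarity_rank_correlation(hists[1:2], hists[1:2]),
               class = "gridrt_insufficient_population")
})

test_that("similarity ranking separates a structured synthetic cohort", {
  # well-separated generating parameters; fitted hists = fresh simulations
  # at the generating triples (a perfect-fit stand-in)
  pars <- list(obstacles_params(3, 0.25, 60), obstacles_params(4, 0.45, 90),
               obstacles_params(5, 0.6, 120), obstacles_params(2, 0.3, 40),
               obstacles_params(6, 0.5, 80))
  real <- lapply(seq_along(pars), function(i)
    bin_rt(gen_rt_sample(pars[[i]], 20000, seed = 100 + i)))
  fitted <- lapply(seq_along(pars), function(i)
    bin_rt(gen_rt_sample(pars[[i]], 20000, seed = 200 + i)))
  names(real) <- names(fitted) <- paste0("p", seq_along(pars))
  r <- similarity_rank_correlation(real, fitted)
  expect_true(all(r > 0.9))
})

test_that("fit_players enforces the minimum-game threshold", {
  rec <- toy_records(c(1200, 1800), list(obstacles_params(3, 0.3, 80),
                                         obstacles_params(3, 0.5, 80)),
                     n_moves = 60, seed = 7)
  rec_small <- toy_records(1500, list(obstacles_params(3, 0.4, 80)),
                           n_moves = 5, seed = 8)
  rec_small$player_id <- "tiny"
  fits <- fit_players(rbind(rec, rec_small), min_games = 20,
                      space = tiny_space(3), models = "obstacles",
                      base_seed = 2, control = tiny_control())
  expect_setequal(names(fits), c("T01", "T02"))
  expect_s3_class(fits$T01$obstacles, "fit_result")
  # the generating-density ordering survives the fit
  expect_lt(fits$T01$obstacles$params$density,
            fits$T02$obstacles$params$density)
})

test_that("a single whole-window instant bin reduces to the pooled fit", {
  rec <- toy_records(1500, list(obstacles_params(3, 0.4, 80)),
                     n_moves = 300, seed = 9)
  per <- fit_per_instant(rec, instant_bin_width_s = 1000,
                         space = tiny_space(3), base_seed = 10,
                         control = tiny_control(), min_records = 100)
  expect_length(per, 1)
  pooled <- fit_model("obstacles", bin_rt(rec$rt_s), tiny_space(3),
                      base_seed = 10 + 1, control = tiny_control())
  expect_equal(per[[1]]$obstacles$params, pooled$params)
  expect_equal(per[[1]]$n, 300)
  expect_lt(abs(per[[1]]$obstacles_median_s - per[[1]]$empirical_median_s),
            0.5)
  # undersized bins are skipped with a report
  per2 <- fit_per_instant(rec, instant_bin_width_s = 1000,
                          space = tiny_space(3), base_seed = 10,
                          control = tiny_control(), min_records = 1000)
  expect_length(per2, 0)
  expect_equal(attr(per2, "skipped")$n, 300)
})
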