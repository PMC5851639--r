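# Population-level analyses: per-instant fits, per-player fits,
# similarity rankings, and rating-quintile specificity.

move_columns <- c("player_id", "rating", "game_id", "total_time_s",
                  "remaining_time_s", "rt_s")

check_records <- function(records) {
  missing <- setdiff(move_columns, names(records))
  if (length(missing)) {
    stop_gridrt("gridrt_invalid_parameter",
                "records lack required columns: %s",
                paste(missing, collapse = ", "))
  }
  records
}

#' Read / write a move-record table
#'
#' Comma-delimited UTF-8 with header `player_id, rating, game_id,
#' total_time_s, remaining_time_s, rt_s`: one row per decision.
#'
#' @param path CSV path.
#' @param records a move-record data frame.
#' @return `read_moves_csv` returns the data frame; `write_moves_csv`
#'   returns `path` invisibly.
#' @export
read_moves_csv <- function(path) {
  check_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_moves_csv
#' @export
write_moves_csv <- function(records, path) {
  utils::write.csv(check_records(records)[move_columns], path,
                   row.names = FALSE)
  invisible(path)
}

#' Keep middle-game moves
#'
#' Retains decisions whose remaining-time fraction lies in
#' `[lo, hi]` (closed interval), by default `[0.1, 0.9]`: for a 300 s
#' budget, moves made with between 270 s and 30 s on the clock.  The
#' opening and endgame regimes excluded here are dominated by
#' standardized openings and time pressure.  Idempotent.
#'
#' @param records move-record data frame.
#' @param lo,hi remaining-fraction window.
#' @return Filtered data frame (possibly empty).
#' @export
filter_middle_game <- function(records, lo = 0.1, hi = 0.9) {
  records <- check_records(records)
  frac <- records$remaining_time_s / records$total_time_s
  records[frac >= lo & frac <= hi, , drop = FALSE]
}

#' Fit models per instant of the game
#'
#' Divides the remaining-time axis into bins of `instant_bin_width_s`
#' and fits each requested model independently to the RT histogram of
#' every bin holding at least `min_records` decisions (undersized bins
#' are skipped and reported).  The published analysis used 0.1 s
#' instants over 15M games; desk-scale corpora need far wider bins.
#'
#' @param records move-record data frame (filter first if desired).
#' @param instant_bin_width_s instant bin width, seconds.
#' @param space a [fit_space()].
#' @param models model kinds to fit.
#' @param base_seed seed.
#' @param control a [fit_control()].
#' @param min_records minimum decisions per instant bin (default 500).
#' @param bin_width,cap RT histogram convention.
#' @return List of per-instant entries (`instant_lo`, `instant_hi`,
#'   `n`, `empirical_median_s`, and per model a `fit_result` plus
#'   `model_median_s`), with a `skipped` attribute listing undersized
#'   bins.
#' @export
fit_per_instant <- function(records, instant_bin_width_s, space = fit_space(),
                            models = "obstacles", base_seed = 1,
                            control = fit_control(), min_records = 500,
                            bin_width = 0.1, cap = 300) {
  records <- check_records(records)
  width <- check_number(instant_bin_width_s, "instant_bin_width_s", 0, Inf,
                        strict_lo = TRUE)
  hi <- max(records$remaining_time_s)
  edges <- seq(0, by = width, length.out = ceiling(hi / width) + 1)
  idx <- pmin(findInterval(records$remaining_time_s, edges),
              length(edges) - 1)
  out <- list()
  skipped <- list()
  for (b in sort(unique(idx))) {
    rows <- records[idx == b, , drop = FALSE]
    if (nrow(rows) < min_records) {
      skipped[[length(skipped) + 1]] <-
        data.frame(instant_lo = edges[b], instant_hi = edges[b + 1],
                   n = nrow(rows))
      next
    }
    target <- bin_rt(rows$rt_s, bin_width, cap)
    entry <- list(instant_lo = edges[b], instant_hi = edges[b + 1],
                  n = nrow(rows),
                  empirical_median_s = stats::median(rows$rt_s))
    for (m in models) {
      fit <- fit_model(m, target, space, base_seed = base_seed + b,
                       control = control)
      entry[[m]] <- fit
      entry[[paste0(m, "_median_s")]] <- hist_median(fit$best_hist)
    }
    out[[length(out) + 1]] <- entry
  }
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  out
}

hist_median <- function(hist) {
  cdf <- cumsum(hist$probabilities)
  i <- which(cdf >= 0.5)[[1]]
  hist$bin_edges[[i]] + diff(hist$bin_edges)[[i]] / 2
}

#' Fit models per player
#'
#' Fits each requested model to every player's RT histogram, keeping
#' only players with at least `min_games` distinct games (the published
#' per-player analysis kept the 17 players with more than 20,000 games
#' each).
#'
#' @param records move-record data frame.
#' @param min_games minimum distinct games per player.
#' @param space a [fit_space()].
#' @param models model kinds.
#' @param base_seed seed.
#' @param control a [fit_control()].
#' @param bin_width,cap RT histogram convention.
#' @return Named list (by player id) of entries: `n_games`, `n_moves`,
#'   `rating` (mean), `hist`, and one `fit_result` per model kind.
#' @export
fit_players <- function(records, min_games = 20000, space = fit_space(),
                        models = "obstacles", base_seed = 1,
                        control = fit_control(), bin_width = 0.1, cap = 300) {
  records <- check_records(records)
  out <- list()
  for (pid in unique(records$player_id)) {
    rows <- records[records$player_id == pid, , drop = FALSE]
    n_games <- length(unique(rows$game_id))
    if (n_games < min_games) next
    hist <- bin_rt(rows$rt_s, bin_width, cap)
    entry <- list(n_games = n_games, n_moves = nrow(rows),
                  rating = mean(rows$rating), hist = hist)
    for (m in models) {
      entry[[m]] <- fit_model(m, hist, space,
                              base_seed = base_seed + length(out),
                              control = control)
    }
    out[[as.character(pid)]] <- entry
  }
  out
}

#' Similarity rank correlation between real and fitted distributions
#'
#' For each player, all other players are ranked twice by JSD: once
#' against the player's real RT histogram and once against the player's
#' fitted-model histogram.  A model that captures what makes a player's
#' distribution distinctive yields near-identical orderings.  Returns
#' the Spearman rank correlation (ties by average ranks) per player.
#'
#' @param real_hists named list of `rt_histogram`s, one per player.
#' @param fitted_hists named list of fitted-model histograms on the
#'   same edges, aligned with `real_hists`.
#' @return Named numeric vector of per-player Spearman correlations.
#' @export
similarity_rank_correlation <- function(real_hists, fitted_hists) {
  if (length(real_hists) < 3) {
    stop_gridrt("gridrt_insufficient_population",
                "need at least 3 players")
  }
  stopifnot(length(real_hists) == length(fitted_hists))
  ids <- names(real_hists)
  if (is.null(ids)) ids <- as.character(seq_along(real_hists))
  out <- setNames(numeric(length(ids)), ids)
  for (i in seq_along(ids)) {
    others <- setdiff(seq_along(ids), i)
    d_real <- vapply(others, function(j) jsd(real_hists[[i]], real_hists[[j]]),
                     numeric(1))
    d_fit <- vapply(others, function(j) jsd(fitted_hists[[i]], real_hists[[j]]),
                    numeric(1))
    out[[i]] <- stats::cor(d_real, d_fit, method = "spearman")
  }
  out
}

#' Rating-quintile specificity analysis
#'
#' Sorts decisions by player rating, cuts them into `n_groups` groups
#' with equal record counts (sizes differ by at most one), fits the
#' obstacles model to each group's RT histogram, and correlates each
#' fitted parameter (obstacle fraction, time per step, radius) with the
#' group mean rating (Pearson, two-sided raw p-values).  The expertise
#' prediction is a positive density-rating and negative radius-rating
#' correlation with flat time per step.
#'
#' @param records move-record data frame (typically middle-game
#'   filtered).
#' @param n_groups number of rating groups (default 5, quintiles).
#' @param space a [fit_space()].
#' @param base_seed seed.
#' @param control a [fit_control()].
#' @param bin_width,cap RT histogram convention.
#' @return An object of class `cohort_result`: `groups` data frame
#'   (n, mean rating, fitted parameters, objective) and `correlations`
#'   data frame (parameter, estimate, p_value).
#' @export
quintile_analysis <- function(records, n_groups = 5, space = fit_space(),
                              base_seed = 1, control = fit_control(),
                              bin_width = 0.1, cap = 300) {
  records <- check_records(records)
  n_groups <- check_positive_int(n_groups, "n_groups")
  if (nrow(records) < n_groups) {
    stop_gridrt("gridrt_empty_input",
                "fewer records than groups")
  }
  ord <- order(records$rating)
  records <- records[ord, , drop = FALSE]
  sizes <- rep(nrow(records) %/% n_groups, n_groups)
  extra <- nrow(records) %% n_groups
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  grp <- rep(seq_len(n_groups), times = sizes)
  rows <- vector("list", n_groups)
  for (g in seq_len(n_groups)) {
    sub <- records[grp == g, , drop = FALSE]
    target <- bin_rt(sub$rt_s, bin_width, cap)
    fit <- fit_model("obstacles", target, space, base_seed = base_seed + g,
                     control = control)
    rows[[g]] <- data.frame(
      group = g, n = nrow(sub), mean_rating = mean(sub$rating),
      density = fit$params$density, dt_ms = fit$params$dt_ms,
      radius = fit$params$radius, objective = fit$objective)
  }
  groups <- do.call(rbind, rows)
  correlations <- do.call(rbind, lapply(
    c("density", "dt_ms", "radius"),
    function(par) {
      x <- groups[[par]]
      r <- groups$mean_rating
      if (stats::sd(r) == 0 || stats::sd(x) == 0) {
        return(data.frame(parameter = par, estimate = NA_real_,
                          p_value = NA_real_))
      }
      ct <- stats::cor.test(x, r)
      data.frame(parameter = par, estimate = unname(ct$estimate),
                 p_value = ct$p.value)
    }))
  structure(list(groups = groups, correlations = correlations),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result>\n")
  print(x$groups, row.names = FALSE)
  cat("\nparameter-rating correlations:\n")
  print(x$correlations, row.names = FALSE)
  invisible(x)
}
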