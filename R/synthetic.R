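# Desk-scale synthetic RT corpora with the statistical structure the
# cohort analyses assume: a population of rated players, each producing
# response times from one of the two generative models, with parameters
# tied to rating by affine maps.

#' Configuration of a synthetic cohort
#'
#' Each player draws a rating uniformly on `rating_range`, maps it
#' through affine parameter maps (`value = intercept + slope * rating`,
#' clipped to the fitting search box), and plays `games_per_player`
#' games with a `total_time_s` budget, emitting one move record per
#' decision until the clock runs down.  The default maps embed the
#' expertise structure recovered from the blitz corpus: obstacle
#' density rising with rating (0.30 at rating 1000 to 0.60 at 2000),
#' radius falling (6 to 3), time per step flat at 90 ms.
#'
#' @param n_players number of players.
#' @param games_per_player games per player.
#' @param total_time_s time budget per game (default 300 s).
#' @param rating_range uniform rating interval (default 1000..2000).
#' @param density_map,radius_map,dt_map affine maps `c(intercept, slope)`
#'   from rating to obstacle fraction, radius (rounded to integer) and
#'   time per step (ms).
#' @param density_clip,radius_clip,dt_clip clipping ranges.
#' @param model generative model kind for every player.
#' @param epsilon_map affine map to acceptance noise (DDM cohorts).
#' @param epsilon_clip clipping range for epsilon.
#' @param time_floor_s remaining time below which a game ends.
#' @param seed master seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_players = 20, games_per_player = 10,
                          total_time_s = 300,
                          rating_range = c(1000, 2000),
                          density_map = c(intercept = 0, slope = 3e-4),
                          radius_map = c(intercept = 9, slope = -3e-3),
                          dt_map = c(intercept = 90, slope = 0),
                          density_clip = c(0.2, 0.65),
                          radius_clip = c(1, 10),
                          dt_clip = c(10, 150),
                          model = c("obstacles", "ddm"),
                          epsilon_map = c(intercept = 0.2, slope = 0),
                          epsilon_clip = c(0.001, 0.25),
                          time_floor_s = 0, seed = 1) {
  model <- match.arg(model)
  structure(list(
    n_players = check_positive_int(n_players, "n_players"),
    games_per_player = check_positive_int(games_per_player,
                                          "games_per_player"),
    total_time_s = check_number(total_time_s, "total_time_s", 0, Inf,
                                strict_lo = TRUE),
    rating_range = as.numeric(rating_range),
    density_map = as.numeric(density_map),
    radius_map = as.numeric(radius_map),
    dt_map = as.numeric(dt_map),
    density_clip = as.numeric(density_clip),
    radius_clip = as.numeric(radius_clip),
    dt_clip = as.numeric(dt_clip),
    model = model,
    epsilon_map = as.numeric(epsilon_map),
    epsilon_clip = as.numeric(epsilon_clip),
    time_floor_s = check_number(time_floor_s, "time_floor_s", 0, Inf),
    seed = check_seed(seed)), class = "cohort_config")
}

affine_clip <- function(map, clip, rating) {
  pmin(pmax(map[[1]] + map[[2]] * rating, clip[[1]]), clip[[2]])
}

player_params <- function(config, rating) {
  radius <- round(affine_clip(config$radius_map, config$radius_clip, rating))
  dt <- affine_clip(config$dt_map, config$dt_clip, rating)
  if (config$model == "obstacles") {
    obstacles_params(radius,
                     affine_clip(config$density_map, config$density_clip,
                                 rating),
                     dt)
  } else {
    ddm_params(radius,
               affine_clip(config$epsilon_map, config$epsilon_clip, rating),
               dt)
  }
}

#' Generate a synthetic move-record corpus
#'
#' For each player: draw a rating, map it to model parameters, and play
#' out games by drawing successive RTs from the player's generative
#' model, decrementing the clock after each move.  A drawn RT that
#' would push remaining time below `time_floor_s` ends the game (that
#' record is dropped and counted).  Identical config gives an identical
#' corpus.  Ground-truth parameters are returned in a separate `truth`
#' table, never in the move table.
#'
#' @param config a [cohort_config()].
#' @return List of class `synthetic_cohort`: `moves` (move-record data
#'   frame), `truth` (per-player generating parameters), `n_dropped`.
#' @export
gen_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  ratings <- with_local_rng(config$seed, {
    sort(stats::runif(config$n_players, config$rating_range[[1]],
                      config$rating_range[[2]]))
  })
  moves <- vector("list", config$n_players)
  truth <- vector("list", config$n_players)
  n_dropped <- 0L
  for (i in seq_len(config$n_players)) {
    pid <- sprintf("P%03d", i)
    par <- player_params(config, ratings[[i]])
    truth[[i]] <- data.frame(
      player_id = pid, rating = ratings[[i]], model = config$model,
      radius = par$radius,
      density = if (config$model == "obstacles") par$density else NA_real_,
      epsilon = if (config$model == "ddm") par$epsilon else NA_real_,
      dt_ms = par$dt_ms)
    # draw RTs in chunks; each chunk gets its own derived seed
    pool <- numeric(0)
    chunk <- 0L
    refill <- function(need) {
      while (length(pool) < need) {
        chunk <<- chunk + 1L
        s <- (config$seed * 1009 + i * 104729 + chunk * 7919) %% 2147483647
        pool <<- c(pool, batch_fpt(par, 4096, s)$rt_ms / 1000)
      }
    }
    g_rt <- list()
    g_rem <- list()
    g_id <- list()
    for (g in seq_len(config$games_per_player)) {
      # a move is kept while it leaves at least time_floor_s on the clock;
      # the first overshooting draw ends the game and is dropped
      budget <- config$total_time_s - config$time_floor_s
      need <- 64L
      repeat {
        refill(need)
        k <- sum(cumsum(pool) <= budget)
        if (k < length(pool)) break
        need <- length(pool) + 64L
      }
      rts <- pool[seq_len(k)]
      g_rt[[g]] <- rts
      g_rem[[g]] <- config$total_time_s - c(0, cumsum(rts))[seq_len(k)]
      g_id[[g]] <- rep(sprintf("%s-G%04d", pid, g), k)
      pool <- pool[-seq_len(k + 1)]
      n_dropped <- n_dropped + 1L
    }
    rt_all <- unlist(g_rt)
    moves[[i]] <- data.frame(
      player_id = pid, rating = ratings[[i]], game_id = unlist(g_id),
      total_time_s = config$total_time_s,
      remaining_time_s = unlist(g_rem), rt_s = rt_all)
  }
  structure(list(moves = do.call(rbind, moves),
                 truth = do.call(rbind, truth),
                 n_dropped = n_dropped, config = config),
            class = "synthetic_cohort")
}

#' Draw a response-time sample from a model
#'
#' Thin wrapper over [batch_fpt()] converting step counts to seconds.
#'
#' @param params a parameter object.
#' @param n sample size.
#' @param seed non-negative integer.
#' @param ... passed to [batch_fpt()].
#' @return Numeric RT values in seconds.
#' @export
gen_rt_sample <- function(params, n, seed, ...) {
  batch_fpt(params, n, seed, ...)$rt_ms / 1000
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d players, %d moves (%d dropped at game end), model = %s\n",
    nrow(x$truth), nrow(x$moves), x$n_dropped, x$config$model))
  invisible(x)
}
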