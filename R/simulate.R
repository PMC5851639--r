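#' Acceptance cost of a proposed DDM step
#'
#' Cost of moving in direction `step` given displacement `displacement`
#' from the origin: `C = (1 - cos(theta)) / 2`, where `theta` is the
#' angle between the two vectors.  Radially outward moves are free
#' (`C = 0`), radially inward moves maximally costly (`C = 1`).  The
#' walker accepts a proposal with probability `exp(-C / epsilon)`.
#'
#' @param displacement numeric 2-vector, current position relative to
#'   the origin.
#' @param step numeric 2-vector, a unit lattice step.
#' @return Cost in `[0, 1]`, or `NA_real_` when the walker sits at the
#'   origin (the caller must then accept unconditionally).
#' @examples
#' acceptance_cost(c(0, 3), c(0, 1))   # outward: 0
#' acceptance_cost(c(0, 3), c(0, -1))  # inward: 1
#' acceptance_cost(c(0, 3), c(1, 0))   # perpendicular: 0.5
#' @export
acceptance_cost <- function(displacement, step) {
  if (length(displacement) != 2 || length(step) != 2) {
    stop_gridrt("gridrt_invalid_parameter",
                "displacement and step must be 2-vectors")
  }
  if (sum(abs(step)) != 1 || !all(step %in% c(-1, 0, 1))) {
    stop_gridrt("gridrt_invalid_parameter", "step must be a unit lattice step")
  }
  nz <- sqrt(sum(displacement^2))
  if (nz == 0) return(NA_real_)
  (1 - sum(displacement * step) / nz) / 2
}

default_step_cap <- 1e7

#' Simulate one first-passage walk
#'
#' `walk_fpt_obstacles` runs a single unbiased walker on a fixed
#' obstacle grid; at each iteration one of the four lattice directions
#' is drawn uniformly, a move into an obstacle leaves the walker in
#' place (the iteration still counts), and the walk ends on first
#' arrival at Euclidean distance `>= radius` from the origin.
#' `walk_fpt_ddm` runs a single outward-biased walker (see
#' [acceptance_cost()]).  Both return the number of iterations taken.
#'
#' @param params model parameters ([obstacles_params()] or
#'   [ddm_params()]).
#' @param grid a connected `obstacle_grid` (its radius overrides
#'   `params$radius`).
#' @param seed non-negative integer.
#' @param step_cap iterations before a `gridrt_runaway_error` (default
#'   `1e7`), a guard against mis-specified grids.
#' @return Positive integer step count.
#' @export
walk_fpt_obstacles <- function(params, grid, seed, step_cap = default_step_cap) {
  stopifnot(inherits(params, "obstacles_params"),
            inherits(grid, "obstacle_grid"))
  seed <- check_seed(seed)
  res <- rethrow_cpp(cpp_batch_obstacles(grid$radius, params$density, seed, 1L,
                                         FALSE, grid$occupancy, 1L,
                                         step_cap, 0))
  res$steps[[1]]
}

#' @rdname walk_fpt_obstacles
#' @export
walk_fpt_ddm <- function(params, seed, step_cap = default_step_cap) {
  stopifnot(inherits(params, "ddm_params"))
  seed <- check_seed(seed)
  res <- rethrow_cpp(cpp_batch_ddm(params$radius, params$epsilon, seed, 1L,
                                   step_cap, 0, TRUE))
  res$steps[[1]]
}

#' Simulate a batch of first-passage times
#'
#' Runs `n_sims` independent walks of the model described by `params`.
#' For the obstacles model the disorder is *annealed* by default (a
#' fresh connected grid realization per walk); `disorder = "quenched"`
#' shares a single seeded realization across the batch, and a fixed
#' `grid` may be supplied instead.  Each walk consumes its own RNG
#' substream derived from `seed`, so identical `(params, seed)` give an
#' identical sample.
#'
#' @param params model parameters; the model kind is taken from their
#'   class.
#' @param n_sims number of walks (the published fitting protocol uses
#'   75,000 simulated decisions per parameter combination).
#' @param seed non-negative integer.
#' @param disorder `"annealed"` (default) or `"quenched"`; ignored for
#'   the DDM.
#' @param grid optional fixed `obstacle_grid` (implies quenched
#'   disorder on that realization).
#' @param max_retries connectivity resampling budget per realization.
#' @param step_cap runaway guard per walk.
#' @param absorb_cap_steps if `> 0`, walks still alive after this many
#'   iterations are censored at the cap (recorded in `n_censored`); used
#'   internally so fitting can pool everything beyond the histogram
#'   overflow bin without simulating arbitrarily deep tails.
#' @param count_rejected_ddm should a rejected DDM proposal consume one
#'   iteration (default `TRUE`, hesitation costs time)?
#' @return An object of class `fpt_sample`: list with `steps`, `dt_ms`,
#'   `rt_ms`, `model`, `params`, `seed`, `n_resamples`, `n_censored`.
#' @examples
#' s <- batch_fpt(obstacles_params(4, 0.45, 90), n_sims = 100, seed = 1)
#' summary(s$steps)
#' @export
batch_fpt <- function(params, n_sims = 75000, seed,
                      disorder = c("annealed", "quenched"), grid = NULL,
                      max_retries = 1e4, step_cap = default_step_cap,
                      absorb_cap_steps = 0, count_rejected_ddm = TRUE) {
  disorder <- match.arg(disorder)
  n_sims <- check_positive_int(n_sims, "n_sims")
  seed <- check_seed(seed)
  kind <- model_kind(params)
  if (kind == "obstacles") {
    occ <- NULL
    radius <- params$radius
    if (!is.null(grid)) {
      stopifnot(inherits(grid, "obstacle_grid"))
      occ <- grid$occupancy
      radius <- grid$radius
      disorder <- "quenched"
    }
    res <- rethrow_cpp(cpp_batch_obstacles(
      radius, params$density, seed, n_sims, disorder == "quenched", occ,
      as.integer(max_retries), step_cap, absorb_cap_steps))
  } else {
    res <- rethrow_cpp(cpp_batch_ddm(
      params$radius, params$epsilon, seed, n_sims, step_cap,
      absorb_cap_steps, count_rejected_ddm))
  }
  structure(
    list(steps = res$steps, dt_ms = params$dt_ms,
         rt_ms = res$steps * params$dt_ms, model = kind, params = params,
         seed = seed, disorder = if (kind == "obstacles") disorder else NA,
         n_resamples = res$resamples, n_censored = res$censored),
    class = "fpt_sample"
  )
}

#' @export
print.fpt_sample <- function(x, ...) {
  cat(sprintf(
    "<fpt_sample> %s model, n = %d, dt = %g ms, median RT = %.3f s\n",
    x$model, length(x$steps), x$dt_ms, stats::median(x$rt_ms) / 1000))
  invisible(x)
}

#' Write a first-passage sample to CSV (with a JSON metadata sidecar)
#'
#' @param sample an `fpt_sample`.
#' @param path CSV path; the sidecar is written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_fpt_csv <- function(sample, path) {
  stopifnot(inherits(sample, "fpt_sample"))
  utils::write.csv(data.frame(steps = sample$steps, rt_ms = sample$rt_ms),
                   path, row.names = FALSE)
  meta <- list(model = sample$model, params = unclass(sample$params),
               seed = sample$seed, n_sims = length(sample$steps),
               disorder = sample$disorder, n_resamples = sample$n_resamples,
               n_censored = sample$n_censored, schema_version = 1L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
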