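#' Parameter search space for model fitting
#'
#' Published search ranges: boundary radius `R` in 1..10 grid steps
#' (exhaustive axis), obstacle fraction in `[0.2, 0.65]`, acceptance
#' noise in `[0, 0.25]` (clipped below at 1e-3, where the bias becomes
#' degenerate), time per step in `[10, 150]` ms, and 75,000 simulated
#' decisions per parameter combination.  All are overridable.
#'
#' @param radius_values integer vector of radii searched exhaustively.
#' @param density_bounds obstacle-fraction box (obstacles model).
#' @param epsilon_bounds acceptance-noise box (DDM).
#' @param dt_bounds time-per-step box, ms.
#' @param sims_per_eval simulations per objective evaluation.
#' @return An object of class `fit_space`.
#' @export
fit_space <- function(radius_values = 1:10,
                      density_bounds = c(0.2, 0.65),
                      epsilon_bounds = c(0.001, 0.25),
                      dt_bounds = c(10, 150),
                      sims_per_eval = 75000) {
  radius_values <- vapply(radius_values, check_positive_int, integer(1),
                          name = "radius_values")
  stopifnot(length(density_bounds) == 2, diff(density_bounds) > 0,
            length(epsilon_bounds) == 2, diff(epsilon_bounds) > 0,
            epsilon_bounds[1] > 0,
            length(dt_bounds) == 2, diff(dt_bounds) > 0, dt_bounds[1] > 0)
  structure(list(radius_values = radius_values,
                 density_bounds = as.numeric(density_bounds),
                 epsilon_bounds = as.numeric(epsilon_bounds),
                 dt_bounds = as.numeric(dt_bounds),
                 sims_per_eval = check_positive_int(sims_per_eval,
                                                    "sims_per_eval")),
            class = "fit_space")
}

#' Optimizer control for [fit_model()]
#'
#' @param n_starts number of deterministic Nelder-Mead starts per radius:
#'   the best coarse-scan point, then the box centre, then further
#'   distinct coarse-scan points.
#' @param maxit Nelder-Mead evaluation budget per start.
#' @param max_retries connectivity resampling budget per simulated grid
#'   during fitting (kept smaller than the simulation default so nearly
#'   sealed corners of the box fail fast).
#' @param reltol Nelder-Mead relative convergence tolerance on the
#'   simplex value spread.
#' @param coarse_dt_ms spacing of the deterministic coarse scan along
#'   the time-per-step axis (ms).
#' @param coarse_cont_points number of coarse-scan points along the
#'   continuous model axis (density or epsilon).
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(n_starts = 3, maxit = 40, max_retries = 1000,
                        reltol = 1e-3, coarse_dt_ms = 10,
                        coarse_cont_points = 3) {
  structure(list(n_starts = check_positive_int(n_starts, "n_starts"),
                 maxit = check_positive_int(maxit, "maxit"),
                 max_retries = check_positive_int(max_retries, "max_retries"),
                 reltol = check_number(reltol, "reltol", 0, 1),
                 coarse_dt_ms = check_number(coarse_dt_ms, "coarse_dt_ms", 0,
                                             Inf, strict_lo = TRUE),
                 coarse_cont_points = check_positive_int(coarse_cont_points,
                                                         "coarse_cont_points")),
            class = "fit_control")
}

#' Deterministic per-evaluation seed
#'
#' Derives the simulation seed for one objective evaluation from the
#' base seed and the parameter point (a common-random-numbers policy:
#' re-evaluating the same point always replays the same simulations, so
#' the optimizer sees a deterministic surface).
#'
#' @param base_seed non-negative integer base seed.
#' @param params a parameter object.
#' @return An integer seed in `[1, 2^31 - 1]`.
#' @export
derive_eval_seed <- function(base_seed, params) {
  m <- 2147483647
  h <- check_seed(base_seed) %% m
  mix <- function(h, x) ((h * 48271) %% m + (abs(x) %% m)) %% m
  h <- mix(h, if (model_kind(params) == "obstacles") 1 else 2)
  h <- mix(h, params$radius)
  cont <- if (model_kind(params) == "obstacles") params$density else params$epsilon
  h <- mix(h, round(cont * 1e7))
  h <- mix(h, round(params$dt_ms * 1e4))
  h + 1
}

#' Jensen-Shannon objective of a parameter point
#'
#' Simulates `sims_per_eval` first-passage times at `params` (seed
#' derived deterministically from `base_seed` and the parameter point),
#' bins them on the target's edges, and returns the JSD between target
#' and model histograms.  Walks outlasting the histogram's overflow bin
#' are censored there, which leaves the objective unchanged while
#' bounding the simulation cost.
#'
#' @param params a parameter object.
#' @param target an `rt_histogram` (seconds).
#' @param sims_per_eval number of simulated decisions.
#' @param base_seed common-random-numbers base seed.
#' @param max_retries connectivity resampling budget.
#' @return Objective value in nats; identical arguments give the
#'   identical value.
#' @export
objective_jsd <- function(params, target, sims_per_eval, base_seed,
                          max_retries = 1000) {
  stopifnot(inherits(target, "rt_histogram"))
  hist <- simulate_histogram(params, target, sims_per_eval, base_seed,
                             max_retries)
  jsd(target, hist)
}

simulate_histogram <- function(params, target, sims_per_eval, base_seed,
                               max_retries = 1000) {
  seed <- derive_eval_seed(base_seed, params)
  cap_ms <- max(target$bin_edges) * 1000
  cap_steps <- ceiling(cap_ms / params$dt_ms) + 1
  s <- batch_fpt(params, sims_per_eval, seed, max_retries = max_retries,
                 absorb_cap_steps = cap_steps)
  bin_on_edges(s$rt_ms / 1000, target$bin_edges)
}

box_for <- function(model, space) {
  cont <- if (model == "obstacles") space$density_bounds else space$epsilon_bounds
  rbind(cont = cont, dt_ms = space$dt_bounds)
}

# Deterministic Nelder-Mead with an explicit initial simplex scale per
# dimension and a hard evaluation budget.  Needed instead of optim():
# when target and model are both lattice-valued, the objective has a
# narrow comb minimum in dt (bins align only when the time grids do), so
# the simplex scale in dt must be controlled, not inferred from the
# magnitude of the start.
nelder_mead_box <- function(fn, start, step, maxit, reltol) {
  d <- length(start)
  simplex <- rbind(start, t(vapply(seq_len(d), function(i) {
    v <- start
    v[i] <- v[i] + step[i]
    v
  }, numeric(d))))
  vals <- apply(simplex, 1, fn)
  evals <- d + 1
  while (evals < maxit) {
    o <- order(vals)
    simplex <- simplex[o, , drop = FALSE]
    vals <- vals[o]
    if (abs(vals[d + 1] - vals[1]) <
        reltol * (abs(vals[1]) + reltol)) break
    centroid <- colMeans(simplex[seq_len(d), , drop = FALSE])
    xr <- centroid + (centroid - simplex[d + 1, ])
    fr <- fn(xr)
    evals <- evals + 1
    if (fr < vals[1]) {
      xe <- centroid + 2 * (centroid - simplex[d + 1, ])
      fe <- fn(xe)
      evals <- evals + 1
      if (fe < fr) {
        simplex[d + 1, ] <- xe
        vals[d + 1] <- fe
      } else {
        simplex[d + 1, ] <- xr
        vals[d + 1] <- fr
      }
    } else if (fr < vals[d]) {
      simplex[d + 1, ] <- xr
      vals[d + 1] <- fr
    } else {
      xc <- centroid + 0.5 * (simplex[d + 1, ] - centroid)
      fc <- fn(xc)
      evals <- evals + 1
      if (fc < vals[d + 1]) {
        simplex[d + 1, ] <- xc
        vals[d + 1] <- fc
      } else {
        for (i in seq_len(d) + 1) {
          simplex[i, ] <- simplex[1, ] + 0.5 * (simplex[i, ] - simplex[1, ])
          vals[i] <- fn(simplex[i, ])
          evals <- evals + 1
        }
      }
    }
  }
  invisible(NULL)
}

#' Fit a model to a target RT histogram by JSD minimization
#'
#' Exhaustive search over the discrete radius axis; for each radius,
#' Nelder-Mead over the two continuous parameters (obstacle fraction or
#' acceptance noise, and time per step) from deterministic multi-starts
#' (box centre plus box corners).  Common random numbers (see
#' [derive_eval_seed()]) make the objective surface deterministic.
#' Points proposed outside the box are clamped onto it with a quadratic
#' penalty, so the returned optimum always lies inside the space.  An
#' evaluation whose simulation fails (e.g. a sealed high-density corner
#' exhausts its connectivity retries) scores the maximal JSD `ln 2`.
#'
#' @param model `"obstacles"` or `"ddm"`.
#' @param target an `rt_histogram` with at least 2 occupied bins.
#' @param space a [fit_space()].
#' @param base_seed common-random-numbers base seed.
#' @param control a [fit_control()].
#' @return An object of class `fit_result`: best parameters, objective
#'   (nats), per-radius table, running-best traces, KS statistic of the
#'   best fit against the target, evaluation counts and seeds.
#' @export
fit_model <- function(model = c("obstacles", "ddm"), target, space = fit_space(),
                      base_seed = 1, control = fit_control()) {
  model <- match.arg(model)
  stopifnot(inherits(target, "rt_histogram"), inherits(space, "fit_space"))
  if (sum(target$probabilities > 0) < 2) {
    stop_gridrt("gridrt_fit_failure",
                "degenerate target: fewer than 2 occupied bins")
  }
  t0 <- proc.time()[["elapsed"]]
  box <- box_for(model, space)
  lo <- box[, 1]
  hi <- box[, 2]
  span <- hi - lo
  per_radius <- vector("list", length(space$radius_values))
  traces <- vector("list", length(space$radius_values))
  total_evals <- 0L
  for (ri in seq_along(space$radius_values)) {
    radius <- space$radius_values[[ri]]
    ev <- new.env(parent = emptyenv())
    ev$best <- Inf
    ev$best_par <- NULL
    ev$n <- 0L
    ev$n_failed <- 0L
    ev$trace <- numeric(0)
    fn <- function(x) {
      xc <- pmin(pmax(x, lo), hi)
      pen <- 10 * sum(((x - xc) / span)^2)
      par <- if (model == "obstacles") {
        obstacles_params(radius, xc[1], xc[2])
      } else {
        ddm_params(radius, xc[1], xc[2])
      }
      val <- tryCatch(
        objective_jsd(par, target, space$sims_per_eval, base_seed,
                      control$max_retries),
        gridrt_error = function(e) {
          ev$n_failed <- ev$n_failed + 1L
          log(2)
        })
      ev$n <- ev$n + 1L
      if (val < ev$best) {
        ev$best <- val
        ev$best_par <- xc
      }
      ev$trace[[ev$n]] <- ev$best
      val + pen
    }
    # deterministic coarse scan of the box (the dt axis is combed: the
    # objective dips sharply where the model's time lattice aligns with
    # the target's, so it must be sampled finely before refinement)
    cont_grid <- lo[1] + span[1] *
      (seq_len(control$coarse_cont_points) - 0.5) / control$coarse_cont_points
    dt_grid <- seq(lo[2], hi[2], by = control$coarse_dt_ms)
    coarse <- expand.grid(cont = cont_grid, dt = dt_grid)
    coarse$val <- apply(coarse, 1, function(x) fn(c(x[["cont"]], x[["dt"]])))
    coarse <- coarse[order(coarse$val), ]
    # starts: best coarse point (fine steps), box centre (broad steps),
    # then further coarse points at distinct dt
    starts <- list(list(par = c(coarse$cont[1], coarse$dt[1]),
                        step = c(0.1 * span[1], control$coarse_dt_ms / 4)))
    starts[[2]] <- list(par = lo + span / 2,
                        step = c(0.25 * span[1], 2 * control$coarse_dt_ms))
    seen_dt <- coarse$dt[1]
    k <- 2
    while (length(starts) < control$n_starts && k <= nrow(coarse)) {
      if (all(abs(coarse$dt[k] - seen_dt) >= control$coarse_dt_ms)) {
        starts[[length(starts) + 1]] <-
          list(par = c(coarse$cont[k], coarse$dt[k]),
               step = c(0.1 * span[1], control$coarse_dt_ms / 4))
        seen_dt <- c(seen_dt, coarse$dt[k])
      }
      k <- k + 1
    }
    for (st in starts[seq_len(min(control$n_starts, length(starts)))]) {
      nelder_mead_box(fn, st$par, st$step, control$maxit, control$reltol)
    }
    if (!is.finite(ev$best) || is.null(ev$best_par) ||
        ev$n_failed >= ev$n) {
      stop_gridrt("gridrt_fit_failure",
                  "all starts failed at radius %d", radius,
                  data = list(trace = ev$trace))
    }
    per_radius[[ri]] <- data.frame(
      radius = radius, objective = ev$best, cont = ev$best_par[[1]],
      dt_ms = ev$best_par[[2]], n_evals = ev$n, n_failed = ev$n_failed)
    traces[[ri]] <- ev$trace
    total_evals <- total_evals + ev$n
  }
  per_radius <- do.call(rbind, per_radius)
  names(per_radius)[names(per_radius) == "cont"] <-
    if (model == "obstacles") "density" else "epsilon"
  best_row <- per_radius[which.min(per_radius$objective), ]
  best_params <- if (model == "obstacles") {
    obstacles_params(best_row$radius, best_row$density, best_row$dt_ms)
  } else {
    ddm_params(best_row$radius, best_row$epsilon, best_row$dt_ms)
  }
  best_hist <- simulate_histogram(best_params, target, space$sims_per_eval,
                                  base_seed, control$max_retries)
  ks_stat <- max(abs(cumsum(best_hist$probabilities) -
                     cumsum(target$probabilities)))
  structure(
    list(model = model, params = best_params,
         objective = best_row$objective, per_radius = per_radius,
         traces = traces, best_hist = best_hist, ks_stat = ks_stat,
         n_evals = total_evals, base_seed = base_seed, space = space,
         control = control,
         elapsed_s = proc.time()[["elapsed"]] - t0),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  p <- x$params
  cont <- if (x$model == "obstacles") {
    sprintf("q = %.3f", p$density)
  } else {
    sprintf("eps = %.3f", p$epsilon)
  }
  cat(sprintf(
    "<fit_result> %s model: R = %d, %s, dt = %.1f ms | JSD = %.4f nats, KS D = %.3f (%d evals, %.1f s)\n",
    x$model, p$radius, cont, p$dt_ms, x$objective, x$ks_stat, x$n_evals,
    x$elapsed_s))
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' Includes the full per-radius trace for auditability.
#'
#' @param fit a `fit_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
fit_to_json <- function(fit, path) {
  obj <- list(schema_version = 1L, model = fit$model,
              params = unclass(fit$params), objective = fit$objective,
              ks_stat = fit$ks_stat, per_radius = fit$per_radius,
              traces = fit$traces, n_evals = fit$n_evals,
              base_seed = fit$base_seed, elapsed_s = fit$elapsed_s)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Seeded parameter-recovery experiment
#'
#' Simulates `target_sims` first-passage times at a known generating
#' triple, fits the same model kind to the binned sample, and repeats
#' over independent seeds.  This is the package's core validation
#' surface: the published corpora are not deposited, so fits are
#' anchored by recovering the printed representative triples from
#' synthetic targets.
#'
#' @param model `"obstacles"` or `"ddm"`.
#' @param truth generating parameter object (defaults to the
#'   representative mid-game triple for the model).
#' @param n_replicates number of seeded replicates (default 10).
#' @param target_sims simulated decisions per target (default 75,000).
#' @param space a [fit_space()]; its `sims_per_eval` is the
#'   per-evaluation budget.
#' @param control a [fit_control()].
#' @param base_seed integer; replicate `k` uses target seed
#'   `base_seed * 1000 + k` and fit seed `base_seed * 1000 + 500 + k`.
#' @param bin_width,cap RT histogram convention (seconds).
#' @return Data frame with one row per replicate: recovered radius,
#'   density or epsilon, dt_ms, objective.
#' @export
recovery_experiment <- function(model = c("obstacles", "ddm"), truth = NULL,
                                n_replicates = 10, target_sims = 75000,
                                space = fit_space(), control = fit_control(),
                                base_seed = 1, bin_width = 0.1, cap = 300) {
  model <- match.arg(model)
  if (is.null(truth)) truth <- representative_fits()[[model]]
  stopifnot(model_kind(truth) == model)
  rows <- vector("list", n_replicates)
  for (k in seq_len(n_replicates)) {
    tseed <- (check_seed(base_seed) * 1000 + k) %% 2147483647
    target <- bin_rt(gen_rt_sample(truth, target_sims, tseed), bin_width, cap)
    fit <- fit_model(model, target, space,
                     base_seed = (tseed + 500) %% 2147483647,
                     control = control)
    rows[[k]] <- data.frame(
      replicate = k, radius = fit$params$radius,
      density = if (model == "obstacles") fit$params$density else NA_real_,
      epsilon = if (model == "ddm") fit$params$epsilon else NA_real_,
      dt_ms = fit$params$dt_ms, objective = fit$objective)
  }
  do.call(rbind, rows)
}

# Run expr with a locally seeded R RNG, restoring global state after.
with_local_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Cross-validated model comparison
#'
#' Repeatedly splits the RT sample into train/test sets, fits each model
#' on the training histogram, and scores the fitted model's simulated
#' histogram against the held-out histogram by JSD.  The published
#' protocol uses an 80/20 split repeated 1,000 times; desk-scale runs
#' reduce `repeats` and the simulation budgets.
#'
#' @param samples RT values in seconds (>= 100).
#' @param models character vector of model kinds to compare.
#' @param split_fraction training fraction in (0, 1).
#' @param repeats number of random splits.
#' @param base_seed seed for splits and fits.
#' @param space a [fit_space()].
#' @param control a [fit_control()].
#' @param bin_width,cap histogram convention (seconds).
#' @return List with `mean_jsd` (named per model), `win_fraction`
#'   (fraction of repeats each model achieved the lowest test JSD),
#'   `per_repeat` (data frame of test JSDs), `n_failed`.
#' @export
cross_validate <- function(samples, models = c("obstacles", "ddm"),
                           split_fraction = 0.8, repeats = 1000,
                           base_seed = 1, space = fit_space(),
                           control = fit_control(), bin_width = 0.1,
                           cap = 300) {
  if (length(samples) < 100) {
    stop_gridrt("gridrt_empty_input",
                "need at least 100 samples for cross-validation")
  }
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop_gridrt("gridrt_invalid_parameter",
                "split_fraction must be strictly between 0 and 1")
  }
  n <- length(samples)
  res <- matrix(NA_real_, repeats, length(models),
                dimnames = list(NULL, models))
  n_failed <- 0L
  for (r in seq_len(repeats)) {
    split_seed <- (check_seed(base_seed) * 7919 + r) %% 2147483647
    idx <- with_local_rng(split_seed,
                          sample.int(n, floor(split_fraction * n)))
    train_h <- bin_rt(samples[idx], bin_width, cap)
    test_h <- bin_rt(samples[-idx], bin_width, cap)
    for (mi in seq_along(models)) {
      val <- tryCatch({
        fit <- fit_model(models[[mi]], train_h, space,
                         base_seed = split_seed + mi, control = control)
        objective_jsd(fit$params, test_h, space$sims_per_eval,
                      split_seed + 1000 + mi, control$max_retries)
      }, gridrt_error = function(e) NA_real_)
      if (is.na(val)) n_failed <- n_failed + 1L
      res[r, mi] <- val
    }
  }
  complete <- stats::complete.cases(res)
  winners <- apply(res[complete, , drop = FALSE], 1, which.min)
  win_fraction <- vapply(seq_along(models),
                         function(i) mean(winners == i), numeric(1))
  names(win_fraction) <- models
  list(mean_jsd = colMeans(res, na.rm = TRUE), win_fraction = win_fraction,
       per_repeat = as.data.frame(res), n_failed = n_failed)
}
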