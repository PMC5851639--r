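# Closed-form and exact-numeric first-passage references.  Lengths are in
# the units of the continuum convention J = -dP/dx (diffusion constant 1),
# so the 1-D FPT density to an absorbing point at distance `a` is the
# Levy-Smirnov law a / sqrt(4 pi t^3) * exp(-a^2 / (4 t)).

#' First-passage density, infinite 1-D domain
#'
#' Density of the first-passage time of unit-diffusion Brownian motion
#' to an absorbing threshold at distance `a`, with no other boundary:
#' the Levy-Smirnov density, whose tail decays as `t^(-3/2)`.
#'
#' @param a positive distance from start to threshold.
#' @param t positive time (vectorized).
#' @return Density values.
#' @examples
#' fpt_density_infinite(1, 1)  # exp(-1/4) / sqrt(4 * pi)
#' @export
fpt_density_infinite <- function(a, t) {
  a <- check_number(a, "a", 0, Inf, strict_lo = TRUE)
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop_gridrt("gridrt_invalid_parameter", "`t` must be positive")
  }
  a / sqrt(4 * pi * t^3) * exp(-a^2 / (4 * t))
}

bounded_geometry <- function(x0, xT, xR) {
  if (xR == xT) {
    stop_gridrt("gridrt_invalid_parameter", "xR must differ from xT")
  }
  if (!((x0 > min(xT, xR)) && (x0 < max(xT, xR)))) {
    stop_gridrt("gridrt_invalid_parameter",
                "x0 must lie strictly between xT and xR")
  }
  # measure positions from the reflecting boundary
  list(L = abs(xT - xR), y0 = abs(x0 - xR))
}

# Eigenfunction series: P(y, t) = sum a_n cos(k_n y) exp(-k_n^2 t) on
# [0, L] with reflecting 0 / absorbing L, k_n = (2n+1) pi / (2L),
# a_n = (2/L) cos(k_n y0).  The FPT density is the flux at L.
bounded_series <- function(L, y0, t, tol = 1e-10, max_terms = 1e5,
                           survival = FALSE) {
  out <- numeric(length(t))
  for (i in seq_along(t)) {
    ti <- t[[i]]
    acc <- 0
    n <- 0
    repeat {
      k <- (2 * n + 1) * pi / (2 * L)
      damp <- exp(-k^2 * ti)
      term_bound <- (2 / L) * (if (survival) 1 / k else k) * damp
      if (term_bound < tol || n >= max_terms) break
      sgn <- if (n %% 2 == 0) 1 else -1
      coef <- (2 / L) * cos(k * y0) * sgn
      acc <- acc + coef * (if (survival) damp / k else k * damp)
      n <- n + 1
    }
    out[[i]] <- acc
  }
  out
}

# Method of images for short times: sources at 4mL +/- y0 (sign +) and
# (4m + 2)L -/+ y0 (sign -); the flux at L is the signed sum of
# (L - p) / (2t) * G(L - p, t) over image positions p.
bounded_images <- function(L, y0, t, n_images = 8) {
  gauss <- function(d, ti) exp(-d^2 / (4 * ti)) / sqrt(4 * pi * ti)
  out <- numeric(length(t))
  for (m in seq(-n_images, n_images)) {
    for (p in c(4 * m * L + y0, 4 * m * L - y0)) {
      out <- out + (L - p) / (2 * t) * gauss(L - p, t)
    }
    for (p in c((4 * m + 2) * L - y0, (4 * m + 2) * L + y0)) {
      out <- out - (L - p) / (2 * t) * gauss(L - p, t)
    }
  }
  out
}

# Series term count needed scales as L / sqrt(t); switch to images below
# this time (both forms agree to ~1e-10 around the switch).
bounded_switch_time <- function(L) 0.05 * L^2

#' First-passage density, reflecting + absorbing 1-D domain
#'
#' Density of the first-passage time to an absorbing boundary at `xT`
#' starting from `x0`, with a reflecting boundary at `xR` (unit
#' diffusion).  Uses the eigenfunction series truncated when the next
#' term's sup-norm falls below `tol`, switching to a method-of-images
#' sum at short times where the series converges slowly.  The tail is
#' exponential with rate `(pi / (2 L))^2`, `L = |xT - xR|`.
#'
#' @param x0 starting position, strictly between the boundaries.
#' @param xT absorbing boundary position.
#' @param xR reflecting boundary position.
#' @param t positive times (vectorized).
#' @param tol series truncation tolerance.
#' @return Density values.
#' @export
fpt_density_bounded <- function(x0, xT, xR, t, tol = 1e-10) {
  geo <- bounded_geometry(x0, xT, xR)
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop_gridrt("gridrt_invalid_parameter", "`t` must be positive")
  }
  short <- t < bounded_switch_time(geo$L)
  out <- numeric(length(t))
  if (any(short)) out[short] <- bounded_images(geo$L, geo$y0, t[short])
  if (any(!short)) {
    out[!short] <- bounded_series(geo$L, geo$y0, t[!short], tol = tol)
  }
  out
}

#' @rdname fpt_density_bounded
#' @details `fpt_survival_bounded` gives the survival probability
#'   `S(t) = P(FPT > t)` from the same eigenfunction series.
#' @export
fpt_survival_bounded <- function(x0, xT, xR, t, tol = 1e-12) {
  geo <- bounded_geometry(x0, xT, xR)
  pmin(1, pmax(0, bounded_series(geo$L, geo$y0, t, tol = tol,
                                 survival = TRUE)))
}

#' Exact first-passage pmf on a fixed grid
#'
#' Treats the open interior nodes of `grid` as the transient states of
#' an absorbing Markov chain under the walker's step law (uniform over
#' the four directions, self-loop on obstacle-blocked moves) and
#' returns the exact pmf of the absorption step count from the origin,
#' truncated when the residual transient mass drops below `tol`.
#'
#' @param grid a connected `obstacle_grid`.
#' @param tol residual-mass truncation (default `1e-10`).
#' @param max_steps hard iteration cap.
#' @return Numeric vector `p` where `p[k]` is `P(FPT = k steps)`, with
#'   attribute `residual` (untruncated mass).
#' @export
exact_fpt_markov <- function(grid, tol = 1e-10, max_steps = 1e6) {
  stopifnot(inherits(grid, "obstacle_grid"))
  if (!is_connected(grid)) {
    stop_gridrt("gridrt_connectivity_error",
                "grid origin is sealed off from the absorbing boundary")
  }
  ch <- grid_chain(grid)
  p <- numeric(ch$n)
  p[ch$origin] <- 1
  pmf <- numeric(1024)
  steps <- 0L
  repeat {
    absorbed <- sum(p * ch$a)
    steps <- steps + 1L
    if (steps > length(pmf)) pmf <- c(pmf, numeric(length(pmf)))
    pmf[steps] <- absorbed
    p <- as.numeric(p %*% ch$T)
    if (sum(p) < tol || steps >= max_steps) break
  }
  out <- pmf[seq_len(steps)]
  attr(out, "residual") <- sum(p)
  out
}

#' Exact mean exit time on a fixed grid
#'
#' Solves the discrete exit-time linear system `(I - T) h = 1` for the
#' absorbing chain of [exact_fpt_markov()] and returns the expected
#' number of steps from the origin.
#'
#' @param grid a connected `obstacle_grid`.
#' @return Expected step count (numeric scalar).
#' @export
exact_mean_exit_steps <- function(grid) {
  stopifnot(inherits(grid, "obstacle_grid"))
  if (!is_connected(grid)) {
    stop_gridrt("gridrt_connectivity_error",
                "grid origin is sealed off from the absorbing boundary")
  }
  ch <- grid_chain(grid)
  h <- solve(diag(ch$n) - ch$T, rep(1, ch$n))
  h[[ch$origin]]
}

# Transient transition matrix T, absorption vector a, and origin index
# for the walker chain on the open nodes of a grid.
grid_chain <- function(grid) {
  occ <- grid$occupancy
  R <- grid$radius
  side <- nrow(occ)
  open_lin <- which(occ == 0L)
  n <- length(open_lin)
  id <- integer(length(occ))
  id[open_lin] <- seq_len(n)
  Tm <- matrix(0, n, n)
  a <- numeric(n)
  dirs <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  for (k in seq_len(n)) {
    lin <- open_lin[[k]]
    r <- (lin - 1L) %% side + 1L
    cc <- (lin - 1L) %/% side + 1L
    x <- cc - R - 1L
    y <- r - R - 1L
    for (d in dirs) {
      nx <- x + d[[1]]
      ny <- y + d[[2]]
      if (nx * nx + ny * ny >= R * R) {
        a[[k]] <- a[[k]] + 0.25
      } else if (occ[ny + R + 1L, nx + R + 1L] == 1L) {
        Tm[k, k] <- Tm[k, k] + 0.25
      } else {
        Tm[k, id[(nx + R) * side + ny + R + 1L]] <-
          Tm[k, id[(nx + R) * side + ny + R + 1L]] + 0.25
      }
    }
  }
  list(T = Tm, a = a, n = n, origin = id[R * side + R + 1L])
}

#' Least-squares slope of a log tail
#'
#' Fits `log(y) ~ t` (`scale = "semilog"`, exponential-tail diagnostic)
#' or `log(y) ~ log(t)` (`scale = "loglog"`, power-law diagnostic) by
#' ordinary least squares over the supplied window and returns the
#' slope with its standard error.  `y` may be density or survival
#' values; only positive entries enter the fit.
#'
#' @param t times.
#' @param y positive density or survival values at `t`.
#' @param scale `"semilog"` or `"loglog"`.
#' @return List with `slope`, `stderr`, `n`.
#' @export
tail_log_slope <- function(t, y, scale = c("semilog", "loglog")) {
  scale <- match.arg(scale)
  keep <- is.finite(t) & is.finite(y) & y > 0
  t <- t[keep]
  y <- y[keep]
  if (length(t) < 10) {
    stop_gridrt("gridrt_invalid_window",
                "need at least 10 positive points in the window")
  }
  x <- if (scale == "loglog") log(t) else t
  ly <- log(y)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (ly - mean(ly))) / sxx
  resid <- ly - mean(ly) - slope * (x - mean(x))
  s2 <- sum(resid^2) / max(length(x) - 2, 1)
  list(slope = slope, stderr = sqrt(s2 / sxx), n = length(t))
}

#' Export a density evaluated on a time grid as two-column CSV
#'
#' @param t evaluation times.
#' @param density density values at `t`.
#' @param path output path (columns `t`, `density`).
#' @return `path`, invisibly.
#' @export
density_to_csv <- function(t, density, path) {
  stopifnot(length(t) == length(density))
  utils::write.csv(data.frame(t = t, density = density), path,
                   row.names = FALSE)
  invisible(path)
}

#' Empirical survival function of a sample
#'
#' @param sample numeric sample.
#' @param t evaluation times.
#' @return `P(sample > t)` for each `t`.
#' @export
empirical_survival <- function(sample, t) {
  vapply(t, function(ti) mean(sample > ti), numeric(1))
}
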