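#' Build a disordered-grid realization
#'
#' Generates one realization of the obstacle lattice: a square grid of
#' side `2 * radius + 1` centred on the origin.  Interior nodes are the
#' lattice points with Euclidean distance `< radius` from the origin;
#' every node at distance `>= radius` is absorbing.  Each non-origin
#' interior node is independently a reflecting obstacle with probability
#' `density`.  The origin is never an obstacle.
#'
#' The occupancy matrix is coded `-1` (absorbing exterior), `0` (open)
#' or `1` (obstacle), with row index `y + radius + 1` and column index
#' `x + radius + 1`.  Identical `(radius, density, seed)` give a
#' bit-identical realization.
#'
#' @param radius positive integer boundary radius (grid steps).
#' @param density obstacle probability per interior node, in `[0, 1]`.
#' @param seed non-negative integer driving the realization.
#' @return An object of class `obstacle_grid`.
#' @examples
#' g <- build_grid(4, 0.45, seed = 1)
#' sum(g$occupancy == 1)
#' @export
build_grid <- function(radius, density, seed) {
  radius <- check_positive_int(radius, "radius")
  density <- check_number(density, "density", 0, 1)
  seed <- check_seed(seed)
  occ <- cpp_build_grid(radius, density, seed)
  new_obstacle_grid(radius, occ, density, seed)
}

new_obstacle_grid <- function(radius, occupancy, density, seed,
                              rejected = 0L) {
  structure(
    list(radius = as.integer(radius), occupancy = occupancy,
         density = density, seed = seed, rejected = as.integer(rejected)),
    class = "obstacle_grid"
  )
}

#' Make an `obstacle_grid` from a hand-written occupancy mask
#'
#' Intended for fixtures: validates that the mask is square with odd
#' side, marks the exterior, and forces the origin open.
#'
#' @param occupancy square integer matrix of 0/1 interior codes (entries
#'   outside the circular boundary are overwritten with -1).
#' @return An `obstacle_grid`.
#' @export
grid_from_mask <- function(occupancy) {
  side <- nrow(occupancy)
  if (ncol(occupancy) != side || side %% 2 != 1) {
    stop_gridrt("gridrt_invalid_parameter",
                "occupancy must be a square matrix with odd side")
  }
  radius <- (side - 1L) %/% 2L
  occ <- matrix(-1L, side, side)
  for (r in seq_len(side)) {
    for (cc in seq_len(side)) {
      x <- cc - radius - 1L
      y <- r - radius - 1L
      if (x * x + y * y < radius * radius) {
        occ[r, cc] <- as.integer(occupancy[r, cc] != 0)
      }
    }
  }
  occ[radius + 1L, radius + 1L] <- 0L
  new_obstacle_grid(radius, occ, NA_real_, NA_real_)
}

#' Is the origin connected to the absorbing boundary?
#'
#' `TRUE` iff a 4-neighbour path of open nodes leads from the origin to
#' a node adjacent to the absorbing region (so an absorbing node is
#' reachable in one step).  Dense disorder can seal the origin in, which
#' would make first-passage times infinite.
#'
#' @param grid an `obstacle_grid`.
#' @return Logical scalar.
#' @export
is_connected <- function(grid) {
  stopifnot(inherits(grid, "obstacle_grid"))
  cpp_is_connected(grid$occupancy)
}

#' Sample a connected grid realization
#'
#' Draws seeded realizations at the given parameters and returns the
#' first one that passes [is_connected()].  The number of rejected
#' realizations is recorded in the `rejected` field as a diagnostic.
#'
#' @param params an [obstacles_params()] object.
#' @param seed non-negative integer.
#' @param max_retries maximum number of realizations to try (default
#'   `1e4`); exhaustion raises a `gridrt_connectivity_error` carrying
#'   the rejection count.
#' @return A connected `obstacle_grid`.
#' @export
sample_connected_grid <- function(params, seed, max_retries = 1e4) {
  stopifnot(inherits(params, "obstacles_params"))
  seed <- check_seed(seed)
  max_retries <- check_positive_int(max_retries, "max_retries")
  res <- cpp_sample_connected_grid(params$radius, params$density, seed,
                                   max_retries)
  if (!res$ok) {
    stop_gridrt("gridrt_connectivity_error",
                "no connected realization in %d attempts (R = %d, q = %g)",
                res$rejected, params$radius, params$density,
                data = list(rejected = res$rejected))
  }
  new_obstacle_grid(params$radius, res$occupancy, params$density, seed,
                    rejected = res$rejected)
}

#' Serialize / deserialize a grid as JSON
#'
#' The JSON object holds `radius`, `seed`, `density` and the row-major
#' 0/1/-1 occupancy list, so fixtures are plain text.
#'
#' @param grid an `obstacle_grid`.
#' @param path file path.
#' @return `grid_to_json` returns `path` invisibly; `grid_from_json`
#'   returns an `obstacle_grid`.
#' @export
grid_to_json <- function(grid, path) {
  stopifnot(inherits(grid, "obstacle_grid"))
  obj <- list(
    radius = grid$radius, seed = grid$seed, density = grid$density,
    side = nrow(grid$occupancy),
    occupancy = as.integer(t(grid$occupancy))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname grid_to_json
#' @export
grid_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  occ <- matrix(as.integer(obj$occupancy), nrow = obj$side, byrow = TRUE)
  new_obstacle_grid(obj$radius, occ,
                    if (is.null(obj$density)) NA_real_ else obj$density,
                    if (is.null(obj$seed)) NA_real_ else obj$seed)
}

#' @export
print.obstacle_grid <- function(x, ...) {
  n_obs <- sum(x$occupancy == 1L)
  n_int <- sum(x$occupancy >= 0L)
  cat(sprintf("<obstacle_grid> R = %d, %d/%d interior nodes blocked (%.1f%%)\n",
              x$radius, n_obs, n_int, 100 * n_obs / max(n_int, 1)))
  invisible(x)
}
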