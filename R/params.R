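#' Obstacles-model parameters
#'
#' The obstacles model has three parameters: the radius of the circular
#' absorbing boundary `radius` (in grid-step units), the obstacle
#' density `density` (fraction of non-origin interior lattice nodes that
#' are reflecting obstacles), and the wall-clock cost of one walker
#' iteration `dt_ms` (milliseconds).  `density = 0` recovers a pure
#' Euclidean (obstacle-free) lattice.
#'
#' Density is stored as the *obstacle fraction*: a reported smoothness
#' `rho` under the convention "`rho = 0.45` means 45% of grid points are
#' obstacles" equals `density`; under the complementary convention
#' (`p(obstacle) = 1 - rho`) it equals `1 - density`.  All gridrt
#' reporting uses the obstacle fraction.
#'
#' @param radius positive integer, absorbing-boundary radius in grid steps.
#' @param density obstacle fraction in `[0, 1]`.
#' @param dt_ms positive real, milliseconds per walker iteration.
#' @return An object of class `obstacles_params`.
#' @examples
#' obstacles_params(4, 0.45, 90)
#' @export
obstacles_params <- function(radius, density, dt_ms) {
  structure(
    list(
      radius = check_positive_int(radius, "radius"),
      density = check_number(density, "density", 0, 1),
      dt_ms = check_number(dt_ms, "dt_ms", 0, Inf, strict_lo = TRUE)
    ),
    class = c("obstacles_params", "gridrt_params")
  )
}

#' Grid drift-diffusion-model parameters
#'
#' The grid DDM has three parameters: the absorbing-boundary radius
#' `radius` (grid steps), the acceptance noise `epsilon` (small values
#' give a strong outward drift, large values recover the unbiased walk),
#' and the time per iteration `dt_ms` (milliseconds).
#'
#' @param radius positive integer, absorbing-boundary radius in grid steps.
#' @param epsilon positive real acceptance noise.
#' @param dt_ms positive real, milliseconds per walker iteration.
#' @return An object of class `ddm_params`.
#' @examples
#' ddm_params(8, 0.2, 60)
#' @export
ddm_params <- function(radius, epsilon, dt_ms) {
  structure(
    list(
      radius = check_positive_int(radius, "radius"),
      epsilon = check_number(epsilon, "epsilon", 0, Inf, strict_lo = TRUE),
      dt_ms = check_number(dt_ms, "dt_ms", 0, Inf, strict_lo = TRUE)
    ),
    class = c("ddm_params", "gridrt_params")
  )
}

#' Model kind of a parameter object
#'
#' @param params an `obstacles_params` or `ddm_params` object.
#' @return `"obstacles"` or `"ddm"`.
#' @export
model_kind <- function(params) {
  if (inherits(params, "obstacles_params")) return("obstacles")
  if (inherits(params, "ddm_params")) return("ddm")
  stop_gridrt("gridrt_invalid_parameter",
              "`params` must be an obstacles_params or ddm_params object")
}

#' Build a parameter object from a model kind and plain values
#'
#' @param model `"obstacles"` or `"ddm"`.
#' @param radius,dt_ms shared parameters.
#' @param density obstacle fraction (obstacles model).
#' @param epsilon acceptance noise (DDM).
#' @return A parameter object of the requested kind.
#' @export
make_params <- function(model = c("obstacles", "ddm"), radius, density = NULL,
                        epsilon = NULL, dt_ms) {
  model <- match.arg(model)
  if (model == "obstacles") {
    obstacles_params(radius, density, dt_ms)
  } else {
    ddm_params(radius, epsilon, dt_ms)
  }
}

#' The representative mid-game best-fit parameter triples
#'
#' Published fits of the two models to the pooled blitz-chess RT
#' distribution at 50% of the game: obstacles model `R = 4`, obstacle
#' fraction `0.45`, `dt = 90` ms; grid DDM `R = 8`, `epsilon = 0.2`,
#' `dt = 60` ms.  These are the anchors used by the parameter-recovery
#' experiments.
#'
#' @return Named list with elements `obstacles` and `ddm`.
#' @export
representative_fits <- function() {
  list(
    obstacles = obstacles_params(4, 0.45, 90),
    ddm = ddm_params(8, 0.2, 60)
  )
}

#' @export
print.gridrt_params <- function(x, ...) {
  kind <- model_kind(x)
  vals <- vapply(x, function(v) format(v), character(1))
  cat(sprintf("<%s model> %s\n", kind,
              paste(names(x), vals, sep = " = ", collapse = ", ")))
  invisible(x)
}
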