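#' Warp specification
#'
#' Parameters of the efficient-coding (boundary-attraction) warp of the
#' direction axis: more neurons are allocated near the horizontal boundary.
#'
#' @param a Warp amplitude (dimensionless, >= 0): how strongly the observer's
#'   population over-represents the boundary region. `a = 0` (or `w_b = 0`)
#'   gives a uniform density, i.e. no warping and unbiased likelihoods.
#' @param w_b Width (degrees, >= 0) of the region over which tuning curves are
#'   drawn toward the boundary.
#' @param sigma_b Edge softness (degrees, > 0) of the density template.
#' @return An object of class `warp_spec`.
#' @export
warp_spec <- function(a = 1, w_b = 20, sigma_b = 3) {
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0)
    stop("'a' must be a single non-negative number")
  if (!is.numeric(w_b) || length(w_b) != 1L || is.na(w_b) || w_b < 0)
    stop("'w_b' must be a single non-negative number")
  if (!is.numeric(sigma_b) || length(sigma_b) != 1L || is.na(sigma_b) || sigma_b <= 0)
    stop("'sigma_b' must be a single positive number")
  structure(list(a = a, w_b = w_b, sigma_b = sigma_b), class = "warp_spec")
}

# Unnormalized cell-density template: a pedestal plus an amplitude-scaled
# soft boxcar of width w_b centred on the boundary, with cumulative-Gaussian
# edges of SD sigma_b. At the boundary h ~ 2 + a, far away h -> 2. With a = 0
# or w_b = 0 the density is uniform and the warp is the identity (likelihoods
# then symmetric and unbiased).
warp_density_raw <- function(s, warp) {
  2 + warp$a *
    (stats::pnorm(s, mean = -warp$w_b / 2, sd = warp$sigma_b) -
       stats::pnorm(s, mean = warp$w_b / 2, sd = warp$sigma_b))
}

#' Build the warp: normalized cell density and cumulative warp map
#'
#' The cell density says how densely neurons tile each part of the direction
#' axis; its cumulative integral, rescaled to the full cycle, is a monotone
#' bijection of the direction domain (the warp map). The map expands the axis
#' where density is high (near the boundary), so equally spaced neurons in the
#' homogeneous coordinate end up densely packed near 0 degrees in stimulus
#' space.
#'
#' @param warp A [warp_spec()].
#' @param grid A [direction_grid()].
#' @param extra_density Optional extra unnormalized density evaluated on
#'   `grid$values`, added to the template before normalization (used by the
#'   tuning-change model variant).
#' @return A list with `density` (normalized to unit integral on the grid),
#'   `map` (warped coordinate of each grid point, a monotone bijection of
#'   `(-180, 180]`), and `grid`.
#' @examples
#' w <- build_warp(warp_spec(a = 0, w_b = 20, sigma_b = 2), direction_grid(0.5))
#' sum(w$density) * 0.5  # integrates to 1
#' @export
build_warp <- function(warp, grid, extra_density = NULL) {
  stopifnot(inherits(warp, "warp_spec"), inherits(grid, "direction_grid"))
  s <- grid$values
  h <- warp_density_raw(s, warp)
  if (!is.null(extra_density)) {
    stopifnot(length(extra_density) == length(s), all(extra_density >= 0))
    h <- h + extra_density
  }
  dens <- h / (sum(h) * grid$step)
  # Cumulative integral (midpoint rule), rescaled so the map spans
  # (-180, 180]. The density template is symmetric about the boundary, so the
  # map is explicitly symmetrized (made odd) to kill the half-cell offset of
  # the grid; this pins map(0) = 0 exactly.
  cum <- cumsum(dens) - dens / 2
  cum <- cum / (cum[length(cum)] + dens[length(dens)] / 2)
  map <- -180 + 360 * cum
  n <- length(map)
  k <- seq_len(n - 1L)
  map <- c((map[k] - map[n - k]) / 2, 180)
  list(density = dens, map = map, grid = grid)
}

# Identity warp (homogeneous population), same structure as build_warp().
identity_warp <- function(grid) {
  list(density = rep(1 / 360, length(grid$values)), map = grid$values,
       grid = grid)
}

# Inverse of the warp map at homogeneous coordinates u (monotone interpolation).
warp_map_inverse <- function(warp_built, u) {
  stats::approx(x = warp_built$map, y = warp_built$grid$values, xout = u,
                rule = 2)$y
}
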