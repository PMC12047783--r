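#' Shared (across-observer) model parameters
#'
#' @param n Number of neurons in the encoding population (default 10).
#' @param w_t Tuning-curve full width at half maximum, degrees (default 71),
#'   measured on the above-baseline response in the homogeneous (unwarped)
#'   coordinate.
#' @param b Baseline firing rate, spikes per trial (default 0.5).
#' @param sigma_m Motor-noise SD, degrees (default 2).
#' @param sigma_g SD of the Gaussian post-training gain profile over preferred
#'   directions, degrees (default 4).
#' @return An object of class `shared_params`.
#' @export
shared_params <- function(n = 10, w_t = 71, b = 0.5, sigma_m = 2, sigma_g = 4) {
  stopifnot(n >= 2, n == round(n), w_t > 0, b >= 0, sigma_m >= 0, sigma_g > 0)
  structure(list(n = as.integer(n), w_t = w_t, b = b, sigma_m = sigma_m,
                 sigma_g = sigma_g),
            class = "shared_params")
}

#' Per-observer model parameters
#'
#' The six per-observer parameters (warp amplitude `a`, boundary width `w_b`,
#' edge softness `sigma_b`, pre-training gain `g_pre`, peak post-training gain
#' `g_post`, lapse `lambda`) together with the shared parameters.
#'
#' @param warp A [warp_spec()] (holds `a`, `w_b`, `sigma_b`).
#' @param g_pre Pre-training gain, spikes/trial above baseline (> 0); identical
#'   for all neurons before training.
#' @param g_post Peak post-training gain (>= g_pre for learning variants; the
#'   gain of the most responsive neuron after training).
#' @param lambda Lapse parameter in \[0, 1\].
#' @param shared A [shared_params()].
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(warp = warp_spec(), g_pre = 10, g_post = g_pre,
                            lambda = 0, shared = shared_params()) {
  stopifnot(inherits(warp, "warp_spec"), inherits(shared, "shared_params"))
  if (!is.numeric(g_pre) || length(g_pre) != 1L || g_pre <= 0)
    stop("'g_pre' must be a single positive number")
  if (!is.numeric(g_post) || length(g_post) != 1L || g_post < g_pre)
    stop("'g_post' must be a single number >= g_pre")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
    stop("'lambda' must lie in [0, 1]")
  structure(list(warp = warp, g_pre = g_pre, g_post = g_post,
                 lambda = lambda, shared = shared),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf(paste0("<observer_params> a=%.3g w_b=%.3g sigma_b=%.3g ",
                     "g_pre=%.3g g_post=%.3g lambda=%.3g (n=%d, w_t=%g)\n"),
              x$warp$a, x$warp$w_b, x$warp$sigma_b, x$g_pre, x$g_post,
              x$lambda, x$shared$n, x$shared$w_t))
  invisible(x)
}

# Exponent p such that the single-cycle raised-cosine bump cos^2(s/2)^p has
# the requested FWHM (degrees). Solved numerically; closed form exists but the
# numeric root keeps the FWHM the binding constraint.
tuning_exponent <- function(fwhm) {
  stopifnot(fwhm > 0, fwhm < 360)
  f <- function(p) 4 * acos(0.5^(1 / (2 * p))) * 180 / pi - fwhm
  stats::uniroot(f, c(1e-3, 1e3), tol = 1e-12)$root
}

# Canonical (unit-peak) tuning bump at angular offset delta (degrees, any
# range; wrapped internally). Single cycle of cos^2 raised to a power; support
# is the full cycle, peak 1 at delta = 0.
tuning_bump <- function(delta, fwhm = 71) {
  p <- tuning_exponent(fwhm)
  cos((wrap_angle(delta)) * pi / 360)^(2 * p)
}

#' Build the encoding/decoding tuning population
#'
#' Neuron anchors are equally spaced in the homogeneous coordinate over the
#' full cycle, phase-offset to straddle the boundary symmetrically. The
#' *encoding* curves are the canonical bumps
#' evaluated at the warped grid positions, so neurons crowd near the boundary;
#' session `"post"` elevates gains by a Gaussian profile over preferred
#' directions, centred at 0 with SD `sigma_g`, peaking at `g_post`. The
#' *decoding* curves are what the (unaware) decoder assumes: identity warp and
#' pre-training gains, for every session.
#'
#' @param params An [observer_params()].
#' @param session `"pre"` or `"post"`.
#' @param grid A [direction_grid()].
#' @param warp_built Optional precomputed [build_warp()] result (for the
#'   encoding side); defaults to building from `params$warp`. Pass
#'   [identity_warp()] output to disable warping (no-boundary-avoidance
#'   variant).
#' @param gain_change If `FALSE`, post-training gains are tied to `g_pre`
#'   (no-gain-change / tuning-change variants).
#' @return An object of class `tuning_population`: list with `anchors`
#'   (homogeneous coordinate), `preferred` (stimulus-space preferred
#'   directions), `gains`, `tuning_encode` and `tuning_decode` (n x grid
#'   matrices of mean rates, all >= baseline `b`), `log_decode` (floored log of
#'   the decode curves), `grid`, `session`, and `params`.
#' @export
build_population <- function(params, session = c("pre", "post"), grid,
                             warp_built = NULL, gain_change = TRUE) {
  session <- match.arg(session)
  stopifnot(inherits(params, "observer_params"), inherits(grid, "direction_grid"))
  sh <- params$shared
  if (is.null(warp_built)) warp_built <- build_warp(params$warp, grid)
  # Equally spaced in the homogeneous coordinate, phase-offset so the
  # population straddles the boundary symmetrically (no neuron at 0 or 180):
  # the neurons boosted by training then flank the trained directions.
  anchors <- -180 + (seq_len(sh$n) - 0.5) * 360 / sh$n
  preferred <- warp_map_inverse(warp_built, anchors)

  gains <- rep(params$g_pre, sh$n)
  if (session == "post" && gain_change) {
    prof <- exp(-preferred^2 / (2 * sh$sigma_g^2))
    # normalized so the most responsive neuron's gain is exactly g_post
    gains <- params$g_pre + (params$g_post - params$g_pre) * prof / max(prof)
  }

  # n x G matrices of mean rates
  offs_enc <- outer(anchors, warp_built$map, function(u, m) m - u)
  bump_enc <- tuning_bump(offs_enc, sh$w_t)
  tuning_encode <- sh$b + gains * bump_enc

  offs_dec <- outer(anchors, grid$values, function(u, s) s - u)
  bump_dec <- tuning_bump(offs_dec, sh$w_t)
  tuning_decode <- sh$b + params$g_pre * bump_dec

  structure(list(anchors = anchors, preferred = preferred, gains = gains,
                 tuning_encode = tuning_encode,
                 tuning_decode = tuning_decode,
                 log_decode = log(pmax(tuning_decode, 1e-12)),
                 grid = grid, session = session, params = params),
            class = "tuning_population")
}

#' @export
print.tuning_population <- function(x, ...) {
  cat(sprintf("<tuning_population> %d neurons, session %s, grid step %g deg\n",
              nrow(x$tuning_encode), x$session, x$grid$step))
  invisible(x)
}

#' Numerically measure the FWHM of a tuning curve
#'
#' Width (degrees) of the region where the above-baseline response exceeds
#' half its peak, measured on the curve's own grid by linear interpolation of
#' the half-maximum crossings.
#'
#' @param rate Mean-rate vector over `grid$values`.
#' @param grid The [direction_grid()] the curve lives on.
#' @param baseline Baseline rate subtracted before measuring (default 0).
#' @return FWHM in degrees.
#' @export
measure_fwhm <- function(rate, grid, baseline = 0) {
  y <- rate - baseline
  s <- grid$values
  half <- max(y) / 2
  above <- y >= half
  idx <- which(above)
  stopifnot(length(idx) > 1, idx[1] > 1, idx[length(idx)] < length(y))
  i1 <- idx[1]; i2 <- idx[length(idx)]
  # interpolate the two crossings
  xl <- s[i1 - 1] + (half - y[i1 - 1]) / (y[i1] - y[i1 - 1]) * grid$step
  xr <- s[i2] + (half - y[i2]) / (y[i2 + 1] - y[i2]) * grid$step
  xr - xl
}
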