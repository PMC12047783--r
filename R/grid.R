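#' Direction grid for the observer model
#'
#' Constructs the discrete space of motion directions on which tuning curves,
#' likelihoods and posteriors are evaluated: a uniform grid covering one full
#' cycle, `(-180, 180]` degrees, containing 0 (the discrimination boundary,
#' rightward horizontal). Positive directions are clockwise (upward) of
#' horizontal after the collapsing convention.
#'
#' @param step Grid step in degrees (default 0.1).
#' @return An object of class `direction_grid`: a list with `values` (ordered
#'   directions), `step`, and `boundary` (always 0).
#' @examples
#' g <- direction_grid(0.5)
#' range(g$values)
#' @export
direction_grid <- function(step = 0.1) {
  stopifnot(is.numeric(step), length(step) == 1L, step > 0)
  k <- round(360 / step)
  if (abs(360 / step - k) > 1e-9)
    stop("'step' must divide 360 evenly")
  values <- seq_len(k) * step - 180
  structure(list(values = values, step = step, boundary = 0),
            class = "direction_grid")
}

#' @export
print.direction_grid <- function(x, ...) {
  cat(sprintf("<direction_grid> %d points on (-180, 180], step %g deg\n",
              length(x$values), x$step))
  invisible(x)
}

# Wrap angles (degrees) to (-180, 180].
wrap_angle <- function(x) {
  w <- (x + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}
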