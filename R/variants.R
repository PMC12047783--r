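#' Model variants: full, reduced, and tuning-change alternatives
#'
#' Builds the constraint structure for one of the model variants compared in
#' the analysis:
#' * `full` -- all mechanisms (warp, conditional inference, gain change).
#' * `no_GC` -- no gain change: `g_post` tied to `g_pre`.
#' * `no_BA` -- no boundary avoidance: identity warp (no efficient coding).
#' * `no_CI` -- no conditional inference: estimates are unconditional
#'   posterior means over the full direction domain.
#' * `TC` -- tuning change: gains tied across sessions, but the post-training
#'   cell density gains additive Gaussian bumps at the trained directions
#'   (+/-4 deg) with fitted amplitude `A_tc` and width `sigma_tc` (the decoder
#'   stays unaware).
#' * `TC_reduced` -- `TC` with the bump width fixed at 4 degrees.
#'
#' Each variant carries its free-parameter names and box bounds, maps between
#' free vectors and [observer_params()], and knows how to build the session's
#' encoding population.
#'
#' @param name Variant name (see above).
#' @param shared A [shared_params()] used by all populations the variant
#'   builds.
#' @return An object of class `model_variant`: list with `name`, `free`,
#'   `lower`, `upper`, `conditional`, `theta_to_params`, `params_to_theta`,
#'   `make_pop`.
#' @export
make_variant <- function(name = c("full", "no_GC", "no_BA", "no_CI",
                                  "TC", "TC_reduced"),
                         shared = shared_params()) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("full", "no_GC", "no_BA", "no_CI", "TC", "TC_reduced"))
    stop("unknown variant; valid names: full, no_GC, no_BA, no_CI, TC, TC_reduced")

  bounds <- list(a = c(0, 100), w_b = c(0, 90), sigma_b = c(0.5, 30),
                 g_pre = c(1, 100), dg = c(0, 280), lambda = c(0, 0.5),
                 A_tc = c(0, 50), sigma_tc = c(1, 10))
  free <- switch(name,
    full = c("a", "w_b", "sigma_b", "g_pre", "dg", "lambda"),
    no_CI = c("a", "w_b", "sigma_b", "g_pre", "dg", "lambda"),
    no_GC = c("a", "w_b", "sigma_b", "g_pre", "lambda"),
    no_BA = c("g_pre", "dg", "lambda"),
    TC = c("a", "w_b", "sigma_b", "g_pre", "lambda", "A_tc", "sigma_tc"),
    TC_reduced = c("a", "w_b", "sigma_b", "g_pre", "lambda", "A_tc"))

  lower <- vapply(free, function(f) bounds[[f]][1], numeric(1))
  upper <- vapply(free, function(f) bounds[[f]][2], numeric(1))

  get <- function(theta, nm, default = 0) {
    i <- match(nm, free)
    if (is.na(i)) default else theta[[i]]
  }

  theta_to_params <- function(theta) {
    stopifnot(length(theta) == length(free))
    warp <- if (name == "no_BA") warp_spec(0, 0.001, 1) else
      warp_spec(get(theta, "a"), get(theta, "w_b"),
                max(get(theta, "sigma_b", 1), 0.5))
    g_pre <- get(theta, "g_pre", 10)
    g_post <- g_pre + get(theta, "dg", 0)
    observer_params(warp, g_pre = g_pre, g_post = g_post,
                    lambda = get(theta, "lambda"), shared = shared)
  }

  params_to_theta <- function(p) {
    vals <- c(a = p$warp$a, w_b = p$warp$w_b, sigma_b = p$warp$sigma_b,
              g_pre = p$g_pre, dg = p$g_post - p$g_pre, lambda = p$lambda,
              A_tc = 0, sigma_tc = 4)
    unname(vals[free])
  }

  make_pop <- function(theta, session, grid) {
    prm <- theta_to_params(theta)
    gain_change <- name %in% c("full", "no_CI", "no_BA")
    if (name %in% c("TC", "TC_reduced") && session == "post") {
      A <- get(theta, "A_tc")
      s_tc <- if (name == "TC") get(theta, "sigma_tc") else 4
      extra <- A * (stats::dnorm(grid$values, 4, s_tc) +
                      stats::dnorm(grid$values, -4, s_tc))
      wb <- build_warp(prm$warp, grid, extra_density = extra)
      build_population(prm, "post", grid, warp_built = wb,
                       gain_change = FALSE)
    } else {
      wb <- if (name == "no_BA") identity_warp(grid) else
        build_warp(prm$warp, grid)
      build_population(prm, session, grid, warp_built = wb,
                       gain_change = gain_change)
    }
  }

  structure(list(name = name, free = free, lower = lower, upper = upper,
                 conditional = name != "no_CI", shared = shared,
                 theta_to_params = theta_to_params,
                 params_to_theta = params_to_theta,
                 make_pop = make_pop),
            class = "model_variant")
}

#' @export
print.model_variant <- function(x, ...) {
  cat(sprintf("<model_variant> %s: free = %s\n", x$name,
              paste(x$free, collapse = ", ")))
  invisible(x)
}
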