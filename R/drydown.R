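# Epidermal (minimum) conductance from fresh-weight drydown kinetics.
#
# After detachment in the dark the leaf first loses water through closing
# stomata (steep phase), then through the cuticle/epidermis alone (linear
# tail). The tail slope, leaf area and leaf-air absolute humidity
# difference give the epidermal conductance via
# ge = 2.31e6 * |dw/dt| / (A * de), with the published conversion factor
# 2.31e6 treated as given (its exact unit derivation is not stated with
# the equation; de is consumed in the equation's own units).

#' Timed fresh-weight series of a darkened drying leaf
#'
#' @param times Weighing times, s, strictly increasing.
#' @param fresh_weights Fresh weights, g.
#' @param leaf_area Leaf area, m^2.
#' @param delta_e Leaf-air absolute humidity difference (equation units).
#' @param saturated_weight,dry_weight Saturated and oven-dry weights, g.
#' @return A validated list of class `mass_loss_series`.
#' @export
mass_loss_series <- function(times, fresh_weights, leaf_area, delta_e,
                             saturated_weight, dry_weight) {
  stopifnot(length(times) == length(fresh_weights))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (dry_weight >= min(fresh_weights))
    stop("dry weight must be below all fresh weights")
  if (any(fresh_weights > saturated_weight + 1e-9))
    stop("fresh weights must not exceed the saturated weight")
  if (leaf_area <= 0) stop("leaf_area must be positive")
  structure(list(times = as.numeric(times),
                 fresh_weights = as.numeric(fresh_weights),
                 leaf_area = leaf_area, delta_e = delta_e,
                 saturated_weight = saturated_weight, dry_weight = dry_weight),
            class = "mass_loss_series")
}

#' Fit the two-phase drydown model and locate the epidermal tail
#'
#' Fits every admissible two-segment piecewise-linear model (each segment
#' holding at least three points) to weight vs time by ordinary least
#' squares and keeps the breakpoint minimizing total squared error. The
#' later segment is the post-stomatal-closure (epidermal) phase; its OLS
#' slope is the water-loss rate used by [epidermal_conductance()].
#'
#' @param series A [mass_loss_series()] with at least 6 observations.
#' @return Object of class `drydown_fit`: list with `tail_slope` (g s-1,
#'   negative), `tail_range` (index range of the tail), `breakpoint`
#'   (last index of the stomatal phase), segment fits, `sse` and the
#'   series itself.
#' @export
detect_epidermal_phase <- function(series) {
  stopifnot(inherits(series, "mass_loss_series"))
  t <- series$times; w <- series$fresh_weights
  n <- length(t)
  if (n < 6L) stop("need at least 6 observations to separate the phases")
  ols <- function(i) {
    f <- stats::lm.fit(cbind(1, t[i]), w[i])
    list(coef = f$coefficients, sse = sum(f$residuals^2))
  }
  best <- NULL
  for (k in 3:(n - 3L)) {
    a <- ols(1:k); b <- ols((k + 1L):n)
    sse <- a$sse + b$sse
    if (is.null(best) || sse < best$sse)
      best <- list(breakpoint = k, sse = sse, head = a, tail = b)
  }
  structure(list(
    breakpoint = best$breakpoint,
    tail_range = c(best$breakpoint + 1L, n),
    tail_slope = unname(best$tail$coef[2L]),
    tail_intercept = unname(best$tail$coef[1L]),
    head_slope = unname(best$head$coef[2L]),
    sse = best$sse,
    series = series
  ), class = "drydown_fit")
}

#' @export
print.drydown_fit <- function(x, ...) {
  cat("Two-phase drydown fit\n")
  cat(sprintf("  breakpoint after observation %d of %d\n",
              x$breakpoint, length(x$series$times)))
  cat(sprintf("  stomatal-phase slope : %.3e g s-1\n", x$head_slope))
  cat(sprintf("  epidermal tail slope : %.3e g s-1 (obs %d..%d)\n",
              x$tail_slope, x$tail_range[1L], x$tail_range[2L]))
  invisible(x)
}

#' @export
plot.drydown_fit <- function(x, ...) {
  s <- x$series
  graphics::plot(s$times, s$fresh_weights, xlab = "time (s)",
                 ylab = "fresh weight (g)", ...)
  i <- x$tail_range[1L]:x$tail_range[2L]
  graphics::abline(x$tail_intercept, x$tail_slope, lty = 2)
  graphics::points(s$times[i], s$fresh_weights[i], pch = 16)
  invisible(x)
}

#' Epidermal conductance from the drydown tail
#'
#' ge = 2.31e6 * |slope| / (A * de), homogeneous of degree -1 in both
#' leaf area and humidity difference.
#'
#' @param series A [mass_loss_series()].
#' @param fit Optional precomputed [detect_epidermal_phase()] fit.
#' @return ge in the equation's units (mmol m-2 s-1 scale), with
#'   attribute `fit` carrying the phase fit.
#' @examples
#' s <- generate_mass_loss_series(ge_true = 231, noise_sd = 0)
#' epidermal_conductance(s)
#' @export
epidermal_conductance <- function(series, fit = NULL) {
  stopifnot(inherits(series, "mass_loss_series"))
  if (series$leaf_area <= 0) stop("leaf area must be positive")
  if (series$delta_e <= 0) stop("delta_e must be positive")
  if (is.null(fit)) fit <- detect_epidermal_phase(series)
  ge <- 2.31e6 * abs(fit$tail_slope) / (series$leaf_area * series$delta_e)
  attr(ge, "fit") <- fit
  ge
}

#' Leaf-air absolute humidity difference from temperature and humidity
#'
#' Optional helper, kept separate from [epidermal_conductance()] because
#' the conductance equation consumes `delta_e` in its own (non-SI) units.
#' Saturation vapor pressure via the Tetens formula; vapor density from
#' the ideal-gas law. The leaf interior is assumed saturated at leaf
#' temperature.
#'
#' @param temp_leaf,temp_air Temperatures, deg C.
#' @param rh_air Air relative humidity, fraction in [0, 1].
#' @return Absolute humidity difference, g m-3.
#' @export
absolute_humidity_difference <- function(temp_leaf, temp_air = temp_leaf,
                                         rh_air) {
  stopifnot(rh_air >= 0, rh_air <= 1)
  vap_density <- function(tc, frac) {
    es_pa <- 610.8 * exp(17.27 * tc / (tc + 237.3))
    1000 * frac * es_pa / (461.5 * (tc + 273.15))   # g m-3
  }
  vap_density(temp_leaf, 1) - vap_density(temp_air, rh_air)
}
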