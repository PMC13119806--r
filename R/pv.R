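# Pressure-volume curve analysis.
#
# During a bench drydown, leaf water potential (measured as pressure-
# chamber balance pressure, psi = -P) is recorded against fresh weight.
# In the transformed plane x = 1 - RWC, y = 1/psi, the purely osmotic
# region below the turgor loss point is linear; the fit extrapolates the
# osmotic potential at full saturation (1/intercept), reads the
# apoplastic water fraction off the x-intercept, and takes the turgor
# loss point at the wettest observation still on the line. The linear
# region is selected automatically by growing the point set from the
# driest observation while the fit stays linear (R^2 threshold and a
# residual gate for the next candidate point) - these selection
# thresholds are this package's own, documented choices.

#' Pressure-volume observation sequence
#'
#' @param balance_pressure Positive balance pressures, MPa (psi = -P).
#' @param fresh_weight Fresh weights, g, non-increasing along the series.
#' @param saturated_weight,dry_weight Saturated and oven-dry weights, g.
#' @return A validated list of class `pv_curve`.
#' @export
pv_curve <- function(balance_pressure, fresh_weight, saturated_weight,
                     dry_weight) {
  stopifnot(length(balance_pressure) == length(fresh_weight))
  if (any(balance_pressure <= 0))
    stop("balance pressures must be positive (pressure-chamber convention)")
  if (any(diff(fresh_weight) > 1e-9))
    stop("fresh weights must be non-increasing along the series")
  if (saturated_weight <= dry_weight)
    stop("saturated weight must exceed dry weight")
  structure(list(balance_pressure = as.numeric(balance_pressure),
                 fresh_weight = as.numeric(fresh_weight),
                 saturated_weight = saturated_weight,
                 dry_weight = dry_weight),
            class = "pv_curve")
}

#' Fit pressure-volume parameters
#'
#' Transforms the observations to (x = 1 - RWC, y = -1/P), selects the
#' post-turgor-loss linear region by growing the accepted set from the
#' driest point towards wetter ones; a candidate is admitted while the
#' enlarged OLS fit keeps R^2 at or above `r2_min` or the candidate's
#' residual stays within `resid_k` times the current RMSE (the RMSE band
#' alone is unstable for very small regions). Growth stops at the first
#' point failing both. The fit then derives:
#' \itemize{
#'   \item `psi_sat` = 1/intercept (osmotic potential at full saturation);
#'   \item `apoplastic_fraction` = 1 - x0 where the line crosses y = 0;
#'   \item `rwc_tlp` = RWC of the wettest accepted point (or the midpoint
#'     to the next wetter observation with `interpolate = TRUE`);
#'   \item `psi_tlp` = the osmotic line evaluated at `rwc_tlp`.
#' }
#'
#' @param curve A [pv_curve()] with at least 6 observations.
#' @param r2_min Minimum R^2 to keep growing the region (default 0.99).
#' @param resid_k Residual gate in RMSE multiples (default 2.5).
#' @param min_points Minimum points in the region (default 3).
#' @param interpolate Report the turgor loss point midway to the next
#'   wetter observation instead of at the wettest accepted point.
#' @return Object of class `pv_fit` with the fitted parameters, the
#'   osmotic line (slope/intercept), the accepted region and the
#'   transformed data.
#' @examples
#' cv <- generate_pv_curve(pv_gen_params(noise_sd = 0), seed = 1)
#' fit_pv(cv)
#' @export
fit_pv <- function(curve, r2_min = 0.99, resid_k = 2.5, min_points = 3L,
                   interpolate = FALSE) {
  stopifnot(inherits(curve, "pv_curve"))
  n <- length(curve$balance_pressure)
  if (n < 6L) stop("need at least 6 pressure-volume observations")
  rwc <- relative_water_content(curve$fresh_weight, curve$saturated_weight,
                                curve$dry_weight)
  ord <- order(rwc)                       # driest first
  x <- (1 - rwc)[ord]
  y <- (-1 / curve$balance_pressure)[ord]
  ols <- function(i) {
    f <- stats::lm.fit(cbind(1, x[i]), y[i])
    ssr <- sum(f$residuals^2)
    sst <- sum((y[i] - mean(y[i]))^2)
    list(a = unname(f$coefficients[1L]), b = unname(f$coefficients[2L]),
         r2 = if (sst > 0) 1 - ssr / sst else 1,
         rmse = sqrt(ssr / max(length(i) - 2L, 1L)),
         k = length(i), xbar = mean(x[i]),
         sxx = sum((x[i] - mean(x[i]))^2))
  }
  if (stats::sd(x[seq_len(min_points)]) == 0)
    stop("no linear osmotic region found: the driest observations do not ",
         "span distinct relative water contents")
  region <- seq_len(as.integer(min_points))
  fit <- ols(region)
  pres <- -1 / y                          # balance pressures, driest first
  # residuals are gated in the pressure domain, where chamber noise is
  # homoscedastic (the 1/psi transform inflates it at the wet end)
  presid <- function(fit, i) {
    yhat <- fit$a + fit$b * x[i]
    ifelse(yhat < 0, abs(pres[i] - (-1 / yhat)), Inf)
  }
  prmse <- function(fit, i)
    sqrt(sum(presid(fit, i)^2) / max(length(i) - 2L, 1L))
  # pilot noise scale over the driest points (exactly linear there),
  # stabilizing the band while the accepted region is still small
  sigma0 <- prmse(ols(seq_len(min(6L, n))), seq_len(min(6L, n)))
  # grow towards wetter points; isolated outliers are skipped, and growth
  # stops once departures become systematic (two consecutive rejections,
  # the signature of turgor onset)
  cand <- max(region)
  miss <- 0L
  while (cand < n && miss < 2L) {
    cand <- cand + 1L
    # band scales with the prediction standard error so that small,
    # extrapolating regions are not miscalibrated
    pred_fac <- sqrt(1 + 1 / fit$k + (x[cand] - fit$xbar)^2 / fit$sxx)
    band <- resid_k * max(prmse(fit, region), sigma0) * pred_fac + 1e-10
    if (presid(fit, cand) <= band) {
      region <- c(region, cand)
      fit <- ols(region)
      miss <- 0L
    } else miss <- miss + 1L
  }
  k <- max(region)
  if (fit$r2 < r2_min)
    warning("osmotic line R^2 = ", signif(fit$r2, 4), " below ", r2_min,
            "; the pressure-volume data are noisy or barely span the ",
            "post-turgor-loss region")
  if (fit$a >= 0)
    stop("osmotic line intercept is non-negative (implies psi_sat >= 0); ",
         "check that the curve spans the post-turgor-loss region ",
         "(intercept = ", signif(fit$a, 4), ", region size = ", k, ")")
  psi_sat <- 1 / fit$a
  x0 <- -fit$a / fit$b
  af <- 1 - x0
  rwc_sorted <- rwc[ord]
  rwc_tlp <- rwc_sorted[k]
  if (interpolate && k < n) rwc_tlp <- mean(c(rwc_sorted[k], rwc_sorted[k + 1L]))
  psi_tlp <- 1 / (fit$a + fit$b * (1 - rwc_tlp))
  structure(list(
    psi_sat = psi_sat, psi_tlp = psi_tlp, rwc_tlp = rwc_tlp,
    apoplastic_fraction = af,
    slope = fit$b, intercept = fit$a, r2 = fit$r2,
    n_points_on_line = length(region), n_obs = n,
    data = data.frame(rwc = rwc_sorted, x = x, y = y,
                      on_line = seq_len(n) %in% region),
    call = match.call()
  ), class = "pv_fit")
}

#' @export
print.pv_fit <- function(x, ...) {
  cat("Pressure-volume fit\n")
  cat(sprintf("  psi_sat  : %7.3f MPa (osmotic potential at full turgor)\n",
              x$psi_sat))
  cat(sprintf("  psi_tlp  : %7.3f MPa (turgor loss point)\n", x$psi_tlp))
  cat(sprintf("  RWC_tlp  : %7.3f\n", x$rwc_tlp))
  cat(sprintf("  apoplastic fraction: %.3f\n", x$apoplastic_fraction))
  cat(sprintf("  osmotic line: %d/%d points, R^2 = %.4f\n",
              x$n_points_on_line, x$n_obs, x$r2))
  invisible(x)
}

#' @export
summary.pv_fit <- function(object, ...) {
  print(object)
  cat("\nTransformed observations (driest first):\n")
  print(utils::head(object$data, 10))
  invisible(object)
}

#' @export
coef.pv_fit <- function(object, ...) {
  c(psi_sat = object$psi_sat, psi_tlp = object$psi_tlp,
    rwc_tlp = object$rwc_tlp,
    apoplastic_fraction = object$apoplastic_fraction)
}

#' Water potential on the fitted osmotic line
#'
#' @param object A `pv_fit`.
#' @param rwc Relative water contents at which to evaluate the osmotic
#'   component (defaults to the fitted observations).
#' @param ... Unused.
#' @return Osmotic water potential, MPa.
#' @export
predict.pv_fit <- function(object, rwc = object$data$rwc, ...) {
  1 / (object$intercept + object$slope * (1 - rwc))
}

#' @export
plot.pv_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$x, d$y, xlab = "1 - RWC", ylab = "1 / psi (MPa-1)",
                 pch = ifelse(d$on_line, 16, 1), ...)
  graphics::abline(x$intercept, x$slope, lty = 2)
  invisible(x)
}
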