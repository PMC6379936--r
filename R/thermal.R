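# Gas constant (J mol^-1 K^-1) and Celsius -> Kelvin offset used by the
# two-state thermodynamics; housed here so every caller shares one value.
GAS_CONSTANT <- 8.314
KELVIN_OFFSET <- 273.15

#' CD melting curve
#'
#' Molar ellipticity at 222 nm versus temperature for one protein sample.
#' The 222 nm channel tracks alpha-helical content; thermal unfolding shows
#' as a sigmoidal relaxation from a strongly negative native baseline toward
#' a shallower denatured baseline.
#'
#' @param variant Variant label.
#' @param replicate Replicate identifier.
#' @param temperature Temperatures in degrees C, strictly increasing, within
#'   `[0, 100]`.
#' @param theta222 Molar ellipticity (degree cm^2 dmol^-1) at 222 nm.
#' @return An object of class `"melt_curve"`.
#' @export
melt_curve <- function(variant, replicate, temperature, theta222) {
  temperature <- as.numeric(temperature)
  theta222 <- as.numeric(theta222)
  if (length(temperature) != length(theta222)) {
    bm_error("'temperature' and 'theta222' must have equal length", "domain_error")
  }
  if (any(!is.finite(temperature)) || any(!is.finite(theta222))) {
    bm_error("melt curves must be finite throughout", "domain_error")
  }
  if (any(temperature < 0) || any(temperature > 100)) {
    bad <- which(temperature < 0 | temperature > 100)
    bm_error(sprintf("temperature outside [0, 100] degC at point(s) %s",
                     paste(bad, collapse = ", ")), "domain_error")
  }
  if (any(diff(temperature) <= 0)) {
    bad <- which(diff(temperature) <= 0) + 1L
    bm_error(sprintf("temperatures must be strictly increasing (violated at point(s) %s)",
                     paste(bad, collapse = ", ")), "domain_error")
  }
  structure(list(variant = as.character(variant)[1],
                 replicate = replicate[1],
                 data = data.frame(temperature = temperature, theta222 = theta222)),
            class = "melt_curve")
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("Melt curve: %s (replicate %s), %d points, %.1f-%.1f degC\n",
              x$variant, as.character(x$replicate), nrow(x$data),
              min(x$data$temperature), max(x$data$temperature)))
  invisible(x)
}

#' Two-state fraction folded
#'
#' Equilibrium fraction folded under the two-state van't Hoff model with
#' temperature-independent enthalpy (delta Cp = 0):
#' \deqn{K(T) = \exp[-(\Delta H_{vH}/R)(1/T - 1/T_m)], \quad
#'       f_{folded} = 1/(1+K),}
#' with absolute temperatures. At `T = Tm` exactly half the population is
#' unfolded.
#'
#' @param T_celsius Temperature(s), degrees C; vectorized.
#' @param Tm Melting temperature, degrees C.
#' @param dH_vH van't Hoff enthalpy, kJ mol^-1; strictly positive for a
#'   cooperative transition.
#' @return Fraction folded in `[0, 1]`, strictly decreasing in temperature.
#' @examples
#' fraction_folded(36.6, Tm = 36.6, dH_vH = 200)  # 0.5 at the midpoint
#' @export
fraction_folded <- function(T_celsius, Tm, dH_vH) {
  bm_check_number(Tm, "Tm")
  if (!is.numeric(dH_vH) || length(dH_vH) != 1L || !is.finite(dH_vH) || dH_vH <= 0) {
    bm_error("'dH_vH' must be a single positive enthalpy (kJ/mol)", "domain_error")
  }
  Ta <- T_celsius + KELVIN_OFFSET
  Tma <- Tm + KELVIN_OFFSET
  K <- exp(-(dH_vH * 1000 / GAS_CONSTANT) * (1 / Ta - 1 / Tma))
  1 / (1 + K)
}

.two_state_theta <- function(p, T_celsius) {
  # p = (Tm, dH, aN, bN, aD, bD)
  f <- fraction_folded(T_celsius, p[1], p[2])
  f * (p[3] + p[4] * T_celsius) + (1 - f) * (p[5] + p[6] * T_celsius)
}

#' Savitzky-Golay smoothing of a melt curve
#'
#' Local polynomial least-squares smoothing of the ellipticity channel; a
#' documented stand-in for instrument-software smoothing. Endpoints are
#' handled by the filter's polynomial-extension transients, so a signal that
#' is already an order-`order` polynomial passes through unchanged.
#'
#' @param curve A [melt_curve()].
#' @param window Odd window length in points (default 11); must be smaller
#'   than the number of points.
#' @param order Polynomial order (default 3); must be smaller than `window`.
#' @return A smoothed [melt_curve()].
#' @export
smooth_melt <- function(curve, window = 11L, order = 3L) {
  if (!inherits(curve, "melt_curve")) bm_error("'curve' must be a melt_curve", "domain_error")
  n <- nrow(curve$data)
  if (window %% 2 != 1 || window < 3) {
    bm_error("'window' must be an odd integer >= 3", "config_error")
  }
  if (window >= n) bm_error("'window' must be smaller than the number of points", "config_error")
  if (order >= window) bm_error("'order' must be smaller than 'window'", "config_error")
  sm <- signal::sgolayfilt(curve$data$theta222, p = order, n = window)
  melt_curve(curve$variant, curve$replicate, curve$data$temperature, sm)
}

#' Melting temperature by the derivative method
#'
#' Locates the temperature of maximum `|d theta / dT|` on the (smoothed)
#' curve, refined by quadratic interpolation through the discrete maximum and
#' its neighbours. Robust fallback estimator and cross-check for the
#' parametric two-state fit; biased when the baselines slope steeply.
#'
#' @param curve A [melt_curve()].
#' @param window,order Savitzky-Golay settings applied before
#'   differentiation when `smooth = TRUE`.
#' @param smooth Smooth before differentiating (default `TRUE`).
#' @return Tm in degrees C.
#' @export
tm_by_derivative <- function(curve, window = 11L, order = 3L, smooth = TRUE) {
  if (!inherits(curve, "melt_curve")) bm_error("'curve' must be a melt_curve", "domain_error")
  n <- nrow(curve$data)
  if (n < 5L) bm_error("too few points for a derivative estimate", "insufficient_data")
  smoothed <- smooth && n > window
  if (smoothed) curve <- smooth_melt(curve, window, order)
  x <- curve$data$temperature
  y <- curve$data$theta222
  g <- abs(pracma::gradient(y, x))
  # the filter's one-sided endpoint transients amplify noise; search for the
  # peak only where the smoother had a full two-sided window
  k <- if (smoothed && n > 2L * (window %/% 2) + 4L) window %/% 2 else 1L
  lo <- 1L + k
  hi <- n - k
  i <- lo - 1L + which.max(g[lo:hi])
  if (i == lo || i == hi || g[i] < 2 * stats::median(g)) {
    bm_error("no interior transition: |d theta/dT| has no prominent peak inside the temperature range",
             "no_transition")
  }
  # quadratic vertex through the three points around the discrete maximum
  xs <- x[(i - 1):(i + 1)]
  ys <- g[(i - 1):(i + 1)]
  co <- tryCatch(stats::coef(stats::lm(ys ~ xs + I(xs^2))), error = function(e) NULL)
  if (is.null(co) || !is.finite(co[3]) || co[3] >= 0) return(x[i])
  vert <- -co[2] / (2 * co[3])
  if (vert < xs[1] || vert > xs[3]) x[i] else unname(vert)
}

#' Fit a two-state thermal denaturation model
#'
#' Six-parameter least squares of
#' \deqn{\theta(T) = f_{folded}(T; T_m, \Delta H_{vH})\,\theta_N(T) +
#'       (1 - f_{folded})\,\theta_D(T)}
#' with linear native and denatured baselines, fitted to the raw (unsmoothed)
#' ellipticities. Initial values come from the derivative-method Tm and
#' baseline regressions on the pre- and post-transition points; the
#' derivative-method Tm is also reported as a cross-check.
#'
#' @param curve A [melt_curve()] with at least 20 points spanning both sides
#'   of the transition.
#' @param dH_init Starting van't Hoff enthalpy, kJ mol^-1 (default 200, a
#'   typical small-globular-protein cooperativity).
#' @param window,order Smoothing settings for the internal derivative
#'   estimate.
#' @return An object of class `"melt_fit"`: `Tm` (degC), `dH_vH` (kJ/mol),
#'   `native_baseline` and `denatured_baseline` (intercept, slope), `se_Tm`,
#'   `tm_derivative`, `method`, `rss`, `n_points`.
#' @export
fit_melt <- function(curve, dH_init = 200, window = 11L, order = 3L) {
  if (!inherits(curve, "melt_curve")) bm_error("'curve' must be a melt_curve", "domain_error")
  d <- curve$data
  n <- nrow(d)
  if (n < 20L) {
    bm_error(sprintf("melt fit needs >= 20 points spanning the transition (got %d)", n),
             "insufficient_data")
  }
  tm0 <- tm_by_derivative(curve, window, order)  # propagates no_transition
  Tc <- d$temperature
  th <- d$theta222

  f0 <- fraction_folded(Tc, tm0, dH_init)
  nat <- which(f0 > 0.9)
  den <- which(f0 < 0.1)
  k <- max(2L, n %/% 6L)
  if (length(nat) < 2L) nat <- seq_len(k)
  if (length(den) < 2L) den <- seq.int(n - k + 1L, n)
  cN <- .baseline_start(Tc[nat], th[nat])
  cD <- .baseline_start(Tc[den], th[den])

  rngT <- range(Tc)
  lower <- c(rngT[1] + 1e-6, 1, -Inf, -Inf, -Inf, -Inf)
  upper <- c(rngT[2] - 1e-6, 5000, Inf, Inf, Inf, Inf)
  start <- pmin(pmax(c(tm0, dH_init, cN, cD), lower), upper)
  resfn <- function(p) .two_state_theta(p, Tc) - th
  out <- minpack.lm::nls.lm(
    par = start, fn = resfn, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-14, ptol = 1e-14))
  p <- out$par
  rss <- out$deviance

  if (p[1] - rngT[1] < 0.5 || rngT[2] - p[1] < 0.5) {
    bm_error("fitted midpoint sits at the edge of the temperature range; transition not bracketed",
             "no_transition")
  }
  if (p[2] <= 0) bm_error("non-positive fitted enthalpy; no cooperative transition", "no_transition")

  dof <- max(n - 6L, 1L)
  covm <- (rss / dof) * safe_solve(out$hessian)
  se_Tm <- sqrt(max(covm[1, 1], 0))

  structure(list(
    Tm = p[1], dH_vH = p[2],
    native_baseline = c(intercept = p[3], slope = p[4]),
    denatured_baseline = c(intercept = p[5], slope = p[6]),
    method = "two_state_fit", se_Tm = se_Tm,
    tm_derivative = tm0, rss = rss, n_points = n,
    temperature_range = rngT, variant = curve$variant,
    replicate = curve$replicate, converged = out$info %in% 1:4),
    class = "melt_fit")
}

.baseline_start <- function(x, y) {
  if (length(x) >= 2L && stats::var(x) > 0) {
    unname(stats::coef(stats::lm(y ~ x)))
  } else {
    c(mean(y), 0)
  }
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("Two-state melt fit: %s (replicate %s)\n", x$variant,
              as.character(x$replicate)))
  cat(sprintf("  Tm = %.2f +/- %.2f degC   dH_vH = %.0f kJ/mol   (derivative Tm: %.2f degC)\n",
              x$Tm, x$se_Tm, x$dH_vH, x$tm_derivative))
  invisible(x)
}

#' Normalized fraction denatured
#'
#' Baseline-corrects a melt curve using a fitted two-state description:
#' `(theta - theta_N(T)) / (theta_D(T) - theta_N(T))`. Values are expected in
#' `[-0.05, 1.05]`; noisier excursions are flagged via the `"flagged"`
#' attribute rather than clipped.
#'
#' @param curve A [melt_curve()].
#' @param fit Its [fit_melt()] result.
#' @return Data frame with `temperature` and `fraction_denatured`; attribute
#'   `flagged` is `TRUE` when any value leaves `[-0.05, 1.05]`.
#' @export
fraction_denatured <- function(curve, fit) {
  if (!inherits(fit, "melt_fit")) bm_error("'fit' must be a melt_fit", "domain_error")
  Tc <- curve$data$temperature
  thN <- fit$native_baseline[1] + fit$native_baseline[2] * Tc
  thD <- fit$denatured_baseline[1] + fit$denatured_baseline[2] * Tc
  fd <- (curve$data$theta222 - thN) / (thD - thN)
  out <- data.frame(temperature = Tc, fraction_denatured = fd)
  attr(out, "flagged") <- any(fd < -0.05 | fd > 1.05)
  out
}

#' Average replicate melts
#'
#' Fits each replicate melt independently, reports the per-replicate Tm values
#' with their mean and sample standard deviation, and averages the normalized
#' fraction-denatured curves on the first replicate's temperature grid
#' (other replicates are linearly interpolated onto it).
#'
#' @param replicates List of [melt_curve()] objects for one variant.
#' @param ... Passed to [fit_melt()].
#' @return An object of class `"melt_average"`: `tm_values`, `tm_mean`,
#'   `tm_sd` (`NA` for a single replicate), `curve` (mean normalized curve)
#'   and the per-replicate `fits`.
#' @export
average_melts <- function(replicates, ...) {
  if (inherits(replicates, "melt_curve")) replicates <- list(replicates)
  if (!length(replicates) || !all(vapply(replicates, inherits, logical(1), "melt_curve"))) {
    bm_error("'replicates' must be melt_curve objects", "domain_error")
  }
  variant <- replicates[[1]]$variant
  fits <- lapply(replicates, fit_melt, ...)
  tms <- vapply(fits, function(f) f$Tm, numeric(1))
  grid <- replicates[[1]]$data$temperature
  fds <- mapply(function(cv, f) {
    fd <- fraction_denatured(cv, f)
    stats::approx(fd$temperature, fd$fraction_denatured, xout = grid, rule = 2)$y
  }, replicates, fits)
  fds <- matrix(fds, nrow = length(grid))
  structure(list(
    variant = variant,
    tm_values = tms,
    tm_mean = mean(tms),
    tm_sd = if (length(tms) >= 2L) stats::sd(tms) else NA_real_,
    curve = data.frame(temperature = grid,
                       fraction_denatured = rowMeans(fds)),
    fits = fits), class = "melt_average")
}

#' @export
print.melt_average <- function(x, ...) {
  sd_txt <- if (is.na(x$tm_sd)) "single replicate" else sprintf("+/- %.2f", x$tm_sd)
  cat(sprintf("Melt average: %s, %d replicate(s), Tm = %.2f %s degC\n",
              x$variant, length(x$tm_values), x$tm_mean, sd_txt))
  invisible(x)
}
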