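#' Evaluate the burst model
#'
#' Product formed at time `t` under the biphasic model
#' \eqn{A_0 (1 - e^{-k_1 t}) + k_2 t}: a fast exponential burst reflecting the
#' first catalytic turnover followed by a slow linear steady-state phase.
#'
#' @param params A [burst_params()] object.
#' @param t Time(s) in minutes, non-negative; vectorized.
#' @return Product concentration(s) in nM; non-negative and non-decreasing in
#'   `t`.
#' @examples
#' wt <- burst_params(14.2, 1.4, 0.09)
#' eval_burst(wt, c(0, 1, 5, 30))
#' @export
eval_burst <- function(params, t) {
  if (!inherits(params, "burst_params")) {
    bm_error("'params' must be a burst_params object", "domain_error")
  }
  if (!is.numeric(t) || any(!is.finite(t))) bm_error("'t' must be finite numeric", "domain_error")
  if (any(t < 0)) bm_error("negative time is outside the model domain", "domain_error")
  params$A0 * (1 - exp(-params$k1 * t)) + params$k2 * t
}

# Residual and analytic Jacobian of the burst model for the least-squares
# solver. Parameter order: (A0, k1, k2).
.burst_residual <- function(p, t, P) p[1] * (1 - exp(-p[2] * t)) + p[3] * t - P
.burst_jacobian <- function(p, t, P) {
  e <- exp(-p[2] * t)
  cbind(1 - e, p[1] * t * e, t)
}

# Deterministic starting values: k2 from the slope of the last third of the
# points, A0 from the late points after removing the k2 line, k1 from the time
# to half-amplitude.
.burst_start <- function(t, P, A0_max) {
  ord <- order(t)
  t <- t[ord]; P <- P[ord]
  n <- length(t)
  tail_idx <- seq.int(max(1L, floor(2 * n / 3) + 1L), n)
  k2_0 <- 0
  if (length(tail_idx) >= 2L && stats::var(t[tail_idx]) > 0) {
    k2_0 <- max(0, unname(stats::coef(stats::lm(P[tail_idx] ~ t[tail_idx]))[2]))
  }
  k2_0 <- min(k2_0, 10)
  resid0 <- P - k2_0 * t
  A0_0 <- mean(utils::tail(resid0, 2))
  A0_0 <- min(max(A0_0, 1e-3), A0_max)
  ih <- which(resid0 >= A0_0 / 2)[1]
  t_half <- if (is.na(ih) || t[ih] <= 0) max(t[t > 0], 1) / 2 else t[ih]
  k1_0 <- min(max(log(2) / t_half, 1e-3), 100)
  c(A0_0, k1_0, k2_0)
}

.fit_burst_ls <- function(t, P, A0_max) {
  lower <- c(0, 1e-6, 0)
  upper <- c(A0_max, 100, 10)
  starts <- list(.burst_start(t, P, A0_max))
  # cheap fallback starts guard against a bad half-time estimate
  for (k1_alt in c(0.1, 1, 10)) {
    starts <- c(starts, list(c(min(max(max(P), 1e-3), A0_max), k1_alt, 0)))
  }
  best <- NULL
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14, ptol = 1e-14)
  for (s in starts) {
    s <- pmin(pmax(s, lower), upper)
    out <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = .burst_residual, jac = .burst_jacobian,
                         t = t, P = P, lower = lower, upper = upper, control = ctrl),
      error = function(e) NULL)
    if (is.null(out)) next
    if (is.null(best) || out$deviance < best$deviance) best <- out
  }
  if (is.null(best)) {
    bm_error("burst-model least squares failed from every starting point",
             "fit_error")
  }
  best
}

#' Fit the burst model to a time course
#'
#' Bounded trust-region least squares of the three-parameter burst model, with
#' an analytic Jacobian, deterministic initial guesses and (optionally) an
#' extra-sum-of-squares F-test against the one-parameter line `P = k2 t` to
#' guard against fitting a burst to burstless data. When the linear model is
#' selected, `A0` and `k1` are reported as `NA` (absent), not as zeros with
#' spurious standard errors.
#'
#' Standard errors come from the Jacobian-based covariance scaled by the
#' residual variance. With `n_boot > 0` a residual-resampling bootstrap adds
#' `se_boot` and percentile intervals — useful honesty at small n, since fit
#' covariance and replicate spread need not agree.
#'
#' @param tc A [time_course()].
#' @param average_replicates Fit the replicate-averaged curve (default, the
#'   conventional treatment of triplicated assays) rather than the pooled
#'   points.
#' @param select_model Run the burst vs linear-only model comparison (default
#'   `TRUE`).
#' @param alpha Significance level of the model-comparison F-test.
#' @param n_boot Number of residual bootstrap draws (0 = off).
#' @param seed Seed for the bootstrap.
#' @return An object of class `"burst_fit"`: `params` (named vector `A0`,
#'   `k1`, `k2`), `se`, `cov`, `rss`, `model` (`"burst"` or `"linear_only"`),
#'   `n_points`, `fitted`, `residuals`, `converged`, `model_test`, and
#'   bootstrap summaries when requested.
#' @examples
#' spec <- burst_params(14.2, 1.4, 0.09)
#' tms <- c(0.5, 1, 2, 3, 5, 8, 12, 20, 30)
#' tc <- time_course("WT", "standard", tms, eval_burst(spec, tms))
#' fit_burst(tc)
#' @export
fit_burst <- function(tc, average_replicates = TRUE, select_model = TRUE,
                      alpha = 0.01, n_boot = 0, seed = NULL) {
  if (!inherits(tc, "time_course")) bm_error("'tc' must be a time_course", "domain_error")
  if (average_replicates && length(unique(tc$data$replicate)) > 1L) {
    tc <- aggregate_replicates(tc)
  }
  if (n_distinct_times(tc) < 5L) {
    bm_error(sprintf(
      "burst fit needs >= 5 distinct time points (got %d): 3 parameters plus a noise scale",
      n_distinct_times(tc)), "insufficient_data")
  }
  ord <- order(tc$data$time)
  t <- tc$data$time[ord]
  P <- tc$data$product[ord]
  n <- length(t)
  A0_max <- tc$substrate_total

  ls <- .fit_burst_ls(t, P, A0_max)
  p <- ls$par
  rss <- ls$deviance
  converged <- ls$info %in% 1:4

  cm <- if (select_model) .model_comparison(t, P, rss, n, alpha) else NULL
  model <- if (!is.null(cm) && cm$model == "linear_only") "linear_only" else "burst"

  if (model == "linear_only") {
    k2_lin <- cm$k2_linear
    rss_lin <- cm$rss_linear
    se_k2 <- if (n > 1) sqrt(rss_lin / (n - 1) / sum(t^2)) else NA_real_
    fit <- structure(list(
      params = c(A0 = NA_real_, k1 = NA_real_, k2 = k2_lin),
      se = c(A0 = NA_real_, k1 = NA_real_, k2 = se_k2),
      cov = matrix(se_k2^2, 1, 1, dimnames = list("k2", "k2")),
      rss = rss_lin, model = "linear_only", n_points = n,
      fitted = k2_lin * t, residuals = P - k2_lin * t,
      time = t, product = P, substrate_total = tc$substrate_total,
      variant = tc$variant, condition = tc$condition,
      converged = TRUE, model_test = cm), class = "burst_fit")
    return(fit)
  }

  J <- .burst_jacobian(p, t, P)
  dof <- max(n - 3L, 1L)
  sigma2 <- rss / dof
  covm <- sigma2 * safe_solve(crossprod(J))
  dimnames(covm) <- list(c("A0", "k1", "k2"), c("A0", "k1", "k2"))
  se <- sqrt(pmax(diag(covm), 0))

  fit <- structure(list(
    params = c(A0 = p[1], k1 = p[2], k2 = p[3]),
    se = se, cov = covm, rss = rss, model = "burst", n_points = n,
    fitted = P - ls$fvec, residuals = -ls$fvec,
    time = t, product = P, substrate_total = tc$substrate_total,
    variant = tc$variant, condition = tc$condition,
    converged = converged, info = ls$info, message = ls$message,
    model_test = cm), class = "burst_fit")
  if (!converged) warning("burst fit did not report clean convergence: ", ls$message)

  if (n_boot > 0) {
    fit$boot <- with_seed_or_stream(seed, {
      res <- fit$residuals - mean(fit$residuals)
      draws <- matrix(NA_real_, n_boot, 3,
                      dimnames = list(NULL, c("A0", "k1", "k2")))
      for (b in seq_len(n_boot)) {
        Pb <- pmin(pmax(fit$fitted + sample(res, n, replace = TRUE), 0),
                   tc$substrate_total)
        bfit <- tryCatch(.fit_burst_ls(t, Pb, A0_max), error = function(e) NULL)
        if (!is.null(bfit)) draws[b, ] <- bfit$par
      }
      draws <- draws[stats::complete.cases(draws), , drop = FALSE]
      list(n_boot = nrow(draws),
           se_boot = apply(draws, 2, stats::sd),
           ci = apply(draws, 2, stats::quantile, probs = c(0.025, 0.975)))
    })
  }
  fit
}

#' @export
print.burst_fit <- function(x, ...) {
  cat(sprintf("Burst fit: %s / %s  [model: %s, n = %d]\n",
              x$variant, x$condition, x$model, x$n_points))
  if (x$model == "burst") {
    cat(sprintf("  A0 = %.3g +/- %.2g nM   k1 = %.3g +/- %.2g min^-1   k2 = %.3g +/- %.2g nM min^-1\n",
                x$params["A0"], x$se["A0"], x$params["k1"], x$se["k1"],
                x$params["k2"], x$se["k2"]))
  } else {
    cat(sprintf("  linear only: k2 = %.3g +/- %.2g nM min^-1 (A0, k1 absent)\n",
                x$params["k2"], x$se["k2"]))
  }
  cat(sprintf("  RSS = %.4g\n", x$rss))
  invisible(x)
}

# Shared by fit_burst and compare_models. The linear-only candidate is the
# least-squares line through the origin.
.model_comparison <- function(t, P, rss_burst, n, alpha) {
  k2_lin <- max(0, sum(t * P) / sum(t^2))
  rss_lin <- sum((k2_lin * t - P)^2)
  df2 <- n - 3L
  scale <- max(abs(P), 1)
  tol <- n * (1e-7 * scale)^2
  if (rss_lin <= tol) {
    # the line already explains the data to numerical precision: parsimony
    return(list(model = "linear_only", statistic = 0, p_value = 1,
                df = c(2L, df2), rss_burst = rss_burst, rss_linear = rss_lin,
                k2_linear = k2_lin, alpha = alpha))
  }
  if (df2 < 1L) bm_error("too few points for the model-comparison F-test", "insufficient_data")
  Fstat <- ((rss_lin - rss_burst) / 2) / (rss_burst / df2)
  if (!is.finite(Fstat)) Fstat <- Inf
  pval <- stats::pf(Fstat, 2, df2, lower.tail = FALSE)
  list(model = if (pval < alpha) "burst" else "linear_only",
       statistic = Fstat, p_value = pval, df = c(2L, df2),
       rss_burst = rss_burst, rss_linear = rss_lin,
       k2_linear = k2_lin, alpha = alpha)
}

#' Burst vs linear-only model comparison
#'
#' Extra-sum-of-squares F-test between the three-parameter burst model and the
#' one-parameter line through the origin. Used internally by [fit_burst()] to
#' avoid reporting a spurious burst when the data are a plain steady-state
#' line.
#'
#' @param tc A [time_course()].
#' @param alpha Significance level (default 0.01).
#' @param average_replicates As in [fit_burst()].
#' @return A list with the selected `model`, the F `statistic`, `p_value`,
#'   degrees of freedom and both residual sums of squares.
#' @export
compare_models <- function(tc, alpha = 0.01, average_replicates = TRUE) {
  if (!inherits(tc, "time_course")) bm_error("'tc' must be a time_course", "domain_error")
  if (average_replicates && length(unique(tc$data$replicate)) > 1L) {
    tc <- aggregate_replicates(tc)
  }
  if (n_distinct_times(tc) < 5L) {
    bm_error("model comparison needs >= 5 distinct time points", "insufficient_data")
  }
  ord <- order(tc$data$time)
  t <- tc$data$time[ord]
  P <- tc$data$product[ord]
  ls <- .fit_burst_ls(t, P, tc$substrate_total)
  .model_comparison(t, P, ls$deviance, length(t), alpha)
}

#' Average replicated time courses
#'
#' Collapses replicates sharing a common time grid into one point per distinct
#' time, carrying the per-time mean, sample standard deviation (n - 1) and
#' replicate count.
#'
#' @param tcs A single multi-replicate [time_course()] or a list of
#'   single-replicate time courses sharing variant, condition and substrate
#'   total.
#' @param tol Alignment tolerance between replicate time grids, in minutes.
#' @return A [time_course()] whose `data` has columns `time`, `product`
#'   (mean), `sd` and `n`.
#' @export
aggregate_replicates <- function(tcs, tol = 1e-6) {
  if (inherits(tcs, "time_course")) tcs <- list(tcs)
  if (!length(tcs) || !all(vapply(tcs, inherits, logical(1), "time_course"))) {
    bm_error("'tcs' must be a time_course or a list of them", "domain_error")
  }
  variant <- tcs[[1]]$variant
  condition <- tcs[[1]]$condition
  st <- tcs[[1]]$substrate_total
  for (tc in tcs[-1]) {
    if (!identical(tc$variant, variant) || !identical(tc$condition, condition) ||
        abs(tc$substrate_total - st) > 1e-9) {
      bm_error("replicates must share variant, condition and substrate total",
               "alignment_error")
    }
  }
  d <- do.call(rbind, lapply(seq_along(tcs), function(i) {
    di <- tcs[[i]]$data[, c("time", "product", "replicate")]
    di$replicate <- paste(i, di$replicate, sep = ".")
    di
  }))
  grid <- sort(unique(tcs[[1]]$data$time))
  idx <- vapply(d$time, function(x) which.min(abs(grid - x)), integer(1))
  off <- abs(d$time - grid[idx]) > tol
  if (any(off)) {
    bm_error(sprintf("replicate times not alignable to the reference grid (tolerance %g min): %s",
                     tol, paste(unique(signif(d$time[off], 8)), collapse = ", ")),
             "alignment_error")
  }
  g <- grid[idx]
  mean_p <- tapply(d$product, g, mean)
  sd_p <- tapply(d$product, g, stats::sd)
  n_p <- tapply(d$product, g, length)
  tt <- as.numeric(names(mean_p))
  ord <- order(tt)
  time_course(variant, condition, tt[ord], as.numeric(mean_p)[ord],
              replicate = "mean", substrate_total = st,
              sd = as.numeric(sd_p)[ord], n = as.integer(n_p)[ord])
}

#' Activity relative to a reference variant
#'
#' Ratio of burst-phase rate constants, `100 * k1(variant) / k1(reference)`,
#' in percent — the conventional headline comparison of variant excision
#' activity. Uncertainty is propagated to first order from both fits'
#' standard errors.
#'
#' @param variant_fit,reference_fit [fit_burst()] results with
#'   `model = "burst"`.
#' @return A list with `percent`, its propagated `se` and the two `k1` values.
#' @examples
#' tms <- c(0.5, 1, 2, 3, 5, 8, 12, 20, 30)
#' wt <- fit_burst(time_course("WT", "std", tms, eval_burst(burst_params(14.2, 1.4, 0.09), tms)))
#' mu <- fit_burst(time_course("R154H", "std", tms, eval_burst(burst_params(8.4, 0.23, 0.14), tms)))
#' relative_activity(mu, wt)$percent
#' @export
relative_activity <- function(variant_fit, reference_fit) {
  for (f in list(variant_fit, reference_fit)) {
    if (!inherits(f, "burst_fit")) bm_error("inputs must be burst_fit objects", "domain_error")
    if (!identical(f$model, "burst")) {
      bm_error("relative activity requires burst-model fits on both sides", "domain_error")
    }
  }
  k1v <- variant_fit$params[["k1"]]
  k1r <- reference_fit$params[["k1"]]
  if (!is.finite(k1r) || k1r <= 0) {
    bm_error("reference k1 must be positive", "domain_error")
  }
  pct <- 100 * k1v / k1r
  sev <- variant_fit$se[["k1"]]
  ser <- reference_fit$se[["k1"]]
  se <- if (k1v > 0) pct * sqrt((sev / k1v)^2 + (ser / k1r)^2) else NA_real_
  list(percent = pct, se = se, k1_variant = k1v, k1_reference = k1r)
}
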