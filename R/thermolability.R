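#' Pre-incubation condition
#'
#' Describes the thermal challenge applied before the excision assay: the
#' study design pre-incubates enzyme for 90 min at either 4 degC (control,
#' assumed lossless) or 37 degC (challenge), with or without stoichiometric
#' undamaged competitor DNA.
#'
#' @param temperature Pre-incubation temperature, degC (study values 4 or 37).
#' @param duration Duration in minutes (study value 90).
#' @param competitor_dna Logical; competitor DNA present during pre-incubation.
#' @param competitor_stoichiometry Competitor:enzyme ratio; positive only when
#'   `competitor_dna` is `TRUE` (study value 1.0 when present).
#' @return An object of class `"preincubation_condition"`.
#' @export
preincubation_condition <- function(temperature, duration = 90,
                                    competitor_dna = FALSE,
                                    competitor_stoichiometry = if (competitor_dna) 1 else 0) {
  bm_check_number(temperature, "temperature")
  bm_check_number(duration, "duration", lower = 0)
  bm_check_number(competitor_stoichiometry, "competitor_stoichiometry", lower = 0)
  if (!competitor_dna && competitor_stoichiometry > 0) {
    bm_error("competitor stoichiometry must be 0 when no competitor DNA is present",
             "domain_error")
  }
  structure(list(temperature = temperature, duration = duration,
                 competitor_dna = isTRUE(competitor_dna),
                 competitor_stoichiometry = competitor_stoichiometry),
            class = "preincubation_condition")
}

condition_label <- function(cond) {
  base <- sprintf("pre%g", cond$temperature)
  if (cond$competitor_dna) paste0(base, "+DNA") else base
}

#' Scalar activity metric for a time course or fit
#'
#' Reduces a measurement to one activity number. The default metric is the
#' fitted burst amplitude `A0` — loss of folded enzyme scales the amplitude
#' of the first turnover rather than its rate constant — with the mean
#' product at the latest time point as a fallback when no burst can be fitted
#' (degenerate, near-background data).
#'
#' @param x A `burst_fit` or a [time_course()].
#' @param tc Optional [time_course()] backing a `burst_fit`, used for the
#'   fallback when the fit is `linear_only`.
#' @param at_time Time (min) of the fixed-time metric; defaults to the latest
#'   time present.
#' @return List with `value`, `metric` (`"burst_amplitude"` or
#'   `"fixed_time_product"`) and `flagged` (`TRUE` when the fallback was
#'   forced).
#' @export
activity_metric <- function(x, tc = NULL, at_time = NULL) {
  if (inherits(x, "burst_fit")) {
    if (identical(x$model, "burst")) {
      return(list(value = unname(x$params["A0"]), metric = "burst_amplitude",
                  flagged = FALSE))
    }
    if (is.null(tc)) {
      # rebuild a minimal time course from the data stored on the fit
      tc <- time_course(x$variant, x$condition, x$time, x$product,
                        substrate_total = x$substrate_total)
    }
    m <- activity_metric(tc, at_time = at_time)
    m$flagged <- TRUE
    return(m)
  }
  if (inherits(x, "time_course")) {
    d <- x$data
    if (!nrow(d)) bm_error("no data to compute an activity metric from", "degenerate_data")
    tmax <- if (is.null(at_time)) max(d$time) else at_time
    sel <- abs(d$time - tmax) < 1e-8
    if (!any(sel)) bm_error(sprintf("no measurement at t = %g min", tmax), "degenerate_data")
    return(list(value = mean(d$product[sel]), metric = "fixed_time_product",
                flagged = FALSE))
  }
  bm_error("'x' must be a burst_fit or a time_course", "degenerate_data")
}

#' Activity retention ratio
#'
#' Ratio of challenged to control activity. Values are reported on `[0, Inf)`
#' and flagged (not clipped) above 1.1, where they exceed plausible retention
#' and usually indicate noise or a metric mismatch.
#'
#' @param challenged,control Scalar activities or [activity_metric()] results.
#' @return List with `ratio` and `flagged`.
#' @export
retention <- function(challenged, control) {
  val <- function(x) if (is.list(x)) x$value else x
  ch <- val(challenged); co <- val(control)
  if (!is.finite(co) || co <= 0) bm_error("control activity must be positive", "domain_error")
  if (!is.finite(ch) || ch < 0) bm_error("challenged activity must be non-negative", "domain_error")
  r <- ch / co
  list(ratio = r, flagged = r > 1.1)
}

# Per-replicate scalar activities for one condition. Fits each replicate
# separately when the metric is the burst amplitude; returns the fallback
# metric for every replicate if ANY replicate fit is degenerate, so a
# challenged/control pair can stay like-for-like.
.replicate_metrics <- function(tcs, metric, at_time) {
  if (inherits(tcs, "time_course")) {
    tcs <- split_replicates(tcs)
  }
  if (metric == "fixed_time_product") {
    vals <- vapply(tcs, function(tc) activity_metric(tc, at_time = at_time)$value,
                   numeric(1))
    return(list(values = vals, metric = metric, degenerate = FALSE))
  }
  vals <- numeric(length(tcs))
  degenerate <- FALSE
  for (i in seq_along(tcs)) {
    f <- tryCatch(fit_burst(tcs[[i]]), error = function(e) NULL)
    if (is.null(f) || !identical(f$model, "burst")) { degenerate <- TRUE; break }
    vals[i] <- unname(f$params["A0"])
  }
  if (degenerate) {
    vals <- vapply(tcs, function(tc) activity_metric(tc, at_time = at_time)$value,
                   numeric(1))
    return(list(values = vals, metric = "fixed_time_product", degenerate = TRUE))
  }
  list(values = vals, metric = "burst_amplitude", degenerate = FALSE)
}

#' Split a multi-replicate time course into single replicates
#' @param tc A [time_course()].
#' @return List of single-replicate time courses.
#' @export
split_replicates <- function(tc) {
  lapply(split(seq_len(nrow(tc$data)), tc$data$replicate), function(ix) {
    d <- tc$data[ix, ]
    time_course(tc$variant, tc$condition, d$time, d$product,
                replicate = d$replicate, substrate_total = tc$substrate_total)
  })
}

#' Estimate activity retention after thermal challenge
#'
#' Compares replicated time courses measured after a thermal challenge
#' (e.g. 90 min at 37 degC) against their control (4 degC), as a ratio of
#' mean per-replicate activities with a percentile bootstrap interval from
#' resampling replicates with replacement within each condition.
#'
#' When the default burst-amplitude metric cannot be fitted in either
#' condition (activity at background level), both conditions fall back to the
#' fixed-time product metric so the ratio compares like with like; the
#' `metric` field records which was used.
#'
#' @param challenged,control Replicated time courses (a multi-replicate
#'   [time_course()] or a list of single-replicate ones) for the challenged
#'   and control condition.
#' @param metric `"burst_amplitude"` (default) or `"fixed_time_product"`.
#' @param n_boot Bootstrap draws (default 2000).
#' @param seed Bootstrap seed.
#' @param conf Confidence level of the percentile interval.
#' @return An object of class `"retention_result"`: `variant`, `retention`,
#'   `ci_low`, `ci_high`, `metric`, `condition_pair`, the per-replicate
#'   `challenged_values` / `control_values` and `flagged`.
#' @export
estimate_retention <- function(challenged, control,
                               metric = c("burst_amplitude", "fixed_time_product"),
                               n_boot = 2000, seed = NULL, conf = 0.95) {
  metric <- match.arg(metric)
  ch_list <- if (inherits(challenged, "time_course")) split_replicates(challenged) else challenged
  co_list <- if (inherits(control, "time_course")) split_replicates(control) else control
  if (!length(ch_list) || !length(co_list)) {
    bm_error("both conditions need at least one replicate", "degenerate_data")
  }
  variant <- ch_list[[1]]$variant
  if (!identical(co_list[[1]]$variant, variant)) {
    bm_error("challenged and control must belong to the same variant", "pairing_error")
  }
  # latest time present in every replicate of both conditions
  at_time <- min(vapply(c(ch_list, co_list), function(tc) max(tc$data$time), numeric(1)))

  ch <- .replicate_metrics(ch_list, metric, at_time)
  co <- .replicate_metrics(co_list, metric, at_time)
  if (ch$metric != co$metric) {
    m <- "fixed_time_product"
    ch <- .replicate_metrics(ch_list, m, at_time)
    co <- .replicate_metrics(co_list, m, at_time)
  }
  used_metric <- ch$metric

  if (mean(co$values) <= 0) bm_error("control activity is not positive", "domain_error")
  est <- mean(ch$values) / mean(co$values)

  alpha2 <- (1 - conf) / 2
  boot <- with_seed_or_stream(seed, {
    nc <- length(ch$values); nn <- length(co$values)
    r <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      num <- mean(sample(ch$values, nc, replace = TRUE))
      den <- mean(sample(co$values, nn, replace = TRUE))
      r[b] <- if (den > 0) num / den else NA_real_
    }
    r[is.finite(r)]
  })
  ci <- if (length(boot)) stats::quantile(boot, c(alpha2, 1 - alpha2), names = FALSE)
        else c(NA_real_, NA_real_)
  # the interval must bracket the point estimate by construction
  ci[1] <- min(ci[1], est, na.rm = TRUE)
  ci[2] <- max(ci[2], est, na.rm = TRUE)

  structure(list(
    variant = variant, retention = est, ci_low = ci[1], ci_high = ci[2],
    metric = used_metric,
    condition_pair = c(challenged = ch_list[[1]]$condition,
                       control = co_list[[1]]$condition),
    challenged_values = ch$values, control_values = co$values,
    n_boot = n_boot, conf = conf,
    flagged = est > 1.1 || ch$degenerate || co$degenerate),
    class = "retention_result")
}

#' @export
print.retention_result <- function(x, ...) {
  cat(sprintf("Retention: %s  %s vs %s  = %.3f [%.3f, %.3f]  (metric: %s%s)\n",
              x$variant, x$condition_pair["challenged"], x$condition_pair["control"],
              x$retention, x$ci_low, x$ci_high, x$metric,
              if (x$flagged) ", flagged" else ""))
  invisible(x)
}

#' DNA-protection effect on retention
#'
#' Paired comparison of retention with versus without competitor DNA for one
#' variant under the same thermal challenge:
#' `delta = retention_with - retention_without`, with a joint bootstrap
#' interval from resampling the per-replicate activities of all four
#' underlying groups. The effect is called protective when the interval
#' excludes zero in the positive direction.
#'
#' @param no_dna,with_dna [estimate_retention()] results for the same variant
#'   and challenge, differing only in competitor DNA.
#' @param n_boot Bootstrap draws (default 2000).
#' @param seed Bootstrap seed.
#' @param conf Confidence level.
#' @return An object of class `"protection_effect"`: `delta`, `ci_low`,
#'   `ci_high`, `protective` and the two retentions.
#' @export
protection_effect <- function(no_dna, with_dna, n_boot = 2000, seed = NULL,
                              conf = 0.95) {
  for (x in list(no_dna, with_dna)) {
    if (!inherits(x, "retention_result")) {
      bm_error("inputs must be retention_result objects", "pairing_error")
    }
  }
  if (!identical(no_dna$variant, with_dna$variant)) {
    bm_error("protection comparison requires the same variant on both sides",
             "pairing_error")
  }
  delta <- with_dna$retention - no_dna$retention
  alpha2 <- (1 - conf) / 2
  boot <- with_seed_or_stream(seed, {
    d <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      rw_num <- mean(sample(with_dna$challenged_values, replace = TRUE))
      rw_den <- mean(sample(with_dna$control_values, replace = TRUE))
      rn_num <- mean(sample(no_dna$challenged_values, replace = TRUE))
      rn_den <- mean(sample(no_dna$control_values, replace = TRUE))
      d[b] <- if (rw_den > 0 && rn_den > 0) rw_num / rw_den - rn_num / rn_den else NA_real_
    }
    d[is.finite(d)]
  })
  ci <- if (length(boot)) stats::quantile(boot, c(alpha2, 1 - alpha2), names = FALSE)
        else c(NA_real_, NA_real_)
  structure(list(
    variant = no_dna$variant, delta = delta,
    ci_low = ci[1], ci_high = ci[2],
    protective = is.finite(ci[1]) && ci[1] > 0 && delta > 0,
    retention_no_dna = no_dna$retention,
    retention_with_dna = with_dna$retention,
    n_boot = n_boot, conf = conf), class = "protection_effect")
}

#' @export
print.protection_effect <- function(x, ...) {
  cat(sprintf("DNA protection: %s  delta = %+.3f [%.3f, %.3f]  -> %s\n",
              x$variant, x$delta, x$ci_low, x$ci_high,
              if (x$protective) "protective" else "not protective"))
  invisible(x)
}

#' Retention table across a full variant panel
#'
#' Runs [estimate_retention()] for every variant and DNA state in a
#' pre-incubation study (conditions labelled `pre4`, `pre37`, `pre4+DNA`,
#' `pre37+DNA`) and, where both DNA states are present, the paired
#' [protection_effect()]. Missing cells are reported explicitly as `NA`
#' rows, not dropped.
#'
#' @param dataset List of [time_course()] objects carrying the condition
#'   labels above.
#' @param n_boot,seed,conf Bootstrap settings shared by all cells.
#' @return An object of class `"thermolability_panel"`: a data frame `table`
#'   (variant, dna, retention, ci, metric, replicate counts), a `protection`
#'   data frame, and the underlying `results`.
#' @export
thermolability_panel <- function(dataset, n_boot = 2000, seed = NULL, conf = 0.95) {
  if (inherits(dataset, "time_course")) dataset <- list(dataset)
  if (!length(dataset)) bm_error("empty dataset", "degenerate_data")
  if (!all(vapply(dataset, inherits, logical(1), "time_course"))) {
    bm_error("'dataset' must be a list of time_course objects", "domain_error")
  }
  variants <- unique(vapply(dataset, function(x) x$variant, character(1)))
  get_cell <- function(v, cond) {
    Filter(function(x) identical(x$variant, v) && identical(x$condition, cond), dataset)
  }
  rows <- list(); results <- list(); prot_rows <- list()
  seeds <- if (is.null(seed)) rep(list(NULL), 3L * length(variants) * 2L)
           else as.list(seed + seq_len(3L * length(variants) * 2L))
  si <- 0L
  next_seed <- function() { si <<- si + 1L; seeds[[si]] }
  for (v in variants) {
    pair <- list()
    for (dna in c(FALSE, TRUE)) {
      suffix <- if (dna) "+DNA" else ""
      ch <- get_cell(v, paste0("pre37", suffix))
      co <- get_cell(v, paste0("pre4", suffix))
      n_ch <- sum(vapply(ch, function(x) length(unique(x$data$replicate)), integer(1)))
      n_co <- sum(vapply(co, function(x) length(unique(x$data$replicate)), integer(1)))
      sd_b <- next_seed()
      if (!length(ch) || !length(co)) {
        rows[[length(rows) + 1L]] <- data.frame(
          variant = v, dna = dna, retention = NA_real_, ci_low = NA_real_,
          ci_high = NA_real_, metric = NA_character_, n_challenged = n_ch,
          n_control = n_co, flagged = NA)
        next
      }
      if (min(n_ch, n_co) < 3L) {
        warning(sprintf("%s (%s): fewer than 3 replicates per cell (study minimum)",
                        v, if (dna) "with DNA" else "no DNA"))
      }
      ch_reps <- do.call(c, lapply(ch, split_replicates))
      co_reps <- do.call(c, lapply(co, split_replicates))
      rr <- estimate_retention(ch_reps, co_reps, n_boot = n_boot,
                               seed = sd_b, conf = conf)
      results[[paste0(v, if (dna) ".dna" else ".nodna")]] <- rr
      pair[[if (dna) "with" else "without"]] <- rr
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, dna = dna, retention = rr$retention, ci_low = rr$ci_low,
        ci_high = rr$ci_high, metric = rr$metric, n_challenged = n_ch,
        n_control = n_co, flagged = rr$flagged)
    }
    if (!is.null(pair$without) && !is.null(pair$with)) {
      pe <- protection_effect(pair$without, pair$with, n_boot = n_boot,
                              seed = next_seed(), conf = conf)
      prot_rows[[v]] <- data.frame(
        variant = v, delta = pe$delta, ci_low = pe$ci_low, ci_high = pe$ci_high,
        protective = pe$protective)
      results[[paste0(v, ".protection")]] <- pe
    } else {
      next_seed()
    }
  }
  structure(list(table = do.call(rbind, rows),
                 protection = if (length(prot_rows)) do.call(rbind, prot_rows) else NULL,
                 results = results),
            class = "thermolability_panel")
}

#' @export
print.thermolability_panel <- function(x, ...) {
  cat("Thermolability panel (37 degC challenge vs 4 degC control)\n\n")
  tb <- x$table
  tb$dna <- ifelse(tb$dna, "+DNA", "no DNA")
  print(format(tb, digits = 3), row.names = FALSE)
  if (!is.null(x$protection)) {
    cat("\nDNA protection (delta retention, with - without):\n")
    print(format(x$protection, digits = 3), row.names = FALSE)
  }
  invisible(x)
}
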