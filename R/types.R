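#' Burst-model parameters
#'
#' Container for the three parameters of the biphasic product-formation model
#' \deqn{[P](t) = A_0 (1 - e^{-k_1 t}) + k_2 t,}
#' where \eqn{A_0} is the burst amplitude (nM, proportional to the amount of
#' active enzyme engaged in the first turnover), \eqn{k_1} the burst-phase
#' rate constant (min^-1) and \eqn{k_2} the slower linear-phase rate
#' (nM min^-1).
#'
#' @param A0 Burst amplitude in nM; must be non-negative and, when
#'   `substrate_total` is supplied, no larger than it.
#' @param k1 Burst-phase rate constant in min^-1; strictly positive.
#' @param k2 Linear-phase rate in nM min^-1; non-negative.
#' @param substrate_total Optional total substrate concentration (nM) used to
#'   bound `A0` (20 nM in the standard excision assay design).
#' @return An object of class `"burst_params"`.
#' @examples
#' burst_params(14.2, 1.4, 0.09, substrate_total = 20)
#' @export
burst_params <- function(A0, k1, k2, substrate_total = NULL) {
  bm_check_number(A0, "A0", lower = 0)
  bm_check_number(k1, "k1", lower = 0, strict_lower = TRUE)
  bm_check_number(k2, "k2", lower = 0)
  if (!is.null(substrate_total)) {
    bm_check_number(substrate_total, "substrate_total", lower = 0, strict_lower = TRUE)
    if (A0 > substrate_total) {
      bm_error(sprintf("A0 = %g nM exceeds the total substrate concentration (%g nM)",
                       A0, substrate_total), "domain_error")
    }
  }
  structure(list(A0 = A0, k1 = k1, k2 = k2, substrate_total = substrate_total),
            class = "burst_params")
}

#' @export
print.burst_params <- function(x, ...) {
  cat(sprintf("Burst parameters: A0 = %g nM, k1 = %g min^-1, k2 = %g nM min^-1\n",
              x$A0, x$k1, x$k2))
  invisible(x)
}

#' Excision-assay time course
#'
#' One set of (time, product) measurements for a single enzyme variant under a
#' single condition, possibly holding several replicates. Times are minutes,
#' product concentrations nM on the labeled-substrate scale.
#'
#' @param variant Variant label (e.g. `"WT"`, `"R46Q"`).
#' @param condition Condition label (e.g. `"standard"`, `"pre37"`,
#'   `"pre4+DNA"`).
#' @param time,product Numeric vectors of equal length: sampling times (min,
#'   non-negative) and product formed (nM, in `[0, substrate_total]`).
#' @param replicate Replicate identifier(s), recycled to the length of `time`.
#' @param substrate_total Total substrate concentration in nM (default 20, the
#'   standard assay design).
#' @param sd,n Optional per-point standard deviation and replicate count
#'   (filled by [aggregate_replicates()]).
#' @return An object of class `"time_course"` with fields `variant`,
#'   `condition`, `substrate_total` and a data frame `data`.
#' @export
time_course <- function(variant, condition, time, product, replicate = 1L,
                        substrate_total = 20, sd = NULL, n = NULL) {
  time <- as.numeric(time)
  product <- as.numeric(product)
  if (length(time) != length(product)) {
    bm_error("'time' and 'product' must have equal length", "domain_error")
  }
  if (length(time) == 0L) bm_error("a time course needs at least one point", "domain_error")
  bm_check_number(substrate_total, "substrate_total", lower = 0, strict_lower = TRUE)
  if (any(!is.finite(time)) || any(time < 0)) {
    bm_error("all times must be finite and non-negative", "domain_error")
  }
  if (any(!is.finite(product)) || any(product < 0)) {
    bm_error("all product concentrations must be finite and non-negative", "domain_error")
  }
  if (any(product > substrate_total + 1e-9)) {
    bad <- which(product > substrate_total + 1e-9)
    bm_error(sprintf(
      "product exceeds the total substrate concentration (%g nM) at point(s) %s",
      substrate_total, paste(bad, collapse = ", ")), "domain_error")
  }
  d <- data.frame(time = time, product = product,
                  replicate = rep_len(replicate, length(time)))
  if (!is.null(sd)) d$sd <- rep_len(as.numeric(sd), nrow(d))
  if (!is.null(n)) d$n <- rep_len(as.integer(n), nrow(d))
  structure(list(variant = as.character(variant)[1],
                 condition = as.character(condition)[1],
                 substrate_total = substrate_total,
                 data = d),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("Time course: %s / %s  (%d points, %d replicate(s), substrate %g nM)\n",
              x$variant, x$condition, nrow(x$data),
              length(unique(x$data$replicate)), x$substrate_total))
  invisible(x)
}

n_distinct_times <- function(tc) length(unique(tc$data$time))
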