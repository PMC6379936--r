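#' Default assay sampling grid
#'
#' Quench times (min) used by the simulators: dense early points to resolve
#' the burst, sparse late points for the linear phase, over a half-hour
#' reaction.
#' @return Numeric vector of times in minutes.
#' @export
default_time_grid <- function() c(0.5, 1, 2, 3, 5, 8, 12, 20, 30)

#' Ground-truth description of one enzyme variant
#'
#' Generative parameters for a single variant: burst-model kinetics, two-state
#' stability, and a first-order irreversible denaturation model for the
#' pre-incubation step. The denaturation rate is
#' `k_den(T) = k_den_ref * exp(alpha * (T - Tm))` (reference rate at the
#' variant's own midpoint, exponential temperature sensitivity); bound
#' competitor DNA multiplies it by `dna_protection`.
#'
#' @param name Variant label (unique within a study).
#' @param burst A [burst_params()] ground truth.
#' @param Tm Melting temperature, degC, in (0, 100).
#' @param dH_vH van't Hoff enthalpy, kJ/mol.
#' @param k_den_ref Irreversible denaturation rate at `T = Tm`, min^-1.
#' @param alpha Temperature sensitivity of the denaturation rate, degC^-1.
#' @param dna_protection Multiplier in `[0, 1]` applied to the denaturation
#'   rate when competitor DNA is bound (0 = complete protection).
#' @return An object of class `"variant_spec"`.
#' @export
variant_spec <- function(name, burst, Tm, dH_vH = 200, k_den_ref = 0.025,
                         alpha = 0.7, dna_protection = 0.02) {
  if (!inherits(burst, "burst_params")) bm_error("'burst' must be burst_params", "domain_error")
  bm_check_number(Tm, "Tm", lower = 0, upper = 100, strict_lower = TRUE)
  bm_check_number(dH_vH, "dH_vH", lower = 0, strict_lower = TRUE)
  bm_check_number(k_den_ref, "k_den_ref", lower = 0)
  bm_check_number(alpha, "alpha", lower = 0)
  bm_check_number(dna_protection, "dna_protection", lower = 0, upper = 1)
  structure(list(name = as.character(name)[1], burst = burst, Tm = Tm,
                 dH_vH = dH_vH, k_den_ref = k_den_ref, alpha = alpha,
                 dna_protection = dna_protection),
            class = "variant_spec")
}

#' Ground-truth specs for the five study variants
#'
#' Wild-type hOGG1 and the R46Q, A85S, R154H and S232T variants, with the
#' published burst-model parameters and CD melting temperatures as generative
#' ground truth. The denaturation-kinetics parameters (`k_den_ref`, `alpha`,
#' `dna_protection`) are the generator's own calibration: 90 min at 37 degC
#' costs the thermolabile R46Q (Tm barely below 37 degC) about 95% of its
#' activity and wild-type well under 20%, and bound competitor DNA removes
#' almost all of the loss.
#'
#' @return Named list of [variant_spec()] objects.
#' @export
hogg1_variant_specs <- function() {
  mk <- function(name, A0, k1, k2, Tm) {
    variant_spec(name, burst_params(A0, k1, k2, substrate_total = 20), Tm = Tm)
  }
  list(
    `WT`    = mk("WT",    14.2, 1.4,  0.09, 41.8),
    `R46Q`  = mk("R46Q",  10.5, 2.0,  0.14, 36.6),
    `A85S`  = mk("A85S",  14.3, 1.6,  0.08, 42.2),
    `R154H` = mk("R154H",  8.4, 0.23, 0.14, 43.2),
    `S232T` = mk("S232T", 10.5, 0.8,  0.15, 42.2)
  )
}

#' Simulate excision time courses
#'
#' Draws replicated product-formation curves from a variant's burst-model
#' ground truth with additive Gaussian noise, truncated to the physical range
#' `[0, substrate_total]` (20 nM labeled duplex in the study design, enzyme
#' in excess at 100 nM).
#'
#' @param spec A [variant_spec()].
#' @param times Sampling times, min (default [default_time_grid()]).
#' @param noise_sd Gaussian noise SD, nM (default 0.5).
#' @param n_reps Number of replicates (default 3, the study minimum).
#' @param seed Optional seed.
#' @param substrate_total Total substrate, nM (default 20).
#' @param condition Condition label stamped on the output.
#' @return List of `n_reps` [time_course()] objects.
#' @export
gen_time_course <- function(spec, times = default_time_grid(), noise_sd = 0.5,
                            n_reps = 3, seed = NULL, substrate_total = 20,
                            condition = "standard") {
  if (!inherits(spec, "variant_spec")) bm_error("'spec' must be a variant_spec", "domain_error")
  if (!length(times)) bm_error("'times' must be non-empty", "domain_error")
  bm_check_number(noise_sd, "noise_sd", lower = 0)
  mu <- eval_burst(spec$burst, times)
  with_seed_or_stream(seed, {
    lapply(seq_len(n_reps), function(r) {
      P <- mu + stats::rnorm(length(times), 0, noise_sd)
      P <- pmin(pmax(P, 0), substrate_total)
      time_course(spec$name, condition, times, P, replicate = r,
                  substrate_total = substrate_total)
    })
  })
}

#' Emulate gel-lane densitometry
#'
#' Turns a time course into per-lane band intensities: the substrate band
#' (uncleaved 20-mer) and product band (9-mer) split the lane's total
#' intensity according to the cleaved fraction. Lane-loading noise is a
#' multiplicative log-normal factor shared by both bands of a lane, which is
#' exactly what ratio-based quantification cancels.
#'
#' @param tc A [time_course()].
#' @param total_intensity Total band intensity per lane, arbitrary units.
#' @param noise_cv Coefficient of variation of the shared lane factor.
#' @param seed Optional seed.
#' @return An object of class `"gel_lanes"`: data frame `lanes` with `time`,
#'   `I_substrate`, `I_product`, plus the originating labels.
#' @export
gen_gel_lanes <- function(tc, total_intensity = 1e4, noise_cv = 0, seed = NULL) {
  if (!inherits(tc, "time_course")) bm_error("'tc' must be a time_course", "domain_error")
  bm_check_number(noise_cv, "noise_cv", lower = 0)
  frac <- tc$data$product / tc$substrate_total
  lanes <- data.frame(time = tc$data$time,
                      I_substrate = total_intensity * (1 - frac),
                      I_product = total_intensity * frac)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    lanes <- with_seed_or_stream(seed, {
      fac <- stats::rlnorm(nrow(lanes), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      lanes$I_substrate <- lanes$I_substrate * fac
      lanes$I_product <- lanes$I_product * fac
      lanes
    })
  }
  structure(list(lanes = lanes, variant = tc$variant, condition = tc$condition,
                 replicate = tc$data$replicate[1],
                 substrate_total = tc$substrate_total),
            class = "gel_lanes")
}

#' Quantify gel lanes into a time course
#'
#' Ratio-based densitometry: `P = substrate_total * I_product /
#' (I_product + I_substrate)`. Shared lane-loading factors cancel exactly.
#' Lanes with both bands zero carry no information and are dropped with a
#' warning.
#'
#' @param lanes A [gen_gel_lanes()] result.
#' @param substrate_total Total substrate, nM; defaults to the value recorded
#'   on the lanes.
#' @return A [time_course()].
#' @export
quantify_lanes <- function(lanes, substrate_total = lanes$substrate_total) {
  if (!inherits(lanes, "gel_lanes")) bm_error("'lanes' must be a gel_lanes object", "domain_error")
  d <- lanes$lanes
  if (any(d$I_substrate < 0) || any(d$I_product < 0)) {
    bm_error("band intensities must be non-negative", "domain_error")
  }
  tot <- d$I_substrate + d$I_product
  dead <- tot <= 0
  if (all(dead)) bm_error("every lane has zero total intensity", "degenerate_data")
  if (any(dead)) {
    warning(sprintf("dropping %d lane(s) with zero total intensity (t = %s min)",
                    sum(dead), paste(d$time[dead], collapse = ", ")))
    d <- d[!dead, ]
    tot <- tot[!dead]
  }
  P <- substrate_total * d$I_product / tot
  time_course(lanes$variant, lanes$condition, d$time, P,
              replicate = lanes$replicate, substrate_total = substrate_total)
}

#' Simulate CD melting curves
#'
#' Two-state melts on the instrument's 10-95 degC ramp: the ellipticity is a
#' population-weighted mix of linear native and denatured baselines with
#' Gaussian noise. Default baselines give the strongly negative native
#' 222 nm signal of a helical protein relaxing toward a shallower denatured
#' baseline.
#'
#' @param spec A [variant_spec()].
#' @param T_grid Temperature grid, degC (default `seq(10, 95, 0.5)`).
#' @param native_baseline,denatured_baseline `(intercept, slope)` of the two
#'   baselines, degree cm^2 dmol^-1 (and per degC).
#' @param noise_sd Noise SD in ellipticity units; `NULL` (default) uses 2% of
#'   the transition amplitude at `Tm`.
#' @param n_reps Number of replicates (default 3).
#' @param seed Optional seed.
#' @return List of `n_reps` [melt_curve()] objects.
#' @export
gen_melt <- function(spec, T_grid = seq(10, 95, by = 0.5),
                     native_baseline = c(-12000, 20),
                     denatured_baseline = c(-4000, 5),
                     noise_sd = NULL, n_reps = 3, seed = NULL) {
  if (!inherits(spec, "variant_spec")) bm_error("'spec' must be a variant_spec", "domain_error")
  if (any(T_grid < 0) || any(T_grid > 100)) {
    bm_error("temperature grid must lie inside [0, 100] degC", "domain_error")
  }
  f <- fraction_folded(T_grid, spec$Tm, spec$dH_vH)
  thN <- native_baseline[1] + native_baseline[2] * T_grid
  thD <- denatured_baseline[1] + denatured_baseline[2] * T_grid
  mu <- f * thN + (1 - f) * thD
  if (is.null(noise_sd)) {
    amp <- abs((denatured_baseline[1] + denatured_baseline[2] * spec$Tm) -
               (native_baseline[1] + native_baseline[2] * spec$Tm))
    noise_sd <- 0.02 * amp
  }
  with_seed_or_stream(seed, {
    lapply(seq_len(n_reps), function(r) {
      melt_curve(spec$name, r, T_grid, mu + stats::rnorm(length(T_grid), 0, noise_sd))
    })
  })
}

#' Active fraction surviving a pre-incubation
#'
#' First-order irreversible loss over the pre-incubation:
#' `f = exp(-k_den(T) * duration)` with
#' `k_den(T) = k_den_ref * exp(alpha * (T - Tm))`, multiplied by
#' `dna_protection` when competitor DNA is bound.
#'
#' @param spec A [variant_spec()].
#' @param cond A [preincubation_condition()].
#' @return Active fraction in `[0, 1]`.
#' @export
active_fraction <- function(spec, cond) {
  if (!inherits(spec, "variant_spec")) bm_error("'spec' must be a variant_spec", "domain_error")
  if (!inherits(cond, "preincubation_condition")) {
    bm_error("'cond' must be a preincubation_condition", "domain_error")
  }
  k_den <- spec$k_den_ref * exp(spec$alpha * (cond$temperature - spec$Tm))
  if (cond$competitor_dna) k_den <- k_den * spec$dna_protection
  exp(-k_den * cond$duration)
}

#' Simulate a pre-incubated excision time course
#'
#' Scales the ground-truth burst parameters by the surviving active fraction
#' — denatured enzyme contributes neither burst amplitude nor steady-state
#' turnover, so `A0` and `k2` scale with `f` while `k1` (a property of the
#' still-folded molecules) is unchanged — then simulates as
#' [gen_time_course()].
#'
#' @inheritParams gen_time_course
#' @param cond A [preincubation_condition()].
#' @return List of [time_course()] objects labelled `pre4`, `pre37`,
#'   `pre4+DNA` or `pre37+DNA`.
#' @export
gen_preincubated_time_course <- function(spec, cond, times = default_time_grid(),
                                         noise_sd = 0.5, n_reps = 3, seed = NULL,
                                         substrate_total = 20) {
  f <- active_fraction(spec, cond)
  scaled <- variant_spec(spec$name,
                         burst_params(f * spec$burst$A0, spec$burst$k1,
                                      f * spec$burst$k2,
                                      substrate_total = substrate_total),
                         Tm = spec$Tm, dH_vH = spec$dH_vH,
                         k_den_ref = spec$k_den_ref, alpha = spec$alpha,
                         dna_protection = spec$dna_protection)
  gen_time_course(scaled, times = times, noise_sd = noise_sd, n_reps = n_reps,
                  seed = seed, substrate_total = substrate_total,
                  condition = condition_label(cond))
}

#' Mechanistic single-turnover simulator
#'
#' Integrates the minimal glycosylase mechanism
#' `E + S <-> ES -> EP -> E + P` as an independent oracle for the burst
#' model. The observable is `[EP] + [P]`: the alkali quench reveals cleaved
#' DNA whether or not the enzyme has released it, which is exactly why a
#' burst appears when chemistry outruns product release. In the fast-binding
#' / slow-release regime the observable approaches
#' `S0 (1 - exp(-k_chem t))` plus a slow linear tail.
#'
#' @param kon Association rate, nM^-1 min^-1.
#' @param koff Dissociation rate, min^-1.
#' @param kchem Chemistry (base-excision) rate, min^-1.
#' @param krel Product release rate, min^-1.
#' @param E0,S0 Total enzyme and substrate, nM (study design 100 and 20).
#' @param t_grid Output times, min.
#' @param rtol,atol Integrator tolerances.
#' @return Data frame with `time`, the species `S`, `ES`, `EP`, `P`, the free
#'   enzyme `E` and the quench `observable = EP + P`.
#' @export
simulate_mechanism <- function(kon, koff, kchem, krel, E0 = 100, S0 = 20,
                               t_grid = seq(0, 30, by = 0.1),
                               rtol = 1e-10, atol = 1e-10) {
  for (r in c(kon = kon, koff = koff, kchem = kchem, krel = krel)) {
    if (!is.finite(r) || r < 0) bm_error("all rates must be finite and non-negative", "domain_error")
  }
  deriv <- function(t, y, parms) {
    E <- E0 - y["ES"] - y["EP"]
    bind <- kon * E * y["S"]
    list(c(S = -bind + koff * y["ES"],
           ES = bind - (koff + kchem) * y["ES"],
           EP = kchem * y["ES"] - krel * y["EP"],
           P = krel * y["EP"]))
  }
  y0 <- c(S = S0, ES = 0, EP = 0, P = 0)
  sol <- deSolve::ode(y = y0, times = t_grid, func = deriv, parms = NULL,
                      rtol = rtol, atol = atol)
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0) {
    bm_error(sprintf("ODE integration failed (istate = %d)", attr(sol, "istate")[1]),
             "integration_error")
  }
  out <- as.data.frame(sol)
  out$E <- E0 - out$ES - out$EP
  out$observable <- out$EP + out$P
  out
}

#' Generate a complete synthetic study
#'
#' Everything the pipeline consumes for all five variants: kinetics
#' triplicates, melt triplicates, and the 2x2 pre-incubation panel
#' (4/37 degC, with/without competitor DNA), all driven by a single seed.
#'
#' @param specs Named list of [variant_spec()] objects (default the five
#'   study variants).
#' @param seed Master seed; one seed reproduces the whole bundle.
#' @param noise_sd Time-course noise SD, nM.
#' @param melt_noise_sd Melt noise SD (ellipticity units); `NULL` = 2% of
#'   amplitude.
#' @param n_reps Replicates per cell.
#' @return An object of class `"synthetic_study"`: `time_courses` (flat list),
#'   `melts` (list per variant), `preincubation` (flat list of time courses),
#'   `specs` and `seed`.
#' @export
gen_study <- function(specs = hogg1_variant_specs(), seed = 1,
                      noise_sd = 0.5, melt_noise_sd = NULL, n_reps = 3) {
  nms <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nms)) bm_error("variant names must be unique", "domain_error")
  conds <- list(preincubation_condition(4), preincubation_condition(37),
                preincubation_condition(4, competitor_dna = TRUE),
                preincubation_condition(37, competitor_dna = TRUE))
  with_seed_or_stream(seed, {
    tcs <- list(); melts <- list(); pre <- list()
    for (s in specs) {
      tcs <- c(tcs, gen_time_course(s, noise_sd = noise_sd, n_reps = n_reps))
      melts[[s$name]] <- gen_melt(s, noise_sd = melt_noise_sd, n_reps = n_reps)
      for (cond in conds) {
        pre <- c(pre, gen_preincubated_time_course(s, cond, noise_sd = noise_sd,
                                                   n_reps = n_reps))
      }
    }
    structure(list(time_courses = tcs, melts = melts, preincubation = pre,
                   specs = specs, seed = seed), class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d variants, %d kinetics time courses, %d melt curves, %d pre-incubation time courses (seed %s)\n",
              length(x$specs), length(x$time_courses),
              sum(lengths(x$melts)), length(x$preincubation),
              as.character(x$seed)))
  invisible(x)
}
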