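test_that("fraction_folded matches the two-state closed form", {
  expect_identical(fraction_folded(36.6, Tm = 36.6, dH_vH = 200), 0.5)
  # deep in the native baseline the protein is fully folded
  expect_equal(fraction_folded(6.6, Tm = 36.6, dH_vH = 400), 1, tolerance = 1e-6)
  # frozen high-precision value of the closed form
  expect_equal(fraction_folded(40, Tm = 36.6, dH_vH = 200),
               0.30085939160558504, tolerance = 1e-12)
  expect_error(fraction_folded(40, 36.6, -5), class = "domain_error")
  expect_error(fraction_folded(40, 36.6, 0), class = "domain_error")
})

test_that("fraction_folded is 0.5 at Tm and strictly decreasing for random parameters", {
  withr::with_seed(44, {
    for (i in 1:20) {
      Tm <- runif(1, 20, 80)
      dH <- runif(1, 50, 600)
      expect_equal(fraction_folded(Tm, Tm, dH), 0.5, tolerance = 1e-12)
      f <- fraction_folded(seq(5, 95, 1), Tm, dH)
      expect_true(all(diff(f) < 0))
      expect_true(all(f >= 0 & f <= 1))
    }
  })
})

test_that("melt_curve enforces monotone temperatures within range", {
  expect_error(melt_curve("x", 1, c(10, 20, 20), c(1, 2, 3)), class = "domain_error")
  expect_error(melt_curve("x", 1, c(10, 120), c(1, 2)), class = "domain_error")
  expect_silent(melt_curve("x", 1, c(10, 20), c(1, 2)))
})

test_that("Savitzky-Golay smoothing preserves smooth signals and validates its settings", {
  Tg <- seq(10, 95, 0.5)
  spec <- variant_spec("x", burst_params(10, 1, 0.1), Tm = 42)
  # on a grid fine enough that the sigmoid is locally cubic, the filter is
  # transparent to well below the signal range
  cv <- gen_melt(spec, T_grid = seq(10, 95, 0.1), noise_sd = 0, n_reps = 1)[[1]]
  sm <- smooth_melt(cv)
  rng <- diff(range(cv$data$theta222))
  expect_lt(sqrt(mean((sm$data$theta222 - cv$data$theta222)^2)), 1e-6 * rng)
  # a constant passes through unchanged
  const <- melt_curve("c", 1, Tg, rep(-5000, length(Tg)))
  expect_equal(smooth_melt(const)$data$theta222, rep(-5000, length(Tg)))
  expect_error(smooth_melt(cv, window = 10), class = "config_error")
  expect_error(smooth_melt(cv, window = 11, order = 11), class = "config_error")
  expect_error(smooth_melt(melt_curve("x", 1, 1:5, 1:5), window = 7),
               class = "config_error")
})

test_that("smoothing attenuates white noise by roughly the filter's theoretical gain", {
  # noise-variance gain of a linear filter is the sum of squared coefficients;
  # for the interior rows of a Savitzky-Golay filter this is tr(H H^T)/n
  Tg <- seq(0, 100, length.out = 501)
  signal_part <- sin(Tg / 8)
  window <- 11L; order <- 3L
  H <- signal::sgolay(p = order, n = window)
  gain <- sum(H[(window + 1) %/% 2, ]^2)
  ratios <- withr::with_seed(9, {
    vapply(1:30, function(i) {
      noise <- rnorm(length(Tg), 0, 1)
      y <- signal_part + noise
      sm <- signal::sgolayfilt(y, p = order, n = window)
      resid <- sm - signal::sgolayfilt(signal_part, p = order, n = window)
      stats::var(resid) / stats::var(noise)
    }, numeric(1))
  })
  expect_equal(mean(ratios), gain, tolerance = 0.2)
})

test_that("tm_by_derivative finds the transition and rejects monotone signals", {
  Tg <- seq(10, 95, 0.5)
  spec <- variant_spec("x", burst_params(10, 1, 0.1), Tm = 41.8)
  flat <- gen_melt(spec, native_baseline = c(-10000, 0),
                   denatured_baseline = c(-3000, 0), noise_sd = 0, n_reps = 1)[[1]]
  expect_equal(tm_by_derivative(flat), 41.8, tolerance = 0.5)  # grid resolution
  # steep sloping baselines bias the derivative estimate relative to the fit
  sloped <- gen_melt(spec, native_baseline = c(-12000, 60),
                     denatured_baseline = c(-4000, 5), noise_sd = 0, n_reps = 1)[[1]]
  fit <- fit_melt(sloped)
  expect_equal(fit$Tm, 41.8, tolerance = 0.05)
  expect_gt(abs(fit$tm_derivative - fit$Tm), 0.25)
  # a monotone line has no transition to find
  line <- melt_curve("l", 1, Tg, -5000 + 10 * Tg)
  expect_error(tm_by_derivative(line), class = "no_transition")
  expect_error(fit_melt(line), class = "no_transition")
})

test_that("fit_melt recovers generating (Tm, dH) over a grid of values", {
  for (Tm in c(36.6, 41.8, 43.2)) {
    for (dH in c(120, 200, 350)) {
      spec <- variant_spec("x", burst_params(10, 1, 0.1), Tm = Tm, dH_vH = dH)
      fm <- fit_melt(gen_melt(spec, noise_sd = 0, n_reps = 1)[[1]])
      expect_lt(abs(fm$Tm - Tm), 0.05)
      expect_lt(abs(fm$dH_vH - dH) / dH, 0.02)
      expect_lt(fm$rss, 1)
    }
  }
})

test_that("fit_melt needs enough points spanning the transition", {
  spec <- variant_spec("x", burst_params(10, 1, 0.1), Tm = 42)
  short <- gen_melt(spec, T_grid = seq(35, 50, 1), noise_sd = 0, n_reps = 1)[[1]]
  expect_error(fit_melt(short), class = "insufficient_data")
})

test_that("Tm recovery from noisy melts is nearly unbiased with triplicate-level scatter", {
  spec <- variant_spec("R46Q", burst_params(10.5, 2, 0.14), Tm = 36.6)
  tms <- withr::with_seed(50, {
    vapply(1:100, function(i) fit_melt(gen_melt(spec, n_reps = 1)[[1]])$Tm,
           numeric(1))
  })
  expect_lt(abs(mean(tms) - 36.6), 0.2)
  # scatter comparable to the 0.1-0.5 degC replicate spread seen in practice
  expect_gt(sd(tms), 0.05)
  expect_lt(sd(tms), 0.5)
})

test_that("normalized fraction denatured is 0.5 at Tm and stays within bounds", {
  spec <- variant_spec("x", burst_params(10, 1, 0.1), Tm = 41.8)
  cv <- gen_melt(spec, noise_sd = 0, n_reps = 1)[[1]]
  fm <- fit_melt(cv)
  fd <- fraction_denatured(cv, fm)
  expect_false(attr(fd, "flagged"))
  expect_true(all(fd$fraction_denatured > -0.05 & fd$fraction_denatured < 1.05))
  at_tm <- stats::approx(fd$temperature, fd$fraction_denatured, xout = fm$Tm)$y
  expect_equal(at_tm, 0.5, tolerance = 1e-3)
})

test_that("average_melts summarizes replicate Tm values and ranks the variants", {
  spec <- variant_spec("x", burst_params(10, 1, 0.1), Tm = 40)
  reps <- gen_melt(spec, noise_sd = 0, n_reps = 3)
  av <- average_melts(reps)
  expect_equal(av$tm_sd, 0, tolerance = 1e-6)   # identical replicates
  expect_equal(av$tm_mean, 40, tolerance = 0.05)
  single <- average_melts(reps[1])
  expect_true(is.na(single$tm_sd))
  # replicate midpoints {36.1, 36.6, 37.1} average to 36.6 +/- 0.5
  shifted <- lapply(c(36.1, 36.6, 37.1), function(tm)
    gen_melt(variant_spec("x", burst_params(10, 1, 0.1), Tm = tm),
             noise_sd = 0, n_reps = 1)[[1]])
  av3 <- average_melts(shifted)
  expect_equal(av3$tm_mean, 36.6, tolerance = 0.05)
  expect_equal(av3$tm_sd, 0.5, tolerance = 0.05)
})

test_that("seeded triplicates at the published midpoints reproduce the stability ranking", {
  rows <- table1_rows()
  means <- withr::with_seed(60, {
    vapply(names(rows), function(nm) {
      spec <- variant_spec(nm, burst_params(rows[[nm]]$A0, rows[[nm]]$k1,
                                            rows[[nm]]$k2),
                           Tm = rows[[nm]]$Tm)
      average_melts(gen_melt(spec, n_reps = 3))$tm_mean
    }, numeric(1))
  })
  expect_identical(names(which.min(means)), "R46Q")
  expect_identical(names(which.max(means)), "R154H")
  expect_true(means[["R46Q"]] < means[["WT"]])
  expect_true(means[["WT"]] < means[["A85S"]])
  expect_true(means[["WT"]] < means[["S232T"]])
})
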