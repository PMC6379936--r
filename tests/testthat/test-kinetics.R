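test_that("eval_burst matches the closed form and its limits", {
  p <- burst_params(14.2, 1.4, 0.09)
  expect_identical(eval_burst(p, 0), 0)
  # frozen high-precision arithmetic value of the closed form at t = 10
  expect_equal(eval_burst(p, 10), 15.099988192292189, tolerance = 1e-14)
  # with no linear phase the curve plateaus at the burst amplitude
  p2 <- burst_params(7.3, 2.1, 0)
  expect_equal(eval_burst(p2, 1e4), 7.3, tolerance = 1e-12)
  expect_error(eval_burst(p, -1), class = "domain_error")
})

test_that("eval_burst is non-negative and non-decreasing for random valid parameters", {
  withr::with_seed(101, {
    for (i in 1:25) {
      p <- burst_params(runif(1, 0, 20), runif(1, 0.01, 20), runif(1, 0, 5))
      t <- sort(runif(40, 0, 60))
      v <- eval_burst(p, t)
      expect_true(all(v >= 0))
      expect_true(all(diff(v) >= -1e-12))
    }
  })
})

test_that("burst_params enforces its invariants", {
  expect_error(burst_params(-1, 1, 0), class = "domain_error")
  expect_error(burst_params(1, 0, 0), class = "domain_error")
  expect_error(burst_params(1, 1, -0.1), class = "domain_error")
  expect_error(burst_params(25, 1, 0, substrate_total = 20), class = "domain_error")
  expect_silent(burst_params(0, 0.5, 0))
})

test_that("fit_burst recovers all five published parameter sets from noiseless data", {
  for (nm in names(table1_rows())) {
    row <- table1_rows()[[nm]]
    f <- fit_burst(noiseless_tc(row, nm))
    expect_identical(f$model, "burst")
    expect_true(f$converged)
    truth <- c(A0 = row$A0, k1 = row$k1, k2 = row$k2)
    expect_equal(f$params, truth, tolerance = 1e-4)
    # covariance is symmetric PSD and standard errors non-negative
    expect_equal(f$cov, t(f$cov))
    expect_true(all(eigen(f$cov, only.values = TRUE)$values > -1e-12))
    expect_true(all(f$se >= 0))
  }
})

test_that("fit_burst rejects too few distinct times and pure lines select linear_only", {
  tms <- c(1, 2, 5, 10)
  expect_error(fit_burst(time_course("x", "s", tms, 0.1 * tms)),
               class = "insufficient_data")
  # degenerate burst: data on a line through the origin
  tms <- default_time_grid()
  f <- fit_burst(time_course("x", "s", tms, 0.3 * tms))
  expect_identical(f$model, "linear_only")
  expect_true(is.na(f$params["A0"]) && is.na(f$params["k1"]))
  expect_true(is.na(f$se["A0"]) && is.na(f$se["k1"]))
  expect_equal(unname(f$params["k2"]), 0.3, tolerance = 1e-8)
})

test_that("compare_models distinguishes bursts from lines", {
  tms <- default_time_grid()
  # noiseless published wild-type curve is emphatically a burst
  cm <- compare_models(noiseless_tc(table1_rows()$WT))
  expect_identical(cm$model, "burst")
  # constant-zero data: linear only with k2 ~ 0
  cm0 <- compare_models(time_course("x", "s", tms, rep(0, length(tms))))
  expect_identical(cm0$model, "linear_only")
  expect_equal(cm0$k2_linear, 0)
  # noisy null: a line plus noise should rarely be called a burst at alpha 0.01
  calls <- withr::with_seed(7, {
    vapply(1:200, function(i) {
      P <- pmax(0.3 * tms + rnorm(length(tms), 0, 0.5), 0)
      compare_models(time_course("x", "s", tms, P), alpha = 0.01)$model
    }, character(1))
  })
  expect_gte(mean(calls == "linear_only"), 0.95)
})

test_that("fit objective is no worse than an exhaustive grid search", {
  withr::with_seed(33, {
    for (i in 1:5) {
      row <- table1_rows()[[sample(5, 1)]]
      tc <- gen_time_course(
        variant_spec("x", burst_params(row$A0, row$k1, row$k2), Tm = 40),
        n_reps = 1)[[1]]
      f <- fit_burst(tc)
      rss <- if (f$model == "burst") f$rss else f$model_test$rss_burst
      expect_lte(rss, grid_search_rss(tc$data$time, tc$data$product) + 1e-9)
    }
  })
})

test_that("Monte-Carlo recovery from noisy data is unbiased for the slow R154H variant", {
  row <- table1_rows()$R154H
  spec <- variant_spec("R154H", burst_params(row$A0, row$k1, row$k2), Tm = row$Tm)
  est <- withr::with_seed(20, {
    vapply(1:200, function(i) {
      fit_burst(aggregate_replicates(gen_time_course(spec, n_reps = 3)))$params
    }, numeric(3))
  })
  k1_mean <- mean(est["k1", ])
  k1_sem <- sd(est["k1", ]) / sqrt(ncol(est))
  expect_lt(abs(k1_mean - row$k1), 3 * k1_sem)
  # fit-reported standard error is on the scale of the empirical scatter
  f1 <- withr::with_seed(21,
    fit_burst(aggregate_replicates(gen_time_course(spec, n_reps = 3))))
  expect_gt(f1$se["k1"], sd(est["k1", ]) / 5)
  expect_lt(f1$se["k1"], sd(est["k1", ]) * 5)
})

test_that("residual bootstrap reports uncertainty consistent with fit covariance", {
  row <- table1_rows()$WT
  spec <- variant_spec("WT", burst_params(row$A0, row$k1, row$k2), Tm = row$Tm)
  tc <- withr::with_seed(5, aggregate_replicates(gen_time_course(spec, n_reps = 3)))
  f <- fit_burst(tc, n_boot = 300, seed = 6)
  expect_equal(f$boot$n_boot, 300)
  for (p in c("A0", "k1", "k2")) {
    expect_gt(f$boot$se_boot[[p]], f$se[[p]] / 5)
    expect_lt(f$boot$se_boot[[p]], f$se[[p]] * 5)
  }
})

test_that("aggregate_replicates computes per-time mean and n-1 SD", {
  tms <- default_time_grid()
  reps <- lapply(1:3, function(r)
    time_course("v", "s", tms, 0.4 * tms, replicate = r))
  agg <- aggregate_replicates(reps)
  expect_equal(agg$data$product, 0.4 * tms)
  expect_equal(agg$data$sd, rep(0, length(tms)))
  expect_equal(agg$data$n, rep(3L, length(tms)))
  # hand arithmetic at one time point: {10, 12, 14} -> mean 12, SD 2
  one <- lapply(c(10, 12, 14), function(p)
    time_course("v", "s", c(1, 2, 3, 4, 5), c(1, 2, 3, 4, p), replicate = p))
  agg1 <- aggregate_replicates(one)
  expect_equal(agg1$data$product[5], 12)
  expect_equal(agg1$data$sd[5], 2)
  # mismatched grids are an alignment error naming the offending time
  bad <- c(reps, list(time_course("v", "s", tms + 0.25, 0.4 * tms, replicate = 9)))
  err <- expect_error(aggregate_replicates(bad), class = "alignment_error")
  expect_match(conditionMessage(err), "0.75")
})

test_that("per-time SD of simulated triplicates estimates the generating noise", {
  spec <- variant_spec("WT", burst_params(14.2, 1.4, 0.09), Tm = 41.8)
  tms <- seq(0.5, 30, length.out = 60)
  agg <- withr::with_seed(12,
    aggregate_replicates(gen_time_course(spec, times = tms, noise_sd = 0.5,
                                         n_reps = 8)))
  expect_equal(mean(agg$data$sd), 0.5, tolerance = 0.15)
})

test_that("relative activity reproduces the published ~16% and its identities", {
  wt <- fit_burst(noiseless_tc(table1_rows()$WT, "WT"))
  mu <- fit_burst(noiseless_tc(table1_rows()$R154H, "R154H"))
  ra <- relative_activity(mu, wt)
  expect_equal(ra$percent, 100 * 0.23 / 1.4, tolerance = 1e-4)
  expect_equal(round(ra$percent), 16)
  expect_identical(relative_activity(wt, wt)$percent, 100)
  half <- fit_burst(noiseless_tc(list(A0 = 14.2, k1 = 0.7, k2 = 0.09), "half"))
  expect_equal(relative_activity(half, wt)$percent, 50, tolerance = 1e-4)
  # degenerate fits are rejected
  lin <- fit_burst(time_course("x", "s", default_time_grid(),
                               0.2 * default_time_grid()))
  expect_error(relative_activity(lin, wt), class = "domain_error")
})
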