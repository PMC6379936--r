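# Published ground truth used throughout the suite: burst parameters
# (A0 nM, k1 min^-1, k2 nM min^-1) and CD melting temperatures (degC)
# for wild-type hOGG1 and its four variants.
table1_rows <- function() {
  list(
    WT    = list(A0 = 14.2, k1 = 1.4,  k2 = 0.09, Tm = 41.8),
    R46Q  = list(A0 = 10.5, k1 = 2.0,  k2 = 0.14, Tm = 36.6),
    A85S  = list(A0 = 14.3, k1 = 1.6,  k2 = 0.08, Tm = 42.2),
    R154H = list(A0 = 8.4,  k1 = 0.23, k2 = 0.14, Tm = 43.2),
    S232T = list(A0 = 10.5, k1 = 0.8,  k2 = 0.15, Tm = 42.2)
  )
}

noiseless_tc <- function(row, name = "x", times = default_time_grid()) {
  p <- burst_params(row$A0, row$k1, row$k2, substrate_total = 20)
  time_course(name, "standard", times, eval_burst(p, times))
}

# Independent oracle for the least-squares objective: exhaustive evaluation
# of the burst-model RSS on a 30x30x30 grid over the fit's own bounds.
grid_search_rss <- function(t, P, A0_max = 20) {
  A0s <- seq(0, A0_max, length.out = 30)
  k1s <- exp(seq(log(1e-3), log(100), length.out = 30))
  k2s <- seq(0, 10, length.out = 30)
  best <- Inf
  for (A0 in A0s) for (k1 in k1s) {
    burst <- A0 * (1 - exp(-k1 * t))
    for (k2 in k2s) {
      rss <- sum((burst + k2 * t - P)^2)
      if (rss < best) best <- rss
    }
  }
  best
}
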