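make_dff <- function(onset_l, amplitude = 1, tau_r = 20, t_max = 500) {
  t <- 0:t_max
  list(t = t, dff = transient_kernel(t, amplitude, tau_r, Inf, onset_l))
}

test_that("response calls follow the 10%-above-baseline rule", {
  tr <- make_dff(50, amplitude = 0.3)
  call <- detect_response(tr$dff, tr$t, onset = 0, response_window = 500,
                          min_consecutive = 5)
  expect_true(call$responsive)
  expect_equal(call$peak_dff, max(tr$dff[-1]))

  weak <- make_dff(50, amplitude = 0.05)
  call2 <- detect_response(weak$dff, weak$t, onset = 0, response_window = 500,
                           min_consecutive = 5)
  expect_false(call2$responsive)
  expect_true(is.na(call2$latency_ms))
  expect_equal(call2$peak_dff, max(weak$dff[-1]), tolerance = 1e-12)
})

test_that("a fully masked window makes the call indeterminate", {
  call <- detect_response(rep(NA_real_, 50), 0:49, onset = 0,
                          response_window = 40)
  expect_true(is.na(call$responsive))
})

test_that("masked samples break supra-threshold runs", {
  dff <- rep(0, 30)
  dff[c(10, 12)] <- 0.5   # two crossings separated by a masked sample
  dff[11] <- NA
  call <- detect_response(dff, 0:29, onset = 0, response_window = 29,
                          min_consecutive = 2)
  expect_false(call$responsive)
  dff[11] <- 0.5
  expect_true(detect_response(dff, 0:29, onset = 0, response_window = 29,
                              min_consecutive = 2)$responsive)
})

test_that("interpolated latency matches the closed-form crossing", {
  # saturating rise 1 - exp(-(t - L)/20) crosses 0.1 at L - 20*log(0.9)
  for (L in c(37.9, 67.9)) {
    tr <- make_dff(L)
    lat <- estimate_latency(tr$dff, tr$t, onset = 0, response_window = 500,
                            min_consecutive = 5)
    expect_equal(lat, oracle_crossing_time(L, 20, 0.1), tolerance = 1e-3)
    expect_equal(lat, L + 2.107, tolerance = 0.01)
  }
  # audit rule: first at/above-threshold sample, no interpolation
  tr <- make_dff(37.9)
  lat_raw <- estimate_latency(tr$dff, tr$t, onset = 0, response_window = 500,
                              min_consecutive = 5, interpolate = FALSE)
  expect_equal(lat_raw, 41)
})

test_that("no crossing yields an absent latency", {
  tr <- make_dff(50, amplitude = 0.09)
  expect_true(is.na(estimate_latency(tr$dff, tr$t, onset = 0,
                                     response_window = 500,
                                     min_consecutive = 5)))
})

test_that("latency shifts exactly with transient onset (property)", {
  base <- estimate_latency(make_dff(40)$dff, 0:500, 0, 500,
                           min_consecutive = 5)
  for (delta in c(5, 13, 60, 111)) {
    tr <- make_dff(40 + delta)
    lat <- estimate_latency(tr$dff, tr$t, 0, 500, min_consecutive = 5)
    expect_equal(lat, base + delta, tolerance = 1e-9)
  }
})

test_that("latency is invariant to raw-fluorescence rescaling (property)", {
  t <- 0:500
  f0 <- 120
  f <- f0 * (1 + transient_kernel(t, 0.8, 20, Inf, 45))
  for (gain in c(0.2, 3, 17)) {
    lat <- estimate_latency(compute_dff(gain * f, gain * f0), t, 0, 500,
                            min_consecutive = 5)
    expect_equal(lat,
                 estimate_latency(compute_dff(f, f0), t, 0, 500,
                                  min_consecutive = 5))
  }
})

test_that("fold change is the post/pre window-mean ratio", {
  t <- 0:199
  expect_equal(fold_change(rep(3, 200), t, c(0, 100), c(100, 200)), 1.0)
  f <- c(rep(100, 100), rep(140, 100))
  expect_equal(fold_change(f, t, c(0, 100), c(100, 200)), 1.4)
  expect_error(fold_change(rep(0, 200), t, c(0, 100), c(100, 200)),
               "positive")
  expect_error(fold_change(f, t, c(300, 400), c(100, 200)), "no valid")
})

test_that("noisy 1.4x plateau is recovered within sampling error", {
  pt <- simulate_plateau_trace(fold = 1.4, seed = 7)
  fc <- fold_change(pt$trace, pt$time_ms, pt$pre_window, pt$post_window)
  expect_equal(fc, 1.4, tolerance = 0.01)
})

test_that("responder fractions use the majority rule per ROI", {
  calls <- data.frame(
    roi_id = rep(c("a", "b", "c", "d"), each = 3),
    trial_id = rep(1:3, 4),
    responsive = c(TRUE, TRUE, TRUE,    # a: 3/3 responder
                   TRUE, TRUE, FALSE,   # b: 2/3 responder
                   TRUE, FALSE, FALSE,  # c: 1/3 not
                   FALSE, FALSE, FALSE) # d: not
  )
  st <- responder_fraction(calls)
  expect_equal(st$responder_fraction, 0.5)
  expect_equal(st$n_rois, 4)

  all_resp <- data.frame(roi_id = letters[1:5], trial_id = 1,
                         responsive = TRUE)
  expect_equal(responder_fraction(all_resp)$responder_fraction, 1.0)
  one_of_20 <- data.frame(roi_id = paste0("r", 1:20), trial_id = 1,
                          responsive = c(TRUE, rep(FALSE, 19)))
  expect_equal(responder_fraction(one_of_20)$responder_fraction, 0.05)
  expect_error(responder_fraction(all_resp[0, ]), "empty")
})

test_that("fractions aggregate as mean over fields of view", {
  calls <- data.frame(
    roi_id = rep(paste0("r", 1:4), 2),
    field_id = rep(c("f1", "f2"), each = 4),
    trial_id = 1,
    responsive = c(TRUE, TRUE, FALSE, FALSE,  # f1: 0.5
                   TRUE, FALSE, FALSE, FALSE) # f2: 0.25
  )
  st <- responder_fraction(calls)
  expect_equal(st$responder_fraction, 0.375)
  expect_equal(st$n_fields, 2)
  expect_equal(st$sem, sd(c(0.5, 0.25)) / sqrt(2))
})

test_that("classification is unbiased at a known responder rate (property)", {
  # 200 seeded simulations at true fraction p = 0.3 with well-separated
  # amplitudes: the grand mean must fall in the 95% binomial band
  p_true <- 0.3
  n_rois <- 20
  hits <- vapply(1:200, function(s) {
    cfg <- scene_config(n_rois = n_rois, n_trials = 1, baseline_ms = 2000,
                        window_ms = 1000,
                        amplitude = list(dist = "fixed", value = 0.4,
                                         responder = p_true),
                        seed = 9000 + s)
    sim <- simulate_traces(cfg)
    dff <- dff_by_trial(sim$traces, sim$trials, window_ms = 1000,
                        baseline_duration = 2000)
    calls <- call_responses(dff, sim$trials, response_window = 1000)
    sum(calls$responsive)
  }, numeric(1))
  grand <- sum(hits) / (200 * n_rois)
  half_band <- 1.96 * sqrt(p_true * (1 - p_true) / (200 * n_rois))
  expect_lt(abs(grand - p_true), half_band)
})

test_that("latency modes recover unimodal and bimodal structure", {
  expect_equal(latency_modes(rep(70, 10), bandwidth = 5)$modes, 70)
  expect_error(latency_modes(c(1, 2, 3), 5), "at least 5")
  expect_error(latency_modes(rep(70, 10), 0), "bandwidth")

  l5 <- simulate_latencies(latency_mixture(c(40, 70), c(0.6, 0.4), 3),
                           92, seed = 21)
  m5 <- latency_modes(l5, bandwidth = 5)
  expect_length(m5$modes, 2)
  expect_lt(abs(m5$modes[1] - 40), 3)
  expect_lt(abs(m5$modes[2] - 70), 3)

  l4 <- simulate_latencies(latency_mixture(70, 1, 3), 39, seed = 22)
  m4 <- latency_modes(l4, bandwidth = 5)
  expect_length(m4$modes, 1)
  expect_lt(abs(m4$modes - 70), 3)
})

test_that("well-separated mixture modes are recovered across seeds (property)", {
  ok <- vapply(1:20, function(s) {
    x <- simulate_latencies(latency_mixture(c(40, 70), c(0.6, 0.4), 3),
                            92, seed = 300 + s)
    m <- latency_modes(x, bandwidth = 5)$modes
    length(m) == 2 && all(abs(m - c(40, 70)) <= 5)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("KS statistic matches hand-checked and brute-force values", {
  expect_equal(ks_two_sample(1:5, 1:5)$D, 0)
  expect_equal(ks_two_sample(1:5, 1:5)$p_value, 1)
  expect_equal(ks_two_sample(0, 1)$D, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(1.5, 2.5, 3.5))$D, 1 / 3)
})

test_that("KS agrees with the exhaustive ECDF oracle on small samples", {
  set.seed(23)
  for (i in 1:25) {
    na <- sample(1:12, 1); nb <- sample(1:12, 1)
    a <- round(runif(na, 0, 10), 1)
    b <- round(runif(nb, 0, 10), 1)  # rounding forces ties across samples
    expect_equal(ks_two_sample(a, b)$D, oracle_ks_D(a, b))
  }
})

test_that("KS D and asymptotic p match the reference implementation", {
  set.seed(24)
  a <- rnorm(40, 50, 8)
  b <- rnorm(60, 55, 8)
  ours <- ks_two_sample(a, b)
  ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  expect_equal(ours$D, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("population comparison computes percent reduction on means", {
  same <- compare_latency_populations(c(40, 50, 60), c(40, 50, 60))
  expect_equal(same$percent_reduction, 0)
  expect_equal(same$ks$D, 0)

  expect_equal(compare_latency_populations(rep(35, 10),
                                           rep(70, 10))$percent_reduction, 50)

  # exact two-point mixture arithmetic: 0.68 * 40 + 0.32 * 70 = 49.6
  a <- c(rep(40, 68), rep(70, 32))
  cmp <- compare_latency_populations(a, rep(70, 25))
  expect_equal(cmp$mean_a, 49.6)
  expect_equal(cmp$percent_reduction, 100 * (70 - 49.6) / 70)
  expect_error(compare_latency_populations(1:3, c(0, 0, 0)), "positive")
})
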