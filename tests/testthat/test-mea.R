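test_that("an all-zero trace filters to all zeros", {
  rec <- electrode_recording("E", 25000, numeric(1000))
  expect_equal(filter_trace(rec)$samples, numeric(1000))
})

test_that("single-pass response matches the analytic Butterworth curve", {
  spec <- filter_spec(zero_phase = FALSE)
  for (r in c(0.1, 0.5, 1, 2, 10)) {
    analytic <- r^2 / sqrt(1 + r^4)
    expect_lt(abs(measured_gain(r * 200, spec) - analytic) / analytic, 0.01)
  }
  # stop-band and pass-band bounds for spike-band filtering
  expect_lte(measured_gain(20, spec), 0.011)
  expect_gte(measured_gain(2000, spec), 0.99)
})

test_that("zero-phase filtering squares the magnitude response", {
  spec <- filter_spec(zero_phase = TRUE)
  r <- 1
  analytic <- (r^2 / sqrt(1 + r^4))^2
  expect_lt(abs(measured_gain(200, spec) - analytic) / analytic, 0.02)
})

test_that("cutoffs at or above Nyquist are rejected", {
  rec <- electrode_recording("E", 25000, numeric(100))
  expect_error(filter_trace(rec, filter_spec(cutoff = 13000)), "Nyquist")
})

test_that("noise estimators are consistent on Gaussian noise", {
  set.seed(5)
  rec <- electrode_recording("E", 25000, rnorm(250000, 0, 5))
  expect_lt(abs(estimate_noise(rec, "robust") - 5) / 5, 0.05)
  expect_lt(abs(estimate_noise(rec, "plain") - 5) / 5, 0.05)
})

test_that("a constant trace has zero robust noise and spikes inflate the plain SD", {
  rec <- electrode_recording("E", 25000, rep(0, 1000))
  expect_equal(as.numeric(estimate_noise(rec, "robust")), 0)
  set.seed(6)
  x <- rnorm(25000, 0, 5)
  x[seq(1, 25000, by = 50)] <- 100  # dense large spikes
  spiky <- electrode_recording("E", 25000, x)
  expect_lt(estimate_noise(spiky, "robust"), estimate_noise(spiky, "plain"))
})

test_that("subthreshold traces produce no spikes and k must be positive", {
  set.seed(7)
  rec <- electrode_recording("E", 25000, rnorm(25000, 0, 1))
  train <- detect_spikes(rec, k = 50)
  expect_length(train$spike_times, 0)
  expect_error(detect_spikes(rec, k = 0), "k must be")
})

test_that("one suprathreshold pulse inside the dead time is one spike", {
  fs <- 10000
  x <- rep(0.001, fs)          # tiny nonzero floor so noise_sd > 0
  x[5001:5005] <- 1            # 0.5 ms pulse
  rec <- electrode_recording("E", fs, x)
  train <- detect_spikes(rec, k = 5, dead_time = 0.001,
                         noise_sd = 0.01)
  expect_length(train$spike_times, 1)
  expect_equal(train$spike_times, 5000 / fs)
})

test_that("noise-only false positives stay under 2 per minute at k = 5", {
  tr <- trace_sim_truth(60, 1, background_rate = 0, burst_rate = 0,
                        seed = 44)
  rec <- filter_trace(simulate_recording(60, 1, tr)[[1]])
  train <- detect_spikes(rec, k = 5)
  expect_lte(length(train$spike_times), 2)
})

test_that("burst detection matches the worked examples", {
  b1 <- detect_bursts(spike_train("E", c(0, 0.05, 0.10, 0.15)))
  expect_equal(nrow(b1), 1)
  expect_equal(b1$n_spikes, 4L)
  expect_equal(c(b1$start, b1$end), c(0, 0.15))

  b2 <- detect_bursts(spike_train("E", c(0, 0.05, 0.10)))
  expect_equal(nrow(b2), 0)

  ts <- cumsum(c(0.2, 0.05, 0.05, 0.101, 0.05, 0.05, 0.05))
  b3 <- detect_bursts(spike_train("E", ts))
  expect_equal(nrow(b3), 1)
  expect_equal(b3$n_spikes, 4L)
  expect_equal(b3$start, ts[4])
})

test_that("burst detection equals the exhaustive oracle on random trains", {
  for (seed in 1:60) {
    ts <- random_train(sample(4:200, 1), seed = seed)
    got <- detect_bursts(spike_train("E", ts))
    want <- oracle_bursts(ts)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_spikes, want$n_spikes)
    }
  }
})

test_that("electrode QC applies the noise and activity rules", {
  rec <- electrode_recording("E", 25000, rnorm(25000))
  noisy <- spike_train("E", c(1, 2), noise_sd = 60, duration = 1)
  q1 <- electrode_qc(rec, noisy)
  expect_false(q1$include)
  expect_identical(q1$reasons, "noise")

  silent <- spike_train("E", numeric(0), noise_sd = 30, duration = 1)
  q2 <- electrode_qc(rec, silent)
  expect_false(q2$include)
  expect_identical(q2$reasons, "no spontaneous activity")

  active <- spike_train("E", seq(0.1, 0.9, by = 0.1), noise_sd = 30,
                        duration = 1)
  q3 <- electrode_qc(rec, active)
  expect_true(q3$include)
  expect_length(q3$reasons, 0)
})

test_that("raster binning uses half-open bins and conserves spike counts", {
  tr <- spike_train("E", c(0.1, 0.25))
  tr$duration <- 0.4
  expect_equal(bin_raster(tr, 0.2, 0.4), c(1L, 1L))
  expect_equal(bin_raster(spike_train("E", numeric(0)), 0.2, 1), rep(0L, 5))
  set.seed(19)
  ts <- sort(runif(100, 0, 10))
  tr2 <- spike_train("E", ts)
  for (w in c(0.05, 0.2, 0.33, 1)) {
    expect_equal(sum(bin_raster(tr2, w, 10)), 100)
  }
})

test_that("activity summaries normalize to the pre-treatment rate", {
  ep <- function(ts, bursts_n, dur) {
    train <- spike_train("E01", ts, duration = dur)
    bursts <- if (bursts_n > 0) {
      detect_bursts(spike_train("E01", seq(0, by = 0.05,
                                           length.out = 4 * bursts_n)))
    } else {
      detect_bursts(spike_train("E01", numeric(0)))
    }
    list(train = train, bursts = bursts, duration = dur)
  }
  pre <- ep(seq(0, 9.5, by = 0.5), 0, 10)   # 2 Hz
  post <- ep(seq(0, 9.9, length.out = 30), 0, 10)  # 3 Hz
  s <- summarize_activity(pre, post)
  expect_equal(s$spike_pct_baseline, 150)
  expect_true(s$burst_pct_undefined)
  expect_true(is.na(s$burst_pct_baseline))
  same <- summarize_activity(pre, pre)
  expect_equal(same$spike_pct_baseline, 100)
})

test_that("the paired test matches t.test and handles degeneracy", {
  set.seed(29)
  pre <- rnorm(12, 2, 0.5)
  post <- pre + rnorm(12, 0.3, 0.4)
  got <- paired_prepost_test(pre, post)
  ref <- t.test(post, pre, paired = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  d <- post - pre
  expect_equal(got$t, mean(d) / (sd(d) / sqrt(12)), tolerance = 1e-12)

  eq <- paired_prepost_test(pre, pre)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  shift <- paired_prepost_test(pre, pre + 1)
  expect_true(shift$degenerate)
  expect_equal(shift$p, 0)
  expect_error(paired_prepost_test(1, 2), ">= 2")
})
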