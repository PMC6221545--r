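# Synthetic-data generators and generator/analyzer consistency.

test_that("ferredoxin decay generation round-trips the genotype half-lives", {
  expected <- c(WT = 0.416, prx_null = 0.120, C1 = 0.408, C2 = 0.386)
  for (g in names(expected)) {
    tr <- gen_fd_decay(g, duration = 4.5, dt = 0.001)
    fit <- fit_exponential_decay(tr)
    expect_equal(fit$t50, expected[[g]], tolerance = 1e-6)
    expect_equal(fit$amplitude, 1, tolerance = 1e-6)
    expect_equal(fit$offset, 0, tolerance = 1e-6)
  }
  # WT/null contrast: oxidation ~3.5x faster without the peroxiredoxin
  expect_equal(0.416 / 0.120, 3.47, tolerance = 0.01)
  expect_error(gen_fd_decay("unknown"))
})

test_that("generators are bit-identical under a fixed seed", {
  n1 <- noise_spec(sigma = 0.01, seed = 77)
  expect_identical(gen_fd_decay("WT", noise = n1)$signal,
                   gen_fd_decay("WT", noise = n1)$signal)
  expect_false(identical(gen_fd_decay("WT", noise = n1)$signal,
                         gen_fd_decay("WT",
                                      noise = noise_spec(0.01, seed = 78)
                                      )$signal))
  c1 <- gen_inactivation_course("WT", "mdh",
                                noise = noise_spec(1, seed = 5))
  c2 <- gen_inactivation_course("WT", "mdh",
                                noise = noise_spec(1, seed = 5))
  expect_identical(c1$signal, c2$signal)
})

test_that("dark-inactivation courses hit the measured 10-s residuals", {
  expected <- c(WT = 55.8, prx_null = 90.9, C1 = 61.0, C2 = 73.2)
  for (g in names(expected)) {
    tc <- gen_inactivation_course(g, "mdh")
    expect_equal(residual_activity(tc, 10), expected[[g]],
                 tolerance = 1e-9)
    expect_equal(tc$signal[1], 100, tolerance = 1e-12)
  }
  # replicates: independent noise around the same mean course
  reps <- gen_inactivation_course("WT", "mdh",
                                  noise = noise_spec(2, seed = 9),
                                  n_replicates = 4)
  expect_length(reps, 4)
  expect_false(identical(reps[[1]]$signal, reps[[2]]$signal))
  expect_error(gen_inactivation_course("WT", "mdh", sample_times = c(5, 10)),
               "start at 0")
})

test_that("PRK courses decline in WT but stay flat without 2-CysPrx", {
  wt <- gen_inactivation_course("WT", "prk")
  ko <- gen_inactivation_course("prx_null", "prk")
  expect_true(all(diff(wt$signal) < 0))
  expect_true(all(ko$signal == 100))
  # activation ratios from the course: strictly decreasing in WT only
  ratios_wt <- vapply(wt$signal, activation_ratio, 0,
                      total_activity = 100)
  expect_true(all(diff(ratios_wt) < 0))
})

test_that("noise-free assay traces equal the bare simulation", {
  cfg <- build_fbpase_assay(1000, "Trx-f1", 5, 0, params = fast_params())
  plain <- simulate_protocol(cfg, t_end = 300)$trace
  gen <- gen_assay_trace(cfg, noise_spec(), t_end = 300)
  expect_identical(gen$signal, plain$signal)
})

test_that("baseline drift on a dead assay is read back as the drift slope", {
  # no DTT: no activity; the only signal is the linear drift
  cfg <- build_fbpase_assay(0, "none", 0, 0, params = fast_params())
  tr <- gen_assay_trace(cfg, noise_spec(drift = 1e-5), t_end = 300)
  est <- max_slope(tr, 30)$slope
  expect_equal(est, 1e-5, tolerance = 0.05)
  # and without drift the dead assay has (numerically) zero slope
  tr0 <- gen_assay_trace(cfg, noise_spec(), t_end = 300)
  expect_lt(max_slope(tr0, 30)$slope, 1e-7)
})

test_that("slope recovery from noisy assay traces stays within 5%", {
  cfg <- build_fbpase_assay(1000, "Trx-f1", 5, 0, params = fast_params())
  plain <- simulate_protocol(cfg, t_end = 300)$trace
  truth <- max_slope(trace_window(plain, 185, 300), 30)$slope
  set.seed(21)
  ests <- replicate(100, {
    noisy <- plain
    noisy$signal <- noisy$signal + stats::rnorm(length(noisy$signal),
                                                sd = 1e-4)
    max_slope(trace_window(noisy, 185, 300), 30)$slope
  })
  expect_true(all(abs(ests - truth) / truth < 0.05))
})

test_that("estimator spread grows with the generator noise level", {
  t50_sd <- vapply(c(0.002, 0.01, 0.05), function(sg) {
    ests <- vapply(1:30, function(s) {
      tr <- gen_fd_decay("WT", duration = 3, dt = 0.002,
                         noise = noise_spec(sg, seed = s))
      fit_exponential_decay(tr)$t50
    }, numeric(1))
    stats::sd(ests)
  }, numeric(1))
  expect_true(all(diff(t50_sd) > 0))
})
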