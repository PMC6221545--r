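# Event-driven assay simulation: protocol bookkeeping, qualitative assay
# behaviour, variants and dose-response.

test_that("a model without reactions or enzymes stays constant", {
  model <- network_model(
    couples = list(redox_couple("A", -0.3, 10, 0.4)),
    metabolites = c(S = 100))
  cfg <- assay_config(model, list(), readout = "A340_up",
                      readout_species = "S")
  res <- simulate_protocol(cfg, t_end = 100)
  expect_equal(diff(range(res$trace$signal)), 0)
  expect_equal(diff(range(res$states$red.A)), 0)
})

test_that("protocol events keep final-concentration bookkeeping", {
  cfg <- build_fbpase_assay(1000, "Trx-f1", 5, 5,
                            params = fast_params())
  res <- simulate_protocol(cfg, t_end = 240)
  # post-dilution: 1000 uM DTT -> 500 final; 2x pools halved
  expect_equal(res$model$couples[["DTT"]]$total, 500)
  expect_equal(res$model$couples[["Trx"]]$total, 5)
  expect_equal(res$model$couples[["FBPase"]]$total, 2)
  expect_equal(res$model$couples[["2-CysPrx"]]$total, 5)

  cfg2 <- build_fbpase_assay(400, "Trx-f1", 5, 0, params = fast_params())
  res2 <- simulate_protocol(cfg2, t_end = 240)
  expect_equal(res2$model$couples[["DTT"]]$total, 200)

  # MDH assay: 1:1 mixing arithmetic for Trx and Prx
  cfgm <- build_mdh_assay("Trx-m1", 10, 5, params = fast_params())
  resm <- simulate_protocol(cfgm, t_end = 60)
  expect_equal(resm$model$couples[["Trx"]]$total, 5)
  expect_equal(resm$model$couples[["2-CysPrx"]]$total, 2.5)
  expect_equal(resm$model$metabolites[["OAA"]] +
                 resm$model$metabolites[["malate"]], 2000)
})

test_that("event and configuration errors are caught", {
  cfg <- build_fbpase_assay(1000, "Trx-f1", 5, 0, params = fast_params())
  cfg$events <- c(cfg$events, list(
    protocol_event(100, "add", species = "nonexistent", amount = 1)))
  expect_error(simulate_protocol(cfg, t_end = 240), "unknown species")
  expect_error(simulate_protocol(build_fbpase_assay(params = fast_params()),
                                 t_end = 100), "beyond t_end")
  expect_error(build_fbpase_assay(trx_name = "Trx-q"),
               "unknown thioredoxin")
  expect_error(build_mdh_assay("Trx-q"), "unknown thioredoxin")
  expect_error(protocol_event(0, "dilute", factor = 0.5), "factor")
})

test_that("the control assay rises linearly and keeps FBPase reduced", {
  cfg <- build_fbpase_assay(1000, "Trx-f1", 5, 0)
  res <- simulate_protocol(cfg, t_end = 300)
  tr <- res$trace
  # A340 flat before FBP, rising after, non-decreasing throughout
  expect_lt(max(tr$signal[tr$time <= 180]), 1e-9)
  expect_gt(assay_slope(res, 185, 300), 0.005)
  expect_true(all(diff(tr$signal) >= -1e-12))
  # the late slope approaches a constant: consecutive 30-s OLS slopes agree
  s1 <- max_slope(trace_window(tr, 190, 220), 30)$slope
  s2 <- max_slope(trace_window(tr, 220, 250), 30)$slope
  expect_lt(abs(s2 - s1) / s1, 0.1)
  # FBPase reduced fraction moves < 1% across the FBP addition
  st <- res$states
  f180 <- st$red.FBPase[st$time == 180] / 2
  f300 <- st$red.FBPase[st$time == 300] / 2
  expect_lt(abs(f300 - f180) / f180, 0.01)
})

test_that("oxidized 2-CysPrx added in the linear phase cuts the slope", {
  base <- build_fbpase_assay(1000, "Trx-f1", 5, prx_ox_conc = 0)
  treated <- base
  treated$events <- c(treated$events, list(
    protocol_event(300, "add", species = "2-CysPrx_ox", amount = 5)))
  treated <- assay_config(treated$model, treated$events,
                          readout = "A340_up", readout_species = "F6P",
                          t_start = treated$t_start)
  res <- simulate_protocol(treated, t_end = 480)
  before <- max_slope(trace_window(res$trace, 240, 295), 30)$slope
  after <- max_slope(trace_window(res$trace, 330, 420), 30)$slope
  expect_lt(after, 0.5 * before)
  # FBPase reduced fraction declines monotonically after the addition
  st <- res$states
  f <- st$red.FBPase[st$time >= 301 & st$time <= 360]
  expect_true(all(diff(f) < 0))
})

test_that("simulations are deterministic", {
  cfg <- build_fbpase_assay(1000, "Trx-f1", 5, 5, params = fast_params())
  r1 <- simulate_protocol(cfg, t_end = 240)
  r2 <- simulate_protocol(cfg, t_end = 240)
  expect_identical(r1$trace$signal, r2$trace$signal)
  expect_identical(r1$states, r2$states)
})

test_that("2-CysPrx variants gate the Trx exchange as their thiols dictate", {
  expect_true(variant_spec("WT")$exchange_active)
  expect_true(variant_spec("F84R")$exchange_active)
  for (v in c("C54S", "C176S", "C54D")) {
    expect_false(variant_spec(v)$exchange_active)
  }
  expect_error(variant_spec("C99S"))

  cfg <- build_fbpase_assay(1000, "Trx-f1", 5, 5, params = fast_params())
  # WT and F84R leave the configuration untouched
  expect_identical(apply_variant(cfg, "WT"), cfg)
  expect_identical(apply_variant(cfg, "F84R"), cfg)
  # exchange-dead variants zero exactly the Trx/Prx reaction
  cs <- apply_variant(cfg, "C54S")
  roles <- vapply(cs$model$reactions, `[[`, "", "role")
  kf <- vapply(cs$model$reactions, `[[`, 0, "k_forward")
  expect_true(all(kf[roles == "trx_prx"] == 0))
  expect_true(all(kf[roles != "trx_prx"] > 0))
  # and therefore produce no inhibition
  r <- fbpase_inhibition(1000, "Trx-f1", 5, 5, variant = "C54S",
                         params = fast_params())
  expect_lt(r$percent, 1)
})

test_that("inhibition requires thioredoxin and the oxidized peroxiredoxin", {
  # oxidized Prx without any Trx: no path to the target
  r <- fbpase_inhibition(1000, "none", 0, 5, params = fast_params())
  expect_lt(r$percent, 5)

  # reduced (instead of oxidized) Prx leaves the control slope unchanged
  ctl <- build_fbpase_assay(1000, "Trx-f1", 5, 0)
  red <- ctl
  red$events <- c(red$events, list(
    protocol_event(0, "add", species = "2-CysPrx_red", amount = 5)))
  red <- assay_config(red$model, red$events, readout = "A340_up",
                      readout_species = "F6P", t_start = red$t_start)
  s_ctl <- assay_slope(simulate_protocol(ctl, t_end = 240), 185, 215)
  s_red <- assay_slope(simulate_protocol(red, t_end = 240), 185, 215)
  expect_lt(abs(s_red - s_ctl) / s_ctl, 0.02)
})

test_that("inhibition increases and saturates with Trx-f1 concentration", {
  inh <- vapply(c(0.625, 1.25, 2.5, 5), function(tc) {
    fbpase_inhibition(1000, "Trx-f1", tc, 5)$percent
  }, numeric(1))
  expect_true(all(diff(inh) > 0))
  # saturation: increments shrink
  expect_true(all(diff(diff(inh)) < 0))
})

test_that("dose-response is control-normalised and strictly decreasing", {
  base <- build_fbpase_assay(1000, "Trx-f1", 5, prx_ox_conc = 0)
  expect_error(dose_response(base, numeric(0)), "empty")
  dr <- dose_response(base, c(0, 2.5, 5, 10, 20))
  expect_identical(dr$relative_slope[1], 1.0)
  expect_true(all(diff(dr$relative_slope) < 0))
  # deterministic replication is bit-identical
  dr2 <- dose_response(base, c(0, 5))
  expect_identical(dr2$relative_slope[2], dr$relative_slope[3])
})

test_that("MDH inhibition follows the Trx isoform specificity ordering", {
  isoforms <- c("Trx-m1", "CDSP32", "Trx-f1", "Trx-x", "Trx-m4")
  inh <- vapply(isoforms, function(tx) mdh_inhibition(tx, 10, 5)$percent,
                numeric(1))
  expect_true(all(diff(inh) < 0))  # strictly decreasing in the listed order
  expect_gt(inh[["Trx-m1"]] - inh[["Trx-m4"]], 20)
  # no Trx carrier: no inhibition despite oxidized Prx
  expect_lt(mdh_inhibition("none", 0, 5)$percent, 2)
})
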