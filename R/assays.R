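# Builders for the in vitro FBPase and MDH assay protocols, site-directed
# 2-CysPrx variants, dose-response simulation and percent-inhibition
# summaries.
#
# Protocol timeline (seconds, recording starts at t = 0):
#   t_start .. -180   pre-activation in DTT (+Trx) at pre-dilution
#                     concentrations
#   -180              1:1 dilution into the reaction mix (plus, for MDH,
#                     NADPH and oxidized 2-CysPrx)
#   0                 test compounds added (oxidized 2-CysPrx, FBPase assay)
#   180               substrate start (600 uM FBP; FBPase assay only; the
#                     MDH assay is started with OAA at t = 0)

TRX_NAMES <- c("Trx-f1", "Trx-m1", "Trx-m4", "Trx-x", "CDSP32")

#' Site-directed 2-CysPrx variant specification
#'
#' The thiol-disulfide exchange between thioredoxin and 2-CysPrx requires
#' both catalytic cysteines: variants lacking the peroxidatic Cys (C54S,
#' C54D) or the resolving Cys (C176S) cannot drain electrons from Trx and
#' are modelled by disabling the Trx/2-CysPrx exchange. F84R (compromised
#' decamerization only) exchanges like wild type.
#'
#' @param name One of `"WT"`, `"C54S"`, `"C176S"`, `"C54D"`, `"F84R"`.
#' @return A `variant_spec` list with fields `name` and `exchange_active`.
#' @export
variant_spec <- function(name = c("WT", "C54S", "C176S", "C54D", "F84R")) {
  name <- match.arg(name)
  structure(list(name = name,
                 exchange_active = name %in% c("WT", "F84R")),
            class = "variant_spec")
}

#' Apply a 2-CysPrx variant to an assay configuration
#'
#' For exchange-dead variants (C54S, C176S, C54D) every reaction tagged with
#' role `"trx_prx"` is disabled (`k_forward = 0`); for WT and F84R the
#' configuration is returned unchanged.
#'
#' @param config An [assay_config()].
#' @param variant A [variant_spec()] or a variant name.
#' @return The (possibly modified) [assay_config()].
#' @export
apply_variant <- function(config, variant = "WT") {
  stopifnot(inherits(config, "assay_config"))
  if (is.character(variant)) variant <- variant_spec(variant)
  stopifnot(inherits(variant, "variant_spec"))
  if (variant$exchange_active) return(config)
  config$model$reactions <- lapply(config$model$reactions, function(rx) {
    if (identical(rx$role, "trx_prx")) {
      rx$k_forward <- 0; rx$k_reverse <- 0; rx$enabled <- FALSE
    }
    rx
  })
  config
}

trx_mult <- function(table, trx_name) {
  if (trx_name %in% names(table)) table[[trx_name]] else 1
}

#' Build the in vitro FBPase assay configuration
#'
#' Encodes the standard protocol: pre-activation of the FBPase in DTT (with
#' or without thioredoxin) at pre-dilution concentrations, 1:1 dilution into
#' the reaction mix at t = -180 s, addition of oxidized 2-CysPrx at
#' `prx_add_time`, substrate start with 600 uM FBP at t = 180 s, and an
#' A340-up readout of NADPH formed 1:1 with fructose-6-phosphate by the
#' (non-limiting) glucose-6-phosphate dehydrogenase / phosphoglucoisomerase
#' coupling.
#'
#' @param dtt_preincubation DTT concentration during pre-activation, uM
#'   (halved by the dilution: 1000 uM gives the standard 500 uM final).
#' @param trx_name Thioredoxin isoform (`"Trx-f1"`, ..., or `"none"`).
#' @param trx_conc Final (post-dilution) Trx concentration, uM.
#' @param prx_ox_conc Final concentration of oxidized 2-CysPrx added, uM
#'   (0 for the control run).
#' @param prx_add_time Addition time of oxidized 2-CysPrx, seconds.
#' @param variant 2-CysPrx variant name or [variant_spec()].
#' @param params Overrides for [default_kinetics()] entries.
#' @return An [assay_config()].
#' @export
build_fbpase_assay <- function(dtt_preincubation = 1000,
                               trx_name = "Trx-f1", trx_conc = 5,
                               prx_ox_conc = 5, prx_add_time = 0,
                               variant = "WT", params = NULL) {
  if (!trx_name %in% c(TRX_NAMES, "none")) {
    stop("unknown thioredoxin '", trx_name, "'", call. = FALSE)
  }
  stopifnot(dtt_preincubation >= 0, trx_conc >= 0, prx_ox_conc >= 0)
  if (trx_name == "none") trx_conc <- 0
  p <- merge_params(default_kinetics(), params)
  EM <- default_potentials()
  trx_label <- if (trx_name == "none") "Trx-f1" else trx_name

  couples <- list(
    redox_couple("DTT", EM[["DTT"]], total = dtt_preincubation,
                 reduced_fraction = 1),
    redox_couple("Trx", EM[[trx_label]], total = 2 * trx_conc,
                 reduced_fraction = 0),
    redox_couple("FBPase", EM[["FBPase"]],
                 total = 2 * p$fbpase$total, reduced_fraction = 0),
    redox_couple("2-CysPrx", EM[["2-CysPrx"]], total = 0,
                 reduced_fraction = 0)
  )
  reactions <- list(
    exchange_reaction("DTT", "Trx", p$k_dtt_trx, role = "dtt_trx"),
    exchange_reaction("DTT", "FBPase", p$k_dtt_target,
                      role = "dtt_target"),
    exchange_reaction("Trx", "FBPase",
                      p$k_trx_target * trx_mult(p$trx_fbpase_mult,
                                                trx_label),
                      role = "trx_target"),
    exchange_reaction("Trx", "2-CysPrx",
                      p$k_trx_prx * trx_mult(p$trx_prx_mult, trx_label),
                      role = "trx_prx")
  )
  enzymes <- list(
    michaelis_enzyme("FBPase_catalysis", couple = "FBPase",
                     kcat = p$fbpase$kcat, K_m = p$fbpase$K_m,
                     substrate = "FBP", product = "F6P")
  )
  model <- network_model(couples, reactions, enzymes,
                         metabolites = c(FBP = 0, F6P = 0))

  events <- list(protocol_event(-180, "dilute", factor = 2))
  if (prx_ox_conc > 0) {
    events <- c(events, list(
      protocol_event(prx_add_time, "add", species = "2-CysPrx_ox",
                     amount = prx_ox_conc)))
  }
  events <- c(events, list(
    protocol_event(0, "start_recording"),
    protocol_event(180, "add", species = "FBP", amount = 600)))

  assay_config(model, events, readout = "A340_up", readout_species = "F6P",
               epsilon_NADPH = p$epsilon, path_length = p$path_length,
               t_start = -180 - p$preincubation)
}

#' Build the in vitro MDH assay configuration
#'
#' Pre-activation of NADPH-MDH in 500 uM DTT (250 uM final) with 0 or
#' `trx_conc` uM thioredoxin; 1:1 mixing at t = -180 s with the reaction mix
#' supplying 200 uM final NADPH and (optionally) oxidized 2-CysPrx; enzyme
#' start with 2 mM oxaloacetate at t = 0. The A340-down readout follows
#' NADPH consumption. Per the 1:1 mixing arithmetic, final Trx and 2-CysPrx
#' concentrations are half the supplied pre-mix values.
#'
#' @param trx_name Thioredoxin isoform (`"Trx-m1"`, `"CDSP32"`, `"Trx-f1"`,
#'   `"Trx-x"`, `"Trx-m4"` or `"none"`).
#' @param trx_conc Pre-mix Trx concentration, uM (10 uM gives 5 uM final).
#' @param prx_ox_conc Pre-mix oxidized 2-CysPrx, uM (5 uM gives 2.5 uM
#'   final; 0 for the control).
#' @param dtt_preincubation DTT during pre-activation, uM.
#' @param variant 2-CysPrx variant name or [variant_spec()].
#' @param params Overrides for [default_kinetics()] entries.
#' @return An [assay_config()].
#' @export
build_mdh_assay <- function(trx_name = "Trx-m1", trx_conc = 10,
                            prx_ox_conc = 5, dtt_preincubation = 500,
                            variant = "WT", params = NULL) {
  if (!trx_name %in% c(TRX_NAMES, "none")) {
    stop("unknown thioredoxin '", trx_name, "'", call. = FALSE)
  }
  stopifnot(trx_conc >= 0, prx_ox_conc >= 0, dtt_preincubation >= 0)
  if (trx_name == "none") trx_conc <- 0
  p <- merge_params(default_kinetics(), params)
  EM <- default_potentials()
  trx_label <- if (trx_name == "none") "Trx-m1" else trx_name

  couples <- list(
    redox_couple("DTT", EM[["DTT"]], total = dtt_preincubation,
                 reduced_fraction = 1),
    redox_couple("Trx", EM[[trx_label]], total = trx_conc,
                 reduced_fraction = 0),
    redox_couple("MDH", EM[["MDH"]], total = 2 * p$mdh$total,
                 reduced_fraction = 0),
    redox_couple("2-CysPrx", EM[["2-CysPrx"]], total = 0,
                 reduced_fraction = 0)
  )
  reactions <- list(
    exchange_reaction("DTT", "Trx", p$k_dtt_trx, role = "dtt_trx"),
    exchange_reaction("DTT", "MDH", p$k_dtt_target, role = "dtt_target"),
    exchange_reaction("Trx", "MDH",
                      p$k_trx_target * trx_mult(p$trx_mdh_mult, trx_label),
                      role = "trx_target"),
    exchange_reaction("Trx", "2-CysPrx",
                      p$k_trx_prx * trx_mult(p$trx_prx_mult, trx_label),
                      role = "trx_prx")
  )
  enzymes <- list(
    michaelis_enzyme("MDH_catalysis", couple = "MDH", kcat = p$mdh$kcat,
                     K_m = p$mdh$K_m, substrate = "OAA",
                     product = "malate", cofactor = "NADPH",
                     K_m_cofactor = p$mdh$K_m_nadph)
  )
  model <- network_model(couples, reactions, enzymes,
                         metabolites = c(OAA = 0, malate = 0, NADPH = 0))

  events <- list(protocol_event(-180, "dilute", factor = 2),
                 protocol_event(-180, "add", species = "NADPH",
                                amount = 200))
  if (prx_ox_conc > 0) {
    events <- c(events, list(
      protocol_event(-180, "add", species = "2-CysPrx_ox",
                     amount = prx_ox_conc / 2)))
  }
  events <- c(events, list(
    protocol_event(0, "start_recording"),
    protocol_event(0, "add", species = "OAA", amount = 2000)))

  cfg <- assay_config(model, events, readout = "A340_down",
                      readout_species = "NADPH",
                      epsilon_NADPH = p$epsilon,
                      path_length = p$path_length,
                      t_start = -180 - p$preincubation)
  apply_variant(cfg, variant)
}

#' Maximum slope of an assay recording over a measurement window
#'
#' Convenience wrapper: restricts the recorded trace to `[from, to]` and
#' applies [max_slope()]; for a falling A340 the magnitude of the steepest
#' decline is returned.
#'
#' @param result A `simulation_result` from [simulate_protocol()].
#' @param from,to Measurement window, seconds of recording time.
#' @param window OLS window duration, seconds.
#' @return The maximum slope (signal s^-1, positive).
#' @export
assay_slope <- function(result, from, to, window = 30) {
  stopifnot(inherits(result, "simulation_result"))
  tr <- trace_window(result$trace, from, to)
  if (result$config$readout == "A340_down") {
    tr$signal <- -tr$signal
  }
  max_slope(tr, window_length = window)$slope
}

#' Percent inhibition of the simulated FBPase assay by oxidized 2-CysPrx
#'
#' Runs the configured assay and the identical simulation without oxidized
#' 2-CysPrx, extracts the maximum F6P-production slope of each after the
#' substrate start, and reports [percent_inhibition()].
#'
#' @inheritParams build_fbpase_assay
#' @param t_end,window,measure_from,measure_to Recording length, OLS window
#'   and measurement interval (seconds of recording time; the default
#'   interval starts shortly after the FBP addition at t = 180 s).
#' @return List with `percent`, `slope_treated`, `slope_control`.
#' @export
fbpase_inhibition <- function(dtt_preincubation = 1000,
                              trx_name = "Trx-f1", trx_conc = 5,
                              prx_ox_conc = 5, prx_add_time = 0,
                              variant = "WT", params = NULL, t_end = 240,
                              window = 30, measure_from = 185,
                              measure_to = 215) {
  treated <- apply_variant(
    build_fbpase_assay(dtt_preincubation, trx_name, trx_conc, prx_ox_conc,
                       prx_add_time, params = params), variant)
  control <- build_fbpase_assay(dtt_preincubation, trx_name, trx_conc,
                                prx_ox_conc = 0, params = params)
  s_t <- assay_slope(simulate_protocol(treated, t_end = t_end),
                     measure_from, measure_to, window)
  s_c <- assay_slope(simulate_protocol(control, t_end = t_end),
                     measure_from, measure_to, window)
  list(percent = percent_inhibition(s_t, s_c), slope_treated = s_t,
       slope_control = s_c)
}

#' Percent inhibition of the simulated MDH assay by oxidized 2-CysPrx
#'
#' As [fbpase_inhibition()], for the NADPH-consuming MDH assay; slopes are
#' magnitudes of the A340 decline after the OAA start.
#'
#' @inheritParams build_mdh_assay
#' @param t_end,window,measure_from,measure_to Recording length, OLS window
#'   and measurement interval, seconds.
#' @return List with `percent`, `slope_treated`, `slope_control`.
#' @export
mdh_inhibition <- function(trx_name = "Trx-m1", trx_conc = 10,
                           prx_ox_conc = 5, variant = "WT", params = NULL,
                           t_end = 240, window = 10, measure_from = 2,
                           measure_to = 120) {
  treated <- build_mdh_assay(trx_name, trx_conc, prx_ox_conc,
                             variant = variant, params = params)
  control <- build_mdh_assay(trx_name, trx_conc, prx_ox_conc = 0,
                             params = params)
  s_t <- assay_slope(simulate_protocol(treated, t_end = t_end),
                     measure_from, measure_to, window)
  s_c <- assay_slope(simulate_protocol(control, t_end = t_end),
                     measure_from, measure_to, window)
  list(percent = percent_inhibition(s_t, s_c), slope_treated = s_t,
       slope_control = s_c)
}

#' Dose-response of the FBPase assay to oxidized 2-CysPrx
#'
#' For each concentration level, oxidized 2-CysPrx is added at `add_time`
#' (during the established linear phase, i.e. after the FBP start of the
#' base configuration) and the post-addition maximum slope is normalised to
#' the same window of the 2-CysPrx-free control. Level 0 therefore maps to
#' exactly 1.0, and the relative slope decreases strictly with the dose.
#'
#' @param base_config An [assay_config()] from [build_fbpase_assay()] built
#'   *without* oxidized 2-CysPrx (`prx_ox_conc = 0`).
#' @param prx_ox_levels Numeric vector of 2-CysPrx_ox concentrations, uM.
#' @param add_time Addition time, seconds of recording time.
#' @param t_end,window,measure_span Recording length, OLS window and length
#'   of the post-addition measurement interval, seconds.
#' @return A data.frame with columns `prx_ox` and `relative_slope`.
#' @export
dose_response <- function(base_config, prx_ox_levels = c(0, 2.5, 5, 10, 20),
                          add_time = 300, t_end = 600, window = 30,
                          measure_span = 150) {
  stopifnot(inherits(base_config, "assay_config"))
  if (!length(prx_ox_levels)) {
    stop("`prx_ox_levels` must not be empty", call. = FALSE)
  }
  if (any(prx_ox_levels < 0)) {
    stop("`prx_ox_levels` must be non-negative", call. = FALSE)
  }
  run_level <- function(level) {
    cfg <- base_config
    if (level > 0) {
      cfg$events <- c(cfg$events, list(
        protocol_event(add_time, "add", species = "2-CysPrx_ox",
                       amount = level)))
      cfg <- assay_config(cfg$model, cfg$events, readout = cfg$readout,
                          readout_species = cfg$readout_species,
                          epsilon_NADPH = cfg$epsilon_NADPH,
                          path_length = cfg$path_length,
                          t_start = cfg$t_start)
    }
    assay_slope(simulate_protocol(cfg, t_end = t_end),
                from = add_time + 5, to = add_time + 5 + measure_span,
                window = window)
  }
  control <- run_level(0)
  rel <- vapply(prx_ox_levels, function(l) {
    if (l == 0) 1.0 else run_level(l) / control
  }, numeric(1))
  data.frame(prx_ox = prx_ox_levels, relative_slope = rel)
}
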