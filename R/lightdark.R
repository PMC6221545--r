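# Light-to-dark transition model of the in vivo relay: ferredoxin and FTR
# clamped (50% reduced Fd in the light, both fully oxidized after the
# light-phase end), 2-CysPrx clamped at its measured in vivo redox state,
# dynamic thioredoxin and target-enzyme couples.

#' Default in vivo parameter set for the light-dark model
#'
#' Pool sizes (uM): ferredoxin 10, FTR 5, lumped thioredoxin 20, target
#' enzyme 10, 2-CysPrx 100 (its measured stromal abundance). Rate constants
#' (uM^-1 s^-1): Fd->FTR 0.1, FTR->Trx 0.03, Trx->target 1e-3,
#' Trx->2-CysPrx 5e-4, balancing light-phase activation of the target
#' against a dark inactivation that proceeds on the seconds-to-tens-of-
#' seconds scale observed in leaves, several-fold faster with the 2-CysPrx
#' sink than without. Clamps: Fd 50% reduced
#' during the light phase, Fd and FTR fully oxidized from
#' `light_phase_end = 200` s, 2-CysPrx 34% reduced / 66% oxidized
#' throughout.
#'
#' @return Named list; override entries via the `params` argument of
#'   [build_lightdark_config()].
#' @export
default_lightdark_params <- function() {
  list(
    fd_total = 10, ftr_total = 5, trx_total = 20, target_total = 10,
    prx_total = 100,
    k_fd_ftr = 0.1, k_ftr_trx = 0.03, k_trx_target = 1e-3,
    k_trx_prx = 5e-4,
    light_phase_end = 200, fd_reduced_fraction_light = 0.5,
    prx_reduced_fraction = 0.34
  )
}

#' Build a light-dark transition configuration
#'
#' Constructs the in vivo relay Fd -> FTR -> Trx -> target with the
#' 2-CysPrx electron sink. During the light phase ferredoxin is clamped at
#' `fd_reduced_fraction_light`; at `light_phase_end` both Fd and FTR are
#' clamped fully oxidized (electron entry ceases and the relay only drains).
#' The 2-CysPrx couple is clamped at 34% reduced / 66% oxidized throughout
#' (its NTRC/H2O2 turnover is absorbed into the clamp); the `prx_null`
#' genotype carries no 2-CysPrx at all.
#'
#' @param genotype `"WT"` or `"prx_null"`.
#' @param target `"fbpase"`, `"mdh"` or `"prk"` (sets the target couple's
#'   midpoint potential; see [default_potentials()]).
#' @param params Overrides for [default_lightdark_params()] entries.
#' @return An [assay_config()] with a `fraction` readout of the target
#'   couple.
#' @export
build_lightdark_config <- function(genotype = c("WT", "prx_null"),
                                   target = c("fbpase", "mdh", "prk"),
                                   params = NULL) {
  genotype <- match.arg(genotype)
  target <- match.arg(target)
  p <- merge_params(default_lightdark_params(), params)
  EM <- default_potentials()
  target_EM <- switch(target, fbpase = EM[["FBPase"]], mdh = EM[["MDH"]],
                      prk = EM[["PRK"]])
  prx_total <- if (genotype == "prx_null") 0 else p$prx_total

  couples <- list(
    redox_couple("Fd", EM[["Fd"]], total = p$fd_total,
                 reduced_fraction = p$fd_reduced_fraction_light,
                 clamped = TRUE),
    redox_couple("FTR", EM[["FTR"]], total = p$ftr_total,
                 reduced_fraction = 0),
    redox_couple("Trx", EM[["Trx-f1"]], total = p$trx_total,
                 reduced_fraction = 0),
    redox_couple("target", target_EM, total = p$target_total,
                 reduced_fraction = 0),
    redox_couple("2-CysPrx", EM[["2-CysPrx"]], total = prx_total,
                 reduced_fraction = p$prx_reduced_fraction, clamped = TRUE)
  )
  reactions <- list(
    exchange_reaction("Fd", "FTR", p$k_fd_ftr, role = "fd_ftr"),
    exchange_reaction("FTR", "Trx", p$k_ftr_trx, role = "ftr_trx"),
    exchange_reaction("Trx", "target", p$k_trx_target,
                      role = "trx_target"),
    exchange_reaction("Trx", "2-CysPrx", p$k_trx_prx, role = "trx_prx")
  )
  model <- network_model(couples, reactions)
  events <- list(
    protocol_event(p$light_phase_end, "clamp_set", couple = "Fd",
                   reduced_fraction = 0),
    protocol_event(p$light_phase_end, "clamp_set", couple = "FTR",
                   reduced_fraction = 0)
  )
  cfg <- assay_config(model, events, readout = "fraction",
                      readout_species = "target", t_start = 0)
  cfg$light_phase_end <- p$light_phase_end
  cfg$genotype <- genotype
  cfg$target <- target
  cfg
}

#' Simulate a light-to-dark transition
#'
#' Runs the relay from fully oxidized Trx/FTR/target pools: the target's
#' reduced fraction rises toward its light steady state before the
#' light-phase end and declines after it (faster in WT than in the
#' 2-CysPrx-free genotype, whose only electron drain is the oxidized
#' Fd/FTR chain).
#'
#' @param config From [build_lightdark_config()].
#' @param t_end Simulation end, seconds; must exceed the light-phase end.
#' @param dt_out Output sampling interval, seconds.
#' @return A `simulation_result`; `$trace` is the target reduced fraction,
#'   `$states` the full trajectory of all couples.
#' @export
lightdark_simulate <- function(config, t_end = 800, dt_out = 0.5) {
  stopifnot(inherits(config, "assay_config"))
  if (is.null(config$light_phase_end)) {
    stop("config was not built by build_lightdark_config()", call. = FALSE)
  }
  if (t_end <= config$light_phase_end) {
    stop("t_end must exceed the light phase end (",
         config$light_phase_end, " s)", call. = FALSE)
  }
  simulate_protocol(config, t_end = t_end, dt_out = dt_out)
}

#' Half-time of the post-darkening decline of a trace
#'
#' Returns the time after `t_dark` at which the signal has fallen halfway
#' from its value at darkening to its dark asymptote (the final sample),
#' with linear interpolation between samples. For an exponential decline
#' with rate `k` this is `ln 2 / k`.
#'
#' @param trace A [redox_trace()] covering `t_dark` onward.
#' @param t_dark Moment of darkening, seconds.
#' @return Half-time in seconds (> 0).
#' @export
oxidation_halftime <- function(trace, t_dark) {
  stopifnot(inherits(trace, "redox_trace"))
  if (t_dark < min(trace$time) || t_dark >= max(trace$time)) {
    stop("trace does not cover t_dark = ", t_dark, " s onward",
         call. = FALSE)
  }
  keep <- trace$time >= t_dark
  t <- trace$time[keep]; y <- trace$signal[keep]
  v0 <- stats::approx(trace$time, trace$signal, xout = t_dark)$y
  vinf <- y[length(y)]
  span <- v0 - vinf
  if (span <= 1e-9 * max(abs(v0), 1e-12)) {
    stop("trace does not decline after t_dark: half-time undefined",
         call. = FALSE)
  }
  target <- v0 - span / 2
  below <- which(y <= target)
  if (!length(below)) {
    stop("trace never reaches the half-amplitude level", call. = FALSE)
  }
  i <- below[1L]
  if (i == 1L) return(t[1L] - t_dark)
  # linear interpolation within the bracketing interval
  t_cross <- t[i - 1L] + (target - y[i - 1L]) * (t[i] - t[i - 1L]) /
    (y[i] - y[i - 1L])
  t_cross - t_dark
}
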