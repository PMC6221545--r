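# Shipped default parameterisation. Midpoint potentials are literature
# values for the spinach/sorghum/Arabidopsis proteins; rate constants are
# the package's calibration layer: the thermodynamic skeleton is fixed by
# the potentials, the kinetics were chosen once so the standard in vitro
# FBPase assay (500 uM final DTT, 5 uM Trx-f1, 5 uM oxidized 2-CysPrx)
# yields ~75% inhibition and the 200 uM DTT variant ~76%, then frozen.

#' Default midpoint redox potentials (volts)
#'
#' Two-electron dithiol/disulfide midpoint potentials at pH 7-8 used by the
#' protocol builders: 2-CysPrx -315 mV, FBPase and NADPH-MDH -330 mV, PRK
#' and Trx-f1 -290 mV, m-type Trxs (and, lacking published values, Trx-x and
#' CDSP32) -300 mV, PrxIIE -288 mV, DTT -330 mV, ferredoxin -420 mV,
#' FTR -320 mV. All individually overridable through the builders' `params`
#' argument.
#'
#' @return Named numeric vector, volts.
#' @export
default_potentials <- function() {
  c("DTT" = -0.330, "Trx-f1" = -0.290, "Trx-m1" = -0.300,
    "Trx-m4" = -0.300, "Trx-x" = -0.300, "CDSP32" = -0.300,
    "FBPase" = -0.330, "MDH" = -0.330, "PRK" = -0.290,
    "2-CysPrx" = -0.315, "PrxIIE" = -0.288, "Fd" = -0.420, "FTR" = -0.320)
}

#' Default kinetic parameter set for the in vitro assay models
#'
#' The free calibration layer of the in vitro assay simulations (the
#' equilibrium constants are not free; see [nernst_keq()]). Components:
#'
#' * `k_dtt_trx`, `k_dtt_target` (uM^-1 s^-1): slow chemical reduction of
#'   thioredoxins and of target-enzyme regulatory disulfides by DTT. Chosen
#'   so that 900 s of pre-activation in 1 mM DTT nearly fully activates the
#'   target while reduced Trx still adds a little activity, and so that DTT
#'   re-reduction during the recording window is slow.
#' * `k_trx_target`, `k_trx_prx` (uM^-1 s^-1): fast protein-protein
#'   thiol-disulfide exchange between Trx and target, and between Trx and
#'   2-CysPrx.
#' * `trx_fbpase_mult`, `trx_mdh_mult`, `trx_prx_mult`: per-isoform rate
#'   multipliers encoding Trx specificity (ordinal calibration only:
#'   chosen to reproduce the observed inhibition ordering
#'   Trx-m1 > CDSP32 > Trx-f1 > Trx-x > Trx-m4 for MDH, and the Trx-f1
#'   preference of FBPase).
#' * `fbpase`, `mdh`: enzyme pools and catalytic constants. kcat defaults to
#'   2 s^-1 so that the 600 uM FBP / 200 uM NADPH pools support a
#'   multi-minute linear phase as in the recordings; percent-inhibition
#'   readouts are ratios and insensitive to this scale.
#' * `preincubation` (s), `epsilon` (mM^-1 cm^-1 at 340 nm for NADPH),
#'   `path_length` (cm).
#'
#' @return Named list of defaults; override any element via the `params`
#'   argument of [build_fbpase_assay()] / [build_mdh_assay()].
#' @export
default_kinetics <- function() {
  list(
    k_dtt_trx = 5e-7,
    k_dtt_target = 1.2e-6,
    k_trx_target = 1e-3,
    k_trx_prx = 0.2,
    trx_fbpase_mult = c("Trx-f1" = 1, "Trx-m1" = 0.1, "CDSP32" = 0.1,
                        "Trx-x" = 0.05, "Trx-m4" = 0.02),
    trx_mdh_mult = c("Trx-m1" = 10, "CDSP32" = 1.2, "Trx-f1" = 0.3,
                     "Trx-x" = 0.1, "Trx-m4" = 0.03),
    trx_prx_mult = c("Trx-f1" = 1, "Trx-m1" = 1, "CDSP32" = 1,
                     "Trx-x" = 1, "Trx-m4" = 1),
    fbpase = list(total = 2, kcat = 2, K_m = 100),
    mdh = list(total = 2, kcat = 2, K_m = 50, K_m_nadph = 20),
    preincubation = 7200,
    epsilon = 6.22,
    path_length = 1
  )
}

merge_params <- function(defaults, params) {
  if (is.null(params)) return(defaults)
  stopifnot(is.list(params))
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(defaults, params)
}
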