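# redoxrelay

Kinetic modelling of thiol–disulfide redox regulation in the chloroplast:
how the oxidized 2-cysteine peroxiredoxin (2-CysPrx) acts as a
*thioredoxin oxidase*, draining electrons from reductively activated
target enzymes (FBPase, NADPH-MDH, PRK) back through the thioredoxin
pool, and thereby switches light-activated metabolism off again after
darkening.

The package is aimed at plant redox biologists and modellers who want to

* simulate the coupled spectrophotometric **in vitro assays** (DTT
  pre-activation, 1:1 dilution, timed additions of oxidized 2-CysPrx,
  substrate start, A340 readout) and their dose–response, thioredoxin
  specificity and site-directed-variant behaviour;
* simulate the **light-to-dark transition** of the stromal relay
  Fd → FTR → Trx → target with clamped redox pools; and
* run the accompanying **trace-analysis pipeline** (maximum-slope
  activities, percent inhibition, exponential half-life fits, residual
  activities, activation ratios) on measured or synthetic traces.

## The model in one paragraph

Every redox-active species is a two-electron dithiol/disulfide *couple*
with midpoint potential `E'M`, pool size (µM) and reduced fraction.
Thiol–disulfide exchange `D_red + A_ox <-> D_ox + A_red` is mass action
with only the forward constant free: the equilibrium constant is forced by
the Nernst relation, `K_eq = exp(nF(E'M_A − E'M_D)/RT)` with `n = 2`, so
detailed balance holds by construction and no rate choice can violate
thermodynamics. Default potentials are the published values (2-CysPrx
−315 mV, FBPase/MDH −330 mV, PRK and Trx-f1 −290 mV, Trx-m −300 mV).
Catalysis by the reduced enzyme is Michaelis–Menten; clamped couples are
chemostats (used for the in vivo 2-CysPrx redox state, 66 % oxidized /
34 % reduced, and for the Fd/FTR light switch). Integration uses a stiff
solver (`deSolve::lsoda`) restarted at every protocol event.

## Worked example

```r
library(redoxrelay)

# Thermodynamics: oxidized 2-CysPrx can drain FBPase through Trx-f1
nernst_keq(-0.330, -0.290)   # FBPase -> Trx-f1
#> [1] 22.50870
1 / nernst_keq(-0.290, -0.315)  # Trx-f1_red + 2-CysPrx_ox, oxidase direction
#> [1] 7.001951

# Standard in vitro FBPase assay: 1 mM DTT pre-activation (500 uM final),
# 5 uM Trx-f1, 5 uM oxidized 2-CysPrx added at recording start
r <- fbpase_inhibition(dtt_preincubation = 1000, trx_name = "Trx-f1",
                       trx_conc = 5, prx_ox_conc = 5)
r$percent
#> [1] 75.20308

# Dose-response of the ongoing assay to oxidized 2-CysPrx
base <- build_fbpase_assay(1000, "Trx-f1", 5, prx_ox_conc = 0)
dose_response(base, c(0, 2.5, 5, 10, 20))
#>   prx_ox relative_slope
#> 1    0.0     1.00000000
#> 2    2.5     0.39466618
#> 3    5.0     0.22990006
#> 4   10.0     0.13434961
#> 5   20.0     0.07944409

# Synthetic ferredoxin reoxidation decay, fitted half-life
fit <- fit_exponential_decay(gen_fd_decay("WT"))
round(1000 * fit$t50)   # ms
#> [1] 416
```

The inhibition numbers are percent of the control's maximum A340 slope
lost after adding oxidized 2-CysPrx: 75.2 % under the standard condition
(printed experimental outcome: 75 %), and the relative slopes fall
strictly with the 2-CysPrx dose, as in the recorded traces. The 416 ms
half-life is the wild-type ferredoxin reoxidation time after darkening;
the 2-CysPrx-null genotype default gives 120 ms (3.5× faster — the
in vivo signature of the missing electron sink).

A light–dark run:

```r
wt <- lightdark_simulate(build_lightdark_config("WT", "mdh"))
ko <- lightdark_simulate(build_lightdark_config("prx_null", "mdh"))
c(WT = oxidation_halftime(wt$trace, t_dark = 200),
  prx_null = oxidation_halftime(ko$trace, t_dark = 200))  # seconds
#>       WT prx_null
#> 11.33597 25.65292
```

Models can also be defined in YAML (`load_model_config()`, units µM /
volts / seconds; equilibrium constants are always derived, never
user-set) and exported to SBML Level 3 (`export_sbml()`). A thin
command-line wrapper with subcommands `simulate-assay`,
`simulate-lightdark`, `dose-response`, `analyze-trace` and `generate`
ships in `inst/cli/redoxrelay.R`; every run writes a JSON manifest next
to its output.

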