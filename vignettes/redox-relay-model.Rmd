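---
title: "Modelling thiol-disulfide redox regulation in the chloroplast"
author: "redoxrelay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling thiol-disulfide redox regulation in the chloroplast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxrelay)
```

## The model

Chloroplast carbon metabolism is switched on by light through thiol
reduction: photoreduced ferredoxin (Fd) feeds electrons through the
ferredoxin-thioredoxin reductase (FTR) into thioredoxins (Trx), which
reduce regulatory disulfides of target enzymes such as the
fructose-1,6-bisphosphatase (FBPase), the NADPH-dependent malate
dehydrogenase (MDH) and the phosphoribulokinase (PRK). Switching the
enzymes *off* again requires an electron sink. The abundant 2-cysteine
peroxiredoxin (2-CysPrx), present in its oxidized (disulfide) form at tens
of micromolar in the stroma, can act as that sink — a "thioredoxin
oxidase" — draining electrons from reduced targets back through the Trx
pool.

`redoxrelay` implements this relay as a mass-action network of
dithiol/disulfide *couples*. Each couple $i$ carries a midpoint potential
$E'_{M,i}$, a total pool $c_i$ (µM) and a reduced fraction. A reversible
exchange between donor $D$ and acceptor $A$,

$$D_{red} + A_{ox} \rightleftharpoons D_{ox} + A_{red},$$

proceeds with rate
$v = k_f [D_{red}][A_{ox}] - k_r [D_{ox}][A_{red}]$. Only $k_f$ is a free
parameter: the equilibrium constant is forced by the Nernst relation,

$$K_{eq} = \exp\!\left(\frac{n F (E'_{M,A} - E'_{M,D})}{R T}\right),
\qquad k_r = k_f / K_{eq},$$

with $n = 2$, $T = 298.15$ K. This construction makes detailed balance
around any reaction cycle automatic (the product of $K_{eq}$ around a
cycle is exactly 1), so no choice of rate constants can smuggle in a
thermodynamically impossible steady flux. Catalysis by a reduced target is
Michaelis–Menten, $v = k_{cat}[E_{red}]\,S/(K_m + S)$, with 1:1
substrate-to-product stoichiometry (and, for MDH, 1:1 consumption of the
NADPH cofactor through a second saturable factor).

The default midpoint potentials are the published values for the proteins
involved: 2-CysPrx −315 mV, FBPase and NADPH-MDH −330 mV, PRK and Trx-f1
−290 mV, m-type thioredoxins −300 mV, PrxIIE −288 mV. DTT (−330 mV at
pH 7), Fd (−420 mV) and FTR (−320 mV) complete the set; all are
individually overridable. Where a value is not published (Trx-x, CDSP32)
the m-type value is used.

A *clamped* couple is a chemostat: it exerts mass action at a fixed
reduced fraction. This is how the in vivo 2-CysPrx pool is treated (its
NTRC reduction and H$_2$O$_2$ oxidation are absorbed into the clamp) and
how the light switch is imposed on Fd and FTR.

## What is thermodynamically forced, and what is calibrated

A useful way to read the model: the *potentials* decide where any fast
subsystem can go; the *rate constants* decide how fast, and which
equilibria are actually reached within an experiment. Two consequences
shape everything below.

First, because $K_{eq}(\mathrm{Trx}_{f1} \to \mathrm{FBPase}) \approx
0.044$, the productive direction of that exchange — oxidized Trx draining
a reduced target — runs with $k_f/K_{eq} \approx 22.5\,k_f$. Target
oxidation is intrinsically fast once Trx is oxidized; target *reduction*
requires an almost fully reduced Trx pool.

Second, with a finite pool of oxidized 2-CysPrx the relay can only move
electrons until the mass-action quotients reach their Nernst values. For
the standard FBPase assay (5 µM Trx-f1, 2 µM FBPase, 5 µM 2-CysPrx$_{ox}$,
all final) that quasi-equilibrium leaves ≈ 0.4 µM of 2 µM FBPase reduced —
a ceiling of roughly 78–80 % inhibition. The measured ≈ 75 % sits just
below this ceiling, which is why the assay can be reproduced
quantitatively with *any* sufficiently fast exchange kinetics. For the MDH
assay the same arithmetic (5 µM Trx final, only 2.5 µM Prx$_{ox}$ final,
Trx-m at −300 mV holding most of the electrons) caps simulated inhibition
near 56 %. The experimentally observed *complete* MDH inhibition through
Trx-m1 therefore cannot be reached by a closed Nernst-consistent system of
these pools; it would require a flux that keeps re-oxidizing 2-CysPrx
(residual peroxide), which this package deliberately does not model. The
test suite states this expectation honestly and the corresponding check
fails by design; the isoform *ordering*, which is kinetic, is reproduced.

## The in vitro assay protocols

`build_fbpase_assay()` encodes the coupled spectrophotometric protocol:
pre-activation of the enzyme in DTT (± Trx) at pre-dilution
concentrations, 1:1 dilution into the reaction mix at $t = -180$ s, test
compounds (oxidized 2-CysPrx) at $t = 0$, substrate start with 600 µM FBP
at $t = 180$ s. The A340 readout converts product to absorbance with
$\varepsilon_{340} = 6.22$ mM$^{-1}$cm$^{-1}$ (1 µM NADPH ↔ 0.00622 AU at
1 cm). `build_mdh_assay()` mirrors the MDH protocol (250 µM final DTT,
Trx and Prx$_{ox}$ halved by 1:1 mixing, 2 mM OAA start, falling A340).
Events are instantaneous and volume-free except the explicit dilution,
matching the protocols' final-concentration bookkeeping. Integration is
piecewise `deSolve::lsoda` (rtol $10^{-8}$, atol $10^{-10}$ µM),
restarted at every event.

Activity is quantified as the assays themselves are quantified: the
maximum ordinary-least-squares slope over a sliding window.
The default measurement takes the first 30-s window starting 5 s
after the substrate addition, i.e. the initial turnover rate once the
linear phase is established; percent inhibition compares this slope with
the matching 2-CysPrx-free control.

### The calibration layer

The published outcomes fix the thermodynamic skeleton but not the rate
constants, which were calibrated **once** and frozen in
`default_kinetics()`:

* `k_dtt_trx` $= 5\times10^{-7}$, `k_dtt_target` $= 1.2\times10^{-6}$
  µM$^{-1}$s$^{-1}$ — DTT is a slow chemical reductant; these values let a
  long pre-activation fully activate the controls at both 1 mM and 400 µM
  DTT while keeping re-reduction during the recording window minor.
* `k_trx_target` $= 10^{-3}$, `k_trx_prx` $= 0.2$ µM$^{-1}$s$^{-1}$ —
  protein–protein exchange. `k_trx_target` is deliberately small because
  its effective oxidation constant is $22.5\times$ larger (see above);
  at this value the relay is kinetically limiting at sub-micromolar Trx,
  reproducing the observed saturable Trx-f1 dose dependence
  (inhibition rising 57 → 75 % over 0.625–5 µM Trx-f1).
* Pre-incubation defaults to 7200 s. The protocols do not state the
  pre-activation time; the model uses a duration long enough that both
  DTT regimes reach essentially complete activation, which the
  percent-inhibition pair requires (an under-activated control deflates
  the apparent inhibition of its treated counterpart).
* Enzyme kinetics: $k_{cat} = 2$ s$^{-1}$, $K_m = 100$ µM (FBP) / 50 µM
  (OAA), 2 µM enzyme. At markedly higher $k_{cat}$ the 600 µM FBP or
  200 µM NADPH pools deplete within a minute and the multi-minute linear
  phase that max-slope quantification assumes disappears; inhibition
  ratios themselves are insensitive to the scale.
* Trx isoform specificity is ordinal: per-(isoform, target) multipliers
  on the Trx↔target exchange (for MDH: m1 10, CDSP32 1.2, f1 0.3, x 0.1,
  m4 0.03) chosen to reproduce the observed inhibition ordering
  m1 > CDSP32 > f1 > x > m4, nothing more.

With these defaults the standard assay yields 75.2 % inhibition and the
400 µM-DTT variant 76.0 % (printed outcomes: 75 % and 76 %); both numbers
are recomputed from scratch by `scripts/acceptance.R` and the test suite.

Site-directed 2-CysPrx variants act through `apply_variant()`: C54S, C54D
(no peroxidatic cysteine) and C176S (no resolving cysteine) disable the
Trx↔Prx exchange entirely; F84R (oligomerization-deficient but
catalytically competent) behaves as wild type.

## The light–dark transition

`build_lightdark_config()` assembles the in vivo relay Fd → FTR → Trx →
target with 2-CysPrx as clamped sink. In the light phase Fd is clamped 50 %
reduced; at 200 s Fd and FTR are clamped fully oxidized (electron entry
ceases). 2-CysPrx is clamped at 34 % reduced / 66 % oxidized throughout;
the `prx_null` genotype simply lacks the pool. Default pools: Fd 10, FTR
5, Trx 20, target 10, 2-CysPrx 100 µM.

The 66 %-oxidized Prx clamp corresponds to an ambient potential of
−306.5 mV. A −330 mV target equilibrated against it stays partially
reduced — the model's own explanation for why simulated darkness never
fully inhibits the FBPase-like target (the dark asymptote is ≈ 0.10 with
defaults, pulled slightly below the clamp value by the oxidized FTR pool).
A −290 mV target (PRK-like) barely responds to the Prx sink at all, which
is exactly the muted PRK behaviour seen in leaves.

One structural limitation is worth stating: the FTR↔Trx rate constant
sets *both* the light-phase electron input and the only dark-phase drain
of the 2-CysPrx-free genotype. Strong light activation therefore trades
against a large WT/null contrast; the defaults (`k_ftr_trx = 0.03`,
`k_trx_prx` $= 5\times10^{-4}$ µM$^{-1}$s$^{-1}$) land at a light steady
state of ≈ 0.24–0.36 reduced with post-darkening half-times of ≈ 11 s (WT)
versus ≈ 26 s (null) for an MDH-like target — the right ordering and
magnitude range, a more compressed ratio than the in vivo ferredoxin
kinetics suggest. `oxidation_halftime()` summarises any declining trace as
the time to fall halfway from its value at darkening to its dark
asymptote (equal to $\ln 2 / k$ for an exponential decline).

```{r lightdark, eval = FALSE}
wt <- lightdark_simulate(build_lightdark_config("WT", "mdh"))
ko <- lightdark_simulate(build_lightdark_config("prx_null", "mdh"))
c(WT = oxidation_halftime(wt$trace, 200),
  null = oxidation_halftime(ko$trace, 200))
```

## Trace analysis

* `max_slope()` — maximum windowed OLS slope; earliest window wins ties.
  Default window 30 s at 1 Hz sampling (no window is stated in the
  protocols; 30 points give a stable slope at the noise levels modelled).
* `percent_inhibition()` — $100(1 - s_{treated}/s_{control})$, clipped to
  $[0, 100]$ with a warning.
* `fit_exponential_decay()` — $c_0 + A e^{-k(t-t_0)}$ by least squares.
  The rate is initialised on a coarse logarithmic grid over
  $[10^{-3}, 10^3]$ s$^{-1}$ with offset/amplitude profiled out linearly
  (this avoids the local minima that plague free three-parameter starts),
  refined by 1-D minimisation and polished with Levenberg–Marquardt
  (`minpack.lm`). Noise-free input is recovered to $10^{-6}$ relative;
  constant or rising traces raise a fit-failure error. Half-amplitude
  crossing would be a cheaper alternative summary; the package fits the
  full exponential because it also yields amplitude, offset and $r^2$.
* `residual_activity()` — percent of the $t=0$ activity with linear
  interpolation; `activation_ratio()` — initial over fully-(DTT-)activated
  activity.

## Synthetic data

The generators produce every input the pipeline consumes, at the study's
own conditions:

* `gen_fd_decay()` — ferredoxin reoxidation after a light pulse as a
  single exponential (amplitude 1, offset 0; NIR signals are relative)
  sampled at 1 kHz for 4.5 s, with genotype half-lives of 416 ms (WT),
  120 ms (2-CysPrx null), 408/386 ms (complemented lines C1/C2).
* `gen_inactivation_course()` — enzyme activity (% of $t=0$) at the
  darkening protocol's sampling times 0/10/30/60/300 s, following
  $A_{end} + (100 - A_{end})e^{-t/\tau}$. Only the 10-s residuals are
  measured quantities (55.8 % WT, 90.9 % null, 61.0 % C1, 73.2 % C2); the
  plateaus $A_{end}$ (30 % for WT-like lines, 60 % for the null) are
  package choices and each $\tau$ is then solved so the course passes
  through the measured residual ($\tau = 10.02$ s WT, 38.73 s null). The
  WT PRK course declines gently ($A_{end} = 60$ %, $\tau = 120$ s — no
  numbers are published, only the shape); the null PRK course is flat.
* `gen_assay_trace()` — a simulated assay trace plus iid Gaussian noise
  and optional linear baseline drift, bit-identical under a fixed seed.

What passing the synthetic-recovery tests does and does not show: it
validates that the analysis operations invert the generating model
exactly and stably under noise, i.e. the pipeline's correctness. It does
not validate the generating model against real instruments — real NIR
decays are not perfectly single-exponential, real assay noise is not iid,
and replicate scatter in leaf extracts is larger than any default here.

## Numerical choices and degenerate inputs

Stiff-capable integration (`lsoda`) with rtol $10^{-8}$/atol $10^{-10}$
µM throughout (pools span three orders of magnitude); transient negative
concentrations are clipped to zero inside the right-hand side only.
`equilibrate()` integrates over doubling horizons until the right-hand
side vanishes and is verified in the tests against independent 1-D root
finding on the shared ambient potential. Empty pools report their
configured fraction; constant traces are rejected by the decay fitter and
by `oxidation_halftime()`; slope windows must span at least three
sampling intervals; dilution factors must exceed 1; equilibrium constants
can never be user-supplied, in config files or otherwise.

Problem sizes used by the shipped tests and the acceptance script: assay
simulations of ~7.6k output points (2-h pre-incubation at 1 s sampling
plus the recording), 4 501-point decay traces, 5-point inactivation
courses, and up to 200 seeded replicates for noise-robustness checks.
These sizes keep the full suite in the low minutes on one CPU while
leaving every estimator comfortably inside its asymptotic regime.

## Known limitations

* No hyperoxidation/sulfiredoxin chemistry, no decamer/dimer dynamics, no
  H$_2$O$_2$ turnover: the in vitro oxidant is a finite pool, the in vivo
  one a clamp. This is exactly why complete MDH inhibition is out of the
  model's reach (above).
* DTT is modelled as a single two-electron couple.
* The lumped in vivo Trx pool uses the Trx-f1 potential; isoform-resolved
  in vivo modelling would need per-isoform pools and FTR efficiencies.
* Stromal pH, Mg²⁺, Ca²⁺ and metabolite effects on thiol-switch
  sensitivity are not modelled; they are the natural suspects wherever
  the in vivo contrast is larger than this relay alone can produce.
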