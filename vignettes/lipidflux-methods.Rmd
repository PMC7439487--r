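---
title: "Methods: a kinetic model of balanced membrane synthesis in E. coli"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a kinetic model of balanced membrane synthesis in E. coli}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Growing bacteria must make membrane exactly as fast as they make everything
else. In *Escherichia coli* the building blocks of both membranes — fatty
acyl chains for phospholipid (PL) and the C14:0-OH precursor of
lipopolysaccharide (LPS) — are carried on acyl carrier protein (ACP), a
small, conserved pool shuttling between the fatty-acid synthesis cycle, the
LPS initiation step (LpxA/LpxC) and the first committed PL enzyme, the
glycerol-3-phosphate acyltransferase PlsB. Many regulatory mechanisms have
been proposed in this pathway; the question this package is built around is
which of them *suffices* to couple membrane synthesis to growth rate. The
model's answer: posttranslational control of PlsB activity alone, combined
with feedback inhibition of acetyl-CoA carboxylase (ACC) by long-chain
acyl-ACP, reproduces the steady-state behaviour of the whole pathway —
enzyme concentrations need not change.

`lipidflux` implements two connected layers:

1. a kinetic ODE model of the late saturated fatty-acid, PL and LPS
   pathways (steady states, Vmax scans, metabolic control analysis,
   perturbation time courses), and
2. the steady-state statistical analysis used on LC/MS condition tables:
   an operational PL flux (total PE signal × growth rate µ), normalization
   conventions, and Pearson correlations of analyte abundance with flux —
   plus a synthetic-data generator that lets the whole statistical pipeline
   be tested against planted truth.

## The model

Ten dynamic species (µM): six ACP forms — holo-ACP, malonyl-ACP,
C14:0-OH-ACP, C14:0-ACP, C16:0-ACP, C18:0-ACP — whose sum is conserved, and
four PL intermediates — LPA, PA, CDP-DAG, PS. Twelve irreversible reactions,
each a one- or two-substrate Michaelis–Menten rate law:

* `ACC` (lumped with FabD): acetyl-CoA + holo-ACP → malonyl-ACP,
  competitively inhibited by C16:0-ACP and C18:0-ACP at the acetyl-CoA site
  (the model's only regulatory interactions);
* `ELONG_C14OH` (early cycles, lumped): malonyl-ACP → C14:0-OH-ACP;
* `FABZ` (FabZ/FabI lumped): C14:0-OH-ACP → C14:0-ACP;
* `LPXC` (LpxA/LpxC lumped): C14:0-OH-ACP → LPS sink, releasing holo-ACP;
  its rate **is** the model's LPS flux;
* `ELONG_C16`, `ELONG_C18`: condensation of C14:0-/C16:0-ACP with
  malonyl-ACP, releasing holo-ACP;
* `PLSB_C16`, `PLSB_C18`: acyl-ACP + G3P → LPA + holo-ACP; these share one
  Vmax scale, so "scanning PlsB" scales both; they carry the optional
  noncompetitive ppGpp factor `1/(1 + ppGpp/Ki)`;
* `PLSC` → `CDSA` → `PSSA` → `PSD`: LPA → PA → CDP-DAG → PS → PE sink;
  the `PSD` rate **is** the model's PE (PL) flux.

Boundary species held fixed: acetyl-CoA (500 µM), G3P (1000 µM, saturating
— PlsB is observed to be G3P-saturated *in vivo*), C16:1-ACP (1 µM, the
PlsC acyl donor, experimentally invariant) and ppGpp (0 µM at steady state).
Every reaction is ACP-neutral by construction — `LPXC` and the PlsB steps
release holo-ACP as they export carbon — so the six-species ACP total is a
conserved moiety, which the constructor asserts and the tests track along
every trajectory (relative drift ≤ 1e-6; in practice ~1e-15).

Two modelling choices were genuinely open and are worth stating. C18:0-ACP
needs a sink; it is consumed by `PLSB_C18`, otherwise it would accumulate
without bound. And "competitively inhibited" is realized in the standard
form — inhibitors scale the apparent Km of the *first* substrate site.
Whether ppGpp inhibits PlsB directly or through an intermediary cannot be
settled by this kind of model; the simulator's direct inhibition factor is
a modeling device, taken in multiples of its Ki so that no conversion from
cellular ppGpp units needs to be invented.

## Parameters and calibration

The default parameter set is *anchored*: `baseline_state()` (holo-ACP 20,
malonyl-ACP 5, C14:0-OH-ACP 1, C14:0-ACP 1, C16:0-ACP 2, C18:0-ACP 1, LPA
0.5, PA 1, CDP-DAG 0.5, PS 0.5 µM; ACP total 30 µM) is an exact steady
state carrying a PE flux of 10 µM/min and an LPS flux of 3 µM/min. Given
the anchor, each Km is fixed by choosing that reaction's substrate
saturation at baseline — so every Km is automatically of the order of its
substrate's concentration — and each Vmax follows as flux/saturation.
Intermediate (elongation, branch and downstream PL) enzymes are kept at low
saturation (0.15–0.2) so they have catalytic headroom: an enzyme near
saturation at baseline could not passively carry a doubled flux, and would
acquire spurious flux control.

Two knobs remain free and set how steady-state flux control is shared
between supply and demand:

* `th_plsb = 0.13` — PlsB's acyl-ACP saturation at baseline (demand
  elasticity: how much PlsB output responds to its substrates);
* `L = 5` — the total competitive-inhibition load on ACC, `Σ I/Ki` over
  C16:0- and C18:0-ACP, split evenly (supply elasticity: how strongly
  long-chain accumulation throttles initiation).

They are calibrated (`inst/scripts/calibrate.R` reproduces the grid) so
that a 4-fold increase of either the PlsB or the ACC Vmax raises
steady-state PE flux by close to 2-fold — the pathway's headline
supply/demand symmetry — giving 1.87 (PlsB) and 1.83 (ACC) with the
shipped values. The anchor itself was revised once during calibration: with
holo-ACP dominating the pool too strongly, its simulated decline across the
flux range was only a few percent, much flatter than the clearly visible
experimental decline of holo-ACP with PL flux; the shipped anchor gives
holo-ACP a log2 slope of about −0.23 against PE flux, commensurate with
observation, which also makes its trend recoverable under realistic
measurement noise.

Because all rate laws are homogeneous of degree one in Vmax, the flux
control coefficients `d ln J / d ln Vmax` over the twelve reactions must
sum to exactly 1 for each output flux (the summation theorem); the
implementation recovers this to ~1e-6, a strong end-to-end check on solver
and differencing accuracy. The control structure that emerges is the
point of the model: ACC and PlsB share essentially all PE-flux control;
FabZ and LpxC exert strong, nearly equal-and-opposite control over LPS flux
(they set the branch split at C14:0-OH-ACP) while leaving PE flux almost
untouched; and the four downstream PL enzymes have *identically* zero flux
control, because an irreversible chain passes whatever flux arrives and
only its intermediate concentrations adjust. The shared Km of the two
C14:0-OH-ACP consumers makes the branch split concentration-independent, so
PE and LPS fluxes move exactly in parallel under PlsB or ACC variation —
the model's expression of "PL flux drags LPS flux along".

## Numerical choices

* **Steady states** are found by integrating the mass balances
  (`deSolve::lsoda`, rtol 1e-10/atol 1e-12) over log-spaced horizons up to
  `t_max = 1e6` min, then Newton-refining the endpoint (`pracma::fsolve`)
  on the conservation-reduced system: holo-ACP is eliminated via the ACP
  total of the starting state, making the root problem square; iteration is
  in log-concentration space, which keeps iterates positive. Convergence is
  declared at residual `max |dx/dt| ≤ 1e-9` µM/min; failure returns an
  unconverged result, not an error. The two pure routes
  (`method = "integrate"`, `method = "refine"`) are kept as independently
  runnable oracles and are required by the tests to agree to relative 1e-6
  on the default and twenty randomly perturbed parameter sets.
* **Scans** warm-start each solve from the neighbouring factor's solution,
  for speed and branch continuity.
* **Control coefficients** use centred finite differences with a 1%
  symmetric perturbation in log space — adequate at these problem sizes and
  much simpler than analytic Jacobians.
* **Perturbation time courses** integrate piecewise between events with
  exact restarts at each boundary-input step; depletion times interpolate
  linearly between grid points, with a default threshold of 0.5 of the
  pre-event baseline.
* **Normalization** centres log2 values on the geometric mean of the
  included conditions (equivalently: log2 values are mean-centred), so a
  centred series always averages to exactly zero and centring commutes with
  condition exclusions. Pearson r is computed on these centred series and
  its two-tailed P from `t = r·sqrt(n-2)/sqrt(1-r²)` with n−2 degrees of
  freedom; the tests pin this against `stats::cor.test` and against a
  10,000-draw permutation null.

## What the synthetic generator emulates — and what it does not

`generate_steady_state_dataset()` emulates the structure of a steady-state
LC/MS campaign: 6 growth conditions spanning a 3-fold range of µ (0.3–0.9
h⁻¹), 2 biological replicate series, 3 sampling replicates each, per-analyte
raw counts with matched internal-standard counts, OD per sample, and
total-PE rows from which the operational PL flux (total PE × µ) is formed.
Growth rate maps to a PlsB Vmax multiplier log-linearly across a 4-fold
span, under which the calibrated model's PE flux spans about 2-fold while µ
spans 3-fold — hence total PE per OD declines gently with µ, as observed
for membrane per biomass. Counts are concentrations times per-analyte
response factors (log-uniform, 10³–10⁵ counts/µM, redrawn per dataset;
correlations are scale-invariant so these are free), times OD, times
multiplicative lognormal measurement noise (CV 0.1, a typical targeted
LC/MS figure) and a lognormal biological-series factor (CV 0.05). Flat
"enzyme" analytes (PlsB, LpxC), a constant acetyl-CoA and a ppGpp surrogate
declining as 1/µ are included so the pipeline sees null and negative
controls. The planted truth is the same table without noise, pushed through
the same correlation pipeline.

The generator does **not** emulate chromatographic drift, batch effects,
missingness, saturation nonlinearity of detectors, or the chemistry of the
nucleotide and G3P assays. Passing recovery tests therefore shows that the
statistical pipeline is correct and adequately powered under well-behaved
multiplicative noise — not that it is robust to every pathology of real
LC/MS data.

## Replicate pooling

The published correlations use n = 12 for most analytes (6 media × 2
biological series) — sampling replicates are averaged, biological series
kept as separate points. That convention is the default
(`pool = "bio"`); `pool = "condition"` averages everything within a
condition instead, since the exact pooling behind every published n is not
stated. P values are reported raw, with no multiple-testing correction,
matching the published table's convention.

## Problem sizes

The test-suite and acceptance runs use the sizes the analyses were designed
at: steady-state checks on the default and 20 jittered parameter sets;
trend-sign robustness over 100 log-uniform parameter draws within a 4-fold
range; sign recovery over 100 seeded datasets at CV 0.1; test size over
1,000 null analytes. A full acceptance run takes about two to three minutes
on one core.

## Known limitations

* The PL branch into PE/PG/cardiolipin is not modelled (PE stands for total
  PL output), nor are PGP species or cyclopropyl-PL chemistry.
* All kinetics are irreversible; there is no enzyme synthesis or
  degradation, so transcriptional regulation can only be emulated by
  changing Vmax between runs.
* Dynamic simulations reproduce the *qualitative* cascade after ppGpp or
  acetyl-CoA steps (long-chain acyl-ACP accumulation, malonyl-ACP
  depletion, ordered LPA → PA → CDP-DAG → PS drainage); quantitative time
  constants of real cultures are outside the model's reach.
* Absolute concentrations and fluxes are in model units; only normalized,
  relative statements (fold changes, slopes, correlations) are meant to be
  compared with experiment.
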