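---
title: "Measuring insertion forces and membrane dimpling with a cantilever-beam sensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring insertion forces and membrane dimpling with a cantilever-beam sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microforce)
library(dplyr)
```

## The measurement problem

Implanting a microelectrode into the brain requires pushing its tip through
the meningeal membranes -- the tough dura mater and, beneath it, the thin
pia mater. Before the membrane ruptures, the advancing tip elastically
depresses the brain surface ("dimpling"), and the peak force just before
the sudden drop -- the rupture force -- decides whether a slender microwire
penetrates or buckles. These forces range from tens of micro-newtons for a
12 µm wire on pia to over a hundred milli-newtons for dura penetration, a
range no single commercial force sensor covers in vivo.

A practical solution is a vertical cantilever beam: the microwire is
mounted near the free end, the anesthetized animal is driven into the wire
by a linear stage at a constant feed rate (100 µm/s), and a laser
displacement sensor (0.01 µm repeatability, 2 mm range) reads the beam
deflection `d_c` at a known height. Calibration turns `d_c` into the
insertion force `F_i` and the deflection at the load point `d_l`; the
stage travel `d_t` is known from time, and the dimpling is

    d_i = d_t - d_l.

This package implements the computational side of that instrument: the
beam mechanics and calibration, the trace-to-profile conversion with
rupture detection, a synthetic-data generator with the statistical
structure of an in vivo insertion study, and the study-level statistics.

## Beam mechanics and calibration

Each sensing beam is a rectangular aluminium cantilever with flexural
rigidity `EI = E b h^3 / 12`. Under a point load `F` at the load point,
Euler--Bernoulli theory for a cantilever clamped over its bottom
`clamp_height` gives the deflection at height `x` above the clamp as
`F x^2 (3a - x) / (6 EI)`, with `a` the load arm. The two calibration
ratios follow:

* force per laser deflection `F_i/d_c = 6 EI / (x^2 (3a - x))` (mN/mm),
* load-point per laser deflection `d_l/d_c = 2 a^3 / (x^2 (3a - x))`.

```{r}
calibration_report()
```

A convention note: the effective arms are measured from the **top of the
clamp** (`a = l - 15` mm, `x = c - 15` mm). The source tables never state
this, but it is the only convention that reproduces the published ideal
ratios for the beams, which we verified numerically against an
independent double integration of the beam curvature (the test suite
holds both routes to six significant figures).

Two caveats are deliberate:

* The finite-element calibration coefficients (which include gravity of
  the mounted top plate and capillary) are consumed as instrument
  constants; no gravity-loaded beam model is attempted. The up-to-20%
  difference between ideal and FEM force ratios on the softest beam is a
  real, gravity-driven effect.
* The published ideal force ratio for the second beam (16.62 mN/mm) is
  inconsistent with beam theory for its geometry (theory gives
  ~7.94 mN/mm, while its `d_l/d_c` row *is* consistent). We treat this as
  a typo in the source table: `calibration_registry("ideal")` recomputes
  from geometry by default, and the published value is available with
  `published = TRUE` but excluded from validation.

Measurement capacity is linear bookkeeping -- ratio times laser range for
the maximum force, ratio times the quantization step for resolution --
and the tilt of the top plate under load costs a relative error of
`1 - cos(alpha)`, negligible (< 0.05%) below 2 degrees:

```{r}
measurement_capacity(calibration_registry("fem"))
tilt_error_report()
```

For slender microwires the Euler critical load `P = m pi^2 E I / L_u^2`
(`I = pi d^4 / 64` for circular wires) sets the ceiling on transmissible
force. The end-condition factor `m` depends on how the wire is supported
during insertion and is never pinned down numerically in the source
study; it is exposed as a user parameter with default 1 (pinned--pinned,
the conservative textbook choice).

## From displacement trace to force profile

`convert_trace()` applies the calibration linearly at every 2 ms sample
and reconstructs the stage channel from the feed rate; the dimpling
identity `d_i = d_t - d_l` then holds exactly by construction. Readings
at the laser range limit are flagged, never clipped silently.

Rupture detection (`detect_rupture()`) looks for the signature of
membrane failure: a force drop completing within at most 100 ms. The
slow physiologic oscillation from breathing (1--2 s period) cannot fall
far in 100 ms, so a short-window criterion separates the two time
scales. The drop must exceed both

* 5% of the running maximum (relative criterion), and
* an absolute floor `min_drop` of 0.2 mN.

The absolute floor is this package's addition: early in a trace the
running maximum is small and a purely relative threshold would trip on
breathing. The default is set from the physics -- the largest possible
100 ms breathing fall at default amplitude (0.1 mN) is about 0.06 mN, and
the smallest default-scale rupture drops are several times 0.2 mN. The
rupture force is read at the running maximum immediately preceding the
drop, matching how the force-drop points were captured in the original
analysis, and the dimpling at rupture is the dimpling channel at that
maximum.

Outcome classification treats a trial with no detected rupture as
*buckled* when the force plateaus (fitted slope below 0.1 mN/s over the
final 4 s -- at least two breathing periods, so the sinusoid averages
out) at a level within 25% of the wire's Euler load; a buckled slender
column sustains roughly its critical load. This criterion is our
construction: the source study identified buckled trials from the
recordings without stating a formal signature. Anything neither ruptured
nor plateaued near the critical load is *invalid* with a diagnostic.

Breathing itself is estimated (`extract_breathing()`) from the linearly
detrended pre-rupture force: an FFT locates the dominant peak in the
0.2--5 Hz band and a harmonic regression on a fine grid around that bin
refines the frequency and fits the amplitude, avoiding the leakage bias
of reading the amplitude off the raw periodogram.

## The synthetic-data generator

No raw traces or trial tables were deposited with the source study, so
every downstream stage is exercised on synthetic data whose structure --
not whose absolute values -- mimics the instrument's recordings.

A single trace (`simulate_insertion()`) is quasi-static: the beam
(stiffness at the load point `k_b = (F_i/d_c)/(d_l/d_c)`) and a linear
membrane spring `k_m` act in series, so force rises at
`k_eff = (1/k_b + 1/k_m)^{-1}` per mm of stage travel until the
programmed rupture force, consistent with the observed linear dimpling
ramp. Rupture is instantaneous: the membrane spring vanishes and the
beam re-equilibrates against a shallow friction line, releasing its
stored deflection into insertion depth (the "beam rebound"). Retraction
ramps the force down through an adhesion dip. Breathing (period drawn
uniformly from 1--2 s), Gaussian sensor noise, and 0.01 µm quantization
are applied to the laser reading.

Defaults are chosen once, to be physiologically plausible, and labelled
synthetic throughout:

| parameter | default | rationale |
|---|---|---|
| membrane stiffness (pia / dura) | 3 / 10 mN/mm | puts dimpling at rupture in the observed ranges (a few tenths of a mm for pia, 2--3x more for dura) |
| breathing amplitude | 0.1 mN | visible but subdominant oscillation, as in the published profiles |
| sensor noise | 0.05 µm | a few quantization steps |
| friction slope | 0.2 mN/mm | shallow post-rupture plateau |
| adhesion force | 0.1 mN | small negative retraction dip |

A whole study (`simulate_study()`) draws per-trial rupture forces from

    (intercept + slope * diameter) * tip_mult^(sharp) * membrane_mult^(dura)
      * material_factor + animal effect + residual

with defaults intercept 0.3 mN, slope 0.02 mN/µm (so pia-only blunt means
run ~0.5--2.3 mN across 12--100 µm), dura multiplier 10 (an order of
magnitude, as observed), sharp multiplier 0.6 (motivated by the reported
>40% reduction from sharpening -- a default, not a measured constant),
material factor 1 for both materials (a true null, matching the finding
of no material effect), animal/residual standard deviations 0.05/0.15 mN
for pia and 0.5/1.5 mN for dura. Dimpling is force over membrane
stiffness plus noise. A trial whose drawn force exceeds the wire's Euler
load is recorded as buckled. All randomness flows through one seeded
generator; in the end-to-end pipeline, per-trial sub-seeds are derived
from the master seed keyed to the condition-sorted order, so the
randomized trial order never changes the results.

What the generator does *not* emulate -- and hence what passing tests do
not show about real data: viscoelastic or rate-dependent tissue response
(the feed rate is fixed), heterogeneity from blood vessels or local
membrane microstructure, drift in membrane properties over a session,
and cardiac pulsation. Recovery of the programmed rupture force by the
pipeline demonstrates the measurement chain, not the biology.

## Statistics

The statistical layer reproduces the shape of the study's analyses:

* **Buckling rates** (`buckling_rate_table()`): buckled trials as a
  percentage of all trials, per condition and pooled. The published
  per-condition counts ship with the package (`penetration_counts()`)
  and the pooled rates (2.6% pia-only, 16.3% dura-pia) follow exactly.
* **Diameter linearity** (`diameter_linearity_fit()`): ordinary least
  squares of per-condition *mean* response on diameter -- explicitly the
  source study's procedure -- with a raw-trial option, plus a competing
  fit on diameter squared (the cross-sectional-area model) for
  comparison.
* **ANOVA** (`three_factor_anova()`): main effects of material, tip and
  diameter (as a factor), penetrated trials only, with partial (type II)
  sums of squares via `car::Anova()`. The source study names neither the
  ANOVA type nor software; type II is the standard choice for an
  unbalanced main-effects-only design. Reproducing the published F
  values is not attempted -- the raw data were never deposited.
* **Correlations** (`rupture_dimpling_correlation()`): two-sided Pearson
  tests within the study's strata (all trials, per tip, per diameter),
  with the study's strength bands (strong: `|r| > 0.7` and `p < 0.05`;
  moderate: `0.3 < |r| <= 0.7`). Strata with fewer than 3 trials report
  an undefined p.
* **Ratio** (`dimpling_force_ratio()`): dimpling per unit rupture force,
  the quantity whose strong tip- and diameter-dependence argues against
  using dimpling alone as a force proxy.

One calibration subtlety worth knowing: under the generator's *full*
defaults the material F-test is conservative (empirically ~1--2%
rejection at nominal 5%), because the multiplicative tip effect creates
a tip-by-diameter interaction that a main-effects model leaves in the
residual, and the animal effect further inflates the error variance --
exactly what happens when a plain ANOVA meets clustered, interacting
data. The test's own level is therefore verified under its proper null
(no material effect, no interaction, independent residuals), where the F
null distribution holds exactly and the empirical rate sits at 5% up to
Monte-Carlo error.

```{r}
tab <- simulate_study(study_design(animals = 4), seed = 1)
study_report(tab)$buckling_rates |> filter(scope != "condition")
tidy(three_factor_anova(tab, "rupture_force_mn", "pia_only"))
```

## Numerical choices and degenerate inputs

* Internal computation is SI (m, N, Pa); user-facing units are the
  instrument's (mm, mN, µN, µm). The conversion lives at the function
  boundaries, not inside formulas.
* The time base is sample index times 2 ms; no resampling.
* The forward-window minimum used by the drop detector is computed with
  a block prefix/suffix running-minimum decomposition, O(n) and fully
  vectorized, so 200-trace simulations stay cheap.
* Contact (`start_index`) is taken from the simulator's ground truth
  when available; on real traces it defaults to the first sample whose
  force exceeds three times the pre-contact noise level, with the
  threshold computable from the first half second of recording. The
  source study identified contact visually.
* Constant or too-short profiles return empty results with a diagnostic
  attribute rather than errors; a factor with fewer than two observed
  levels aborts the ANOVA naming the factor; a zero total count aborts
  the rate table.
* A constant response in the ANOVA (zero variance) is reported as F = 0
  for every factor rather than delegating to the general-purpose routine,
  which rejects zero residual variance.

## Problem sizes

The shipped validation exercises the chain at sizes that keep a full run
comfortable on a laptop: 200 simulated traces per detection setting
(about 25,000 pre-rupture samples each at 500 Hz), 1000 replicate studies
for the ANOVA level check, and 100 replicate studies for slope-recovery
and model-comparison checks. These sizes give Monte-Carlo standard
errors comfortably inside the tolerances they are checked against.

## Known limitations

* The mechanics are quasi-static; beam dynamics after rupture (ringing,
  overshoot) are reduced to a single-step re-equilibration.
* The post-rupture plateau is carried through conversion but not
  decomposed into friction, cutting and clamping components; the source
  provides no separating model.
* No mixed-effects treatment of animal as a random factor (the source
  used plain ANOVA); the vignette section above documents the
  consequences.
* Silicon multi-shank probes are supported in the buckling formula
  (rectangular section) but the study's multi-shank force values were
  explicitly underpowered and are out of scope.
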