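---
title: "Aerodynamics and assay metrics for porous microrods: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aerodynamics and assay metrics for porous microrods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodaero)
```

## The problem

Rod-shaped microparticles are candidates for pulmonary drug delivery and for
targeting alveolar macrophages: a fiber-like particle aligns with the flow
and settles like a much smaller sphere, so a particle that is geometrically
large (which resists exhalation and phagocytic clearance by other cell types)
can still deposit in the deep lung. Whether a given rod is respirable is
governed by its aerodynamic diameter `da` — the diameter of the unit-density
sphere with the same settling velocity — which this package computes,
measures from cascade-impactor data, and inverts for the dynamic shape
factor. Around that core it implements the supporting in vitro metrics used
in carrier development: MTT viability, LDH cytotoxicity, disintegration
kinetics and size-distribution statistics.

## The aerodynamic model

For a nonspherical, porous particle,

$$ d_a = d_{ve} \sqrt{ \frac{\rho_{\mathrm{eff}}\, C_c(d_{ve})}
                            {\rho_0\, C_c(d_a)\, \chi} } $$

where

* $d_{ve}$ is the volume-equivalent diameter (for a cylinder of width $w$
  and length $l$: $d_{ve} = (\tfrac{3}{2} w^2 l)^{1/3}$, µm);
* $\rho_{\mathrm{eff}}$ is the effective envelope density — the
  crystallographic density times the packing fraction when the particle is a
  porous assembly of primary crystallites; the default packing fraction 0.64
  is the random-close-packing limit of equal spheres. Porosity enters only
  through density; drag reduction by pore permeability is not modelled;
* $\rho_0 = 1$ g/cm³ is the unit-density convention;
* $\chi \ge 1$ is the dynamic shape factor (drag of the particle over the
  drag of its volume-equivalent sphere at equal velocity; 1 for spheres);
* $C_c$ is the Cunningham slip correction in the Davies form
  $C_c(d) = 1 + \frac{2\lambda}{d}\left(A_1 + A_2 e^{-A_3 d/\lambda}\right)$
  with defaults $\lambda = 0.066$ µm (air at 20 °C), $A_1 = 1.257$,
  $A_2 = 0.400$, $A_3 = 0.55$.

Because $C_c$ is evaluated at $d_a$ itself, the relation is implicit.

### Numerical solution

`aerodynamic_diameter()` starts from the no-slip solution
$d_{ve}\sqrt{\rho_{\mathrm{eff}}/(\rho_0\chi)}$ and applies a damped
fixed-point iteration (each update averages the current iterate with the
mapped value), stopping when the update falls below the tolerance
(`tol = 1e-6` µm, `max_iter = 100`). $C_c$ varies slowly with diameter, so
the map is strongly contracting and converges in ~10 iterations for
physical inputs; two undamped polishing steps after convergence push the
residual orders of magnitude below the tolerance. If the damped iteration
stalls or oscillates the solver falls back to bracketed root finding
(`stats::uniroot`) on the monotone residual; if that also fails, a
non-convergence condition carrying the last iterate is signalled. The test
suite checks the solver against an independent bisection oracle on 100
random parameter draws (agreement to 1e-6 µm) and round-trips the
closed-form inversion
$\chi = (d_{ve}/d_a)^2 (\rho_{\mathrm{eff}}/\rho_0) C_c(d_{ve})/C_c(d_a)$
to the same tolerance.

$\lambda$ is kept at its 20 °C value by default even though cell-culture
work is at 37 °C, so computed values match the usual room-temperature
calculation convention; it is overridable via `slip_params()`.

### Shape factors

`shape_factor_provider()` has two branches. The `constant` branch passes a
literature value through unchanged — the shipped default is $\chi = 2.13$,
an empirical literature value for rods of aspect ratio ≈ 3.6. The
`lau_correlation` branch evaluates a user-supplied polynomial of $\chi$ on
aspect ratio; **no coefficients are shipped** because the original
correlation's coefficients are not reproduced here, and inventing them would
silently change every downstream number. Requesting the correlation without
coefficients is an error directing the user to transcribe them from the
original source.

A worked comparison (`run_table2_comparison()`):

```{r}
run_table2_comparison()[, c("particle", "structure", "chi", "da_rounded")]
```

The porous rod (5.74 µm) is aerodynamically smaller than the porous sphere
of equal volume (8.41 µm): elongation and porosity together roughly halve
the aerodynamic size. Inverting the model at a *measured* mass median
aerodynamic diameter of 4.76 µm gives

```{r}
rod <- particle_geometry("cylinder", 3.41, 12.12)
shape_factor_from_measurement(4.76, volume_equivalent_diameter(rod),
                              rho_eff = 3.09 * 0.64)
```

i.e. the aerosol behaved as if its drag were ~45% higher than the literature
shape factor predicts — per-batch inversion and averaging of measured MMADs
yields the same picture (a batch-mean near 3.1).

## Impactor data reduction

`mass_balance()` follows conventional cascade-impactor accounting: recovered
dose = stages + terminal collector + inlet + pre-separator + device +
capsule; emitted (ex-device) dose excludes capsule and device; the sized
distribution uses only the stages plus the terminal collector, because inlet
and pre-separator deposits have no cutoff diameter.

MMAD and GSD come from two-point interpolation of probit(cumulative mass
fraction undersize) against log10(cutoff diameter) between the bracketing
stages — the standard pharmacopoeial practice. This interpolation is *exact*
for a lognormal aerosol on any cutoff grid (probit of a lognormal CDF is
linear in log diameter), which the tests exploit: a noise-free lognormal
discretized onto the shipped NGI 60 L/min cutoff table (8.06, 4.46, 2.82,
1.66, 0.94, 0.55, 0.34 µm; archival calibration of Marple et al. 2003,
J Aerosol Med 16:283–299) is recovered to floating-point accuracy in MMAD
and to ~1e-4 in GSD (the 84.13%/15.87% percentile convention rounds
$100\,\Phi(\pm 1)$). A distribution whose cumulative curve never crosses the
required percentiles raises a "not bracketed" error rather than
extrapolating.

The fine particle fraction interpolates the cumulative mass at 5 µm on the
same scale. When both stages bracketing 5 µm are saturated (0% or 100%) the
probit transform is undefined and the saturated value is passed through; a
mixed bracket falls back to linear interpolation in log diameter. The FPF
denominator is configurable (`emitted` default, `recovered`, `sized`) and is
echoed in the output as `denominator_used`, because reporting conventions
differ between laboratories and the choice changes the number by the loss
fractions.

## Plate assays

Net OD is measurement minus reference wavelength per well. Viability
(MTT) and cytotoxicity (LDH) are control-anchored percentages:

$$ V = 100\,\frac{OD_s - \overline{OD}_{pos}}{\overline{OD}_{neg} - \overline{OD}_{pos}},
\qquad
 T = 100\,\frac{OD_s - \overline{OD}_{neg}}{\overline{OD}_{pos} - \overline{OD}_{neg}}. $$

Controls are aggregated as arithmetic means of net OD *per plate* (no
cross-plate pooling, to avoid plate effects). Both formulas can
mathematically leave [0, 100]; values are reported as computed with a
warning, never clipped, so systematic control drift remains visible.
Threshold classification is strict — a condition fails only when
cytotoxicity exceeds 20% or viability falls below 80%; boundary values pass.
Thresholds are arguments. Blank wells are accepted in the schema but unused
by default (whether an extra blank correction beyond reference-wavelength
subtraction is appropriate depends on the reader protocol; it is left to the
user).

Disintegration series are reduced to percent remaining relative to the mean
of reference counts (independent batches measured at t = 0 in water), with
mean ± SD over batches per timepoint. Size distributions are summarised by
type-7 (linear-interpolation) empirical quantiles; the span
$(d_{90}-d_{10})/d_{50}$ is scale-invariant.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes with known ground
truth; all are deterministic given a seed.

* `gen_impactor_run()` — lognormal aerodynamic mass distribution (defaults
  MMAD 4.76 µm, GSD 1.38, matching the measured batch means of the motivating
  study) discretized onto the cutoff table; `noise = "none"` is the exact CDF
  increment, `multinomial` resamples a finite number of mass quanta. Losses
  are fixed fractions of the sized mass (defaults: capsule 0.15, device 0.05,
  inlet 0.20, pre-separator 0.25 — typical magnitudes for a capsule DPI).
* `gen_rod_population()` — intact rod lengths normal-truncated at the
  template pore length plus a uniform fragment mixture; emulates
  imaging-flow summary output (mean lengths ~11.5–13.3 µm for the
  template-grown batches that motivated the defaults).
* `gen_plate()` — net ODs back-computed from a 4-parameter logistic
  viability curve through the viability definition, plus Gaussian read
  noise; the dose series default (0.025–0.4 mg/mL) matches the study's
  concentration range.
* `gen_disintegration()` — per-batch counts Poisson-distributed around
  first-order decay $n_0 e^{-kt}$; presets `acidic_fast` (k = 0.05/min) and
  `neutral_slow` (k = 5e-4/min) emulate rapid disintegration in acidic
  phagolysosomal simulant vs stability near neutral pH.

These are testing devices, not physical claims: real impactor noise includes
wall losses and re-entrainment, not just multinomial sampling; real plates
have spatial effects; and the true disintegration kinetics are unlikely to be
exactly first order. Passing recovery tests therefore demonstrates that the
*reduction pipeline* is correct and unbiased under its stated assumptions,
not that real instruments will achieve those error bounds. Problem sizes in
the tests (≤ 5000 particles, ≤ 1e6 multinomial quanta, ≤ 30-stage grids) keep
the suite fast while leaving Monte-Carlo error well below the asserted
tolerances.

## Design choices on open points

* **FPF denominator** — not standardised across studies; default `emitted`,
  always echoed in the output.
* **MMAD interpolation** — two bracketing points rather than a regression
  over all stages: exact for lognormals, robust to tail stages with near-zero
  mass, and the standard practice of the data-reduction literature.
* **Rods per milligram** — the density basis (porous vs crystallographic,
  with or without polymer payload) materially changes the count; the function
  takes an explicit `porous` flag and no attempt is made to reproduce any
  particular published rod-to-cell ratio, whose underlying counts were not
  published in full.
* **Sphere geometry** reuses the `width` field as the diameter — one type
  serves both shapes, with the convention documented in the type.
* **Reporting precision** — diameters print at 2 decimals and ratios at 1
  decimal (matching the conventions of the tables the model reproduces);
  full precision is retained in all returned objects.

## Limitations

Orientation-resolved fiber aerodynamics, interception/sedimentation lung
deposition, CFD, and drag reduction by pore permeability are out of scope;
$\chi$ enters only as a scalar. The shipped cutoff fixture covers the NGI at
60 L/min only — supply a `cutoff_table()` for other impactors or flow rates.
No dose–response curve fitting (IC50/4PL) or hypothesis testing is included;
the assay module is deliberately descriptive (mean ± SD and thresholds).
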