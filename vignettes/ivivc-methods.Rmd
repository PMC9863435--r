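---
title: "Methods: Level C IVIVC from release testing and tape stripping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Level C IVIVC from release testing and tape stripping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermivivc)
```

## The problem

For topical products acting locally in the skin there is no plasma
concentration to measure, so generic approval normally requires clinical
endpoint trials. A Level C in vitro–in vivo correlation offers a way
out: if a single in vitro release parameter predicts a single in vivo
skin-exposure parameter linearly across formulations, release testing
can stand in for the human study when comparing a test product to a
reference. This package implements that workflow end to end for
cream-type semisolids, with metronidazole as the worked case.

## The in vitro side: IVRT and the apparent release constant

A vertical diffusion cell holds the product against a synthetic
membrane over a stirred receptor (defaults: 7.9 mL cell, 15 mm orifice,
32 °C, samples of 0.2 mL every 15 min for 90 min, each replaced by
blank medium). Because each withdrawal removes drug, the cumulative
amount released per unit area at sample $n$ is reconstructed as

$$Q_n = \frac{C_n V_{cell} + \sum_{i<n} C_i V_{sample}}{A}.$$

Under Higuchi kinetics $Q$ is linear in $\sqrt{t}$; the OLS slope of
$Q$ on $\sqrt{t\,(\mathrm{min})}$ is the apparent release constant
(ARC, µg/cm²/min^½). Design choices:

- the intercept is **estimated**, not forced through the origin — a lag
  or burst then perturbs the intercept, not the slope; with a zero
  intercept the slope estimate is unchanged;
- all six time points are used by default; `time_window` can exclude
  points and the exclusion is logged;
- a run is summarised by the arithmetic mean ± sample SD (n−1) of the
  per-cell slopes; runs sharing a reference are never pooled at this
  stage.

The test/reference ratio interval is, by default, a Welch two-sample
$t$ interval on mean log-slopes, exponentiated — the standard small-$n$
choice for a ratio of positive means; Fieller's interval is available
when slopes may be non-positive. The method is recorded in the output
because the choice is a convention, not a measurement. Empirical
coverage of the 90% interval is verified by simulation in the test
suite (2000 replicates, coverage required in [0.87, 0.93]).

## The in vivo side: tape stripping and the depth-profile AUC

Twenty pre-weighed adhesive strips sequentially remove SC from a
2 × 2 cm site after a 60-min application of ~15 mg of cream. Strip $i$
removes mass $m_i = \mathrm{post}_i - \mathrm{pre}_i$ (small negative
balances are clipped to zero with a warning; gross negatives error),
converted to depth via $x = m /(A\,\rho)$ with $\rho = 1$ g/cm³ — the
conventional SC density, configurable.

SC thickness $L$ comes from TEWL on a blank site: at Fick steady state
TEWL $\propto 1/(L-x)$, so $1/\mathrm{TEWL}$ declines linearly with
stripped depth and extrapolates to zero at $L$. The estimator requires
a positive decline with $R^2 \ge 0.8$; otherwise the thickness is
declared non-identifiable. This genuinely happens for thick-SC
participants — 20 strips may sample only a quarter of their barrier, so
the $1/\mathrm{TEWL}$ signal is shallow relative to measurement noise.
The per-series estimator errors; the pipeline's default policy
(`thickness_on_unidentifiable = "exclude"`) drops the participant with
a logged warning, which is what an analyst does in practice.

Each strip is plotted at the **midpoint** of the depth interval it
removed, as a percent of $L$ (leading/trailing-edge positions are
selectable; the midpoint is the unbiased single-point summary of the
interval). Strips reaching beyond 100% of $L$ are kept and flagged;
beyond 150% the record is rejected as inconsistent. The first strip is
included by default (`drop_first_n` exists because some protocols
discard surface-residue strips). The AUC is the composite trapezoid
over (relative depth %, µg/strip) with no extrapolation beyond the
observed positions (an optional zero-anchor at 0% and at the last depth
is off by default). Blank subtraction is off by default: blanks serve
the TEWL measurement, not the assay. Study level: replicate sites are
averaged within participant (switchable), then mean ± SD across
participants.

## The correlation and the bioequivalence windows

The Level C model is OLS of AUC on ARC. A product measured in two IVRT
runs contributes one point per run against its single observed AUC —
with the bundled five-point metronidazole table this is the only
configuration that reproduces the published coefficients, and it is the
honest representation of the design (the reference's release was
measured twice). Observed-vs-predicted agreement is reported as the
two-value CV, $|obs-pred|/\sqrt{2}$ divided by the pair mean.

BE windows: pooled reference ARC = mean of the reference run ARCs
(a single-run mode exists); ARC window = pooled × (0.7999, 1.2501);
AUC window = ARC window mapped through the model. The default ratio
bounds are the exact working values that reproduce the published limit
table after 2-decimal rounding; `0.80/1.25` are selectable. The verdict
uses the ARC window on the product's mean ARC (inclusive); because the
map is affine and increasing, ARC- and AUC-window membership coincide,
which the tests assert. A stricter CI-inside-window mode exists but is
off by default, matching the point-estimate practice of the reporting
convention this package follows.

## The synthetic world

The generator exists because the study's raw per-cell and per-strip
records are not public: it produces data with exactly the statistical
structure the analysis assumes, so every stage is validated by
parameter recovery rather than against an inaccessible gold standard.

- **IVRT**: per-cell true slopes ~ Normal(ARC, 5% CV between cells);
  concentrations obtained by exactly inverting the withdrawal
  bookkeeping (so the analysis-side correction is the identity at zero
  noise) with 2% multiplicative measurement CV.
- **Drug–depth profile**: transient Fickian series solution for a
  membrane with constant surface concentration $KC_v$ and a sink at the
  viable epidermis,
  $C(x,t) = KC_v[(1-\tfrac{x}{L}) - \tfrac{2}{\pi}\sum_n \tfrac1n
  \sin\tfrac{n\pi x}{L} e^{-n^2\pi^2 (D/L^2) t}]$, truncated when the
  geometric tail bound falls below 1e−12. $D/L^2 = 0.002$/min makes the
  60-min profile clearly non-steady-state. Strip amounts are the exact
  analytic depth integrals over each removed interval, scaled by the
  product strength (% w/w) and capped at the applied drug dose.
- **Strip masses**: geometric decay (150 µg first strip, 5% per strip,
  10% lognormal CV). The spec-sheet value of 400 µg for the first strip
  is *not* usable: it would strip ~5.1 mg of SC from a site whose 10 µm
  barrier holds only ~4 mg, violating the generator's own mass
  invariant; 150 µg removes ~48% of a mean SC in 20 strips, typical of
  real studies. The config constructor enforces this bound.
- **SC thickness**: lognormal, mean 10 µm, 20% CV — the dominant
  between-subject AUC variability source (study CV ≈ 12–17%, consistent
  with the published between-subject SDs).
- **TEWL**: $\mathrm{TEWL}_k = \mathrm{TEWL}_0\, L/(L - x_k)$ with
  intact-skin baseline 8 g/m²/h and 5% lognormal noise; blank-site
  masses are rescaled if a thin SC would otherwise be stripped through,
  keeping recorded masses and TEWL consistent.
- Noise CVs without stated values (drug 5%, TEWL 5%) were fixed once at
  typical assay/instrument repeatability. All randomness flows from one
  integer seed through a local RNG scope; the caller's RNG state is
  untouched and identical seeds give byte-identical CSVs.

What a green test does **not** establish: the generator has no
inter-day or inter-run effects, no assay error structure beyond
multiplicative CV, no participant-level diffusivity variability, and a
depth profile that is Fickian by construction — so recovery tests prove
the pipeline's internal consistency and statistical calibration, not
the biological adequacy of the Fickian model.

## Numerical choices

- OLS everywhere is closed-form (centred normal equations); tests check
  it against `lm()` to 1e−10. The trapezoid is checked against a
  fine-grid integral of the linear interpolant to 1e−9, and the series
  solution against an explicit finite-difference solver to 0.5%.
- Reported tables round half-to-even at 2 decimals (base `round`);
  internal computation is full precision.
- Depth/mass unit bridge: 1 µg over 1 cm² at 1 g/cm³ = 0.01 µm.
- Degenerate inputs error early with the offending field or record
  named: fewer than 3 fit points, zero variance in the regressor, flat
  TEWL, stripped depth > 150% of $L$, ratio bounds not bracketing 1.

## Known limitations

- Only a single-point (Level C) correlation: no point-to-point
  (Level A), statistical-moment (Level B) or multiple-Level-C support.
- The published per-run 90% ratio CIs cannot be reproduced exactly
  because the raw per-cell data are unavailable; the implemented CI
  methods are instead validated by coverage simulation.
- The five-point fit leans on two points from the same reference
  product; the $R^2$ is dominated by the deliberate strength spread of
  the test products, as in any small Level C exercise.
- Thickness estimation degrades when strips sample a small fraction of
  the SC (see above); the exclusion policy trades a smaller n for
  unbiasedness.
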