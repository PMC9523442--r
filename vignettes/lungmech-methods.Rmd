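---
title: "Models and methods in lungmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in lungmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungmech)
```

`lungmech` analyses two experiment families on developing lung tissue:
uniaxial tension/compression tests of punched tissue cylinders, and
Ussing-chamber electrophysiology of distal lung epithelial monolayers. This
vignette documents the models, the tunable parameters and their defaults,
the numerical choices, and the known limitations.

## The van der Waals hyperelastic network model

Soft lung parenchyma behaves like a rubber network of collagen and elastin:
linear at small strain, then strongly strain-stiffening. The package uses
the van der Waals (Kilian) network model, a phenomenological
rubber-elasticity model with finite chain extensibility and a global
interaction term. For uniaxial stretch $\lambda$ (deformed over undeformed
length) the nominal stress — force per *undeformed* cross-section — is

$$f(\lambda) = G\,D(\lambda)\left(\frac{1}{1-\eta} - a\,\Phi^{1/2}(\lambda)\right),
\qquad
D = \lambda - \lambda^{-2},\quad
\Phi = \tfrac12\!\left(\lambda^2 + \tfrac2\lambda - 3\right),\quad
\eta = \sqrt{\Phi/\Phi(\lambda_m)} .$$

* $G$ (Pa) — shear modulus, the small-strain scale. The infinitesimal slope
  $df/d\lambda$ at $\lambda = 1$ is exactly $3G$.
* $a$ (dimensionless, $\ge 0$) — global interaction across network
  junctions; it softens the mid-strain response.
* $\lambda_m$ ($> 1$) — limiting stretch from finite chain extensibility;
  $f$ diverges as $\eta \to 1$, producing the stiffening tail.
* $\nu$ — Poisson ratio, fixed at 0.5 (incompressible hydrated tissue) and
  not fitted; it only enters the reported Young's modulus $E = 2G(1+\nu) = 3G$.

The strain-energy density
$W(\lambda) = -G\{2\Phi_m[\ln(1-\eta)+\eta] + \tfrac23 a\,\Phi^{3/2}\}$
is the exact potential of $f$ ($dW/d\lambda = f$, verified numerically in
the test suite), and the model reduces to neo-Hookean
$f = G(\lambda-\lambda^{-2})$ as $a \to 0$, $\lambda_m \to \infty$.

Evaluation at $\eta \ge 1$ raises an error rather than returning an
infinity: silent infinities corrupt least squares, and the fitting code
instead constrains $\lambda_m$ away from the observed stretches.

### A caution on mean parameter tables

Group-mean parameter triples $(E, a, \lambda_m)$ averaged over many fits
need not form a valid single curve: if $a$ exceeds
$\min_\lambda [1/(1-\eta)]/\Phi^{1/2}$ over the strain range, the bracket
term goes negative and the "curve" would oppose the loading direction. One
published fetal-tension mean set (1 mm/min: $a = 5.8$, $\lambda_m = 1.9$)
has exactly this property. The synthetic generator therefore validates sign
consistency at generation time and refuses such parameter sets; fixture
families use the model-valid rows.

## From force–distance records to moduli

* **Strain and stress.** Engineering strain is deformation distance over the
  machine-measured sample height; nominal stress is force over the punch
  cross-section $\pi(d/2)^2$. Reported stress magnitudes are positive in the
  loading direction.
* **Stretch convention.** $\lambda = 1 + \varepsilon$ in tension,
  $\lambda = 1 - \varepsilon$ in compression (so 50 % compression is
  $\lambda = 0.5$). The fit compares signed stresses internally.
* **Contact.** Instrument records include an approach phase; start of
  contact is the first sample with $|F| \ge 1$ mN (the contact force the
  instrument itself uses), and displacement is re-zeroed there. For
  synthetic tests whose first sample is exactly the undeformed state,
  `contact = "none"` skips the threshold — the model stress near zero strain
  is below 1 mN, so thresholding synthetic data would shift the strain
  origin.
* **Linear regime.** The linear-regression modulus is the free-intercept OLS
  slope for strains at or below 0.15 (compression) or 0.10 (tension), both
  configurable, with at least 5 points required. On an exact model curve the
  band slope sits a few percent below $3G$ — the first-order curvature of
  the model over a finite band — which is why tight-band checks in the test
  suite use a 1 % band.
* **Full-range fit.** $(G, a, \lambda_m)$ minimise unweighted least squares
  over all points. Bounds: $G \in (0, 10^6]$ Pa, $a \in [0, 20]$,
  $\lambda_m$ between $1.01\times$ the conformation-equivalent maximum
  observed stretch (so $\eta < 1$ on all data, for compression computed by
  inverting $\Phi$) and 10. The deviance surface has local minima in
  $(a, \lambda_m)$, so the optimiser (bounded Levenberg–Marquardt) runs a
  small deterministic multistart — $a_0 \in \{0.5, 2, 5, 10\}$ crossed with
  three $\lambda_m$ starts — keeping the best converged fit and stopping
  early when an essentially exact fit appears; seeded random restarts remain
  as a fallback. $G_0$ is the linear-regime modulus over 3. Degenerate
  inputs (zero stress or strain range) and non-convergence are flagged, not
  guessed.
* **Peaks.** The global stress maximum is reported alongside local maxima —
  interior peaks whose stress drops on both sides by more than a prominence
  threshold before a higher value occurs. The default 50 Pa sits below the
  100–200 Pa amplitude of the local rupture events seen in compression
  experiments, so those events are detected; raising the prominence can only
  reduce the count.

Whether the reference fits operate on nominal or true stress inside their
black-box optimiser is not documented; this package exposes and fits nominal
stress throughout, the quantity the instrument geometry defines.

## Ventilation physiology

The deformation velocities used in testing protocols derive from ventilation
parameters: tidal volume over FRC gives the inspiratory volume fraction;
treating the lung as a homogeneous sphere converts it to linear strain
$(1+v)^{1/3}-1$; dividing by inspiration time and scaling by sample length
gives a plate velocity. All intermediate values are carried unrounded —
the conventional printed figures (5.9 %, 8.6 %, 26 and 52 mm/min for the
preterm scenario) only reproduce from unrounded fractions — and rounding
happens at display. The slow end of the range pairs the smallest strain with
the longest inspiration time, the fast end the largest strain with the
shortest time. For an adult scenario (FRC 30, tidal 6 ml/kg, 1–2 s) the same
arithmetic gives ≈ 3.8–7.5 mm/min, slightly wider than the conventionally
quoted 3–7 mm/min; the package reports the unrounded values and does not
hard-code the quoted range.

## Ussing-chamber quantification

Units are fixed throughout: mV, Ω·cm², µA/cm², cmH₂O.

* **QC.** Only monolayers whose baseline $R_{te}$ (mean before the first
  inhibitor event) *strictly* exceeds 300 Ω·cm² enter analysis.
* **Plateaus.** A sliding window (default 6 samples — two minutes at the
  20 s current-clamp sampling) is *flat* when its per-sample OLS slope is
  below 1 % of the window mean magnitude, **or** within twice its own
  standard error. The second clause is needed because a purely relative
  criterion can never certify flatness of a plateau near zero (e.g. a
  0.2 mV post-amiloride level under 0.1 mV noise). `detect_plateau()`
  reports the *earliest* flat window (plateau onset, as when waiting for
  $I_{base}$); inhibitor deltas instead use the *latest* flat window of each
  segment, i.e. the fully relaxed level, which avoids biasing the post-event
  plateau with the relaxation tail.
* **Deltas.** Inhibitor-sensitive components are differences of plateau
  means, not single samples: apical amiloride gives
  $\Delta V_{amil} = V_{base} - V_{amil}$ (the decomposition is additive by
  construction), basolateral ouabain gives $\Delta V_{ouab}$, and under
  voltage clamp the amiloride-sensitive $\Delta I_{sc}$. Whether the
  reference analyses took the post-inhibitor level as a plateau mean or a
  time-matched sample is not documented; the plateau mean is used here.
* **amil_max.** After amphotericin permeabilization the short-circuit
  current rises to a maximum set by apical Na⁺ entry; basolateral amiloride
  then blocks ENaC. `amil_max()` returns the post-permeabilization maximum
  minus the post-amiloride plateau. Taking a maximum of a noisy segment
  biases the estimate up by a few percent of the noise amplitude; this is a
  property of the protocol's estimator, not of the implementation.
* **Equivalent current.** $I_{sc} = V_{te}/R_{te}$, with $R_{te}$ averaged
  over the same pre-event window as $V_{base}$.

## Group-comparison decision tree

Shapiro–Wilk per group, then Bartlett across groups. Two groups: independent
Student's *t*, Welch-corrected when Bartlett rejects at $\alpha = 0.05$.
More than two: ANOVA + Tukey HSD under homogeneity, Welch ANOVA +
Games–Howell otherwise. Games–Howell is implemented directly (it is absent
from the installed stack): for each pair the Welch *t* statistic with
Welch–Satterthwaite degrees of freedom is referred to the studentized range
distribution, $p = P(q_{k,\nu} > |t|\sqrt2)$; the implementation is
validated in the test suite against an independently computed worked
example. Stars follow the strict thresholds 0.05/0.01/0.001. Groups with
fewer than three values, or zero variance, are flagged and skipped. When
normality fails, the comparison still proceeds on the chosen branch and the
violation is flagged — the reference workflow names no nonparametric
fallback, and none is invented here.

## Synthetic data: what it emulates, and what it does not

The mechanical generator produces constant-velocity ramps sampled at a
configurable storage interval (instrument default 2 ms) whose noiseless
stress equals the model stress of the generating parameters. It emulates:

* velocity-dependent stiffening under compression via multiplicative $G$
  scaling — default multipliers 1 : 4441/2646 : 7617/2646 at 1 : 7 :
  70 mm/min, the ratios of the published fetal-compression moduli — and
  rate-independent tension;
* heteroscedastic measurement noise, multiplicative on stress by default
  (the spread of instrument curves grows with stress; additive is available);
* local rupture events as 100–200 Pa step drops at random locations between
  15 % and 45 % strain, either at an exact count or Poisson-distributed.

The Ussing generator produces piecewise first-order relaxations between
configured plateaus with additive Gaussian noise, at 20 s (current clamp) or
5 s (voltage clamp) sampling, with the inhibitor schedule as events and
group-level $R_{te}$ (e.g. its decrease under basolateral pressure) set per
pressure group.

Neither generator is a biophysical simulation: there is no poroelastic fluid
flux, no alveolar microstructure, no viscoelastic creep or hysteresis, no
drifting electrode offsets. Passing tests therefore demonstrate that the
*analysis* recovers what the *assumed data model* encodes — parameter
recovery, orderings, calibration — not that real tissue follows the model.
All randomness flows from explicit seeds; the same seed reproduces a dataset
byte for byte.

## Problem sizes and runtime choices

The test suite and the acceptance script use synthetic curves of one to a
few hundred points (a 0.05 s storage interval instead of the instrument's
2 ms), cohorts of 8–20 replicates, 20-replicate noisy-recovery studies, and
1000-replicate null simulations for the decision-tree calibration. These
sizes keep the whole suite under a minute while leaving Monte-Carlo error
well inside the asserted tolerances; the generators accept the instrument's
native 2 ms interval unchanged when denser data are wanted.

## Known limitations

* Nominal (not true) stress throughout; no 3-D tensor formulation, no
  compressible variants, no Mooney–Rivlin/Ogden alternatives.
* No stress-relaxation, creep or cyclic-hysteresis protocols; slippage is
  not detected from data.
* The linear-regime bound is a fixed threshold, not estimated per curve.
* Plateau detection assumes approximately piecewise-stationary traces;
  strongly drifting baselines are flagged rather than modelled.
* The decision tree implements exactly the named tests; no effect sizes,
  Bayesian alternatives, or multiplicity control beyond the post-hoc
  procedures.
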