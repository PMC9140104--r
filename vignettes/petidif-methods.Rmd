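---
title: "Image-derived input functions by model-based matrix factorization: models, design and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-derived input functions by model-based matrix factorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petidif)
```

## The problem

Kinetic quantification of reversible PET tracers — here motivated by
TSPO imaging of neuroinflammation with ¹⁸F-DPA-714 — needs the arterial
input function (AIF): the tracer concentration in arterial plasma over the
scan. Measuring it requires arterial catheterization and laborious sample
processing, which is the main obstacle to kinetic analysis in clinical
studies. Reference-region shortcuts fail for TSPO tracers because no brain
region is free of specific binding; when binding rises globally, a
reference-normalized index cancels out the very signal of interest.

`petidif` implements a noninvasive alternative: an image-derived input
function (IDIF) extracted from the carotid arteries visible in the dynamic
brain PET itself, in three automatic steps — carotid voxel segmentation,
model-based matrix factorization (MBMF) of the voxel-by-frame matrix into
an arterial and a tissue component, and a scaling step that restores
physical activity units — followed by a population metabolite correction
and Logan graphical quantification.

## Signal model

Because PET resolution is coarse relative to the ~6 mm carotid lumen,
every segmented voxel mixes blood and surrounding tissue:

$$C_{i}(t) \;=\; \alpha_i\, C_{AIF}(t) + (1-\alpha_i)\, C_{TISSUE}(t),$$

with a voxel-specific arterial fraction $\alpha_i$ and a single tissue
type shared by all segmented voxels. Stacking $n$ voxels over $m$ frames
gives a matrix $A \approx W H$, where the two rows of $H$ are the frame
averages of $C_{AIF}$ and $C_{TISSUE}$ and $W$ holds per-voxel weights.

Unlike blind factorizations (NMF, ICA), both rows of $H$ are generated by
parametric models:

* the arterial input is a seven-parameter input model (delay $\tau$, a
  linear-rise term $A_1 (t-\tau) e^{-\lambda_1 (t-\tau)}$, and two slower
  exponentials with amplitudes $A_2, A_3$ and rates
  $\lambda_2 > \lambda_3$);
* the tissue curve is the output of a two-tissue compartment (2TC) model —
  the input convolved with
  $\frac{K_1}{B_2-B_1}[(k_3{+}k_4{-}B_1)e^{-B_1 t} +
  (B_2{-}k_3{-}k_4)e^{-B_2 t}]$, where $B_{1,2}$ are the roots of the
  characteristic quadratic of $(k_2,k_3,k_4)$.

The factorization estimates the 11 model parameters by minimizing
$\lVert W H - A\rVert^2$, with $W$ solved in closed form (ordinary least
squares, no sign constraint) at every objective evaluation.

## Identifiability, and the three design choices that address it

Because $W$ is unconstrained, the residual depends only on the *span* of
the two rows of $H$, not on the rows individually. The parametric families
pin the curves in principle, but the input's slow tail and a tissue curve
are similar enough that a family member with a depressed tail plus a
tissue component that absorbs the difference fits almost equally well.
Under noise this flat valley is real and, if ignored, the later scaling
step can fail catastrophically (the fitted "tissue" row leans toward the
arterial tail and the mixing-fraction regression changes sign). Three
choices stabilize the problem; all are package defaults and all are
overridable:

1. **Inverse-variance frame weighting.** Reconstructed PET noise variance
   scales inversely with frame duration. Weighting the residual columns by
   $\sqrt{d_j}$ is the statistically efficient norm and, in practice, pins
   the late tail where the long frames carry most information. (Unweighted
   fitting is available via `frame_weighting = "none"`.)
2. **Levenberg–Marquardt on the full residual with variable projection.**
   The objective is a separable least-squares problem; optimizing the nine
   shape parameters with a bound-constrained Levenberg–Marquardt pass over
   the full residual matrix (weights projected out analytically) converges
   to machine precision on noise-free data where a quasi-Newton scalar
   minimizer stalls in the valley. Amplitudes $A_1$ and $K_1$ are fixed at
   1 during the search: row scales of $H$ are absorbed by $W$, so they are
   structurally unidentifiable and removing them is a pure
   reparameterization. The rate ordering
   $\lambda_1 > \lambda_2 > \lambda_3$ is enforced by optimizing
   $\lambda_2, \lambda_3$ as fractions of the next-faster rate.
3. **Admissibility across multi-starts.** Among converged starts (one
   physiological start with the delay initialized from the first frame
   whose mask-mean activity exceeds 10% of the mask maximum, plus seeded
   Latin-hypercube starts), the package prefers the lowest-residual
   solution whose mixing-fraction scaling (below) has a strictly positive
   solution. Degenerate valley solutions fail this check; they are only
   returned, with a warning, if no start is admissible.

The tissue component is by default modeled as driven by the
metabolite-corrected plasma input (the population model below) rather than
raw whole blood, since the parent compound in plasma is what exchanges
with tissue; `metab = NULL` restores the whole-blood-driven form.

## Restoring physical units

After fitting, both rows of $H$ are normalized to unit sum (the arterial
row's unit sum is the method's stated convention; normalizing the tissue
row too is symmetric bookkeeping, with $W$ rescaled so $WH$ is unchanged).
The normalized curves are dimensionless; units are restored through the
constraint that each voxel's arterial and tissue mixing fractions sum to
one, solved as linear least squares:

$$\hat s = \arg\min_s \sum_i
  (\omega_{i,AIF}\, s_{AIF} + \omega_{i,TISSUE}\, s_{TISSUE} - 1)^2 .$$

Taken literally, this product form and the unit-restoring relation
$C_{AIF} = s\, C_{Norm,AIF}$ are mutually inconsistent: with unit-sum
components the argmin of the product form is the *reciprocal* of the
multiplicative scale (if the true frame-sum of the arterial curve is
$S_A$, the argmin is $1/S_A$). Both conventions are implemented
(`convention = "printed"` is the product form and the default,
`"reciprocal"` the quotient form); they have reciprocal argmins and yield
the *identical* restored input function, because `scale_idif()` always
applies the mathematically consistent multiplier (`unit_scale_aif`).
A closed-form solve is used (the problem is linear); an iterative
optimizer path is retained and tested for parity. Non-positive solutions
are warned about (or abort in strict mode); an optional plausibility range
can clip them.

## Metabolite correction

The IDIF is whole-blood activity and cannot separate labeled metabolites
from parent tracer, so a population correction converts it to
metabolite-corrected plasma concentration:

$$C_{plasma}(t) = C_{AIF}(t)\,\bigl(1 - a\,(1 - e^{-b t})\bigr),
\qquad a = 0.29,\; b = 0.03\ \mathrm{min}^{-1},$$

with $t$ in minutes. The packaged defaults are the population constants;
`fit_composite_fraction()` re-estimates them from user blood tables by
averaging parent-fraction × plasma-to-whole-blood ratios at the 5, 15, 30
and 60 minute draws across subjects and fitting the single-exponential-
with-constant form. The multiplier is 1 at injection and approaches
$1-a$ at late times.

## Quantification

* `logan_vt()` — Logan graphical analysis with a blood input: the slope of
  $\int_0^t C_T/C_T(t)$ on $\int_0^t C_p/C_T(t)$ over frames with
  midpoints at or after $t^\ast = 30$ min estimates the total distribution
  volume $V_T$. Integrals are trapezoidal with a leading triangle from
  $(0,0)$; the input integral uses the fine IDIF grid.
* `logan_ref()` — the same construction against a reference-region TAC
  (cerebellum), without an efflux correction term; the slope approximates
  the distribution-volume ratio.
* `compute_suv()` — duration-weighted mean activity over the 40–60 min
  window divided by injected dose per body weight (density 1 g/mL).
* `percent_error()` and `compare_groups()` (pooled-variance two-sample
  t-test, Welch optional) implement the comparison statistics.

A caveat the tests make explicit: Logan regression is asymptotic. On a
60-minute acquisition with slow kinetics ($k_4 \approx 0.03$–$0.04$
min⁻¹) the 30–60 min window underestimates $V_T$ by roughly 5–7%
(equilibration/truncation bias). The package's oracle checks against the
closed form $V_T = (K_1/k_2)(1+k_3/k_4)$ therefore use a dense 300-minute
noise-free acquisition, where the slope converges to the closed form
within 2–3%. On 60-minute data the bias is shared by the arterial and
image-derived inputs and largely cancels from their percent differences.

## The synthetic phantom

The generator emulates a 60-minute dynamic brain acquisition on a
48×48×40 grid (2×2×2.78 mm voxels):

* **Schedules.** 12×10 s, 9×20 s, 5×60 s and 10×300 s frames (36 frames,
  60 min); blood draws every 6 s to 1 min, every 10 s to 2 min, per
  minute to 5 min, then every 5 min (30 samples).
* **Geometry.** Two carotid-like tubes in the 20 inferior slices; the
  cerebellum block just above them (so the segmentation's slice-range rule
  is exercised); eight further labeled regions in two superior layers.
* **Partial-volume mixing.** The arterial fraction $\alpha$ falls off as a
  radial Gaussian ($\sigma$ = 2.5 mm, peak 0.95, support 6 mm) around each
  tube axis — the mixture model holds *exactly*, which is what makes
  ground-truth recovery checks sharp.
* **Kinetics.** The input is a fast-peak/two-tail parameter set with
  amplitudes scaled to a ~185 MBq human injection (peak ≈ 20 kBq/mL
  whole blood). The nine regional 2TC parameter sets are tuned so
  closed-form $V_T$ matches representative high-affinity-binder values
  (1.9–3.5 mL/cm³); the mixed-affinity preset divides them by 1.35,
  giving the built-in ≈35% class separation. Both presets share the same
  input function. Tissue curves are driven by the metabolite-corrected
  plasma input, so closed-form $V_T$ is exactly the quantity Logan
  estimates with a plasma input.
* **Noise.** Seeded Gaussian noise with variance proportional to
  value/duration, scaled so the coefficient of variation at the image
  peak equals `noise_cv` (default 0.05).
* **Blood tables.** Whole blood is the input model evaluated exactly at
  draw times; parent fraction and plasma ratio are plausible decreasing
  factors whose product is exactly the composite model, so the metabolite
  fit can be validated as an inverse crime.
* **Cohorts.** `sample_cohort()` draws per-subject lognormal factors on
  all regional $K_1$ (σ = 0.08) and on the input amplitudes (σ = 0.10).
  Measured cohort differences therefore fluctuate several points around
  the built-in 35%.

What passing on this phantom does **not** show: robustness to motion,
scatter, reconstruction point-spread correlations, attenuation errors,
vein/artery cross-talk, or deviations of real input shapes from the
parametric family. The phantom's mixture model is the method's own
assumption made literal; real data violate it in all the above ways.

## Numerical choices

* Model curves are evaluated analytically: the input (and its
  metabolite-corrected variant) is a sum of $(p_0 + p_1 t)e^{-\lambda t}$
  terms, and its convolution with the 2TC impulse response is computed in
  closed form with cancellation-safe combined exponentials and series
  fallbacks for near-equal rates. A numerical fine-grid convolution
  serves as the independent oracle in the tests. The repeated-eigenrate
  case ($|B_2 - B_1| \le 10^{-9}$) uses the analytic limit.
* Frame averages use per-frame trapezoid rules (9 nodes per frame by
  default; the generator and the fit share the rule, so noise-free
  self-consistency is exact).
* Internal time unit: minutes; interfaces accept seconds (schedules,
  TACs, blood tables).
* Optimizer: bound-constrained Levenberg–Marquardt, up to 200 iterations
  per start, 8 starts by default (3 in cohort batch runs, where the
  physiological start dominates anyway); deterministic given the seed.
* Seed-argmax ties in the segmentation break to the lowest linear index;
  the midline column belongs to the left half.
* Degenerate inputs error early with specific messages (empty regions,
  rank-1 weight matrices, irreversible $V_T$, insufficient Logan frames).

## Problem sizes used by the test-suite and acceptance script

Single-phantom recovery runs on the default 48×48×40 phantom at 5% peak
noise (≈550 carotid voxels); cohort separation uses 8 subjects per arm
with 3 factorization starts each; the replicate-mean noise check uses 12
phantom replicates; oracle comparisons use dense 300-minute noise-free
acquisitions. These sizes keep the full validation desk-scale while
leaving every statistical conclusion comfortably powered (the cohort
t-test detects the built-in separation at $p < 10^{-4}$).

## Known limitations

* The population metabolite correction ignores between-subject metabolism
  differences; per-subject correction requires blood data the method is
  designed to avoid.
* The single-tissue-type assumption around the carotids is an
  approximation; violations become model mismatch in the factorization.
* The scaling step inherits noise from the voxel weights; its error enters
  $V_T$ multiplicatively and is the dominant per-run error source (a few
  percent at the default noise level).
* Logan estimates carry the usual noise-dependent and truncation biases;
  the package reports slopes as-is.
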