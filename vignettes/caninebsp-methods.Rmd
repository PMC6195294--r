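---
title: "Measuring and modelling body segment parameters of the German Shepherd dog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling body segment parameters of the German Shepherd dog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caninebsp)
```

## The problem

Inverse-dynamics analysis of quadruped gait — computing joint forces and
moments from motion capture — needs per-segment inertial parameters: mass,
centre of mass (CoM) location, and the full inertia tensor. For the German
Shepherd, the working dog most widely deployed in police and military
service, `caninebsp` packages a complete 17-segment body-segment-parameter
(BSP) set measured by cadaver segmentation on a cohort of six adult male
service dogs (mean body mass 36.8 kg, range 34.29–39.41 kg), together with
the computational machinery of the measurement itself, 44 regression
equations that predict BSPs from external morphometrics, a whole-dog model
builder, and a synthetic-data generator that lets every step of the pipeline
be validated against known ground truth.

The 17 segments are five axial (head, neck, thorax, abdomen, tail) and six
paired limb segments (brachium, antebrachium, manus; thigh, crus, pes).
Reference values pool left and right sides.

## The measurement model

### Compound-pendulum moments of inertia

Each frozen segment is fixed in a close-fitting rigid box and swung as a
compound pendulum about a horizontal pivot. In the small-angle regime the
period obeys $T = 2\pi\sqrt{I_{\mathrm{pivot}}/(mgl)}$, where $l$ is the
pivot-to-CoM distance; inverting gives `pivot_moi()`:
$$I_{\mathrm{pivot}} = \frac{m\,g\,l\,T^2}{4\pi^2}.$$

The box swings twice per axis — with and without the segment — and the
segment's CoM moment follows by subtraction and the parallel-axis theorem
(`segment_com_moi()`):
$$I_{\mathrm{CoM}} = \frac{m_c g l_c T_c^2 - m_b g l_b T_b^2}{4\pi^2}
 - m_s l_s^2,$$
with subscripts $c$, $b$, $s$ for composite, empty box and segment. Moments
are measured about six box axes: the orthogonal xx, yy, zz triad (yy is the
flexion/extension axis for every segment) and three coplanar skew axes xy,
xz, yz. With the skew axis at angle $\theta$ from the second axis of its
pair, the product of inertia is recovered by `product_moi()`:
$$P_{ab} = \frac{I_{bb} + I_{aa}\tan^2\theta - (1+\tan^2\theta)\,I^*}
{2\tan\theta}.$$

We store products in the integral convention $P_{ab} = \int ab\,dm$, with
tensor off-diagonals $-P_{ab}$. Under that convention the formula above is
the *exact* algebraic inverse of the quadratic form
$I^* = u^\top M u$ for $u = \sin\theta\,\hat a + \cos\theta\,\hat b$:
substituting $I^* = I_{aa}\sin^2\theta + I_{bb}\cos^2\theta -
2P_{ab}\sin\theta\cos\theta$ collapses the numerator to
$2P_{ab}\tan\theta$ identically. The identity holds for all
$\theta \in (0, \pi/2)$ and is property-tested over random physical tensors;
$\theta$ defaults to 45°, where conditioning is best. (The bracket is
sometimes typeset ambiguously in print as "l + tan2θ"; only
$1+\tan^2\theta$ makes the inversion exact, which is the reading
implemented.)

Two further measurement operations complete the protocol: `com_from_balance()`
recovers the segment CoM from knife-edge balance points by moment balance,
and `average_masses()` takes the mean of the three repeated mass
measurements used to monitor sublimation loss, warning when the spread
exceeds a threshold (default 5%).

A negative extracted moment is physically impossible but can arise from
measurement error in the subtraction; the package returns it with a warning
rather than clamping, because the packaged measured data themselves contain
physically impossible values (see *Data quirks*), and fidelity to the
measurement is preferred over cleanliness.

### Period estimation

The period of each trace is estimated by zero crossings with linear
interpolation between samples, preceded by a light centred moving average
(window ≈ one eighth of the dominant period, found from the periodogram;
a symmetric window preserves the zero-crossing phase of a sinusoid exactly),
and finished by least-squares regression of crossing time on crossing index.
The regression matters: the segment-MoI subtraction cancels pivot terms
$m l^2$ that are orders of magnitude larger than small-segment moments, so
period errors are amplified by roughly $m_c g l\,T/(2\pi^2)$ in absolute
terms. Regressing over all ~80 crossings of a 40-cycle trace reduces the
period error by a factor of about $\sqrt{n}/2$ relative to using the first
and last crossing alone, which is what makes 5%-noise traces invertible to
a few-percent tensor error. Traces with fewer than three full cycles raise
an insufficient-data error.

### Study conditions assumed by the simulator

The defaults of `generate_pendulum_session()` are fixed once as the
package's study conditions: pendulum length $l = 0.3$ m, 40 cycles per
trace, three trials per axis (averaged), 100 Hz capture, 8° amplitude,
$g = 9.81\ \mathrm{m/s^2}$ (overridable). Short pendulums keep the
$m l^2$ cancellation manageable; 8° stays in the small-angle regime
(amplitude error in $T$ below 0.1%, and the simulator is simple harmonic by
construction). The segment is saddled so its CoM coincides with the box
centroid — standard centring practice that keeps the hanging box in
equilibrium for every axis orientation and makes the slant-distance
parallel-axis correction exact.

## Rigid-body inertia arithmetic

`solid_inertia()` provides closed-form mass, CoM and diagonal tensors for
the five candidate segment geometries — cylinder, rectangular pyramid, cone,
conical frustum, ellipsoid — as homogeneous solids (uniform density is the
standing assumption of the cadaveric method). The frustum forms are exact
polynomial slice integrals; the pyramid transverse moment about its CoM is
$m(b^2/20 + 3h^2/80)$.

`numeric_inertia()` is an independent deterministic oracle: a midpoint-rule
voxel quadrature on a regular grid (default 200 cells per axis) over the
solid's bounding box, implemented as exact per-slice membership sums so it
is fast and seed-free. Because the grid scales with the solid, its relative
error is essentially a function of resolution only (about 0.08% at 200 for
the worst component across all five shapes); the oracle-agreement tolerance
used in tests is 1% at resolution 200, a comfortable bound on the
discretization error. `parallel_axis()` and `moi_about_axis()` complete the
arithmetic; both are tested against algebraic round trips and trace
invariance over orthonormal triads.

## The packaged reference set

Two transcribed tables ship in `inst/extdata` (rebuilt by
`data-raw/build_reference_tables.R`): normalised segment masses, CoM ratios
from both endpoints, densities and volumes with SDs; and the measured
moments and products of inertia with the per-segment map from box axes to
anatomical axes (internal/external, abduction/adduction,
flexion/extension).

**Units.** The inertia table's magnitudes are stored as $10^{-4}$ kg m²; a
manus moment of order $10^{-3}$ kg m² is the physically coherent scale for a
0.26 kg paw, and it is the scale the regression equations reproduce when
evaluated at cohort-mean inputs. Every accessor (`ref_segment()`,
`ref_tensor()`) returns SI kg m²; the stored scale is an implementation
detail of the data file.

**Reference lengths.** Segment lengths are not part of the measured table
but are needed for scaling. `equivalent_cylinder_length()` recovers one per
segment from mass, volume and the mean transverse moment by eliminating the
radius of an equivalent homogeneous cylinder, leaving
$L^3 - (12 I_t/m)L + 3V/\pi = 0$ and taking the largest positive root. The
derived lengths (21 cm manus to 47 cm tail) are anatomically plausible and
ship in the data file; a test asserts the shipped values match the
derivation.

**Scaling.** `scale_to_dog()` applies the standard normalisation in
reverse: mass scales with body mass, the CoM sits at the proximal ratio
times segment length, and tensors scale as body mass times length squared
relative to the reference length. Lateral and dorso-ventral CoM offsets are
not reported in the source tables, so the CoM is placed on the
proximal–distal axis and the output carries an approximation flag. Body
masses outside 34.29–39.41 kg warn (extrapolation), mirroring the cautious
transfer advice to breeds of similar stature.

### Data quirks, reported not repaired

Measured data are kept as measured:

* The tail tensor violates the perpendicular-axis-type inequality
  ($8.21 + 48.50 < 60.70$ in table units) — its enormous product SDs point
  to the difficulty of swinging a light, floppy appendage. The validator
  `triangle_check()` reports the violation; it never raises.
* The head's printed volume (1000 cm³) is irreconcilable with its mass
  fraction and density (which imply ≈2820 cm³); its printed volume SD
  duplicates the density SD, suggesting a typesetting slip. The value is
  transcribed as printed and the consistency audit documents the
  discrepancy. The synthetic generator uses self-consistent volumes
  (mass/density) throughout, so it is unaffected.
* A handful of regression coefficients have anomalous typography
  (double-zero prefixes, one implausibly large intercept). They are
  transcribed as printed and flagged in the `note` column of the
  transcription file, since no independent information can repair them.

## The regression stage

`bsp_equations()` loads the 44 transcribed equations — 11 segment masses and
33 moments — each of the form
$$y = \beta_a a + \beta_g\,[a]\,g(\text{dims}) + \beta_0,$$
where $a$ is whole-body mass, $g$ a geometric-solid regressor and the
bracketed $a$ present in all MoI equations. The regressor kinds encode the
candidate geometries: cylinder/frustum/box volumes for masses;
transverse-cylinder forms $0.076c^2+b^2$ and $(c/\pi)^2+b^2$ (both are the
cylinder identity $3r^2+L^2$ expressed through a circumference,
$0.076 \approx 3/4\pi^2$), the axial frustum form $(c^5-d^5)/(c^3-d^3)$
(continuous at $c=d$ with limit $\tfrac53 c^2$), squared dimensions and
ellipsoid sums for moments. Ambiguously grouped printed terms are parsed so
that every regressor is dimensionally homogeneous (m²), which is what the
$3/4\pi^2$ identity forces; the parse is recorded equation-by-equation in
the transcription file.

`evaluate_equation()` and `predict_bsp()` evaluate the printed equations
literally, flagging extrapolated body masses and non-physical (≤ 0)
predictions without suppressing them. `fit_bsp()` refits the same model
family by ordinary least squares (`lm`), `select_shape()` ranks candidate
geometry terms by $R^2$ (ties: fewer parameters, then lexical), and
`repeatability_filter()` implements the paired *t*-test pre-filter from
first principles (cross-checked against `t.test()` in the suite).

Candidate sets for shape selection should be geometrically distinct
hypotheses — e.g. for a trunk segment: frustum over both girths, cylinder
anchored at either girth, ellipsoid-sum. Near-collinear parameterisations
of the *same* hypothesis (box volume evaluated on two circumferences versus
the frustum term, or the two transverse-cylinder conventions) are not
distinguishable at $n = 12$ and are not meaningful competitors; the
historical comparison was between shapes, not circumference conventions.

## The synthetic cohort

`generate_dog()` draws a virtual dog as 11 homogeneous solids (cylinders
for manus, a cone for the tail, frusta for the tapering segments, an
ellipsoid head, a pyramidal pes), with dimensions scattering log-normally
(cv 5% by default — the packaged SDs describe derived BSPs, not raw
dimensions, so a measurement-style cv is the remaining free choice) and
densities scattering with the cv implied by the packaged density SDs.
Densities are then rescaled by a common factor so segment masses (limbs
twice) sum *exactly* to the drawn body mass. Each segment is tilted by a
small random rotation (5–15°) inside its box so box-frame products of
inertia are non-zero and the skew-axis machinery is genuinely exercised.
A single global seed fans out to fixed per-segment substreams
(`derive_seed()`), so adding a segment never perturbs another's draws; all
generators are pure functions of (spec, seed).

**Landmark calibration.** Baseline morphometrics are not literal equivalent-
solid circumferences everywhere: real measurement landmarks (an axilla
circumference, a carpal-joint girth) do not coincide with the girth of the
volume-equivalent solid, and the printed mass equations are numerically
inconsistent with literal $2\pi r$ values for several segments. The
baselines therefore solve each printed mass equation exactly at the cohort
mean, and each morphometric key tracks one generating solid dimension
through a fixed landmark ratio (ratio 1 where the identity holds — for the
thorax the printed frustum-volume mass term matches the packaged volume to
0.1%). Consequences: the virtual cohort is jointly consistent with the
packaged masses, densities and volumes *and* sits inside the calibration
domain of the printed equations, so predicted segment masses sum close to
the generating body mass (within a few percent; the suite asserts 15%).

**What the generator does not emulate.** Real dogs are not unions of five
ideal solids; densities are not uniform within a segment; left–right
asymmetry, posture effects of freezing, soft-tissue motion and dissection
error are absent. Passing recovery tests therefore demonstrates that the
*computational pipeline* is correct and well-conditioned under the stated
noise model — not that the original measurements were error-free.

## The whole-dog model

`build_dog_model()` assembles the 17 segments from the reference tables (or
any user-supplied BSP set), mirrors pooled limb values to both sides,
applies the right-brachium frame reversal (a y-axis reversal negates
$P_{xy}$ and $P_{yz}$, leaves diagonals and $P_{xz}$ unchanged — unit-tested
against the $R\,M\,R$ conjugation from first principles), and audits mass
closure (the packaged table closes to 0.9998, the residual being dissection
cut waste of 0.49% of body mass). `export_dog_model()` /
`import_dog_model()` serialise to JSON or YAML with embedded units and a
schema version; round trips are lossless and imports reject models without
exactly 17 segments. Joint centres and posture are deliberately *not*
modelled: frozen-posture inertial properties are only valid for the
measured pose, so the export is a parameter file for a downstream
inverse-dynamics chain, with the frame origin at the proximal endpoint and
`parallel_axis()` available for conversions.

## Problem sizes and numerical choices

The validation suite uses: 100 random solids per shape at voxel resolution
200 for oracle agreement (1% tolerance); full six-axis sessions for all 11
segment types, noise-free (1% tolerance on the tensor Frobenius error) and
at 5% trace noise over 20 seeds (median below 5%); 1000 random
(tensor, θ) cases for exactness of the product-of-inertia inversion
(10⁻¹⁰ relative); and 50 cohorts of n = 12 for coefficient recovery and
shape selection. The Frobenius metric is used for whole-tensor recovery
because per-component relative error is ill-defined for the near-zero
products of nearly axisymmetric segments. The 2-SE coefficient check has an
expected per-coefficient coverage of 92.3% ($t$, df = 9), so the pooled
acceptance threshold is set a priori at 85%, three binomial standard
deviations below that expectation. Ill-conditioned skew angles
(θ within ~0.06° of 0 or 90°) raise errors rather than returning garbage;
degenerate frustum radii take the analytic limit.

## A worked pass through the pipeline

```{r pipeline}
dog <- generate_dog(seed = 42)
dog$body_mass

sess <- generate_pendulum_session(dog, "thigh", noise = 0.05, seed = 7)
rec <- invert_pendulum_session(sess, theta = sess$theta)
rec$tensor
sess$truth$tensor

pred <- predict_bsp(dog$morphometrics$body_mass_kg, dog$morphometrics$dims)
head(pred[pred$quantity == "mass", c("segment", "value")])

model <- build_dog_model("reference", body_mass = dog$body_mass)
model$audit$mass_closure
```

## Known limitations

The reference set derives from six male dogs of one breed and occupation:
transfer beyond similar-stature breeds is extrapolation and is flagged as
such. Pooled SDs mix inter-dog and inter-side variance, which the source
data do not decompose. The thigh dimension "b" is ambiguously defined in
the source and marked in the dimension dictionary. The scaling model
(mass × length²) is the standard convention, not a fitted allometry. The
package stops at the parameter file: kinematics, joint centres and inverse
dynamics are downstream concerns.
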