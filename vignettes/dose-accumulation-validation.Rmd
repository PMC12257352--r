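---
title: "Validating deformable dose accumulation against a known ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating deformable dose accumulation against a known ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosewarpqa)
```

## The problem

In online adaptive radiotherapy (OART) every treatment session is delivered
on that day's anatomy, so there is no single planning dose that can stand in
for the delivered dose. Clinical systems therefore *accumulate* dose: a
deformable image registration (DIR) links each day's treatment image to the
planning CT, and the fraction dose is pulled back along that registration
(direct dose mapping, DDM) and summed on the planning anatomy. If the DIR is
wrong, the accumulated dose is wrong — and there is normally no ground truth
to check it against, because the true anatomical deformation of a patient is
unknowable.

`dosewarpqa` implements the validation strategy in which the ground truth is
*manufactured*: a known, invertible deformation field is applied to a
planning CT to synthesize the "treatment" image, so the registration that a
dose-accumulation system estimates can be compared against the exact field
that generated the data. The fraction dose is accumulated twice — once
through the inverse of the applied (true) field, once through the
registration under test — and the two accumulated doses are compared with
the field's standard QA instruments: 3-D gamma analysis, DVH clinical-goal
adherence, per-structure displacement statistics, and Dice/Hausdorff contour
overlap.

The pipeline for one simulated fraction is:

1. build the pelvic phantom: planning CT, structure set, prescription;
2. author the true pull-back field $u$ (`mod_to_plan`):
   $CT_{mod}(x) = CT_{plan}(x + u(x))$;
3. synthesize the treatment image and day-of-treatment structures;
4. compute the *scheduled-plan* fraction dose on the deformed anatomy
   (planning beam geometry frozen in room coordinates);
5. invert $u$ numerically to get $\varphi_{true}$ (`plan_to_mod`) and
   accumulate $D_{true}(y) = D_{fx}(y + \varphi_{true}(y))$;
6. estimate $\varphi_{est}$ with the registration under test and accumulate
   $D_{est}$ the same way;
7. compare $D_{true}$ (reference) with $D_{est}$ (evaluated).

A perfect registration must reproduce $D_{true}$ exactly (up to the
inversion tolerance); the package ships a perfect-registration oracle
(`register_with_oracle()`) as the control arm that verifies this end to end.

## The synthetic phantom

`build_phantom()` generates a male- or female-pelvis-like anatomy on a
128 × 128 × 64 grid at 2 × 2 × 2.5 mm (about the CT slice spacing of pelvic
protocols), centered on the target organ the way cone-beam treatment images
are centered on the isocenter. Structures are analytic solids: an elliptical
body cylinder (115 × 90 mm semi-axes, 35 HU), a fluid-filled bladder (0 HU),
a gas-cored rectum tube (40 HU wall, −750 HU lumen), the target organ
(prostate sphere or uterus ellipsoid, 45 HU), bony femoral heads (700 HU),
and for the female site a bowel compartment. CTV equals the target organ and
PTV is the CTV expanded isotropically (7 mm default) via a Euclidean
distance transform, clipped to the body.

Two deliberate departures from a piecewise-constant phantom matter for
registration realism:

* **Intensity texture.** A seeded Gaussian random field (20 HU SD, 6 mm
  correlation length) is added inside the body. Soft tissue in real CT is
  not homogeneous, and an intensity-driven DIR needs gradients away from
  organ boundaries to recover deformations there. The correlation length is
  deliberately about three voxels: much rougher texture cannot be
  resampled by trilinear interpolation without itself injecting more
  image difference than the deformations under study.
* **Plan-like dose, not transport.** `synth_fraction_dose()` is analytic:
  a prescription plateau over the PTV (at 101.5% of the fraction
  prescription — real plans slightly overcover, so coverage goals such as
  D95% > 100% hold with margin on the planned dose), a Gaussian penumbra
  (σ = 4 mm default; the falloff of the emulated delivery system is not
  publicly characterized, so this is a free parameter), and an
  entrance-fluence term from either nine discrete gantry angles (`imrt9`,
  visible beam-edge steps near the surface) or a 72-angle sweep (`vmat`,
  no discrete edges), attenuated along closed-form ray depths through the
  analytic body ellipse. What the accumulation analysis needs is a dose
  with realistic gradients in realistic places, which is what drives
  accumulation error; absolute dosimetric accuracy is irrelevant here.
  For deformed fractions the beam geometry stays frozen in room
  coordinates and only the body mask follows the anatomy — the
  scheduled-plan situation, avoiding the confound of re-optimization.

Prescriptions are 60 Gy in 20 fractions (prostate-style) and 45 Gy in 25
fractions (cervix-style), with eviQ-style clinical goal sets shipped as JSON
(22 goals for the prostate site; the cervix set is adapted to the phantom's
structures).

## Authoring ground-truth deformations

`author_field()` builds the pull-back field directly in the `mod_to_plan`
direction, so image synthesis needs no inversion and the accumulation truth
is obtained by inverting the exact field that generated the image.
Deformations are radial displacement profiles about the organ (per-slice
centerline for the tubular rectum): a smoothstep ramp from zero at the
center to the target magnitude $M$ at the anchor radius, with Gaussian decay
(length `decay_mm`) beyond. Expansions pull samples inward; shrinks pull
them outward. The map $x \mapsto x + u(x)$ is provably monotone along rays
for any shipped magnitude, and `verify_invertibility()` screens the full
Jacobian determinant at every voxel (accept above 0.05).

Numerical choices worth knowing:

* **Smooth tapers, never hard cuts.** Displacement is exactly zero outside
  the body, inside femoral heads, and at the image faces, but it *tapers*
  to those zeros (magnitude capped at 0.6 × distance-to-frozen-region,
  with a one-voxel dead shell at the skin). A hard cut next to a multi-mm
  displacement is non-invertible, makes fixed-point inversion oscillate,
  and lets warps alias air into the body through partial-volume skin
  voxels. The practical consequence: very large requested magnitudes are
  attained where the anatomy has room, and attenuated toward the skin —
  the 30 mm bladder expansion peaks near 26 mm on the default phantom.
* **Decay defaults.** Shrink fields decay with σ = max(8, 0.8 M) mm — the
  outward-decaying shrink profile is only invertible when the falloff is
  gentle (slope < 1 requires σ > 0.61 M). Expansions are invertible for
  any falloff and default to the tighter σ = max(8, 0.4 M) mm, which keeps
  a large bladder change from unrealistically dragging the whole pelvis.
* **Magnitude classes.** Peak displacement below 5 mm is *small*, 5–10 mm
  *medium*, above 10 mm *large* (boundaries inclusive into medium).
  Scenario presets place magnitudes mid-class (7.5 / 15 mm, 30 mm for the
  prostate bladder large-expansion; the cervix rectum large-shrink uses
  11 mm, the largest the 14 mm lumen admits).
* **Composition.** Multi-organ scenarios compose maps (bladder first, then
  rectum — an arbitrary but fixed order), not add fields; addition does
  not commute with invertibility.

## Inversion

`invert_field()` solves $v(x) = -u(x + v(x))$ by damped fixed-point
iteration, $v \leftarrow v + \alpha(-u(x+v) - v)$, stopping when the largest
update falls below 0.05 mm (50 iterations cap). The damping
$\alpha = \min(1, 1.8/(1+L))$ is set from a row-norm bound $L$ on the
displacement Jacobian: the classical $\alpha = 1$ iteration is only a
contraction for $L < 1$, and shrink fields violate that. The composition
residual $\max|u(x + v(x)) + v(x)|$ over the body is reported on the result;
every shipped scenario stays below 0.05 mm at study resolution, and the
pipeline refuses to continue above 0.25 mm.

## The registration under test

The system under test is pluggable: anything that maps a fixed/moving image
pair to a `plan_to_mod` field satisfies the interface (the `dosewarp-qa`
script exposes the file-level equivalent). The shipped reference
implementation, `estimate_field()`, is a multi-resolution, Gaussian-
regularized demons registration — mono-modal intensity forces are
appropriate here because the phantom pairs share one intensity scale; the
commercial systems' mutual-information and structure-guidance machinery is
deliberately out of scope, since the framework's job is to *evaluate*
registrations, not to reproduce any particular one. The estimate is exported
on a grid coarsened 4× relative to the CT, as clinical systems do, and is
suppressed in the partial-volume shell at the patient surface and toward the
image faces, where images carry no deformation signal.

`degrade_factor` blends the estimate toward a smooth seeded noise field
(RMS 3 mm): 0 is the best estimate, 1 is noise. This knob exists so the
pipeline can demonstrate *discrimination* — an accurate and an inaccurate
DIR must produce measurably different gamma pass rates on the same scenario,
which is the property that makes the framework useful as QA.

Known limitation: the gas-filled rectum is where the unguided demons
struggles. Its ±790 HU interface saturates the demons force (which scales
like $\nabla I / \Delta I$ where the intensity difference is large and the
gradient support narrow), and the organ interior carries little texture, so
displaced gas interfaces are recovered only partially. Bladder-driven
scenarios reduce the body mean-squared HU difference by well over 50%
(90%+ for medium changes); rectum- and uterus-driven scenarios improve the
*field* error substantially (and the extreme 30 mm bladder expansion, which
shoves the rectum by over 20 mm, cuts mean field error by ~80%) but leave
most of the image difference at the gas interface in place. This is a
faithful rendition of the practical experience that thin high-contrast
structures and large anatomical change are precisely where DIR — and
therefore dose accumulation — should be distrusted, and it is what the
structure-guidance machinery of clinical systems exists to fix. Evaluating
such a system through the plug-in interface is the intended use.

## Measuring accumulation error

**Gamma analysis** (`gamma_index()`): for every reference voxel at or above
10% of the reference global maximum, the minimum over candidate points $p$
of $\sqrt{|p-r|^2/\Delta d^2 + (D_{eval}(p)-D_{ref}(r))^2/\Delta D^2}$, with
the dose criterion a percentage of the reference global maximum (global
normalization), candidates on a sub-voxel lattice (pitch = distance
criterion / 10, radius 2 × distance criterion) and trilinear evaluation.
The reference is always the truth-accumulated dose, so the denominator of
"percent of points passing" is defined by the ground truth. The production
search sorts candidates by distance and exits early; an exhaustive
full-scan twin (`brute_force = TRUE`) exists purely as a test oracle and
agrees to well under 0.2 percentage points. Criteria default to 1%/1 mm,
3%/2 mm and 5%/3 mm.

**DVH goals** (`eval_goal()` and friends): D-metrics interpolate partial
voxels on the sorted dose-volume curve (so 0.03 cc metrics are
grid-independent), V-metrics count voxels. All goal evaluation happens after
scaling to the prescribed fractionation (a single fraction stands for the
course, multiplied by the fraction count; a summed course of $F$ simulated
fractions is rescaled by $n_{fx}/F$). Goal inequalities are strict — ties
fail — and allowed-variation thresholds are tracked separately. The
discrepancy statistic counts goals whose met/not-met status differs between
the system-accumulated and truth-accumulated dose, reported as an
integer-rounded percentage of goals × fractions; pass/fail for this count
uses the primary threshold, with the variation-based variant available by
passing the `within_variation` flags instead.

**Contour and field statistics**: per-structure maximum/mean displacement
magnitude (range of motion, evaluated over the planning structure set),
voxel-wise field error against the truth (which per-structure maxima cannot
capture — two fields can share a maximum and still disagree everywhere),
Dice overlap, and Hausdorff distance computed as the maximum symmetric
surface distance on erosion-extracted surfaces with anisotropic distance
transforms (a 95th-percentile variant is available; unqualified "HD"
conventionally means the maximum).

## What passing tests do and do not show

The phantom is analytic and its deformations are radial organ-centric
fields. Real pelvic anatomy deforms with sliding interfaces, bowel gas
appearing and disappearing, CBCT artifacts, and contouring variability —
none of which the generator emulates. Passing the control arm shows the
*accumulation machinery* is self-consistent; the degradation test shows the
*metrics discriminate* good from bad registration. Neither says a particular
clinical system is accurate — that requires this framework applied to that
system's own fields, which is the intended use of the plug-in interface.

Problem sizes were chosen to keep a full validation course interactive on a
single core: the study-resolution grid is ~1M voxels, a nine-fraction
oracle course runs in about 90 s, and unit tests use a coarse 64 × 64 × 32
grid over the same physical anatomy.

## A worked run

```{r course, eval = FALSE}
library(dosewarpqa)

report <- run_course(scenario_presets("prostate_like"),
                     phantom_config(seed = 3),
                     registration = "oracle")
print(report)
#> <validation_report> prostate_like course, 9 fractions
#>   summed-dose gamma 1%/1 mm: 100.0%
#>   summed-dose gamma 3%/2 mm: 100.0%
#>   summed-dose gamma 5%/3 mm: 100.0%
#> <discrepancy> 22 goals x 9 fractions: 0 passed-in-system-only,
#>   0 passed-in-truth-only -> 0%

emit_report(report, "runs/oracle-course")
```

With the demons stand-in instead of the oracle, the same course produces
sub-100% pass rates that drop further as `degrade_factor` rises — the
framework detecting the bad registration it was fed.
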