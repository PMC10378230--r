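---
title: "Neutral-track cephalometric analysis in 2D and 3D"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neutral-track cephalometric analysis in 2D and 3D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutraltrack)
```

## The model

Enlow's neutral-track analysis evaluates the *rotational factor* of
craniofacial growth: how far a subject's structural planes — the middle
cranial floor (MCF), the pterygo-mandibular plane (PM), the mandibular
ramus (MR) and the functional occlusal plane (FOP) — deviate from an
idealized, "balanced" configuration rebuilt from the subject's own
dimensions. That idealized configuration is the *neutral track*. Its one
normative constant is the cranial-base angle: in the neutral track the
neutral middle cranial floor (MCFn) meets the neutral pterygo-mandibular
plane (PMn) at exactly **40.3°** at the neutral sphenoethmoidal point
(SEn). Everything else follows from the subject's anatomy by ruler-and-
compass rules.

Classically the analysis is traced on a lateral cephalogram (2D). This
package also implements a 3D counterpart operating on named landmark
coordinates picked from CBCT volumes, and a paired-comparison procedure to
check that the two give statistically indistinguishable diagnostic
angles.

### The individual track

In 2D the track is four lines through six landmarks: MCF = SE–Ar,
PM = SE–Ptm, MR = Ar–Go, FOP = Poc–Aoc. In 3D each line becomes a plane
through three points:

* MCF through rMCF, lMCF and Ba,
* PM through lMCF, rMCF and PNS,
* MR through mCo (condylar midpoint) and the two gonions,
* FOP through rPoc, lPoc and mAoc (anterior occlusal midpoint).

The diagnostic angles are MCF^PM (anterior cranial-base angle) and
MCF^MR (posterior, typically obtuse, ramus angle).

### The neutral construction (3D)

1. Estimate the mid-sagittal plane: through Ba, normal along the
   normalized sum of the unit left-to-right vectors of the lMCF–rMCF,
   lCo–rCo and lGo–rGo pairs. This replaces any assumption that the scan
   was acquired in a canonically aligned frame.
2. MCFx = intersection of the rMCF–lMCF chord with the mid-sagittal
   plane; the construction sphere is centred in Ba with radius |Ba–MCFx|.
3. Cut the sphere with the mid-sagittal plane to obtain the sagittal
   circumference; build CPBa, the plane through Ba parallel to PM.
4. SEn is the circumference point whose ray from Ba makes 40.3° with the
   trace of CPBa on the sagittal slice, on the anterior-superior branch
   (the candidate maximizing the dot product with Ba→MCFx).
5. PMn is the plane through SEn parallel to PM; by the
   parallel-lines-cut-by-a-transversal rule, Ba–SEn meets PMn at 40.3°.
6. MCFn is the plane through Ba and two lateral helper points rSEn/lSEn
   flanking SEn.
7. CPCo (through mCo parallel to PMn) and GoP (through both gonions,
   perpendicular to PMn) locate the neutral gonions: each gonion slides
   purely along the PMn normal until it is halfway between PMn and CPCo,
   which keeps it inside GoP ("the same level as Go"). MRn passes through
   mCo and the two neutral gonions.
8. FOPn is the plane through rPoc and lPoc perpendicular to PMn.

The construction carries three self-check identities that hold by
construction on *every* valid input and are asserted continuously by the
test suite: MCFn^PMn = 40.3° (sagittal trace), FOPn^PMn = 90°, PMn^PM = 0°,
plus the gonion equidistance |d(Gon, PMn)| = |d(Gon, CPCo)|.

## Design choices where the construction is genuinely open

**Trace versus dihedral angles.** A 2D cephalogram angle is intrinsically
sagittal, so the default 3D convention (`angle_convention = "trace"`)
cuts both planes with the estimated mid-sagittal section and measures the
angle between the oriented traces; this is the convention under which 2D
and 3D values are directly comparable, which is exactly the package's
validation claim. Orientation hints are anatomical (MCF trace toward Ba
for the anterior angle, toward the cranial end for the posterior one; PM
trace toward PNS; MR trace toward the gonial level), so each measured
angle is the clinically named one rather than its supplement. The
classical inter-normal dihedral angle remains available via
`track_config(angle_convention = "dihedral")`.

**The in-slice 40.3° angle.** The angle to a tilted plane and the angle to
that plane's trace on the sagittal slice differ by a second-order term in
the tilt. For asymmetric subjects CPBa is slightly tilted relative to the
mid-sagittal plane, and only the in-slice (trace) reading keeps
MCFn^PMn = 40.3° exact; the package therefore builds the angle in the
slice, which is also how a protractor on a sagittal view would do it.

**rSEn/lSEn placement** (`mcfn_mode`). The helper points are "arbitrarily
positioned" left and right of SEn, which leaves their rule open.

* `"tangent"` (default): rSEn/lSEn = SEn ± δ along the sagittal normal.
  MCFn then contains the Ba–SEn ray exactly, so the 40.3° identity is
  exact and independent of the arbitrary δ — an arbitrary helper distance
  should not leak into the one normative constant.
* `"on_sphere"`: the helpers stay on the construction sphere, on the
  axial circle through SEn (axial direction taken from the FOP normal,
  oriented superiorly), the literal axial-view reading. The sagittal
  mid-direction of the resulting plane is displaced by r′(1−cos β) with
  β = 2 asin(δ/2r′), giving a trace-angle deviation of order
  δ²/(2 r′ r) · sin∠(u₀, Ba→SEn) — about 0.37° at δ = 5 mm on the
  bundled template, vanishing as δ → 0. The tests pin both the size and
  the monotone decay of this deviation.

δ defaults to 5 mm and is guarded below 0.1 mm.

**Neutral gonion.** "Same level as Go" and "halfway between PMn and CPCo"
are simultaneously satisfiable only if the gonion moves purely along the
PMn normal; any in-plane drift would change its level within GoP. That is
the implemented rule, in 2D and 3D alike.

**2D versus 3D centres.** The 2D neutral circle is centred in Ar
(articulare), the 3D sphere in Ba — articulare is an image-shadow
construct with no 3D counterpart. Both are implemented as written; the
package does not harmonize them, and the paired cohort comparison is
precisely the instrument that quantifies the consequences.

**The neutral constant** is a named configuration value
(`neutral_angle = 40.3`) so sensitivity analyses are possible; every
default and every validation run pins it at 40.3°.

## The synthetic-data generator

Patient CBCT landmark sets are not redistributable, so every stage is
exercised on synthetic subjects built from a fixed, bilaterally
mirror-symmetric template with plausible magnitudes (Ba at the origin,
cranial-floor chord 50 mm wide at (·, 45, 18), sphere radius
√(45² + 18²) ≈ 48.47 mm). Two template choices are deliberate:

* the condylar midpoint lies **on** the Ba–MCFx line, so the emulated 2D
  articulare (Ar = projected mCo) sits on the projected cranial-floor
  trace and the 2D lines are exactly the projections of the 3D traces —
  noise-free subjects then give *identical* 2D and 3D angles, which turns
  method agreement into a machine-precision test rather than a vague
  similarity check;
* all other coordinates are chosen for bilateral symmetry, and validity
  is asserted by the invariant suite, not by anatomical authority.

Per-subject deformations, applied in this order:

| knob | default (cohort draw) | effect |
|---|---|---|
| `cranial_base_offset` | N(0, 3°) | rotates Ba + condyles about the lateral axis through the MCF mid-chord; shifts MCF^PM by exactly its value |
| `ramus_angle_offset` | N(0, 3°) | rotates the gonions about the lateral axis through mCo; shifts MCF^MR by exactly its value |
| `scale` | exp N(0, 0.05) | global size about Ba; all angles invariant |
| `asymmetry` | amplitude U(0, 2) mm | seeded lateral (x-only) shifts; provably leaves every sagittal trace and projection unchanged |
| `noise_sd` | 0.5 mm | isotropic Gaussian landmark noise; the only knob that makes 2D and 3D disagree |

The cranial-base rotation carries the condyles because the
temporomandibular joint rides on the cranial base; this also preserves
the Ba–MCFx–mCo collinearity, so the articulare emulation stays exact
under rotation. The exact-shift properties make the offsets recoverable
ground truth for the rotational factor. The paired 2D set is the exact
mid-sagittal projection (drop x) of the noisy 3D set: SE = proj(MCF
mid-chord), Ar = proj(mCo), Ptm = proj(PNS), Go/Poc = projected
mid-chords, Aoc = proj(mAoc).

What the generator does **not** emulate: real landmark-identification
error structure (which is anisotropic and operator-dependent), occlusal
artifacts, true articulare shadow geometry, or any anatomical covariance
between regions. Passing tests therefore demonstrate the geometric and
statistical machinery, not clinical performance on real CBCT data.

```{r example}
subject <- generate_subject(subject_params(ramus_angle_offset = 4,
                                           noise_sd = 0.5, seed = 7))
report <- analyze_subject(subject$lm3d, subject = "synthetic-07")
report
tidy(report)
```

## The validation procedure

For a cohort (default n = 18, the size of a typical single-centre
validation sample), each subject is measured in 2D and 3D and the paired
table is summarized per angle: mean ± SD for each modality, a
Kolmogorov–Smirnov normality check of each sample, and a two-sided paired
Student's t-test at α = 0.05.

```{r cohort}
cohort <- generate_cohort(n = 18, seed = 42)
comparison <- analyze_cohort(cohort)
tidy(comparison)
```

Because the parameters of the reference normal are estimated from the
sample, the naive one-sample KS p-value is anticonservative; the default
therefore applies the Lilliefors correction with a seeded Monte-Carlo
null (10⁴ replicates) for n ≤ 500 and the Dallal–Wilkinson closed-form
approximation above that, where the Monte-Carlo cost would dominate the
analysis for no accuracy gain. `ks_normality(..., method = "naive")`
gives the uncorrected value for strict literalism. Two-sided p-values
are used throughout, the standard choice for method agreement. The
paired-t type-I error is calibrated by simulation in the test suite
(2000 null replicates at n = 18, SD 4°, rejection rate 0.05 ± 0.015).

## Numerical choices

* Angles between unit vectors use `atan2(|a × b|, a·b)`, accurate near 0°
  and 180° where the parallelism identities live; `acos` of a dot product
  loses ~10⁻⁷ degrees exactly there.
* Geometric degeneracy tolerance 10⁻⁹ (mm or mm²): collinear generators,
  chords parallel to a reference normal, parallel planes asked for a
  trace, zero-radius spheres and tangent planes all raise typed errors.
* Branch selection is by maximal dot product with a landmark-derived hint
  (Ba→MCFx in 3D, Ar→SE in 2D); a tie between materially different
  candidates (score gap < 10⁻⁹ with separation > 10⁻⁶·radius) is a typed
  ambiguity error rather than a silent choice.
* Derived midpoints (mCo, mAoc) are recomputed from their parents on
  every construction; files supplying them are accepted but overridden.
* The mid-sagittal normal's sign is arbitrary (swapped bilateral labels
  can flip it); every downstream quantity is either sign-insensitive or
  re-oriented by hints, and a dedicated test pins this.
* Validation problem sizes: invariance is checked over 100 random rigid
  motions and scalings; construction identities over 100 seeded subjects;
  the SEn placement against a 10⁶-point brute-force circle search
  (agreement within 0.01 mm); the cohort conclusion over ten seeded
  18-subject cohorts.

## Limitations

* The 3D MCF plane uses Ba where the 2D line uses Ar; on real data the
  two angles differ systematically by the offset of the condylar shadow
  from the cranial-floor line, and the package quantifies rather than
  hides this (on synthetic data the generator's articulare rule removes
  it by design).
* The mid-sagittal estimator assumes roughly bilateral anatomy; gross
  hemifacial asymmetry degrades every trace-convention angle.
* No normative database ships with the package: individual-versus-neutral
  deltas (`track_delta()`) are reported, not classified.
* Landmark coordinates are trusted as given; no image processing, no
  landmark detection, no DICOM handling.
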