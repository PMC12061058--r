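---
title: "Quantifying eccentric fixation: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying eccentric fixation: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fixtrack)
```

## The measurement problem

In retinal dystrophies that destroy central photoreceptors, patients
fixate with a non-foveal retinal location — the preferred retinal locus
(PRL). Quantifying *where* that locus sits relative to the anatomic fovea,
and *how stable* it is, requires combining two devices that do not share a
coordinate system: a microperimeter, which tracks gaze on its own scanning
laser ophthalmoscopy (SLO) image, and OCT/autofluorescence imaging, which
shows the anatomy. `fixtrack` implements that combination as a computable
pipeline:

1. **Registration.** Landmark correspondences (vessel bifurcations, optic
   nerve silhouette) between each acquired frame and a common
   autofluorescence (FAF) frame are fit with a least-squares planar
   transform.
2. **Foveal center (FC).** The en-face footprints of the selected
   horizontal and vertical transfoveal OCT scans are registered into the
   common frame; the FC is the intersection of the two infinite lines.
3. **Calibration.** The 200 µm scale bar burned into the FAF export,
   measured in pixels, gives the per-eye ruler (µm/px). In the worked
   example a 23-px bar yields 200/23 ≈ 8.696 µm/px.
4. **Metrics.** The fixation cloud is mapped into the common frame;
   distance from the foveal center (DFC), distance between PRLs (DPRL),
   quadrant, bivariate contour ellipse area (BCEA), P1/P2 and the
   stability class are computed; two-grader repeatability is summarized
   with Pearson correlation and Bland–Altman statistics.

## Models and estimators

**Registration.** The default transform family is the 4-parameter
similarity (isotropic scale $s$, rotation $\theta$, translation $t$),
matching what a rigid manual overlay with zoom can express; an affine fit
is available for modality-specific distortion. The similarity estimate
uses the closed-form linear least-squares solution in the parametrization
$(a, b, t_x, t_y)$ with linear part $\begin{pmatrix}a & -b\\ b &
a\end{pmatrix}$, which is the orthogonal-Procrustes-with-scale optimum
(no reflection) and is exact on noise-free data. We chose a closed form
over iterative optimization for determinism and testability. A fitted
transform records its RMS landmark misfit; `overlay_quality()` gates
registrations at a configurable ceiling (default 2 px, inclusive). The
ceiling is a package choice — no residual criterion accompanies manual
overlays — and should be revisited if landmarks are clicked on low-quality
images.

**Foveal center.** The FC is defined as the crossing of the two *infinite*
lines through the registered scan-line endpoints, not of the segments:
transfoveal B-scans are chords through the fovea, and their crossing is
the natural reading of the manual construction. Lines closer than 5° to
parallel are rejected (the intersection would be numerically meaningless);
crossings outside 60°–120° are kept but flagged unreliable. An
intersection farther than 1.5× the image diagonal from both segments is
rejected when an image size is supplied — without an image there is no
diagonal, so the check is skipped. Which B-scans are "the" transfoveal
scans remains an upstream human judgement (guided by the foveal reflex
when visible); the package consumes the annotation.

**PRL positions.** PRLi is the centroid of samples in the first 10 s of
the exam; PRLf is the centroid of the full exam, read as the cumulative
reference the device reports at test end. The centroid is the arithmetic
mean — the same moment basis as the BCEA — with a coordinate-wise median
available (`center = "median"`) for robustness; "center of the cluster"
admits either reading.

**Distances.** DFC is the Euclidean distance FC→PRLf in common-frame
pixels times the ruler; DPRL likewise for PRLi→PRLf. Both are symmetric
and rigid-invariant (property-tested). The longitudinal change of
fixation position between visits is the distance between the two PRLf
positions — the third side of the triangle they form with the FC — and
reduces to $|DFC_1 - DFC_0|$ when the three points are collinear.

**Quadrant.** Two perpendicular axis-aligned lines through the FC define
the quadrants. On a superior-up raster, smaller y is superior; laterality
decides the nasal/temporal meaning of image left/right (OD: nasal =
image-right, where the optic disc sits; OS mirrored). This mapping is
implicit in clinical practice but is stated here because every
sign convention downstream depends on it. Coordinate ties within $10^{-9}$
px classify as `on_axis` rather than forcing an arbitrary quadrant.

**BCEA.** $\mathrm{BCEA}(P) = \chi^2_2(P)\,\pi\,\sigma_x \sigma_y
\sqrt{1-\rho^2}$, with sample standard deviations and correlation
($n-1$ denominators). Coverage defaults to 0.95
($\chi^2_2(0.95) \approx 5.991$, so a unit isotropic cloud has area
$\approx 18.82\ \mathrm{deg}^2$); 0.63 is selectable since devices differ
and the convention is not universal. Degenerate clouds (zero variance on
an axis or $|\rho| = 1$) return area 0 with a `degenerate` flag instead of
an error: they are legitimate, if extreme, exams.

**P1/P2 and stability.** P1 and P2 are the percentages of samples within
1° and 2° of PRLf, with *inclusive* radii. The stability rule uses strict
inequalities: `stable` iff P1 > 75%, else `relatively_unstable` iff
P2 > 75%, else `unstable`; consequently P1 = P2 = 75 exactly is
`unstable`. The boundary behavior is documented and tested rather than
left to floating-point accident.

**Validity.** An exam is reliable iff its fixation-loss percentage is
≤ 15% (inclusive); this is the only reliability index the microperimeter
provides (no catch trials).

**Agreement.** `grader_agreement()` reports per-grader mean, sample SD and
range, the Pearson correlation, and Bland–Altman bias with 95% limits of
agreement. Differences are taken grader 2 − grader 1, and SDs use the
$n-1$ denominator; both choices are confirmed by recomputing the bundled
nine-eye dataset, whose printed bias (+31.78 µm) and SD (≈55.0 µm) only
arise under exactly these conventions. The LoA multiplier is fixed at
1.96.

## Units and coordinate conventions

* Image coordinates: 0-based pixels, origin top-left, x rightward,
  y downward; sub-pixel positions are real-valued. Positive rotation
  angles turn +x towards +y (clockwise on screen).
* Fixation files store visual degrees relative to the fixation target
  with y positive *upward* (device display convention); the reader flips
  y at load so that all in-memory math shares the raster convention, and
  the writer flips back.
* Degrees → microns uses a configurable constant, default 288 µm/°, the
  emmetropic schematic-eye approximation. The device's internal factor is
  not published, and no axial-length (Littmann/Bennett) individualization
  is attempted — distances therefore carry the usual magnification caveat
  of fundus photogrammetry.
* Mapping gaze degrees into the common frame multiplies by
  (µm/°)/(µm/px) and rotates the degree axes by the rotation of the
  MAIA→common similarity; the fixation target is taken to sit on the
  anatomic FC (the stimulus grid is re-centred on the fovea for eccentric
  fixators). This mapping requires a similarity — with an affine
  registration the degree axes would shear, and the package refuses
  rather than guess.

## The synthetic-data generator

`phantom_spec()`/`make_phantom()` build a procedural "eye": random-walk
vessel trees rendered with a Gaussian profile into one image per modality
(OCT-IR horizontal and vertical scan frames, microperimetry SLO, FAF with
a scale bar), all derived from one common-frame vessel skeleton under
known similarity transforms. Landmark tables are emitted *analytically* —
exact under the true transforms — so the measurement chain is tested
against ground truth without depending on rendered pixel content; the
images exist so a human can repeat the landmark picks. Scan lines are
constructed in their own frames so that their registered intersection is
exactly the true FC.

`fixation_cloud_spec()`/`make_fixation_exam()` draw gaze samples from a
bivariate normal with programmed per-axis spread, correlation, offset
from the FC, and drift. Drift is defined as the *expected PRLi→PRLf
separation*: the mean path is linear in time and rescaled so that the
expectation of PRLf minus the expectation of PRLi equals the drift vector
exactly, making the programmed DPRL directly checkable. The generator
applies the exact inverse of the degree→frame mapping above, so
generation and recovery are mutual inverses by construction.

Default conditions (chosen once, as a realistic severe-dystrophy exam):
2500 samples at 25 Hz (a 100 s test), σ = 1° per axis, ρ = 0, cloud
center 1398 µm supero-temporal of the fovea for OD (the modal eccentric
location in central dystrophies), drift 750 µm, fixation loss 5%, scale
bar 23 px = 200 µm. Validation suites use smaller clouds (400–2000
samples) and 50 randomized phantom specs (scale 0.9–1.2, rotation ±10°,
translation ±30 px, offsets ±1500 µm) — sizes at which all suites
complete in seconds while sampling error stays well below the tolerances
being asserted.

What the generator does **not** emulate: real fixation clouds are
task-dependent and often non-normal (a two-cluster mixture is a known
pattern), microsaccades give temporally correlated samples, image
distortion is not purely similarity, and landmark picks on real images
carry click error. Passing the recovery suites therefore demonstrates
the correctness of the computation chain, not the clinical accuracy of
any single exam.

## Numerical choices and degenerate inputs

* Similarity estimation is linear least squares (QR); no iteration, no
  tie-breaking. Degenerate configurations — fewer than 2 (similarity) or
  3 (affine) pairs, collinear affine sources, zero source spread — raise
  typed errors rather than returning garbage fits.
* `stability_class`, P1/P2 radii and the 15% validity rule pin their
  boundary behavior explicitly (strict / inclusive / inclusive).
* Result records refuse non-finite metrics before serialization; JSON is
  written at full precision (round-trip better than $10^{-9}$ relative).
* Pixel↔micron and degree↔micron conversions reject negative distances;
  the ruler stores the bar ratio exactly so the worked conversions
  (23 px → 200 µm, 115 px → 1000 µm) are exact in floating point.

## Known limitations

* A global µm/° constant and scale-bar calibration ignore individual
  axial length; between-eye comparisons of µm distances inherit that
  approximation.
* Landmark correspondences are supplied, not detected; automated vessel
  matching is out of scope.
* The pipeline quantifies fixation geometry only — retinal sensitivity
  (the threshold grid) is acquisition-side and out of scope.
* Cohort-scale inferences (interocular correlations and the like) are
  supported by `pearson_r()` on per-eye values but no cohort data ship
  with the package.
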