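---
title: "Methods: diagnostic DNA karyometry in karyoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diagnostic DNA karyometry in karyoscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoscan)
```

karyoscan implements the full chain of diagnostic DNA karyometry —
morphometric nuclear classification plus DNA image cytometry restricted to
the morphologically abnormal nuclei — together with a synthetic slide
simulator that makes every stage testable without real specimens. This
vignette records the models, the tunable parameters and their defaults,
the numerical choices, and the places where a genuine design decision had
to be made.

## The imaging model

The simulator treats a Feulgen-stained nucleus as an absorbing object in a
brightfield microscope. Each nucleus carries a per-pixel optical density
(OD) field; pixel transmittance is $T = 10^{-OD}$, and the rendered
intensity is $I = B \cdot T + \varepsilon$, with $B$ the background
illumination (default 220 grey levels, with a ±3% linear shading ramp per
field) and $\varepsilon$ Gaussian camera noise (default SD 1 grey level).
The OD field is smoothed uniform noise (chromatin texture) normalized so
that its sum over the nucleus mask equals the target integrated optical
density (IOD). Because the densitometric unit is fixed at
`iod_per_2c = 100`, Feulgen stoichiometry — IOD proportional to DNA
content — is *exactly* true for the rendered truth: a 3c nucleus
integrates to 150 before measurement noise. A per-nucleus multiplicative
IOD perturbation (`measurement_cv`, default 3%) emulates staining and
measurement variability; 3% matches the precision reported for
televised-image Feulgen densitometry. Requests denser than a mean OD of
1.8 (`od_max`) are rejected as physically unrenderable rather than
silently clipped.

Seven optical planes are rendered per field. A nucleus sharp at plane $z$
appears at plane $j$ blurred by a Gaussian of
$\sigma = 1.5\,|j - z|$ px (`defocus_sigma_per_plane`); no point-spread
model beyond this is attempted. Defocused-class nuclei have $z$ forced
outside the plane set (−2 or 8), so even their best available plane is
visibly blurred. Transmittances of overlapping objects compose
multiplicatively, i.e. optical densities add, which is what makes doublet
lobes read as a single dense object downstream.

## Class appearance assumptions

No per-class morphometric statistics of real nuclei are published for this
pipeline, so the simulator's eight classes are *stated assumptions*,
chosen to be realistic in scale and learnably separable, and all
overridable: normal epithelial nuclei round (radius ≈ 11 px, low boundary
irregularity, fine chromatin, DNA ≈ 2c with 4% CV); abnormal nuclei larger
(≈ 16 px), irregular (0.4–0.8), coarse-chromatic, with DNA drawn from the
slide's stemline mixture; lymphocytes small and dense (≈ 6 px);
granulocytes three-lobed disc unions; doublets two overlapping
normal-type lobes totalling ≈ 4c; lytic nuclei rendered at 30% stain
uptake (their truth c-value stays 2c — degraded stain, not missing DNA);
artefacts elongated, highly irregular, with nearly unsmoothed
high-variance "grain" texture and no DNA semantics. The grain texture is
deliberate: non-nuclear debris does not exhibit chromatin-like spatial
correlation, and this difference is what lets texture features separate
artefacts from genuinely abnormal nuclei.

Default slide composition is the study-scale mean object counts divided by
ten (≈ 343 normal epithelial nuclei; ≈ 31 abnormal on malignant and ≈ 4 on
benign slides, matching the corrected positive-/negative-follow-up means;
lymphocytes 30, granulocytes 20, doublets/defocused/lytic 10 each,
artefacts 15), so a slide renders in a few seconds; `scale = 1` restores
full scale. Malignant slides default to stemlines {2.0, 3.47}c — 3.47c is
the reported mean aneuploid stemline of positive smears — with 2% of
abnormal nuclei above 9c (≈ 6 events per ≈ 314 abnormal nuclei at study
scale). Benign slides are constrained by construction: stemlines inside
the euploid windows and no truth c-value above 9c.

## Imaging pipeline choices

**Background.** Object-free pixels are identified on the per-pixel maximum
projection across planes (background is bright and focus-invariant); a
second-order polynomial illumination surface is fitted to them. This
replaces the original instrument's physical diffraction/glare/shading
corrections with shading correction only — a documented fidelity gap.

**Segmentation.** Otsu's threshold on the OD image (floored at
`od_floor = 0.02`), morphological opening with a radius-1 disc, hole
filling, connected components, area filter [30, 20000] px. Overlapping
nuclei are returned as one candidate doublet, never split. A global Otsu
threshold can miss very faint lytic nuclei in mixed fields; since lytic
nuclei are excluded from both calibration and DNA analysis anyway, this
costs completeness of the audit counts, not diagnostic correctness.

**Focus selection and fusion.** The focus metric is the variance of the
4-neighbour Laplacian over the object's bounding box per plane; ties break
to the lowest plane index. Whether the original instrument fuses per
pixel or per object is ambiguous in its description; karyoscan fuses *per
object* (each object's pixels copied from its own best plane), with
per-pixel fusion available via `fuse_focal_stack(per_pixel = TRUE)`.
Fusion never invents intensity: every fused pixel exists at the same
coordinate in some plane.

## The 18 features

The feature count and its 11/4/3 split (morphology / pixel / texture) are
fixed by the pipeline being reproduced; the identities are not published
and are therefore a design decision, using standard cytometric
descriptors: area, perimeter, form factor $4\pi A/P^2$, eccentricity,
solidity, extent, major/minor axis, aspect ratio, radial variance and
convex deficiency; mean OD, max OD, OD variance and IOD (the "pixel
values" are OD statistics, not raw intensities — OD is the physically
meaningful scale for an absorbing stain); and co-occurrence contrast,
homogeneity and entropy. Texture uses OD quantized to 32 levels within
the mask, distance 1 px, symmetric, averaged over the four principal
directions, which makes it exactly invariant under 90° rotation.
Perimeter is measured by the coarea identity — the plane integral of the
gradient magnitude of the Gaussian-smoothed ($\sigma = 1.5$ px) mask
indicator equals the contour length. This estimator is rotation-exact and
has sub-percent bias for radii ≥ 10 px, where lattice-direction estimators
oscillate by several percent with radius. Solidity uses a pixel-counted
rasterization of the convex hull, so convex masks score exactly 1.

## Classifier

A probability random forest (ranger): 500 trees, $\sqrt{p}$ candidate
features per split, stratified 70/30 held-out evaluation, fixed seed,
single-threaded for determinism. The gallery-review workflow is emulated
by a corrections table (object_id, new_class): corrections override the
automatic class downstream, the last correction wins, and both uncorrected
and corrected counts are reported, mirroring how reviewed counts are
subtracted in practice. Retraining rounds enrich the training set with
the corrected records and refit; up to eight rounds mirror the original
workflow, though the synthetic classes saturate far earlier. The oral
eight-class schema is the default; a prostate schema (fibroblast, cancer,
lymphocyte, granulocyte, artefact) is available. A k-nearest-neighbour
baseline is deliberately not implemented.

## Calibration

Internal calibration maps IOD to c-units using the slide's own normal
nuclei. The trimming loop removes, per iteration, the single IOD farthest
from the current mean (symmetric in both directions, as "below and above
the mean" requires) until CV < 4%, with a floor of 30 surviving nuclei —
no floor is published, and 30 is the smallest reference population the
package accepts at all. Hitting the floor with CV ≥ 4% is an explicit
error carrying the full trimming trace, never a silent acceptance. The
CV trace is monotone non-increasing by construction (removing the farthest
point cannot increase the CV), and the tests assert it. Conversion is the
exact linear anchor $c = 2\,\mathrm{IOD}/\overline{\mathrm{IOD}}_{ref}$.

## Stemline detection and the ESACP rules

Stemlines are local maxima of a Gaussian kernel density over the analysed
c-values, bandwidth 0.1c; a mode is reported if at least 5% of the nuclei
lie within ±10% of it, its position is the mean c of those members, and
modes resolving within 0.15c of a stronger one are merged. Fewer than 10
analysed nuclei yield an "insufficient" flag and no stemlines. The
consensus interval semantics are applied with *closed euploid windows*:
positions exactly at 1.8, 2.2, 3.6 or 4.4c are euploid, and 9c-exceeding
events are strict (`c > 9.0`) — the published wording is ambiguous exactly
at the boundaries, and the euploid-inclusive reading is the conservative
one for a 100%-specific malignancy marker. The two published phrasings of
the tetraploid window ("<3.6, >4.4" and "3.6–4.4") are read as the same
rule. Single 9cEE events count (the "≥ 1 event" rule); guarding against
artefact-driven false 9cEE events is the job of the corrections workflow,
not of an automated re-review.

DNA grading: grade 1 if all stemlines are peridiploid; grade 2 if all are
euploid with at least one peritetraploid; grade 3 with exactly one
aneuploid stemline; grade 4 with two or more. The published material shows
exemplars, not boundary semantics, so the window assignments above carry
over.

## Specimen diagnosis

Aneuploidy ⇒ positive, regardless of counts. Otherwise the abnormal
percentage — abnormal nuclei as a percentage of the *normal* (reference)
nuclei, not of their sum — is compared strictly (`>`) against the
specimen-type threshold: oral 4% (the 5% alternative is first-class so
both published operating points can be regenerated), effusions 0.75%.
For effusions the denominator is all mesothelial nuclei
(normal + abnormal), following the published description of that ratio;
it is configurable because the wording leaves room for either reading.
Corrected counts feed the decision (review precedes interpretation);
uncorrected counts are kept for audit. Fewer than 300 corrected normal
nuclei trigger an adequacy *warning*, not an error — the reported false
negatives mostly occurred on cell-rich slides, so a hard floor would not
have prevented them.

## Evaluation

Diagnostic accuracy is computed as exact fractions with percentages
rounded half-up to one decimal, matching the printed tables; undefined
ratios render as "n/a", never 0. The 92-smear study is packaged as a
count-level fixture (per rule and reference standard: TP/FN/TN/FP); the
per-slide raw data are not public, so the fixture reproduces the printed
numerators and denominators, not slide-level overlaps — combined-rule
overlap structure is therefore not testable. Both reference standards are
encoded: the original follow-up (20/72) and the modified one (25/67) with
the five documented DNA-aneuploid discordant slides re-rated positive.

## What the tests show — and what they do not

The simulator emulates the statistical structure of the pipeline's inputs:
stoichiometric absorption, focus structure, class-specific morphology,
composition, and slide-level truth. It does not emulate staining
chemistry variation, thionine vs pararosaniline spectra, real chromatin
architecture, cellular overlap beyond deliberate doublets, or the
biological variability of real abnormal populations. Passing tests
therefore demonstrate that the *algorithms* are correct and meet their
stated performance bounds on data whose ground truth is known exactly —
they do not certify clinical accuracy on patient material, and the
published clinical accuracies on effusion and prostate cohorts are
deliberately out of scope. The end-to-end cohort property (sensitivity
≥ 0.9, specificity ≥ 0.95 on strong-effect synthetic cohorts) is a bound
on the pipeline's self-consistency, not a clinical claim.

Problem sizes used by the test-suite and the acceptance script — chosen as
comfortable desk-scale sizes: 100 calibration replicates of n = 50; one
slide of 60 identical reference nuclei for imaging fidelity; 2000 objects
per class (16,000 total) for classifier training; 100 stemline-recovery
replicates of n = 150 at 3% measurement CV; tenfold-scaled slide
compositions for cohort experiments, using the densitometric fast path
(`render = FALSE`) where image rendering adds nothing to the question
under test.

## Known limitations

Shading-only background correction (no diffraction/glare model); global
Otsu can drop very faint lytic nuclei from audit counts; per-object fusion
assumes objects are thin enough to be sharp in a single plane; the
classifier is trained and validated on synthetic appearance models only;
stemline detection with a fixed 0.1c bandwidth can merge true stemlines
closer than ≈ 0.3c; S-phase fractions, 5c-exceeding-event variants and
external DNA standards are not implemented.
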