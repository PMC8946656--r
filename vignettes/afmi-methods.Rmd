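---
title: "Methods: autofluorescence multispectral analysis of ocular surface tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autofluorescence multispectral analysis of ocular surface tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Pterygium (PTG) is a benign ocular-surface growth; ocular surface squamous
neoplasia (OSSN) is its malignant look-alike, and the two can coexist in
the same eye. Autofluorescence multispectral imaging (AFMI) records tissue
autofluorescence in many narrow excitation/emission channels, so that each
piece of tissue yields a spectral signature reflecting its endogenous
fluorophore content (elastin, lipofuscin/lipopigment, flavins,
protoporphyrin IX). `afmi` implements the full analysis chain for such
data: channel metadata, synthetic phantoms, image preprocessing,
sector-level spectral signatures, a per-patient normalization feeding
pooled ("fused") classification, intra-patient boundary mapping, and
per-channel nonparametric statistics.

## Spectral signatures and the fused framework

Images are divided into non-overlapping 16 x 16 pixel sectors anchored at
the image origin (partial edge sectors are dropped). The spectral
signature of a sector is the vector of per-channel mean intensities,
`SS in R^59`. Sector averaging over 256 pixels is also the package's
Poisson variance-reduction step; no explicit denoiser runs by default.

Raw signatures are not comparable across patients: section thickness,
fixation, lamp aging and detector gain all shift and scale intensities
patient by patient. The fused framework removes this with a per-patient,
per-channel standardization against the same patient's normal tissue:

    RSS = (SS - Med) / Std

where `Med` and `Std` are the per-channel median and population standard
deviation over that patient's pure normal-tissue sectors. `RSS` is exactly
invariant under any per-channel affine intensity transform `x -> a x + b`
(`a > 0`) applied to one patient's images, which is the confounder model.
Classifiers are then trained on `RSS` rows pooled across patients
("fused": intra-patient normalization, inter-patient training).
Decisions taken where the source material was open:

* `Std` is the population (ddof = 0) standard deviation, normal sectors
  only; fixed for reproducibility.
* Channels whose `Std` falls below `1e-6 * median(Med)` are floored at
  that epsilon and flagged (degenerate, e.g. dead channels).
* Sector labels come from pixel majority over the pathology mask; tissue
  sectors with purity below 0.8 are labeled `mixed` and excluded from
  classifier training but kept for boundary mapping; sectors with less
  than half their pixels on tissue are `outside`.

## Classification

The 59-dimensional signatures are compressed by centered PCA to their top
five scores (component signs fixed by the largest-loading-positive rule),
then classified by a soft-margin SVM. No SVM implementation ships with
the available R stack, so the package contains a compact SMO optimizer
(Rcpp) with linear and RBF kernels, balanced class weights, and a
deterministic working-set heuristic -- refits on identical data are
bit-identical, which the determinism contracts rely on. Defaults: RBF
kernel, `C = 1`, `gamma = 1 / (k * var(scores))`.

PCA and the SVM are refit inside every cross-validation training split;
fitting PCA once globally would leak test information. K-fold folds are
stratified by class at sector level (patients may span folds; a
patient-grouped variant is available), while leave-one-patient-out (LOPO)
holds out all sectors of one patient per fold and is the patient-disjoint
check. Pairwise AUC is the rank (Mann-Whitney) statistic on continuous
decision values; three-way AUC is the unweighted macro mean of
one-vs-rest AUCs (the aggregation was unspecified in the source
material's headline number; macro is documented here as the package's
choice). Summary statistics are reported as mean +/- sd over folds.

## The synthetic phantom world

No imaging data are publicly deposited, so every pipeline stage is
exercised on synthetic phantoms whose generative structure mirrors the
acquisition:

* **Class spectra.** Five smooth basis curves over channel index
  (truncated Gaussian bumps for elastin at channel 3, lipopigment at 12,
  flavins at 30, PPIX at 52, plus a broad background) combined with
  class-specific nonnegative weights, peak ~800 photon counts. Normal and
  PTG differ only in elastin (normal > PTG > OSSN); OSSN additionally
  gains lipopigment and loses flavins and PPIX. The bumps are hard-zeroed
  beyond 2.5 sd so that channels 12/30/52 have *exactly* equal normal and
  PTG expectations -- the "not significant" cells of the significance
  pattern are then a true null, not a small-effect approximation.
* **Patient variability.** Per-patient, per-channel log-normal gain
  (sd 0.25 log units) and additive offset (sd 10% of the mean class
  signal), applied to tissue pixels. The gain/offset values are *smooth
  curves over channel index* (7 spline knots): real patient-level drift --
  lamp aging, filter transmission, section thickness -- is spectrally
  smooth, and smoothness is what makes it a genuine confounder. (With
  i.i.d. per-channel gains, class information spread over ~15-channel
  spectral bumps simply averages the confounder away and conventional
  inter-patient classification is unimpaired.) The effect is still exactly
  per-channel affine, so the RSS normalization removes it exactly.
* **Biological texture.** A smooth multiplicative field (log-sd 0.15,
  correlation length 32 px) shared across channels. This is a package
  addition: with 256-pixel sector averaging, Poisson noise alone leaves
  classes separable by tens of standard deviations, so every AUC would be
  degenerately 1.0. Fifteen percent regional intensity heterogeneity is a
  realistic tissue property and puts the phantom in a non-degenerate
  regime. It was chosen from this a-priori analysis, not tuned against
  test outcomes. With texture off, pixels equal the class spectra exactly.
* **Degradations** (`Poisson(V * (g*clean + o) + background)`, then dead
  pixels to 0 and saturated pixels to 65535): radial vignette
  `V = 1 - s (d/d_corner)^2` with default strength 0.3; background 20
  counts; dead/saturated fractions 0.1% / 0.05%; Poisson photon noise on.
* **Geometry.** Default layout is three vertical bands
  normal | PTG | OSSN inside a 16-px outside-tissue margin; a blob layout
  provides irregular margins. Default size is 512 x 512 (the sensor is
  1024 x 1024; tests scale further down -- spatial size only changes the
  number of sectors, not the generative conditions).

What a green test does *not* establish: the phantom has no optical PSF, no
spatial spectral gradients within a class, no H&E appearance, and its
patient effect is exactly affine -- real inter-patient variability is
uglier. Results on phantoms validate the machinery, not clinical
performance.

## Preprocessing choices

Order: bad-pixel repair (median of the 8 available neighbors; >20% of a
channel flagged aborts as corrupted input), background subtraction
(5th percentile of the outside-tissue region per channel by default),
then flat-field correction.

The flat-field default deserves a note. A degree-2 polynomial surface on
the log image -- the obvious first choice -- turned out to be wrong for
structured scenes: with six free parameters it absorbs the tissue's own
class layout (on banded phantoms it compressed the OSSN relative-signature
contrast about 15-fold and halved boundary-map agreement). The default is
therefore a *one-parameter* centered radial model, `log I ~ scene + b u`
with `u` the squared normalized center distance and `b <= 0`: block-column
nuisance terms absorb the scene, `b` is identified from within-column
radial variation, and because `exp(b u)` is separable the full 2-D field
is reconstructed from `b` alone. It is fitted on tissue blocks only (the
dark outside-tissue border itself mimics vignetting). `polynomial_fit`
remains available and is exact on flat calibration frames; fitted fields
are normalized to peak one, so a provided ground-truth vignette is an
exact inverse.

Stitching is translation-only phase correlation of each tile against the
composed mosaic over the covered bounding box (zero-masking is avoided:
a shared mask edge pins the correlation peak at zero shift), with linear
feather blending in the overlap. Registration needs image features at the
shift scale; on feature-poor smooth content the phase-correlation peak is
uninformative, which is a property of the method, not a defect.

## Boundary maps and statistics

Boundary detection is intra-patient: a PCA+SVM bundle trained on the
patient's annotated high-purity sectors (normalized with the same
patient's normal reference) labels every non-annotated tissue sector --
the operationalization of "region intersections". Agreement is scored
only on non-training tissue sectors against the mask majority label.
Overlays use the bit-exact legend red (255,0,0) = OSSN,
orange (255,165,0) = PTG, green (0,255,0) = normal over the grayscale
base channel 10 (rescaled to its 1st-99th percentile). Optional modal
smoothing (ties keep the center label, `outside` never changes) is off by
default, mirroring its presentation as a supervised touch-up. PCA
false-color images map the top-3 sector scores to RGB after per-score
min-max rescaling; colors are dataset-relative, so no class-to-color
contract is promised.

Per-channel group comparisons use the two-tailed Mann-Whitney U test:
exact null enumeration when `min(n_a, n_b) <= 8` and the pooled sample is
tie-free, otherwise the normal approximation with tie and continuity
corrections (slightly conservative; measured type-I error ~0.044-0.05 at
alpha = 0.05). Stars: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
Sectors are pooled as independent observations by default (matching the
source analysis); because pooling inflates n, a per-patient aggregation
mode (patient medians as observations) is available. No multiple-testing
correction is applied by default; Benjamini-Hochberg is behind a flag.

## Numerical and interface choices

* The relative-signature normalization is `(SS - Med)/Std` elementwise;
  the alternative reading `SS - Med/Std` is dimensionally incoherent and
  rejected.
* Channel wavelengths are synthesized metadata (five filter cubes,
  excitation 340-450 +/- 5 nm, emissions tiling 400-700 nm): downstream
  computation uses only channel identity and count.
* Stacks serialize to a plain-text format and masks to CSV (no TIFF
  library in the supported stack); overlays write plain-text PPM.
* Run configs are JSON; a single global seed is fanned out to fixed
  per-stage child seeds so partial reruns reproduce; manifests record a
  config hash and reference every artifact.

## Known limitations

Translation-only stitching (no rotation/scale); no spectral unmixing into
fluorophore abundances; no pixel-level (sub-sector) classification; the
SMO implementation precomputes the Gram matrix, so training sets beyond a
few thousand sectors should be subsampled; phantom realism as discussed
above.
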