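# afmi

Sector-level analysis of autofluorescence multispectral imaging (AFMI) of
ocular surface tissue, for researchers who need to tell apart normal
conjunctiva, pterygium (PTG, benign) and ocular surface squamous neoplasia
(OSSN, malignant) from 59-channel autofluorescence image stacks — and to
delineate their boundaries on the image.

## The method

Each spectral channel records tissue autofluorescence in a narrow
excitation/emission window matched to endogenous fluorophores (elastin,
lipopigment, flavins, protoporphyrin IX). Images are divided into 16 × 16
pixel sectors and each sector yields a **spectral signature**
`SS ∈ R^59` of per-channel mean intensities. To make signatures
comparable across patients, each one is standardized against the *same
patient's* normal tissue:

```
RSS = (SS − Med) / Std
```

where `Med` and `Std` are the per-channel median and standard deviation of
the patient's normal-sector signatures. `RSS` is invariant to per-patient,
per-channel affine intensity changes (section thickness, lamp/detector
drift). Pooling `RSS` rows across patients and training a classifier on
them is the **fused framework**: intra-patient normalization with
inter-patient training. Signatures are compressed to their top five PCA
scores and classified with an SVM (a compact SMO implementation ships in
the package); performance is evaluated with rank-based ROC/AUC, stratified
K-fold and leave-one-patient-out cross-validation. Per-channel class
differences are tested with two-tailed Mann–Whitney U tests, and
intra-patient classifiers paint red (OSSN) / orange (PTG) / green (normal)
boundary maps over a grayscale base channel.

Because no imaging data are publicly deposited, the package includes a
first-class synthetic phantom generator (59-channel stacks,
class-distinct fluorophore mixtures, smooth per-patient spectral
gain/offset curves, biological texture, vignetting, background, dead and
saturated pixels, Poisson noise) against which every stage is tested. See
`vignettes/afmi-methods.Rmd` for the full model description and design
rationale.

## Worked example

```r
library(afmi)

spec <- phantom_spec(n_patients = 6, image_shape = c(128, 128), seed = 1)
tab  <- cohort_signature_table(spec)          # generate + preprocess + sectors
rel  <- relative_signatures(tab, min_normal = 8)   # Med/Std per patient, RSS

rep <- cross_validate(rel$table, mode = "kfold", k = 10,
                      framework = "fused", classes = c("PTG", "OSSN"),
                      seed = 1)
rep
#> <afmi_eval_report> fused, kfold, 10 folds
#>   pooled AUC: 1.000
#>   accuracy 100 +/- 0%, sensitivity 100 +/- 0%, specificity 100 +/- 0%

channel_comparison_table(
  rel$table[rel$table$label %in% c("normal", "PTG", "OSSN"), ],
  channels = 3)[, c("group_a", "group_b", "u_statistic", "p_value", "stars")]
#>   group_a group_b u_statistic  p_value stars
#> 1  normal     PTG        5099 1.31e-23   ***
#> 2  normal    OSSN        5184 4.00e-25   ***
#> 3     PTG    OSSN        4784 2.02e-18   ***
```

The AUC of 1.000 says the fused classifier separates PTG from OSSN sectors
perfectly *on this phantom* (whose class spectra are well separated
relative to its 15% biological texture); the channel-3 (elastin) tests
reproduce the expected normal > PTG > OSSN ordering with `***`
significance. On the same cohorts, conventional inter-patient
classification on raw signatures averages AUC ≈ 0.93 — the gap is the
fused framework removing the per-patient spectral confounder.

Boundary mapping for one patient:

```r
st  <- preprocess_stack(generate_patient(spec, 1))
tb  <- extract_signatures(st)
ann <- select_annotations(tb, min_per_class = 8, seed = 1)
bm  <- detect_boundaries(st, ann, table = tb, min_per_class = 8)
bm$agreement                      # held-out sector agreement with truth
write_ppm(render_boundary_overlay(bm), "map.ppm")
```

## Layout

- `R/` — channel scheme, phantom generator, preprocessing (repair /
  background / flat-field / stitching), signatures + RSS, PCA + SVM +
  cross-validation, boundary maps, channel statistics, pipeline runner
- `src/` — SMO support vector machine (Rcpp)
- `inst/extdata/channels_default.csv` — bundled 59-channel scheme
- `inst/cli/afmi.R` — command-line entry point (JSON configs)
- `tests/testthat/` — unit, property and acceptance tests
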