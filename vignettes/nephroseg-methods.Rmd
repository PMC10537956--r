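---
title: "Quantifying acute kidney IRI by whole-section semantic segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying acute kidney IRI by whole-section semantic segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nephroseg)
```

## The problem

Ischaemia-reperfusion injury (IRI) is a standard experimental model of
acute kidney injury: the renal pedicle is clamped, the kidney turns
ischaemic, and reperfusion injury develops over the following days. The
histological read-out is classically a semi-quantitative score: a
pathologist examines ten fields of view (FOVs) from the cortex and the
outer stripe of the outer medulla (OSOM) of a PAS-stained section, grades
each FOV 0–4 by the fraction of damaged tubules, and averages the ten
grades. The method is subjective, samples roughly a tenth of the section,
and loses all spatial information.

`nephroseg` implements the alternative: semantic segmentation of the whole
section. Every pixel of the digitised slide is assigned to one of ten
classes — slide background, six healthy renal structures (adipose tissue,
glomeruli, proximal tubules, distal tubules/collecting ducts, stroma,
transitional epithelium) and three acute-IRI changes (intratubular casts,
tubular necrosis, regenerating epithelium). From the resulting label mask
the package derives:

* a **CNN injury score**: the percentage of the kidney surface (all
  non-background pixels) occupied by the score classes, by default casts +
  necrosis;
* **grid heatmaps**: per 512×512-pixel patch, the percentage of the patch
  occupied by a pathological class, rendered deep blue (0%) to red (100%);
* **pixel-wise evaluation**: confusion matrix, row-normalised percentages,
  per-class precision/recall/specificity/F1;
* a **semi-quantitative scorer** reproducing the traditional 10-FOV 0–4
  protocol, so the two scoring philosophies can be correlated on the same
  sections.

No public dataset accompanies the original experiments, so the package
ships a synthetic generator that emulates PAS-stained kidney sections with
exact ground truth; every pipeline stage is testable end to end without a
download.

## The segmentation network

The model is the descending half of a U-Net: three blocks of 3×3
convolution (stride 2) → batch normalisation → ReLU, then a 1×1
projection to K class scores. There is no decoder, so the output grid is
8× coarser than the input (output stride 8): a 512×1024 patch yields a
64×128×K score grid. At desk scale the stage widths default to 16/32/64
channels (`width_multiplier` scales them).

Design choices the architecture description leaves open were resolved as
the smallest standard options consistent with the stated hyperparameters:

* **Loss**: pixel-wise multinomial cross-entropy on annotated output-grid
  positions. With `class_balancing = TRUE` classes are weighted by damped
  inverse frequency (`sqrt`, clipped to [0.2, 10]), which keeps rare
  classes such as regenerating epithelium from being ignored.
* **Optimiser**: momentum SGD, momentum 0.9 (0.99 supported). The learning
  rate is adaptive within [5e-7, 5e-4]: training starts at the upper
  bound and halves the rate whenever the loss has not improved for
  `patience` (25) steps — a plateau rule standing in for manual
  "on-the-fly" curve monitoring. The rate never leaves the stated bounds.
* **Epochs**: the training protocol is described as one iteration per
  epoch, which we read as one optimizer step on a freshly sampled batch;
  the desk-scale default is 500 steps (configurable to 2300).
* **Normalisation**: batch normalisation after every convolution; conv
  biases are omitted since BN absorbs them.
* **Ground truth at the output grid**: full-resolution masks are reduced
  by majority vote per 8×8 block; blocks where fewer than half the pixels
  are annotated become the `UNANNOTATED` sentinel (255) and contribute
  nothing to loss or evaluation. Annotation is sparse by nature — regions,
  not whole slides, are annotated — and the sentinel is deliberately
  distinct from the background *class* (id 0), which is a real, annotated
  category.
* **Augmentation**: horizontal/vertical flips, right-angle rotations
  (square tiles), and mild brightness (±10%) and saturation (±20%)
  jitter, emulating variation in section morphology and staining
  intensity.
* **Dropout**: supported on the last feature map in [0, 0.1]; desk-scale
  default 0 (the synthetic task shows no overfitting at 500 steps).
* **Argmax ties** are broken toward the lowest class id, making
  prediction fully deterministic.

Prediction is tile-wise: tiles are clipped at section edges, padded to a
multiple of 8 by edge replication, and overlapping tile probabilities are
averaged before the argmax. `upsample_mask()` replicates labels 8×8 to
return to full resolution; class proportions are exactly preserved, which
is why the injury score is identical on either grid. The reverse is not
true — majority downsampling discards within-block detail, so
`upsample(downsample(x))` is not `x`.

## The synthetic generator

`generate_section()` emulates, at desk scale, the structure that matters
to the pipeline rather than photorealistic PAS appearance:

* a kidney-shaped silhouette (wobbly ellipse with a hilar notch) on a
  near-white slide background, stored explicitly as class 0 — background
  is never inferred from pixel colour;
* a jittered-grid Voronoi tessellation of the parenchyma into
  tubule-scale cells with darkened membranes;
* glomeruli stamped as compact round blobs;
* pathological classes clustered around a random injury focus, echoing
  the OSOM-centred distribution of real lesions;
* per-class base colours plus class-specific textures: homogeneous
  strongly stained lumen fills for casts, high-variance fragmented debris
  for necrosis, brush-border speckle for proximal tubules.

Class area quotas are filled cell-by-cell (best fit, stop within half a
cell), so realized fractions track targets to well within the contract of
±20% relative or ±0.5 percentage points. The defaults — glomeruli 5%,
adipose 2%, distal tubules 20%, stroma 8%, transitional epithelium 1.5%
of the kidney surface, proximal tubules absorbing the remainder — are the
package's own choice of a plausible mid-coronal composition; the source
experiments report only that regenerating epithelium averaged 0.02% of
the section, and the generator mirrors that scarcity by scaling it as 2%
of the injury fraction (so zero in healthy sections and always well under
1%). The injury budget splits equally between casts and necrosis unless
targets are given explicitly. When the injury fraction is large the named
healthy quotas shrink proportionally so the total stays below one.

What passing tests on this generator do show: the network machinery
learns, the quantification arithmetic is exact, and the two scoring
systems agree on cohorts with graded injury. What they do not show:
robustness to real stain variation, scanner artefacts, the morphological
ambiguity of regenerating epithelium, or inter-laboratory domain shift —
the synthetic classes are chromatically separable by construction, which
is precisely why a 500-step desk-scale training suffices where the real
model needed days of GPU time.

Default problem sizes were chosen once for desk-scale work: 1024×1024
default sections (real WSIs are ~30,000 px wide; all geometry scales with
the raster), 256×256 training tiles, 40 training + 10 held-out tiles and
500 optimizer steps for the parameter-recovery experiment, and 20-section
cohorts at 256×256 with FOV size 64 for the scorer-correlation
experiment.

## Scoring conventions

Two denominators coexist deliberately, following the respective
definitions literally:

* the **injury score** divides by the non-background kidney surface;
* the **heatmap patch percentage** divides by the whole patch, background
  included (the convention of the rendered figure grids). The
  pixel-weighted mean of patch percentages therefore equals the class's
  share of the *total* section area, not of the kidney surface — an
  identity the tests check numerically.

The semi-quantitative scale is 0 = exactly 0%, 1 = (0, 25%],
2 = (25%, 50%], 3 = (50%, 75%], 4 = (75%, 100%]. The published scale
prints overlapping bins (26–59% / 51–75%); the package adopts the only
disjoint and exhaustive reading, treating the 59 as a typo for 50. FOV
damage is area-based (score-class pixels over non-background pixels in
the FOV); grade 0 requires literally zero damaged pixels, so healthy
controls score 0 under both systems, and the FOV size defaults to 512 px
at full resolution (configurable; the original "200×" field is
microscope-dependent, so the package decouples from optics via
`microns_per_pixel`).

Scorer agreement uses Spearman's rank correlation (Pearson on
average-ranked data, ties receiving mean ranks; p-value from the
t-approximation). Pearson is available as an option — both conventions
appear in practice — but Spearman is the headline, being invariant to the
monotone, non-linear relation between a 0–4 ordinal mean and a 0–100%
area percentage.

## Evaluation conventions

The confusion matrix puts ground truth on rows; row-normalised
percentages read "x% of all pixels labelled as class *i* were classified
as class *j*". Metrics are one-vs-rest with the textbook formulas;
`F1 = 2PR/(P+R) = 2TP/(2TP+FP+FN)` — the identity holds exactly on
integer counts and is asserted in the tests. Division by zero yields an
explicit undefined marker (`NA`), and summary aggregation skips undefined
classes instead of propagating NaN; small synthetic evaluations routinely
contain empty classes. Evaluation aligns grids by majority-downsampling
the truth to the prediction's 8× grid (consistent with training);
upsampling the prediction instead is available but counts each predicted
position 64 times. Macro (unweighted) and pixel-weighted aggregate
metrics are both reported, since the aggregation convention behind
single-number summaries is often unstated.

## Worked example

```{r example, eval = FALSE}
library(nephroseg)
schema <- default_class_schema()

# a synthetic cohort with graded injury
cohort <- generate_dataset(12, synthetic_section_spec(256, 256),
                           injury_grades = c(0, 0.1, 0.2, 0.3, 0.4),
                           seed = 7)

# train the encoder-only model
fit <- train_model(build_model(schema, seed = 7), cohort[1:10],
                   train_config(batch_size = 4L, epochs = 200L, seed = 7))

# segment a held-out section and quantify it
pred <- predict_mask(fit$model, cohort[[11]]$image)
injury_score(pred, schema)

# evaluate pixel-wise against ground truth
cm <- confusion_matrix(cohort[[11]]$mask, pred, schema)
class_metrics(cm)

# heatmap of casts + necrosis
hm <- injury_heatmap(upsample_mask(pred), schema, patch_size = 64L)
img <- render_heatmap(hm)

# compare with the traditional scorer across the cohort
compare_cohort(cohort, model = NULL, fov_size = 64L, seed = 7)$correlation
```

## Known limitations

* The generator is stylised; results on it bound nothing about real
  tissue. It exists to make the pipeline's arithmetic and learning
  machinery testable.
* Regenerating epithelium is rendered rare and is excluded from the
  default score, mirroring its unreliability in practice; its
  quantification is still reported.
* The FOV scorer counts only classes that exist in the mask; criteria a
  pathologist would also weigh (brush-border loss, tubular dilation) have
  no class and are not modelled.
* No colour normalisation, artefact simulation or anatomical (cortex /
  OSOM / medulla) parcellation: damage localisation is visual, via the
  heatmap, as in the source protocol.
* Training is reproducible given a seed up to floating-point
  associativity of the underlying BLAS.
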