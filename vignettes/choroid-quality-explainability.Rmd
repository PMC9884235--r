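---
title: "Choroid-region quality assessment with explainable attention scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choroid-region quality assessment with explainable attention scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choroidqc)
```

## The problem

Automated quantification of choroidal biomarkers (thickness, vascularity
index, volume) from OCT B-scans presumes that the choroid — the vascular
layer between retina and sclera — is imaged with adequate quality. In
practice, scans vary widely: the contrast between luminal (vessel) and
stromal tissue, the contrast at the choroid–sclera interface, speckle
noise, and depth attenuation all degrade independently. A screening
pipeline therefore wants (i) a classifier that labels a scan's choroid
region *good* or *bad*, and (ii) evidence that the classifier actually
looked at the choroid, not at incidental cues elsewhere in the frame.

`choroidqc` implements both halves: the classification protocol
(stratified K-fold evaluation at the maximum-accuracy operating point) and
the explainability audit (Grad-CAM saliency, color transparency maps, and
the coverage scores OCC and CCVR measured against a ground-truth choroid
mask).

## The synthetic B-scan simulator

Clinical OCT datasets with expert quality grades and choroid annotations
are rarely shareable, so the package ships a simulator that makes the
entire method testable end to end. A scan is a vertical stack of tissue
compartments — vitreous, retina, choroid band, sclera — separated by
smooth sinusoidal boundary curves, with elliptical low-reflectivity vessel
lumina placed inside the band. Two degradations are applied after
compositing:

* **speckle** — multiplicative gamma noise with mean one and standard
  deviation `speckle_strength` (OCT speckle is multiplicative);
* **attenuation** — intensity decays as `exp(-4 * attenuation_factor * d)`
  with `d` the depth below the inner retinal surface as a fraction of
  image height. Referencing the decay to the tissue entry rather than the
  image top keeps the vitreous clean and concentrates the visual damage in
  the choroid and sclera, which is where clinically "attenuated" scans
  lose their gradability.

The ground-truth choroid mask is the half-open band `cib[x] <= r < cob[x]`
and is returned exactly as constructed: noise never touches it.

### What the presets encode

The good/bad presets differ primarily on the two *choroid-local*
determinants an expert grades on:

| parameter | good | bad |
|---|---|---|
| luminal level | 0.15 | 0.40 |
| stromal level | 0.75 | 0.50 |
| sclera level | 0.40 | 0.40 |
| luminal/stromal gap | 0.60 | 0.10 |
| stroma/sclera gap | 0.35 | 0.10 |
| speckle strength | 0.25 | 0.35 |
| attenuation factor | 0.20 | 0.35 |

This choice is deliberate: the quality label must be *about the choroid*,
as it is for a clinical grader, so the reliable class signal lives inside
the band (washed-out stroma, invisible vessels, vanishing choroid–sclera
interface) while speckle and attenuation differ only moderately. If
instead the global degradations alone separated the classes, any
classifier could succeed while ignoring the choroid entirely, and the
coverage audit would be meaningless by construction. Retina and vitreous
levels are identical across classes for the same reason.

Cohorts add realistic geometric variation: `"diseased"` scans get a ~30%
thinner choroid with more irregular boundaries. Default canvas is 496×768
pixels; this is a conventional display size for B-scans, not a measured
device constant, and every size ≥ 16 px works.

### What the simulator does not model

No A-scan physics, no device-specific artifacts, no real retinal
lamination, no pathology other than band thinning. Consequently a passing
end-to-end run shows that the *protocol* behaves correctly on data whose
ground truth is known exactly — it does not certify performance on
clinical scans.

## The classifier and its evaluation

The bundled backbone is a compact CNN trained from scratch: two 3×3
convolution blocks (12 and 24 filters, ReLU, 2×2 max-pooling), global
average pooling, and a dense two-class head. Pretrained
ResNet/EfficientNet backbones are deliberately not bundled — the protocol,
not the backbone, is what the package embodies — but the `qc_network()`
constructor accepts arbitrary conv/pool/dense stacks, and `model_config()`
reserves the standard backbone identifiers with their published input
sizes (224/224/300) and learning rate (1e-4). The `small_cnn_config()`
preset raises the learning rate to 1e-3 (Adam, 10 epochs, 64×64 input,
minibatch 16): a from-scratch network needs a larger step than a
fine-tuned pretrained one, and at 64×64 the synthetic classes remain fully
distinguishable while a 5-fold run stays within a few minutes on one CPU.
The 12/24 filter widths were chosen over a narrower 8/16 variant because
the wider network develops markedly more stable band-localized features
across training seeds, which matters for the saliency audit below;
accuracy is saturated in either case.

Evaluation follows the standard protocol: `stratified_kfold()` deals each
class round-robin after a seeded shuffle, guaranteeing every fold's class
count is within one of the exact proportional split. Each fold's held-out
scores yield an ROC AUC and a confusion matrix at the *maximum-accuracy
operating point* — the observed-score threshold maximizing accuracy, ties
broken toward the higher threshold. Precision, recall and F1 use the
conventional definitions with `"good"` as the positive class;
`TP/(TP + 0.5(FP + FN))` is asserted equal to the harmonic-mean form in
the test suite. Undefined metrics (empty denominator) propagate as `NaN`
with a warning rather than a silent 0.

Two caveats are inherent to the protocol and documented rather than
hidden: the operating point is selected on the test scores of each fold
(the literal reading of reporting "at the operating point with maximum
accuracy"), and no early stopping or validation split is carved from the
training folds.

## Grad-CAM, and which class to explain

`gradcam()` backpropagates the chosen class logit to the hooked activation
maps (the ReLU after the final convolution), global-average-pools the
gradients into importance weights, applies ReLU to the weighted activation
sum, upsamples bilinearly to the image, and min-max normalizes to [0, 1].
A constant raw map normalizes to all zeros, so an uninformative
explanation yields an empty visible region downstream instead of a
spuriously "fully relevant" one. The gradient computation is verified
against central finite differences on a fixed two-convolution network
(relative error < 1e-3; in practice ~1e-9), using a pooling-free fixture
because max-pooling ties at zero-valued ReLU cells make one-sided
perturbations genuinely non-differentiable.

The function's default explains the *predicted* class. The pipeline and
the synthetic study, however, explain the **good-class logit for every
scan**. This resolves a genuine ambiguity — the illustrated convention in
the source framework is the good-class map — and has a substantive
justification: in a two-class network the bad-class logit largely encodes
the *absence* of good-quality evidence, and absence has no location, so
bad-class maps degenerate into noise over uninformative regions (we
observe them collapsing onto the vitreous). The good-class map on a
bad-quality scan instead highlights where residual choroid-quality
evidence was sought, which is the clinically meaningful question "did the
model judge the choroid?". Both conventions remain available via the
`explain_class` argument.

## CTMs and coverage scores

A color transparency map keeps relevant structure visible instead of
occluding it with a heat map: the gray image is attenuated by the
relevance (`m = image * g_c`) and a red mask `1 − g_c` is composited into
the red channel. "Composited" is resolved as additive-with-clip
(`red = min(m + 1 − g_c, 1)`), which reproduces both limiting behaviours —
fully relevant pixels show the unmodified gray image, fully irrelevant
pixels are pure red; a `replace` mode (`red = max(m, 1 − g_c)`) is
available behind an argument. Grid overlays (default 1-px cyan lines every
50 px) support area comparisons by eye.

The visible region `T` is operationalized as `g_c >= tau` (default
`tau = 0.5`, sweepable via `coverage_sweep()`), replacing the human
judgment of "transparent enough" with a reproducible rule. Against the
ground-truth choroid mask `C`:

* `OCC = |T ∩ C| / |C|` — how much of the choroid the model makes visible;
* `CCVR = |T ∩ C| / |T|` — how much of what the model shows is choroid.

An empty `T` (fully opaque CTM) or empty `C` yields `NaN` with a warning,
and `group_summary()` excludes such images from the cohort × quality means
with a logged count — mirroring that a grader cannot score a fully opaque
map. The per-image `|OCC − CCVR|` is averaged per group (not the
difference of the group means). The natural chance level for CCVR is the
choroid area fraction (~15% under the default geometry): a spatially
random `T` achieves CCVR equal to it in expectation, so values well above
it demonstrate choroid-directed attention.

## Agreement between two raters

The reliability formula `sum(x*y) / sqrt(sum(x) * sum(y))` is implemented
verbatim as the `"as-printed"` variant for fidelity to its published
definition, but it is not scale-invariant (all-twos series of length two
evaluate to 2.0), so `agreement_report()` always reports the bounded
cosine variant `sum(x*y) / sqrt(sum(x^2) * sum(y^2))` alongside; the
discrepancy is surfaced rather than silently corrected. In the pipeline,
the two "raters" are coverage scored at `tau` and at `tau + 0.1`.

## The end-to-end study and its scale

`quality_assessment_study()` runs the whole method in memory: 200 good +
200 bad preset scans (half diseased per class), 5-fold stratified
cross-validation of the small CNN, a good-class saliency map per scan from
the model that held it out, and coverage at `tau = 0.5`. These problem
sizes are the package's reference configuration: large enough that fold
metrics and coverage means are stable (≈3 minutes on one CPU), small
enough to run routinely. With the default presets the classifier reaches
fold accuracies at or near 100%, mean CCVR over correctly classified
bad-quality scans lands near 25–30% against a ~15% chance level, and
good-quality scans reach CCVR around 70–80%.

`run_all()` executes the same pipeline through files (PNG scans and masks,
CSV manifest and scores, JSON reports) with per-stage toggles and a saved
training checkpoint, which is the form a screening deployment would use.

## Numerical choices and degenerate inputs

* Seeds: every stochastic step (boundary curves, vessel placement, noise,
  fold shuffling, weight initialization, batch order) derives from an
  explicit seed; identical configuration implies bit-identical synthetic
  data and training trajectories.
* Operating-point ties break toward the higher threshold; `Inf` is always
  a candidate (predict nothing positive).
* AUC uses mid-rank tie handling; it is cross-checked against the
  brute-force pairwise oracle in the tests rather than trusted.
* Min-max normalization of a constant saliency map returns zeros (see
  above); bilinear upsampling is clamped at 0 to guard boundary
  arithmetic.
* Masks are written as {0, 255} PNGs and re-binarized at 0.5 on read;
  saliency maps quantize to 8 bits on disk, which perturbs thresholding
  at most by 1/255.

## Known limitations

The simulator's simplicity means the classifier's task is easier than on
clinical data; reported accuracies are a protocol check, not a clinical
claim. Grad-CAM explains at the resolution of the final convolution layer
(29×29 before upsampling at the default geometry), so coverage scores
inherit its smoothing. Bad-class saliency is structurally uninformative
for two-class networks, as discussed. The printed agreement formula is
reported but unbounded; use the cosine variant for interpretation.
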