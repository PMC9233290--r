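---
title: "Methods: lesion-level detection evaluation and presegmentation-based DR grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion-level detection evaluation and presegmentation-based DR grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundusseg)
```

## The problem this package addresses

Automated grading of diabetic retinopathy (DR) is usually posed as whole-image
classification on the five-level ICDR scale (0 = no DR … 4 = proliferative
DR). The levels, however, are *defined by lesions*: microaneurysms (MA) define
level 1; hemorrhages (HEM) level 2; prominent intraretinal microvascular
abnormalities (IRMA) level 3; neovascularizations (NV) — active or treated by
panretinal photocoagulation, whose scars (PC) mark treated disease — level 4.
Hard exudates (HE) and cotton wool spots (CWS) accompany DR but do not by
themselves set the grade. A segmentation model that finds these lesions can
(a) be evaluated as a *detector* of individual abnormalities, and (b) feed a
grading model by superimposing its color-coded mask on the image
("presegmentation") so that tiny lesions survive the aggressive downsampling
that whole-image classifiers require.

`fundusseg` implements the full evaluation protocol around such a model: the
component-level matching metrics, the inter-annotator agreement statistic, the
overlapping-tile inference machinery, the presegmentation preprocessing and
rule-based grading metrics — plus a seeded synthetic data generator so the
entire pipeline is exercisable end to end without clinical images or a trained
network. The heavy CNNs themselves (a U-Net-style segmenter, an Inception-v3
grader) are deliberately out of scope: the package provides the pluggable
`Predictor` contract they would fill.

## Detection protocol

The unit of evaluation is the **connected component** of same-class lesion
pixels (8-connectivity by default; configurable). Matching is by *one-pixel
overlap*: a predicted component is a true positive if any of its pixels
overlaps any same-class reference pixel, otherwise a false positive; a
reference component with no same-class predicted overlap is a false negative.
The matching is one-to-many by construction — precision is computed over
predicted components, recall over reference components; the two sides are
counted independently, which is the only reading under which both the
false-positive and the false-negative definitions are directly computable.

Conventions chosen where the protocol leaves freedom:

* **Connectivity** defaults to 8 (diagonally touching pixels are one lesion),
  the standard choice for blob-like structures.
* **Undefined precision** (no predicted components of a class) is reported
  `NA`, excluded from the mean and flagged — per-class means are unweighted
  arithmetic means over the defined classes. Note that published tables do
  not always behave this way: one widely cited table prints a mean precision
  of 0.52 where the unweighted mean of its printed row is ≈ 0.556, so its
  averaging was presumably done on unrounded or count-weighted values. We
  document rather than emulate this.
* **Confusion attribution** (`fp_confusion`): each predicted component goes to
  exactly one cell — its own class if a same-class overlap exists, else the
  reference class with the largest pixel overlap, else background (BG). Ties
  break by the fixed class order MA < HEM < CWS < HE < PC < IRMA < NV, making
  the tables deterministic.
* **Optic disc** pixels are background for every metric; the disc label exists
  only because segmentation networks train more stably when it is annotated.
* **Adjusted precision** counts a predicted component as correct if it
  overlaps reference lesion pixels of *any* class — the binary
  "detect-anything" reading; it is provably never below standard precision.

`relative_improvement()` is `100·(new − old)/old` rounded to one decimal.
Beware recomputing published improvement percentages from *rounded* table
values: e.g. 0.67 vs 0.47 gives 42.55 → 42.6, while the figure printed
alongside those values is 42.5 (computed before rounding). The acceptance
suite asserts such identities to within one unit in the last printed digit.

## Inter-annotator agreement

Agreement between two annotators is quantified on per-image, per-class
**component counts** with the intraclass correlation coefficient. We use
ICC(2,1) — two-way random effects, absolute agreement, single rater — the
conventional form for interchangeable raters each measuring once:

$$\mathrm{ICC}(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)}$$

computed from the classical mean-squares decomposition of the $n \times k$
count table. Counts (not areas) are used because the downstream detection
protocol is count-based; ICC(3,1) is available via `form =` for consistency
(rather than absolute-agreement) questions. Zero total variance makes the
ratio undefined and is reported as `NA` with a warning, never silently as 0
or 1.

## Overlapping-tile inference

Full-resolution six-field images (6,528² pixels in the motivating setting)
exceed any network input, so inference runs on overlapping tiles whose edge
bands — where segmentation errors concentrate — are discarded:

* tiles of `tile_size` step by `tile_size − 2·margin`, so the retained
  interiors abut exactly; every output pixel is written exactly once;
* at image boundaries, tiles shift inward rather than padding, so pixel
  values are never invented; the retained region of the outermost tiles
  extends to the image edge;
* `margin` defaults to `tile_size/8` (128 px at the 1,024-px default); the
  protocol this mirrors states that edges are cropped but not by how much,
  so the margin is a visible, configurable parameter.

Multi-head predictors (e.g. parallel 1×1/3×3/5×5 output kernels) are fused by
the **argmax of the unweighted mean** of the per-pixel head probabilities,
ties to the lowest class index. The per-head loss weights (0.33 each) carried
in `TileConfig` matter only for training, which is out of scope.

The stitching-correctness property — for any *pixelwise* predictor,
`tiled_predict` equals whole-image prediction exactly, for any margin and any
image size — is the key invariant, tested over random images, margins
{0, 32, 128} and non-divisible sizes. A softmax color-threshold segmenter
(`palette_predictor`) ships as the reference pixelwise backend.

## Presegmentation and rule-based grading

Preprocessing mirrors a fixed-input-size grading network: crop the black
border to the tight bounding box of above-threshold pixels, superimpose the
lesion mask in its class colors (opaque by default — configurable alpha —
because the motivating pipeline shows solid markings), and resize by exact
area averaging to a square input (598² by convention; area resampling reduces
to block averaging at integer factors, which is what the tests pin down).

`rule_grade` maps lesion presence to the ICDR level: NV or PC → 4, else
IRMA → 3, else HEM → 2, else MA → 1, else 0. PC counts as level 4 because
photocoagulation scars mark *treated* proliferative disease. HE and CWS never
raise the grade (alone they indicate other diabetic eye disease, e.g. macular
edema risk). The rule is monotone: adding lesions never lowers the grade.

Grading quality is summarized by the 5×5 confusion table (rows = reference),
per-class accuracy (diagonal over row sum; unweighted mean over non-empty
classes), **quadratic weighted kappa**
$\kappa = 1 - \sum w O / \sum w E$, $w_{ij} = (i-j)^2/(k-1)^2$, and
**macro one-vs-rest ROC AUC** with midrank tie handling. Degenerate cases are
reported as undefined (`NA` with a warning), not guessed.

## The synthetic world: what it is and is not

The generator emulates the *statistical shape* of annotated six-field data,
not its appearance: a dark circular retina with black surround and an optic
disc; MA as 2–5 px discs; HEM as irregular 6–20 px random-walk blobs; CWS/HE
as soft/sharp bright blobs; IRMA/NV as thin dilated random-walk tangles; PC
as pale rings — sizes stated at a 640-px reference frame and scaled with
resolution, since only topology and size statistics matter to the downstream
code. Lesion composition is made consistent with the requested ICDR grade
(level 1 images contain only MA, its canonical presentation; HE/CWS may
accompany level ≥ 2), and `rule_grade(mask) == grade` is asserted on every
generated image. The default 640² resolution (not 6,528²) keeps the full
pipeline in minutes; the published size/intensity statistics of real Danish
screening data are unknown, so the generator's count/size ranges are honest
free parameters chosen once to look like a moderately diseased eye.

A simulated **second annotator** and a simulated **imperfect model** are
derived from the reference mask by dropping whole components (probability
`drop_rate`), relabelling them (`type_swap`, e.g. the IRMA→NV confusion that
plagues real systems), jittering their position, and inventing spurious
components at a Poisson rate — on separate random streams so their errors are
independent. The random stream order (drop uniforms first, then swap
uniforms, then jitter offsets, then the Poisson count) is documented and
frozen so tests can replay it independently.

Consequently a green end-to-end test establishes that the *evaluation
machinery* is correct — matching, bookkeeping, metrics, stitching, grading
arithmetic — and that corruption degrades kappa and concentrates confusion
where seeded. It does **not** establish anything about real fundus images,
real annotator behavior, or any trained network's accuracy; the published
headline numbers (e.g. κ = 0.90 on 4,703 test images) require proprietary
data and GPU training and are reproduced only at the level of their printed
arithmetic.

Dataset splitting reproduces the stated stratification: images of one
patient never span subsets, and ~70% of NV-containing images are steered
into training (NV being rare and precious); infeasible constraints yield a
best-effort split with an explicit warning flag rather than a silent
violation.

## Numerical and reproducibility choices

* One master seed; per-image and per-stage child streams derived by a fixed
  integer hash (`derive_seed`), all below 2³¹, so any artifact is
  reproducible in isolation. Seeded entry points save and restore the
  caller's RNG state.
* Pixel values are quantized to 8 bits at generation, so PNG round trips are
  bit-exact; mask files are RGB PNGs carrying exactly the class palette
  colors (the offline environment has no palette-indexed PNG writer), with
  out-of-palette colors rejected on read.
* Coordinates are 0-based (row, col) in all reported origins; matrices are
  1-based internally, top-left origin.
* Report CSVs print 4 decimals; machine JSON keeps full precision.

## Known limitations

* No photorealism: no camera optics, illumination artifacts, vessel trees, or
  six-field mosaic geometry; the color-threshold reference predictor is a
  stand-in, not a model.
* Pixel-level quality scores (Dice/IoU) are deliberately absent — the
  protocol evaluates at component level only.
* The ICC is count-based; agreement on lesion extent is not measured.
* The rule-based grader ignores venous beading and vitreous hemorrhage
  (not segmented classes here), and level 2's "more than MA" criterion is
  implemented as presence of HEM, the unambiguous computable reading.
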