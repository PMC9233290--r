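# fundusseg

Lesion-level detection evaluation, annotator agreement, overlapping-tile
inference, and rule-based ICDR grading for (six-field) retinal fundus images
— with a seeded synthetic data generator so the whole pipeline runs end to
end without clinical data or a trained network.

## Who this is for

Groups building or evaluating retinal-lesion segmentation models for
diabetic retinopathy (DR) screening. Such models segment seven lesion
classes — microaneurysms (MA), hemorrhages (HEM), cotton wool spots (CWS),
hard exudates (HE), photocoagulation scars (PC), intraretinal microvascular
abnormalities (IRMA), neovascularizations (NV) — and are judged not on pixel
scores but on *detecting individual abnormalities*, then used to improve
whole-image ICDR grading via presegmentation (superimposing the color-coded
mask on the image before classification). This package implements that
entire evaluation protocol as a library plus CLI.

## What it computes

* **Lesion-level detection** (`match_lesions`, `detection_metrics`): connected
  components matched by one-or-more-pixel same-class overlap; per class
  precision = tp/(tp+fp) over predicted components, recall = tp/(tp+fn) over
  reference components, F1 their harmonic mean, plus unweighted means over
  the 7 classes. `adjusted_precision` is the class-agnostic variant.
* **Image-level detection** (`image_level_detection`) and both confusion
  breakdowns: which structures false-positive components overlap
  (`fp_confusion`) and what false-positive images actually contain
  (`image_fp_cooccurrence`).
* **Annotator agreement** (`icc`, `annotator_agreement`): ICC(2,1) on
  per-image lesion counts,
  (MS_R − MS_E) / (MS_R + (k−1)MS_E + k/n(MS_C − MS_E)).
* **Tiled inference** (`tiled_predict`, `fuse_heads`): overlapping tiles with
  edge-margin cropping, exactly equivalent to whole-image prediction for any
  pixelwise predictor; multi-head fusion by argmax of the mean softmax.
* **Grading** (`rule_grade`, `quadratic_weighted_kappa`, `macro_auc`,
  `per_class_accuracy`): ICDR level from lesion presence (NV/PC → 4,
  IRMA → 3, HEM → 2, MA → 1), 5×5 confusion tables, quadratic weighted kappa
  κ = 1 − ΣwO/ΣwE with w_ij = (i−j)²/16, macro one-vs-rest AUC.
* **Synthetic data** (`generate_fundus_image`, `second_annotator`,
  `corrupt_as_model`, `split_dataset`): seeded fundus-like images with
  grade-consistent lesion masks, a noisier simulated second annotator,
  corrupted "model outputs", and patient-exclusive NV-stratified splits.

See `vignettes/fundusseg-methods.Rmd` for the full model description,
parameter conventions, and what the synthetic world does and does not
establish.

## Worked example

```r
library(fundusseg)
spec <- image_spec(320, 320)
ds <- synthesize_dataset(8, spec, seed = 7, grades = c(0,1,2,2,3,3,4,4))
refs <- lapply(ds, `[[`, "mask")

# an imperfect "model": drops 20% of components, confuses IRMA with NV
params <- corruption_params(drop_rate = 0.2, type_swap = c("IRMA->NV" = 0.3))
preds <- lapply(ds, function(im)
  corrupt_as_model(im, params, derive_seed(7, im$image_id)))

cts <- Reduce(function(a, b) {a$tp<-a$tp+b$tp; a$fp<-a$fp+b$fp; a$fn<-a$fn+b$fn; a},
              Map(match_lesions, preds, refs))
detection_metrics(cts)
#> Detection metrics (lesion level)
#>   cls precision recall     f1
#>    MA    1.0000 0.8088 0.8943
#>   HEM    1.0000 0.9091 0.9524
#>   CWS    1.0000 0.8000 0.8889
#>    HE    1.0000 0.8824 0.9375
#>    PC    1.0000 1.0000 1.0000
#>  IRMA    1.0000 0.6429 0.7826
#>    NV    0.7143 1.0000 0.8333
#>  Mean    0.9592 0.8633 0.8984
```

Recall drops where components were dropped; NV precision drops because
swapped IRMA components now masquerade as NV — visible in the confusion
attribution and in the grading metrics:

```r
conf_tab <- Reduce(`+`, Map(fp_confusion, preds, refs))
conf_tab["NV", "IRMA"]   # false-positive NV overlapping reference IRMA
#> [1] 2

ref_g <- vapply(ds, `[[`, integer(1), "grade")
conf <- grading_confusion(vapply(preds, rule_grade, integer(1)), ref_g)
quadratic_weighted_kappa(conf)
#> [1] 0.9668874
per_class_accuracy(conf)$mean
#> [1] 0.9
```

One level-3 image was graded 4 (its IRMA became NV), costing κ and per-class
accuracy exactly as the protocol intends.

## Command line

```sh
Rscript -e 'fundusseg::fundus_cli()' synthesize --out ds --n 60 --seed 1
Rscript -e 'fundusseg::fundus_cli()' detect-eval --pred ds/model --ref ds/masks --out report
Rscript -e 'fundusseg::fundus_cli()' agreement --a ds/masks --b ds/masks2 --out icc.csv
Rscript -e 'fundusseg::fundus_cli()' grade-eval --pred-grades pred.csv --ref-grades ds/grades.csv --out grading
Rscript -e 'fundusseg::fundus_cli()' preprocess --image ds/images/img-00001.png --mask ds/masks/img-00001.png --out pre.png --size 598
```

(`inst/cli/fundusseg` wraps the same entry point.)

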