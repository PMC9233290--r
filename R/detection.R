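#' Lesion-level detection counts by one-pixel-overlap matching
#'
#' Matches individual abnormalities (connected components) between a predicted
#' and a reference mask, class by class. A predicted component counts as a
#' true positive when one or more of its pixels overlap one or more pixels of
#' a same-class abnormality in the reference; otherwise it is a false
#' positive. A reference component none of whose pixels are covered by a
#' same-class prediction is a false negative. Matching is one-to-many: a
#' single predicted component overlapping several reference components yields
#' one true positive on the prediction side while marking every overlapped
#' reference component as detected, so precision is computed over predicted
#' components and recall over reference components.
#'
#' @param pred,ref integer label masks of identical shape.
#' @param connectivity pixel adjacency (4 or 8, default 8).
#' @return a `detection_counts` data frame with columns `cls`, `tp`, `fp`,
#'   `fn` (one row per lesion class) and attribute `level = "lesion"`.
#' @seealso [detection_metrics()], [adjusted_precision()], [fp_confusion()]
#' @export
match_lesions <- function(pred, ref, connectivity = 8) {
  .check_mask(pred, "pred"); .check_mask(ref, "ref")
  .check_same_shape(pred, ref)
  lab_p <- .label_lesions(pred, connectivity)
  lab_r <- .label_lesions(ref, connectivity)
  out <- data.frame(cls = .LESION_CLASSES, tp = 0L, fp = 0L, fn = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(.LESION_CLASSES)) {
    code <- .ALL_LABELS[[.LESION_CLASSES[i]]]
    p_idx <- which(pred == code)
    r_idx <- which(ref == code)
    n_pred <- length(unique(lab_p[p_idx]))
    n_ref <- length(unique(lab_r[r_idx]))
    hit_pred <- length(unique(lab_p[r_idx][pred[r_idx] == code]))
    hit_ref <- length(unique(lab_r[p_idx][ref[p_idx] == code]))
    out$tp[i] <- hit_pred
    out$fp[i] <- n_pred - hit_pred
    out$fn[i] <- n_ref - hit_ref
  }
  structure(out, level = "lesion", class = c("detection_counts", "data.frame"))
}

#' Precision, recall and F1 from detection counts
#'
#' Computes per-class precision `tp/(tp+fp)`, recall `tp/(tp+fn)` and the F1
#' score (harmonic mean of the two), plus an unweighted arithmetic mean row
#' over the seven lesion classes. A class with no predicted components has
#' undefined precision (and F1); undefined values are reported as `NA`,
#' excluded from the mean, and flagged in the `undefined` attribute.
#'
#' @param counts a `detection_counts` data frame from [match_lesions()] or
#'   [image_level_detection()], or any data frame with columns `cls`, `tp`,
#'   `fp`, `fn`.
#' @return a `metric_table` data frame with columns `cls`, `precision`,
#'   `recall`, `f1`; the final row `Mean` holds the unweighted means.
#' @examples
#' cts <- data.frame(cls = lesion_classes(), tp = 5, fp = 2, fn = 1)
#' detection_metrics(cts)
#' @export
detection_metrics <- function(counts) {
  stopifnot(all(c("cls", "tp", "fp", "fn") %in% names(counts)))
  if (any(counts$tp < 0 | counts$fp < 0 | counts$fn < 0))
    stop("counts must be nonnegative")
  prec <- ifelse(counts$tp + counts$fp > 0, counts$tp / (counts$tp + counts$fp), NA_real_)
  rec <- ifelse(counts$tp + counts$fn > 0, counts$tp / (counts$tp + counts$fn), NA_real_)
  f1 <- ifelse(!is.na(prec) & !is.na(rec) & (prec + rec) > 0,
               2 * prec * rec / (prec + rec),
               ifelse(!is.na(prec) & !is.na(rec), 0, NA_real_))
  tab <- data.frame(cls = c(counts$cls, "Mean"),
                    precision = c(prec, metric_mean(prec)),
                    recall = c(rec, metric_mean(rec)),
                    f1 = c(f1, metric_mean(f1)),
                    stringsAsFactors = FALSE)
  undef <- counts$cls[is.na(prec) | is.na(rec)]
  structure(tab, undefined = undef, level = attr(counts, "level"),
            class = c("metric_table", "data.frame"))
}

#' Unweighted mean over defined per-class metric values
#'
#' The summary convention used for all per-class detection tables: the
#' arithmetic mean over the lesion classes whose value is defined (`NA`
#' values, e.g. precision of a class never predicted, are excluded).
#'
#' @param x numeric vector of per-class metric values.
#' @return mean of non-`NA` entries (NaN when all are `NA`).
#' @examples
#' metric_mean(c(0.67, 0.74, 0.46, 0.61, 0.84, 0.67, 0.77)) # 0.68
#' @export
metric_mean <- function(x) mean(x[!is.na(x)])

#' Class-agnostic (adjusted) precision
#'
#' Precision where a predicted component counts as a true positive when it
#' overlaps reference abnormality pixels of any class, not only its own --
#' the binary detect-anything reading of the task. Adjusted precision is
#' never below the standard per-class precision.
#'
#' @inheritParams match_lesions
#' @return named numeric vector of adjusted precision per lesion class (`NA`
#'   for classes with no predicted components), with attributes `tp` and `n`
#'   holding the per-class numerator (any-class-overlap true positives) and
#'   denominator (predicted components), so values can be pooled over many
#'   images.
#' @export
adjusted_precision <- function(pred, ref, connectivity = 8) {
  .check_mask(pred, "pred"); .check_mask(ref, "ref")
  .check_same_shape(pred, ref)
  lab_p <- .label_lesions(pred, connectivity)
  ref_lesion <- ref >= .ALL_LABELS[["MA"]]
  out <- setNames(rep(NA_real_, length(.LESION_CLASSES)), .LESION_CLASSES)
  tp <- n <- setNames(integer(length(.LESION_CLASSES)), .LESION_CLASSES)
  hit_ids <- unique(lab_p[ref_lesion & lab_p > 0L])
  for (cls in .LESION_CLASSES) {
    code <- .ALL_LABELS[[cls]]
    ids <- unique(lab_p[pred == code])
    n[cls] <- length(ids)
    tp[cls] <- sum(ids %in% hit_ids)
    if (length(ids) > 0)
      out[cls] <- tp[cls] / n[cls]
  }
  structure(out, tp = tp, n = n)
}

#' Image-level detection of abnormality presence
#'
#' Evaluates, per lesion class, whether each image was correctly identified
#' as containing at least one abnormality of that class. For every class each
#' image contributes exactly one of: a true positive (predicted and annotated),
#' a false positive (predicted but not annotated), a false negative (annotated
#' but not predicted), or a true negative (neither, contributing no count).
#'
#' @param preds,refs aligned lists of label masks (same length, element `i`
#'   of each referring to the same image).
#' @return list with `counts` (a `detection_counts` data frame, level
#'   `"image"`) and `metrics` (its [detection_metrics()] table).
#' @export
image_level_detection <- function(preds, refs) {
  .check_aligned(preds, refs)
  pres_p <- t(vapply(preds, .class_presence, logical(length(.LESION_CLASSES))))
  pres_r <- t(vapply(refs, .class_presence, logical(length(.LESION_CLASSES))))
  counts <- data.frame(cls = .LESION_CLASSES,
                       tp = as.integer(colSums(pres_p & pres_r)),
                       fp = as.integer(colSums(pres_p & !pres_r)),
                       fn = as.integer(colSums(!pres_p & pres_r)),
                       stringsAsFactors = FALSE)
  counts <- structure(counts, level = "image",
                      class = c("detection_counts", "data.frame"))
  list(counts = counts, metrics = detection_metrics(counts))
}

.class_presence <- function(mask) {
  codes <- .ALL_LABELS[.LESION_CLASSES]
  vapply(codes, function(code) any(mask == code), logical(1))
}

.check_aligned <- function(preds, refs) {
  if (!is.list(preds) || !is.list(refs) || length(preds) != length(refs))
    stop("preds and refs must be lists of equal length, aligned by image")
  invisible(TRUE)
}

#' Confusion attribution of predicted components
#'
#' Attributes every predicted component to exactly one reference structure:
#' its own class when a same-class overlap exists (the diagonal, equal to the
#' lesion-level true positives), otherwise the reference lesion class with
#' the largest pixel overlap (ties broken by canonical class order), and
#' otherwise background (BG; optic-disc pixels count as background).
#'
#' @inheritParams match_lesions
#' @return integer matrix, rows = predicted lesion class, columns = lesion
#'   classes plus `BG`; row sums equal the number of predicted components of
#'   each class.
#' @export
fp_confusion <- function(pred, ref, connectivity = 8) {
  .check_mask(pred, "pred"); .check_mask(ref, "ref")
  .check_same_shape(pred, ref)
  lab_p <- .label_lesions(pred, connectivity)
  cols <- c(.LESION_CLASSES, "BG")
  out <- matrix(0L, nrow = length(.LESION_CLASSES), ncol = length(cols),
                dimnames = list(.LESION_CLASSES, cols))
  n_comp <- max(lab_p)
  if (n_comp == 0L) return(out)
  idx <- which(lab_p > 0L)
  comp_id <- lab_p[idx]
  pred_cls <- pred[idx]
  ref_cls <- ref[idx]
  ref_cls[ref_cls == .ALL_LABELS[["OPTIC_DISC"]]] <- 0L
  # overlap counts per (component, reference class)
  first <- !duplicated(comp_id)
  comp_pred <- setNames(pred_cls[first], comp_id[first])
  for (cid in as.integer(names(comp_pred))) {
    sel <- comp_id == cid
    pcls <- names(.ALL_LABELS)[match(comp_pred[[as.character(cid)]], .ALL_LABELS)]
    rc <- ref_cls[sel]
    if (any(rc == comp_pred[[as.character(cid)]])) {
      out[pcls, pcls] <- out[pcls, pcls] + 1L
      next
    }
    rc <- rc[rc > 0L]
    if (length(rc) == 0L) {
      out[pcls, "BG"] <- out[pcls, "BG"] + 1L
    } else {
      tab <- table(factor(names(.ALL_LABELS)[match(rc, .ALL_LABELS)],
                          levels = .LESION_CLASSES))
      best <- names(tab)[which.max(tab)] # ties: first in canonical order
      out[pcls, best] <- out[pcls, best] + 1L
    }
  }
  out
}

#' Image-level false-positive co-occurrence table
#'
#' For each lesion class, tabulates the image-level true positives and breaks
#' down the falsely positive images (class predicted, but absent from the
#' reference) by which other abnormality classes those images do contain; the
#' `NA` column counts falsely positive images whose reference contains no
#' abnormalities at all.
#'
#' @inheritParams image_level_detection
#' @return integer matrix, rows = predicted lesion class, columns = `TP`,
#'   the seven lesion classes, and `NA`.
#' @export
image_fp_cooccurrence <- function(preds, refs) {
  .check_aligned(preds, refs)
  pres_p <- t(vapply(preds, .class_presence, logical(length(.LESION_CLASSES))))
  pres_r <- t(vapply(refs, .class_presence, logical(length(.LESION_CLASSES))))
  colnames(pres_p) <- colnames(pres_r) <- .LESION_CLASSES
  cols <- c("TP", .LESION_CLASSES, "NA")
  out <- matrix(0L, nrow = length(.LESION_CLASSES), ncol = length(cols),
                dimnames = list(.LESION_CLASSES, cols))
  for (cls in .LESION_CLASSES) {
    out[cls, "TP"] <- sum(pres_p[, cls] & pres_r[, cls])
    fp_imgs <- which(pres_p[, cls] & !pres_r[, cls])
    for (i in fp_imgs) {
      others <- .LESION_CLASSES[pres_r[i, ]]
      if (length(others) == 0L) out[cls, "NA"] <- out[cls, "NA"] + 1L
      else out[cls, others] <- out[cls, others] + 1L
    }
  }
  out
}

#' Relative improvement of a metric, in percent
#'
#' `100 * (new - old) / old`, reported to one decimal -- the convention used
#' when comparing two models (or a model and an expert) on the same metric.
#'
#' @param new_value,old_value metric values; `old_value` must be positive.
#' @return percent change, rounded to one decimal.
#' @examples
#' relative_improvement(0.67, 0.47) # 42.5
#' @export
relative_improvement <- function(new_value, old_value) {
  if (any(old_value <= 0)) stop("old_value must be positive")
  round(100 * (new_value - old_value) / old_value, 1)
}

#' @export
print.detection_counts <- function(x, ...) {
  cat(sprintf("Detection counts (%s level)\n", attr(x, "level") %||% "lesion"))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
print.metric_table <- function(x, ...) {
  lvl <- attr(x, "level")
  cat(sprintf("Detection metrics%s\n",
              if (!is.null(lvl)) paste0(" (", lvl, " level)") else ""))
  y <- x
  for (cn in c("precision", "recall", "f1")) y[[cn]] <- round(y[[cn]], 4)
  print.data.frame(y, row.names = FALSE)
  un <- attr(x, "undefined")
  if (length(un))
    cat("undefined (excluded from mean):", paste(un, collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
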