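#' Crop the black border around the retina
#'
#' Returns the tight bounding box of pixels whose maximum channel intensity
#' exceeds `threshold`, removing the black frame around the circular retina
#' so that subsequent downsampling spends its resolution on tissue. The
#' operation is idempotent.
#'
#' @param image H x W x 3 array in \[0, 1\] (or a single-channel matrix).
#' @param threshold intensity above which a pixel counts as non-border.
#' @return cropped image, with attribute `bbox` = `c(row0, row1, col0, col1)`
#'   (1-based, inclusive) locating the crop in the input.
#' @export
crop_border <- function(image, threshold = 0.02) {
  is_arr <- length(dim(image)) == 3
  mx <- if (is_arr) pmax(image[, , 1], image[, , 2], image[, , 3]) else image
  keep_r <- which(apply(mx > threshold, 1, any))
  keep_c <- which(apply(mx > threshold, 2, any))
  if (!length(keep_r) || !length(keep_c))
    stop("image is entirely below the border threshold; nothing to crop to")
  bbox <- c(min(keep_r), max(keep_r), min(keep_c), max(keep_c))
  out <- if (is_arr) image[bbox[1]:bbox[2], bbox[3]:bbox[4], , drop = FALSE]
  else image[bbox[1]:bbox[2], bbox[3]:bbox[4], drop = FALSE]
  attr(out, "bbox") <- bbox
  out
}

#' Superimpose a lesion mask on a fundus image
#'
#' Replaces the color of every lesion pixel with its class color, producing
#' the presegmented image on which a downstream grading model (or here, the
#' rule-based grader's preprocessing demonstration) operates. Background and
#' optic-disc pixels are untouched; the input image is not modified.
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @param mask integer label mask of matching shape.
#' @param palette color matrix as from [class_palette()].
#' @param alpha opacity of the overlay in (0, 1\]; the default 1 paints
#'   solid color.
#' @return the recolored image array.
#' @export
superimpose_mask <- function(image, mask, palette = class_palette(), alpha = 1) {
  .check_mask(mask)
  .check_same_shape(image, mask, c("image", "mask"))
  stopifnot(alpha > 0, alpha <= 1)
  out <- image
  for (cls in .LESION_CLASSES) {
    idx <- which(mask == .ALL_LABELS[[cls]])
    if (!length(idx)) next
    col <- palette[cls, ]
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[idx] <- (1 - alpha) * plane[idx] + alpha * col[ch]
      out[, , ch] <- plane
    }
  }
  out
}

# exact area-overlap resampling weights from src to dst samples
.area_weights <- function(src, dst) {
  ratio <- src / dst
  w <- matrix(0, dst, src)
  for (i in seq_len(dst)) {
    lo <- (i - 1) * ratio
    hi <- i * ratio
    j0 <- floor(lo) + 1
    j1 <- ceiling(hi)
    for (j in j0:min(j1, src)) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) w[i, j] <- ov / ratio
    }
  }
  w
}

#' Deterministic area-based resampling
#'
#' Resizes an image by exact pixel-area averaging (box filter): each output
#' pixel is the mean of the source area it covers. Downsampling by an integer
#' factor reduces to block averaging; upsampling replicates with fractional
#' blending. Aspect ratio is not preserved -- the image is resized to the
#' requested (square or not) target, mirroring a fixed network input size.
#'
#' @param image H x W x 3 array (or matrix).
#' @param width,height target size in pixels (at least 8).
#' @return resized array of shape `height x width (x 3)`.
#' @export
resize_area <- function(image, width, height = width) {
  stopifnot(width >= 8, height >= 8)
  d <- dim(image)
  if (d[1] == height && d[2] == width) return(image)
  wr <- .area_weights(d[1], height)
  wc <- .area_weights(d[2], width)
  if (length(d) == 3) {
    out <- array(0, c(height, width, d[3]))
    for (ch in seq_len(d[3])) out[, , ch] <- wr %*% image[, , ch] %*% t(wc)
    out
  } else {
    wr %*% image %*% t(wc)
  }
}

#' Presegmentation preprocessing for a grading model
#'
#' The preprocessing chain applied before full-scale grading: crop the black
#' border around the retina, superimpose the color-coded lesion mask, and
#' resize (area resampling) to the fixed square network input size.
#'
#' @param image H x W x 3 array.
#' @param mask matching label mask (cropped identically to the image).
#' @param size square output edge in pixels (default 598).
#' @param threshold border threshold, see [crop_border()].
#' @param palette,alpha overlay options, see [superimpose_mask()].
#' @return `size x size x 3` array.
#' @export
preprocess_presegmentation <- function(image, mask, size = 598,
                                       threshold = 0.02,
                                       palette = class_palette(), alpha = 1) {
  cropped <- crop_border(image, threshold)
  bb <- attr(cropped, "bbox")
  mask_c <- mask[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE]
  resize_area(superimpose_mask(cropped, mask_c, palette, alpha), size, size)
}

#' Rule-based ICDR grade from a lesion mask
#'
#' Assigns the five-level ICDR severity grade implied by which lesion classes
#' are present: level 4 if any neovascularization (NV) or photocoagulation
#' scar (PC, treated proliferative disease) is present; else level 3 if any
#' IRMA; else level 2 if any hemorrhage; else level 1 if any microaneurysm;
#' else level 0. Hard exudates and cotton wool spots do not raise the DR
#' grade (they indicate other diabetic eye disease), though they are
#' segmented and may be present at any level. The rule is monotone: adding
#' lesions never lowers the grade.
#'
#' @param mask integer label mask, or a named per-class count/presence vector
#'   (names among the lesion classes).
#' @return integer grade 0..4.
#' @examples
#' rule_grade(c(MA = 3, HEM = 0)) # 1
#' @export
rule_grade <- function(mask) {
  if (is.matrix(mask)) {
    .check_mask(mask)
    present <- vapply(.LESION_CLASSES,
                      function(cls) any(mask == .ALL_LABELS[[cls]]), logical(1))
  } else {
    stopifnot(!is.null(names(mask)))
    present <- setNames(rep(FALSE, length(.LESION_CLASSES)), .LESION_CLASSES)
    known <- intersect(names(mask), .LESION_CLASSES)
    present[known] <- mask[known] > 0
  }
  if (present[["NV"]] || present[["PC"]]) return(4L)
  if (present[["IRMA"]]) return(3L)
  if (present[["HEM"]]) return(2L)
  if (present[["MA"]]) return(1L)
  0L
}

#' Grading confusion matrix
#'
#' @param pred_levels,ref_levels aligned integer vectors of ICDR levels
#'   (0..4).
#' @return 5 x 5 integer matrix; rows = reference level, columns = predicted
#'   level, dimnames `"0"`..`"4"`.
#' @export
grading_confusion <- function(pred_levels, ref_levels) {
  if (length(pred_levels) != length(ref_levels))
    stop("pred_levels and ref_levels must be aligned and of equal length")
  if (!all(pred_levels %in% 0:4) || !all(ref_levels %in% 0:4))
    stop("ICDR levels must be integers in 0..4")
  tab <- table(factor(ref_levels, levels = 0:4),
               factor(pred_levels, levels = 0:4))
  m <- matrix(as.integer(tab), 5, 5, dimnames = list(ref = 0:4, pred = 0:4))
  m
}

#' Per-class grading accuracy
#'
#' Accuracy for reference level `i` is the fraction of level-`i` images
#' predicted as level `i` (the diagonal over the row sum). Levels with no
#' reference images are reported `NA`, excluded from the mean and flagged.
#'
#' @param conf confusion matrix from [grading_confusion()].
#' @return list with `per_class` (5 values, possibly `NA`), `mean`
#'   (unweighted over defined classes), and `empty_classes`.
#' @export
per_class_accuracy <- function(conf) {
  stopifnot(is.matrix(conf), all(dim(conf) == 5))
  if (sum(conf) == 0) stop("empty confusion matrix")
  rs <- rowSums(conf)
  acc <- ifelse(rs > 0, diag(conf) / rs, NA_real_)
  names(acc) <- rownames(conf) %||% as.character(0:4)
  list(per_class = acc, mean = mean(acc[!is.na(acc)]),
       empty_classes = names(acc)[is.na(acc)])
}

#' Quadratic weighted kappa
#'
#' Chance-corrected agreement for ordinal labels with squared-distance
#' weights: \eqn{\kappa = 1 - \sum w O / \sum w E}, where
#' \eqn{w_{ij} = (i-j)^2 / (k-1)^2}, `O` is the observed confusion matrix and
#' `E` the outer product of its marginals scaled to the same total. Perfect
#' agreement gives 1; chance-level agreement 0.
#'
#' @param conf square confusion matrix of counts (rows reference, columns
#'   predicted).
#' @return kappa in \[-1, 1\], or `NA` with a warning when the expected
#'   disagreement is zero (degenerate marginals).
#' @export
quadratic_weighted_kappa <- function(conf) {
  stopifnot(is.matrix(conf), nrow(conf) == ncol(conf))
  n <- sum(conf)
  if (n <= 0) stop("confusion matrix must contain at least one count")
  k <- nrow(conf)
  idx <- seq_len(k) - 1
  w <- outer(idx, idx, function(i, j) (i - j)^2 / (k - 1)^2)
  e <- outer(rowSums(conf), colSums(conf)) / n
  denom <- sum(w * e)
  if (denom == 0) {
    warning("degenerate marginals: quadratic weighted kappa undefined")
    return(NA_real_)
  }
  1 - sum(w * conf) / denom
}

#' Macro-averaged one-vs-rest ROC AUC
#'
#' For each reference level present, computes the area under the ROC curve of
#' that level's score column against the binary indicator of the level
#' (one-vs-rest), using the rank statistic with midranks for ties, then
#' averages unweighted over the levels present.
#'
#' @param scores numeric matrix, rows = images, 5 columns = per-level scores
#'   (each row nonnegative, summing to 1 within 1e-6).
#' @param ref_levels integer vector of reference levels 0..4; at least two
#'   distinct levels required.
#' @return macro-average AUC in \[0, 1\].
#' @export
macro_auc <- function(scores, ref_levels) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 5, nrow(scores) == length(ref_levels),
            all(ref_levels %in% 0:4))
  if (any(scores < -1e-9) || any(abs(rowSums(scores) - 1) > 1e-6))
    stop("each score row must be nonnegative and sum to 1")
  lv <- sort(unique(ref_levels))
  if (length(lv) < 2)
    stop("macro AUC requires at least two distinct reference levels")
  aucs <- vapply(lv, function(l) {
    pos <- ref_levels == l
    r <- rank(scores[, l + 1], ties.method = "average")
    n1 <- sum(pos); n0 <- sum(!pos)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  mean(aucs)
}

#' Smooth per-level scores from a rule-based grade
#'
#' Converts the hard rule-based grade of a mask into a smooth 5-level score
#' vector (a discretized Gaussian bump centered on the grade), suitable for
#' ROC analysis; the argmax always equals the rule-based grade.
#'
#' @param mask label mask or named count vector, see [rule_grade()].
#' @param sharpness decay of scores with ordinal distance from the grade.
#' @return numeric vector of 5 scores summing to 1.
#' @export
grade_scores <- function(mask, sharpness = 2) {
  g <- rule_grade(mask)
  s <- exp(-sharpness * (0:4 - g)^2)
  s / sum(s)
}
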