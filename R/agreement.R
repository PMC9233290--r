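#' Per-image, per-class lesion counts
#'
#' Counts connected components of each lesion class in each mask -- the
#' per-image summary on which inter-annotator agreement is quantified.
#'
#' @param masks list of label masks.
#' @param connectivity pixel adjacency (4 or 8).
#' @return integer matrix, rows = images, columns = the seven lesion classes.
#' @export
lesion_counts <- function(masks, connectivity = 8) {
  stopifnot(is.list(masks))
  out <- t(vapply(masks, .component_counts, connectivity = connectivity,
                  FUN.VALUE = setNames(integer(length(.LESION_CLASSES)),
                                       .LESION_CLASSES)))
  rownames(out) <- names(masks) %||% NULL
  out
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC computed from
#' the classical mean-squares decomposition:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the row (subject), column
#' (rater) and residual mean squares of the n x k table. This is the
#' conventional form for interchangeable raters measured once; other forms
#' are available via `form`.
#'
#' @param counts numeric matrix, rows = subjects (images), columns = raters.
#' @param form `"ICC2,1"` (default, absolute agreement) or `"ICC3,1"`
#'   (consistency; rater effect excluded).
#' @return the ICC estimate, or `NA` with a warning when total variance is
#'   zero (agreement undefined).
#' @examples
#' m <- cbind(rater1 = c(1, 2, 3, 4), rater2 = c(3, 4, 5, 6))
#' icc(m)
#' @export
icc <- function(counts, form = c("ICC2,1", "ICC3,1")) {
  form <- match.arg(form)
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("counts must have at least 2 subjects and 2 raters")
  if (anyNA(counts)) stop("counts must not contain NA")
  n <- nrow(counts); k <- ncol(counts)
  grand <- mean(counts)
  if (all(counts == counts[1])) {
    warning("zero total variance: ICC undefined")
    return(NA_real_)
  }
  row_m <- rowMeans(counts)
  col_m <- colMeans(counts)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((counts - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (form == "ICC2,1")
    (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  else
    (msr - mse) / (msr + (k - 1) * mse)
}

#' Agreement between two annotators over a mask set
#'
#' Convenience wrapper: counts lesions per image for both annotators and
#' returns the per-class ICC.
#'
#' @param masks_a,masks_b aligned lists of label masks from two annotators.
#' @param connectivity pixel adjacency.
#' @param form ICC form, see [icc()].
#' @return named numeric vector of ICC per lesion class (`NA` where
#'   undefined).
#' @export
annotator_agreement <- function(masks_a, masks_b, connectivity = 8,
                                form = "ICC2,1") {
  .check_aligned(masks_a, masks_b)
  ca <- lesion_counts(masks_a, connectivity)
  cb <- lesion_counts(masks_b, connectivity)
  vapply(.LESION_CLASSES, function(cls) {
    m <- cbind(ca[, cls], cb[, cls])
    if (all(m == m[1])) return(NA_real_)
    icc(m, form)
  }, numeric(1))
}
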