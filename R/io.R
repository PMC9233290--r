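#' Read and write label masks as palette-coded PNG
#'
#' Masks are stored as RGB PNG files in which every pixel carries exactly the
#' fixed class color of its label (see [class_palette()]; background black,
#' optic disc gray). Writing then reading (or reading then writing) is
#' bit-exact; a file containing any color outside the palette is rejected
#' with the offending color and pixel position.
#'
#' @param mask integer label mask.
#' @param path file path.
#' @param palette color matrix as from [class_palette()].
#' @return `read_mask()` returns the integer label matrix; `write_mask()`
#'   returns `path` invisibly.
#' @export
write_mask <- function(mask, path, palette = class_palette()) {
  .check_mask(mask)
  H <- nrow(mask); W <- ncol(mask)
  img <- array(0, c(H, W, 3))
  for (nm in names(.ALL_LABELS)) {
    idx <- which(mask == .ALL_LABELS[[nm]])
    if (!length(idx)) next
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[idx] <- palette[nm, ch]
      img[, , ch] <- plane
    }
  }
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, palette = class_palette()) {
  img <- png::readPNG(path)
  if (length(dim(img)) != 3 || dim(img)[3] < 3)
    stop("mask PNG must be RGB: ", path)
  img <- img[, , 1:3, drop = FALSE]
  key <- function(r, g, b) round(r * 255) * 65536 + round(g * 255) * 256 + round(b * 255)
  pal_key <- key(palette[, 1], palette[, 2], palette[, 3])
  px_key <- key(img[, , 1], img[, , 2], img[, , 3])
  m <- match(px_key, pal_key)
  if (anyNA(m)) {
    bad <- which(is.na(m))[1]
    stop(sprintf(
      "unknown palette entry at pixel %d of %s: rgb(%d, %d, %d) is not a class color",
      bad, path, round(img[, , 1][bad] * 255), round(img[, , 2][bad] * 255),
      round(img[, , 3][bad] * 255)))
  }
  out <- matrix(unname(.ALL_LABELS[m]), nrow(px_key), ncol(px_key))
  storage.mode(out) <- "integer"
  out
}

#' Read and write RGB fundus images as PNG
#' @param image H x W x 3 array in \[0, 1\].
#' @param path file path.
#' @return `read_image()` returns the array; `write_image()` returns `path`
#'   invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(length(dim(image)) == 3)
  png::writePNG(.clip01(image), path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' Read and write grade tables
#'
#' Grade tables are UTF-8 comma-separated files with a header and columns
#' `image_id`, `patient_id`, `grade` (ICDR level 0..4); prediction tables may
#' additionally carry per-level score columns `s0`..`s4`.
#'
#' @param grades data frame with the columns above.
#' @param path CSV file path.
#' @return `read_grades()` returns the validated data frame.
#' @export
write_grades <- function(grades, path) {
  stopifnot(all(c("image_id", "grade") %in% names(grades)))
  write.csv(grades, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grades
#' @export
read_grades <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image_id", "grade") %in% names(df)))
    stop("grade table must have columns image_id and grade: ", path)
  if (!all(df$grade %in% 0:4))
    stop("grades must be ICDR levels 0..4: ", path)
  df
}

# cheap FNV-1a content hash of a serializable object (manifest fingerprint)
.config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(raw)) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Write a reproducibility manifest
#'
#' Records the configuration, master seed and a content hash alongside any
#' generated dataset or report so a run can be reproduced exactly.
#'
#' @param config named list of run settings.
#' @param path YAML file path.
#' @param extra optional named list appended verbatim (e.g. stage timings).
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(config, path, extra = list()) {
  manifest <- c(list(package = "fundusseg",
                     version = as.character(utils::packageVersion("fundusseg")),
                     config_hash = .config_hash(config),
                     config = config), extra)
  yaml::write_yaml(manifest, path)
  invisible(manifest)
}

#' Bundled benchmark tables
#'
#' Small reference tables shipped with the package: the per-class lesion
#' annotation counts of a published six-field segmentation dataset across its
#' train/tune/test splits (`annotation_counts`), the per-level image counts
#' of a grading dataset (`grade_counts`), and the published per-class
#' detection metrics of a segmentation model and a second expert evaluated
#' against a reference annotator (`detection_benchmark`), and the summary
#' grading metrics of a classifier with and without presegmentation
#' (`grading_benchmark`). They feed the worked examples and the
#' metric-arithmetic consistency checks.
#'
#' @return named list of four data frames.
#' @export
benchmark_tables <- function() {
  dir <- system.file("extdata", package = "fundusseg", mustWork = TRUE)
  list(
    annotation_counts = read.csv(file.path(dir, "annotation_counts.csv")),
    grade_counts = read.csv(file.path(dir, "grade_counts.csv")),
    detection_benchmark = read.csv(file.path(dir, "detection_benchmark.csv")),
    grading_benchmark = read.csv(file.path(dir, "grading_benchmark.csv")))
}
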