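#' @useDynLib fundusseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rnorm rpois setNames aggregate
#' @importFrom utils read.csv write.csv
NULL

# Fixed integer label encoding of a per-pixel mask. Background is 0 and the
# optic disc 1; the seven lesion classes follow in the canonical reporting
# order used throughout (MA, HEM, CWS, HE, PC, IRMA, NV). This order is also
# the deterministic tie-break order for confusion attribution.
.LESION_CLASSES <- c("MA", "HEM", "CWS", "HE", "PC", "IRMA", "NV")
.ALL_LABELS <- c(BACKGROUND = 0L, OPTIC_DISC = 1L,
                 MA = 2L, HEM = 3L, CWS = 4L, HE = 5L,
                 PC = 6L, IRMA = 7L, NV = 8L)

#' Lesion classes and label codes
#'
#' The package encodes per-pixel annotation masks as integer matrices with a
#' fixed label set: background = 0, optic disc = 1, and the seven retinal
#' lesion classes relevant to diabetic retinopathy -- microaneurysms (MA),
#' hemorrhages (HEM), cotton wool spots (CWS), hard exudates (HE),
#' photocoagulation scars (PC), intraretinal microvascular abnormalities
#' (IRMA) and neovascularizations (NV) -- numbered 2 to 8 in that order.
#'
#' @return `lesion_classes()` returns the character vector of the seven lesion
#'   class codes in canonical order; `label_codes()` returns the named integer
#'   vector of all nine mask label values (including `BACKGROUND` and
#'   `OPTIC_DISC`).
#' @examples
#' lesion_classes()
#' label_codes()
#' @export
lesion_classes <- function() .LESION_CLASSES

#' @rdname lesion_classes
#' @export
label_codes <- function() .ALL_LABELS

#' Class code for a lesion label
#' @param cls character vector of class names (e.g. `"MA"`).
#' @return integer label value(s) used in masks.
#' @export
label_of <- function(cls) {
  bad <- setdiff(cls, names(.ALL_LABELS))
  if (length(bad)) stop("unknown class name(s): ", paste(bad, collapse = ", "))
  unname(.ALL_LABELS[cls])
}

#' Display palette for lesion classes
#'
#' Fixed color coding used when a segmentation mask is superimposed on a
#' fundus image and when masks are stored as RGB PNG files: MA green,
#' HEM magenta, CWS yellow, HE red, IRMA cyan, NV blue, PC purple; background
#' is black and the optic disc mid-gray.
#'
#' @return a 9 x 3 numeric matrix of RGB values in \[0, 1\], with row names
#'   `BACKGROUND`, `OPTIC_DISC`, and the seven lesion codes.
#' @export
class_palette <- function() {
  pal <- rbind(
    BACKGROUND = c(0, 0, 0),
    OPTIC_DISC = c(128, 128, 128),
    MA   = c(0, 255, 0),
    HEM  = c(255, 0, 255),
    CWS  = c(255, 255, 0),
    HE   = c(255, 0, 0),
    PC   = c(128, 0, 128),
    IRMA = c(0, 255, 255),
    NV   = c(0, 0, 255))
  pal / 255
}

# validate a label mask: integer matrix with values in the fixed label set
.check_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) stop(arg, " must be a matrix")
  vals <- unique(as.integer(mask))
  bad <- setdiff(vals, unname(.ALL_LABELS))
  if (length(bad))
    stop(arg, " contains unknown label value(s): ", paste(sort(bad), collapse = ", "))
  invisible(TRUE)
}

.check_same_shape <- function(a, b, what = c("pred", "ref")) {
  if (!all(dim(a)[1:2] == dim(b)[1:2]))
    stop(what[1], " and ", what[2], " must have identical dimensions (",
         paste(dim(a)[1:2], collapse = "x"), " vs ",
         paste(dim(b)[1:2], collapse = "x"), ")")
  invisible(TRUE)
}
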