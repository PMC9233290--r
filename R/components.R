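#' Extract connected lesion components from a label mask
#'
#' Decomposes a per-pixel annotation mask into individual abnormalities: one
#' component per maximal connected set of same-class lesion pixels. Background
#' and optic-disc pixels never form components; the optic disc is carried in
#' masks only as an auxiliary structure and is ignored by all detection
#' metrics.
#'
#' @param mask integer label matrix (see [label_codes()]).
#' @param connectivity pixel adjacency, 4 or 8 (default 8: diagonally touching
#'   pixels belong to one lesion).
#' @return a list of components, each a list with elements `cls` (class code
#'   string), `id` (integer, unique within the mask, in raster order), and
#'   `pixels` (integer vector of linear indices into the mask, column-major).
#'   Components are ordered by canonical class order, then raster order.
#' @seealso [match_lesions()], [lesion_counts()]
#' @export
extract_components <- function(mask, connectivity = 8) {
  .check_mask(mask)
  lab <- .label_lesions(mask, connectivity)
  if (max(lab) == 0L) return(list())
  idx <- which(lab > 0L)
  pix <- split(idx, lab[idx])
  cls_of <- vapply(pix, function(p) mask[p[1]], integer(1))
  comps <- Map(function(p, cl, id) {
    list(cls = names(.ALL_LABELS)[match(cl, .ALL_LABELS)],
         id = as.integer(id), pixels = as.integer(p))
  }, pix, cls_of, as.integer(names(pix)))
  ord <- order(match(cls_of, .ALL_LABELS),
               vapply(comps, function(co) co$id, integer(1)))
  unname(comps[ord])
}

# component labels over lesion pixels only (background/optic disc -> 0)
.label_lesions <- function(mask, connectivity = 8) {
  m <- mask
  storage.mode(m) <- "integer"
  m[m == .ALL_LABELS[["OPTIC_DISC"]]] <- 0L
  .cc_label(m, as.integer(connectivity))
}

# per-class component count for one mask, named by lesion class
.component_counts <- function(mask, connectivity = 8) {
  lab <- .label_lesions(mask, connectivity)
  counts <- setNames(integer(length(.LESION_CLASSES)), .LESION_CLASSES)
  if (max(lab) > 0L) {
    idx <- which(lab > 0L)
    first <- idx[!duplicated(lab[idx])]
    tab <- table(factor(names(.ALL_LABELS)[match(mask[first], .ALL_LABELS)],
                        levels = .LESION_CLASSES))
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}
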