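# Shared fixtures: all masks and images are built in code at test time.

LBL <- label_codes()

# mask from a list of class -> linear-index pixel sets
make_mask <- function(H, W, ..., base = 0L) {
  m <- matrix(as.integer(base), H, W)
  spots <- list(...)
  for (nm in names(spots)) m[spots[[nm]]] <- LBL[[nm]]
  m
}

rc <- function(H, r, c) (c - 1L) * H + r

# random small multi-class mask (for property tests); density of lesion
# pixels ~dens, classes drawn from the given set
random_mask <- function(H, W, dens = 0.15, classes = c("MA", "HEM", "IRMA")) {
  m <- matrix(0L, H, W)
  n <- round(dens * H * W)
  idx <- sample(H * W, n)
  m[idx] <- LBL[sample(classes, n, replace = TRUE)]
  m
}

# wrap a bare mask into a minimal annotated_image (for corruption functions)
as_annotated <- function(mask, grade = NULL, image_id = "fix", patient_id = "P0") {
  structure(list(image = array(0, c(nrow(mask), ncol(mask), 3)),
                 mask = mask,
                 grade = grade %||% rule_grade(mask),
                 image_id = image_id, patient_id = patient_id,
                 retina = list(center = c((nrow(mask) + 1) / 2,
                                          (ncol(mask) + 1) / 2),
                               radius = 0.46 * min(dim(mask)))),
            class = "annotated_image")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small spec that renders fast in tests
small_spec <- function(side = 160) {
  image_spec(side, side,
             count_ranges = list(MA = c(2, 6), HEM = c(1, 4), CWS = c(0, 1),
                                 HE = c(0, 2), PC = c(2, 5), IRMA = c(1, 3),
                                 NV = c(1, 2)))
}
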