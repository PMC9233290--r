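#' Specification for synthetic six-field-like fundus images
#'
#' Describes the geometry and lesion statistics of the synthetic images
#' produced by [generate_fundus_image()]: a dark circular retina on a black
#' frame, an optic disc, and per-class count and size ranges for the seven
#' lesion classes. All sizes are expressed in pixels at a 640-pixel reference
#' frame and scaled with `min(width, height) / 640`, so the same spec renders
#' consistently at any resolution.
#'
#' @param width,height image dimensions in pixels (at least 64).
#' @param retina_radius_fraction retina disc radius as a fraction of the
#'   smaller image dimension (must leave the disc inside the frame).
#' @param count_ranges named list of `c(min, max)` component counts drawn for
#'   each active lesion class; defaults emulate a moderately diseased eye.
#' @param size_ranges named list of `c(min, max)` component diameters
#'   (pixels, at the 640 reference scale).
#' @return an `image_spec` object.
#' @export
image_spec <- function(width = 640, height = 640,
                       retina_radius_fraction = 0.46,
                       count_ranges = NULL, size_ranges = NULL) {
  stopifnot(width >= 64, height >= 64,
            retina_radius_fraction > 0, retina_radius_fraction <= 0.5)
  def_counts <- list(MA = c(5, 15), HEM = c(3, 8), CWS = c(1, 2),
                     HE = c(1, 4), PC = c(4, 10), IRMA = c(2, 5), NV = c(1, 3))
  def_sizes <- list(MA = c(2, 5), HEM = c(6, 20), CWS = c(8, 16),
                    HE = c(3, 8), PC = c(8, 14), IRMA = c(10, 24), NV = c(12, 28))
  counts <- utils::modifyList(def_counts, count_ranges %||% list())
  sizes <- utils::modifyList(def_sizes, size_ranges %||% list())
  for (cls in .LESION_CLASSES) {
    if (any(counts[[cls]] < 0) || counts[[cls]][1] > counts[[cls]][2])
      stop("invalid count range for ", cls)
    if (any(sizes[[cls]] <= 0) || sizes[[cls]][1] > sizes[[cls]][2])
      stop("invalid size range for ", cls)
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 retina_radius_fraction = retina_radius_fraction,
                 count_ranges = counts[.LESION_CLASSES],
                 size_ranges = sizes[.LESION_CLASSES]),
            class = "image_spec")
}

# ---- low-level stamps (sets of linear indices into an H x W matrix) -------

.rc_to_idx <- function(H, r, c) (c - 1L) * H + r

.disc_idx <- function(H, W, cr, cc, rad) {
  r0 <- max(1L, as.integer(floor(cr - rad))); r1 <- min(H, as.integer(ceiling(cr + rad)))
  c0 <- max(1L, as.integer(floor(cc - rad))); c1 <- min(W, as.integer(ceiling(cc + rad)))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  d2 <- outer((rows - cr)^2, (cols - cc)^2, "+")
  sel <- which(d2 <= rad^2)
  if (!length(sel)) return(integer(0))
  rr <- rows[(sel - 1L) %% length(rows) + 1L]
  cc2 <- cols[(sel - 1L) %/% length(rows) + 1L]
  .rc_to_idx(H, rr, cc2)
}

.annulus_idx <- function(H, W, cr, cc, rout, rin) {
  outer_idx <- .disc_idx(H, W, cr, cc, rout)
  inner_idx <- .disc_idx(H, W, cr, cc, rin)
  setdiff(outer_idx, inner_idx)
}

# irregular blob: short random walk of overlapping discs (always connected:
# step length never exceeds the stamp radius)
.blob_idx <- function(H, W, cr, cc, diam) {
  r0 <- max(1.2, diam / 6)
  pos <- c(cr, cc)
  idx <- .disc_idx(H, W, pos[1], pos[2], r0)
  for (k in seq_len(6)) {
    ang <- runif(1, 0, 2 * pi)
    step <- runif(1, 0.4, 0.95) * r0
    pos <- pos + step * c(sin(ang), cos(ang))
    idx <- c(idx, .disc_idx(H, W, pos[1], pos[2], r0 * runif(1, 0.6, 1)))
  }
  unique(idx)
}

# thin vessel-like tangle: random-walk curve dilated to ~3 px thickness
.curve_idx <- function(H, W, cr, cc, extent) {
  nstep <- max(6L, as.integer(round(extent / 1.5)))
  ang <- runif(1, 0, 2 * pi)
  pos <- c(cr, cc)
  idx <- .disc_idx(H, W, pos[1], pos[2], 1.2)
  for (k in seq_len(nstep)) {
    ang <- ang + rnorm(1, 0, 0.7)
    pos <- pos + 1.5 * c(sin(ang), cos(ang))
    # keep the tangle near its seed so the stated extent is respected
    if (sqrt(sum((pos - c(cr, cc))^2)) > extent / 2) {
      back <- atan2(cr - pos[1], cc - pos[2])
      ang <- back
      pos <- pos + 1.5 * c(sin(ang), cos(ang))
    }
    idx <- c(idx, .disc_idx(H, W, pos[1], pos[2], 1.2))
  }
  unique(idx)
}

.stamp_for <- function(cls, H, W, cr, cc, diam) {
  switch(cls,
         MA = .disc_idx(H, W, cr, cc, diam / 2),
         HE = .disc_idx(H, W, cr, cc, diam / 2),
         HEM = .blob_idx(H, W, cr, cc, diam),
         CWS = .blob_idx(H, W, cr, cc, diam),
         PC = .annulus_idx(H, W, cr, cc, diam / 2, 0.5 * diam / 2),
         IRMA = .curve_idx(H, W, cr, cc, diam),
         NV = .curve_idx(H, W, cr, cc, diam),
         stop("no stamp for class ", cls))
}

# one-pixel 8-neighbourhood dilation of an index set (used to keep newly
# placed components from touching existing structures and merging)
.halo_idx <- function(H, W, idx) {
  if (!length(idx)) return(idx)
  r <- (idx - 1L) %% H + 1L
  c <- (idx - 1L) %/% H + 1L
  out <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    rr <- r + dr; cc <- c + dc
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    out <- c(out, .rc_to_idx(H, rr[ok], cc[ok]))
  }
  unique(out)
}

# ---- generator ------------------------------------------------------------

# natural-looking rendering colors (not the display palette)
.RENDER_COLORS <- list(
  OPTIC_DISC = c(0.95, 0.85, 0.55), MA = c(0.30, 0.06, 0.04),
  HEM = c(0.24, 0.05, 0.04), CWS = c(0.82, 0.80, 0.62),
  HE = c(0.92, 0.88, 0.35), PC = c(0.72, 0.62, 0.50),
  IRMA = c(0.30, 0.08, 0.06), NV = c(0.28, 0.07, 0.08))

# classes allowed / required at each grade: level 1 = MA only; level 2 adds
# HEM; level 3 adds IRMA; level 4 requires NV or PC. HE and CWS do not define
# the grade and may appear from level 2 upward (level 1 stays pure MA, its
# canonical presentation).
.grade_composition <- function(grade) {
  switch(as.character(grade),
         "0" = list(active = character(0), required = character(0)),
         "1" = list(active = "MA", required = "MA"),
         "2" = list(active = c("MA", "HEM", "HE", "CWS"), required = "HEM"),
         "3" = list(active = c("MA", "HEM", "HE", "CWS", "IRMA"), required = "IRMA"),
         "4" = list(active = c("MA", "HEM", "HE", "CWS", "IRMA", "NV", "PC"),
                    required = "NV_OR_PC"),
         stop("grade must be an integer in 0..4, got ", grade))
}

#' Generate one synthetic annotated fundus image
#'
#' Renders a seeded synthetic fundus-like image together with a pixel-level
#' lesion annotation mask whose composition is consistent with the requested
#' severity grade on the five-level ICDR scale ([rule_grade()] of the mask
#' equals `grade`). The retina is a dark shaded disc with an optic disc and
#' black surround; lesions are placed uniformly inside the retina without
#' touching each other: small dark discs (MA), irregular dark blobs (HEM),
#' soft bright patches (CWS), sharp bright deposits (HE), thin dark tangles
#' (IRMA, NV), and pale ring-shaped laser scars (PC).
#'
#' Identical `(spec, grade, seed)` reproduce the output bit for bit; pixel
#' values are quantized to 8 bits so a PNG round trip is lossless.
#'
#' @param spec an [image_spec()].
#' @param grade integer ICDR severity level, 0 to 4.
#' @param seed integer seed for this image's private random stream.
#' @param image_id,patient_id identifiers carried in the result.
#' @return an `annotated_image`: list with `image` (H x W x 3 array in
#'   \[0, 1\]), `mask` (integer label matrix), `grade`, `image_id`,
#'   `patient_id`, and `retina` (list with `center` = (row, col) and
#'   `radius`, in pixels).
#' @export
generate_fundus_image <- function(spec, grade, seed,
                                  image_id = NULL, patient_id = NULL) {
  if (!inherits(spec, "image_spec")) stop("spec must be an image_spec")
  if (length(grade) != 1 || is.na(grade) || grade != as.integer(grade) ||
      grade < 0 || grade > 4)
    stop("grade must be an integer in 0..4, got ", grade)
  grade <- as.integer(grade)
  H <- spec$height; W <- spec$width
  scale <- min(H, W) / 640
  R <- spec$retina_radius_fraction * min(H, W)
  ctr <- c((H + 1) / 2, (W + 1) / 2)

  .with_seed(seed, {
    mask <- matrix(0L, H, W)
    # optic disc: offset left or right of center, slightly above/below
    od_r <- 0.09 * min(H, W)
    od_ang <- runif(1, -0.35, 0.35) + sample(c(0, pi), 1)
    od_ctr <- ctr + 0.55 * R * c(sin(od_ang), cos(od_ang))
    mask[.disc_idx(H, W, od_ctr[1], od_ctr[2], od_r)] <- .ALL_LABELS[["OPTIC_DISC"]]

    comp <- .grade_composition(grade)
    for (cls in .LESION_CLASSES) {
      if (!(cls %in% comp$active)) next
      rng <- spec$count_ranges[[cls]]
      n <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
      if (cls %in% c("HE", "CWS") && runif(1) < 0.3) n <- 0L # optional extras
      if (identical(comp$required, cls)) n <- max(1L, n)
      if (identical(comp$required, "NV_OR_PC") && cls == "NV") n <- max(1L, n)
      if (n == 0L) next
      srng <- spec$size_ranges[[cls]] * scale
      for (k in seq_len(n)) {
        # floor at ~2 px so components stay renderable at small test sizes
        diam <- max(2.2, runif(1, srng[1], srng[2]))
        if (diam / 2 + 2 >= R)
          stop(cls, " lesion of diameter ", round(diam, 1),
               " px cannot fit the retina disc (radius ", round(R, 1), " px)")
        placed <- FALSE
        for (try in seq_len(300)) {
          rad_pos <- (R - diam / 2 - 3) * sqrt(runif(1))
          th <- runif(1, 0, 2 * pi)
          pos <- ctr + rad_pos * c(sin(th), cos(th))
          stamp <- .stamp_for(cls, H, W, pos[1], pos[2], diam)
          if (!length(stamp)) next
          if (all(mask[.halo_idx(H, W, stamp)] == 0L)) {
            mask[stamp] <- .ALL_LABELS[[cls]]
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("could not place ", cls, " component ", k,
               " inside the retina after 300 attempts")
      }
    }

    img <- .render_fundus(mask, ctr, R, H, W)
    out <- structure(list(image = img, mask = mask, grade = grade,
                          image_id = image_id %||% sprintf("img-%06d", seed %% 1000000L),
                          patient_id = patient_id,
                          retina = list(center = ctr, radius = R)),
                     class = "annotated_image")
    stopifnot(rule_grade(mask) == grade)
    out
  })
}

.render_fundus <- function(mask, ctr, R, H, W) {
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  d <- sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2)
  inside <- d <= R
  shade <- 1 - 0.25 * (d / R)^2
  base <- c(0.48, 0.20, 0.08)
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    plane <- base[ch] * shade + rnorm(H * W, 0, 0.012)
    plane[!inside] <- 0
    img[, , ch] <- plane
  }
  # paint annotated structures with per-class blend (CWS soft, rest near-opaque)
  for (nm in names(.RENDER_COLORS)) {
    idx <- which(mask == .ALL_LABELS[[nm]])
    if (!length(idx)) next
    alpha <- if (nm == "CWS") 0.6 else 0.88
    col <- .RENDER_COLORS[[nm]]
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[idx] <- (1 - alpha) * plane[idx] + alpha * col[ch]
      img[, , ch] <- plane
    }
  }
  round(.clip01(img) * 255) / 255
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf("annotated_image %s: %dx%d, grade %d, patient %s\n",
              x$image_id %||% "<unnamed>", nrow(x$mask), ncol(x$mask),
              x$grade, x$patient_id %||% "<none>"))
  cts <- .component_counts(x$mask)
  cat("components:", paste(sprintf("%s=%d", names(cts), cts), collapse = " "), "\n")
  invisible(x)
}

# ---- corruption (simulated second annotator / imperfect model output) -----

#' Corruption parameters for simulated annotators and model outputs
#'
#' Controls how a reference annotation is degraded into a plausible second
#' opinion or an imperfect segmentation-model output: whole components are
#' dropped at `drop_rate`, relabelled to a different class according to
#' `type_swap`, translated by up to `boundary_jitter` pixels, and spurious
#' components (small discs of a random class) are invented at a Poisson rate
#' of `spurious_rate` per image.
#'
#' @param drop_rate probability in \[0, 1\] that a reference component is
#'   omitted.
#' @param spurious_rate expected number of invented components per image.
#' @param type_swap either `NULL`, a named numeric vector like
#'   `c("IRMA->NV" = 0.3)`, or a full 7 x 7 row-stochastic-or-less matrix of
#'   swap probabilities (rows = source class, columns = target class).
#' @param boundary_jitter maximum absolute translation, in pixels, applied
#'   independently per surviving component.
#' @return a `corruption_params` object.
#' @export
corruption_params <- function(drop_rate = 0, spurious_rate = 0,
                              type_swap = NULL, boundary_jitter = 0) {
  stopifnot(drop_rate >= 0, drop_rate <= 1, spurious_rate >= 0,
            boundary_jitter >= 0)
  k <- length(.LESION_CLASSES)
  swap <- matrix(0, k, k, dimnames = list(.LESION_CLASSES, .LESION_CLASSES))
  if (is.matrix(type_swap)) {
    swap[rownames(type_swap), colnames(type_swap)] <- type_swap
  } else if (!is.null(type_swap)) {
    for (nm in names(type_swap)) {
      pair <- strsplit(nm, "->", fixed = TRUE)[[1]]
      if (length(pair) != 2 || !all(pair %in% .LESION_CLASSES))
        stop("type_swap entries must be named 'FROM->TO' over lesion classes: ", nm)
      swap[pair[1], pair[2]] <- type_swap[[nm]]
    }
  }
  if (any(swap < 0) || any(swap > 1) || any(rowSums(swap) > 1 + 1e-12))
    stop("type_swap probabilities must lie in [0,1] with row sums <= 1")
  structure(list(drop_rate = drop_rate, spurious_rate = spurious_rate,
                 type_swap = swap, boundary_jitter = as.integer(boundary_jitter)),
            class = "corruption_params")
}

# Shared corruption engine. The random stream is consumed in a documented,
# fixed order so the result can be replayed by an independent simulation:
# (1) one uniform per reference component (canonical order) for the drop
# decision; (2) one uniform per survivor for the class swap; (3) if jitter
# > 0, a (row, col) offset pair per survivor; (4) one Poisson draw for the
# spurious count, then per spurious component its class, size and placement.
.corrupt_mask <- function(ref, params, seed) {
  if (!inherits(ref, "annotated_image")) stop("ref must be an annotated_image")
  if (!inherits(params, "corruption_params"))
    stop("params must be a corruption_params object")
  mask <- ref$mask
  H <- nrow(mask); W <- ncol(mask)
  comps <- extract_components(mask)
  .with_seed(seed, {
    n <- length(comps)
    keep <- if (n) runif(n) >= params$drop_rate else logical(0)
    survivors <- comps[keep]
    ns <- length(survivors)
    u_swap <- if (ns) runif(ns) else numeric(0)
    offsets <- if (params$boundary_jitter > 0 && ns)
      matrix(sample(seq(-params$boundary_jitter, params$boundary_jitter),
                    2 * ns, replace = TRUE), ncol = 2)
    else matrix(0L, max(ns, 0), 2)

    out <- matrix(0L, H, W)
    od <- which(mask == .ALL_LABELS[["OPTIC_DISC"]])
    out[od] <- .ALL_LABELS[["OPTIC_DISC"]]
    for (i in seq_len(ns)) {
      cls <- survivors[[i]]$cls
      row_p <- params$type_swap[cls, ]
      if (sum(row_p) > 0) {
        cum <- cumsum(row_p)
        j <- which(u_swap[i] < cum)
        if (length(j)) cls <- .LESION_CLASSES[j[1]]
      }
      idx <- survivors[[i]]$pixels
      if (any(offsets[i, ] != 0)) {
        r <- (idx - 1L) %% H + 1L + offsets[i, 1]
        cc <- (idx - 1L) %/% H + 1L + offsets[i, 2]
        ok <- r >= 1L & r <= H & cc >= 1L & cc <= W
        idx <- .rc_to_idx(H, r[ok], cc[ok])
      }
      out[idx] <- .ALL_LABELS[[cls]]
    }
    n_sp <- rpois(1, params$spurious_rate)
    for (k in seq_len(n_sp)) {
      cls <- sample(.LESION_CLASSES, 1)
      rad <- runif(1, 2, 4)
      for (try in seq_len(100)) {
        rp <- (ref$retina$radius - rad - 3) * sqrt(runif(1))
        th <- runif(1, 0, 2 * pi)
        pos <- ref$retina$center + rp * c(sin(th), cos(th))
        stamp <- .disc_idx(H, W, pos[1], pos[2], rad)
        if (length(stamp) && all(out[.halo_idx(H, W, stamp)] == 0L)) {
          out[stamp] <- .ALL_LABELS[[cls]]
          break
        }
      }
    }
    out
  })
}

#' Simulate an independent second annotator
#'
#' Produces a degraded copy of a reference annotation emulating a second
#' human expert: some abnormalities are missed, some relabelled to a
#' similar-looking class, boundaries are jittered, and a few spurious
#' findings are invented. With all rates zero and no jitter the output equals
#' the reference mask exactly.
#'
#' @param ref an `annotated_image` (the reference annotator).
#' @param params a [corruption_params()].
#' @param seed integer seed.
#' @return an integer label mask of the same shape as `ref$mask`.
#' @export
second_annotator <- function(ref, params, seed) {
  .corrupt_mask(ref, params, seed)
}

#' Simulate imperfect segmentation-model output
#'
#' Same corruption model as [second_annotator()], but drawing from a separate
#' random stream derived from `seed`, so that for a given image the simulated
#' model's errors are independent of the simulated second annotator's.
#'
#' @inheritParams second_annotator
#' @return an integer label mask.
#' @export
corrupt_as_model <- function(ref, params, seed) {
  .corrupt_mask(ref, params, derive_seed(seed, "model-output"))
}

# ---- dataset synthesis and splitting --------------------------------------

#' Synthesize a seeded annotated dataset
#'
#' Generates `n` annotated images with patient identifiers and grades. Each
#' image is rendered from its own child seed derived from the master seed and
#' the image id, so any image can be regenerated in isolation. By default,
#' grades are drawn from a screening-like distribution dominated by level 0;
#' pass `grades` to fix the composition exactly.
#'
#' @param n number of images.
#' @param spec an [image_spec()].
#' @param seed master seed.
#' @param grades optional integer vector of length `n` of ICDR levels.
#' @param grade_probs probabilities over levels 0..4 used when `grades` is
#'   `NULL` (default approximates a screening population:
#'   0.51, 0.12, 0.20, 0.06, 0.11).
#' @param images_per_patient mean images per patient; each patient receives
#'   1 + Poisson(mean - 1) consecutive images.
#' @return list of `annotated_image` objects.
#' @export
synthesize_dataset <- function(n, spec = image_spec(), seed = 1L,
                               grades = NULL,
                               grade_probs = c(0.51, 0.12, 0.20, 0.06, 0.11),
                               images_per_patient = 3) {
  stopifnot(n >= 1, images_per_patient >= 1)
  .with_seed(derive_seed(seed, "dataset-plan"), {
    if (is.null(grades))
      grades <- sample(0:4, n, replace = TRUE, prob = grade_probs)
    stopifnot(length(grades) == n, all(grades %in% 0:4))
    patient <- character(n)
    i <- 1L; p <- 0L
    while (i <= n) {
      p <- p + 1L
      size <- 1L + rpois(1, images_per_patient - 1)
      idx <- i:min(n, i + size - 1L)
      patient[idx] <- sprintf("P%04d", p)
      i <- i + size
    }
    grades_local <- grades; patient_local <- patient
  })
  lapply(seq_len(n), function(i) {
    id <- sprintf("img-%05d", i)
    generate_fundus_image(spec, grades_local[i], derive_seed(seed, id),
                          image_id = id, patient_id = patient_local[i])
  })
}

#' Split specification
#'
#' @param fractions named or unnamed numeric vector `(train, tune, test)`
#'   summing to one.
#' @param nv_train_fraction target fraction of NV-containing images assigned
#'   to the training set (the rare proliferative class is deliberately
#'   over-represented in training).
#' @param patient_exclusive if `TRUE`, all images of a patient fall in one
#'   subset.
#' @return a `split_spec` object.
#' @export
split_spec <- function(fractions = c(train = 0.70, tune = 0.15, test = 0.15),
                       nv_train_fraction = 0.7, patient_exclusive = TRUE) {
  stopifnot(length(fractions) == 3, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-9,
            nv_train_fraction >= 0, nv_train_fraction <= 1)
  structure(list(fractions = unname(fractions),
                 nv_train_fraction = nv_train_fraction,
                 patient_exclusive = isTRUE(patient_exclusive)),
            class = "split_spec")
}

#' Split a dataset into train / tune / test
#'
#' Partitions images into three disjoint, exhaustive subsets with the target
#' size fractions, while (a) steering the stated fraction of NV-containing
#' images into the training set and (b), when `patient_exclusive`, keeping
#' every patient's images within a single subset. When the constraints cannot
#' be met exactly (e.g. one patient owns all NV images) a best-effort split
#' is returned with `warning = TRUE` and an explanatory message.
#'
#' @param items list of `annotated_image` objects, or a data frame with
#'   columns `image_id`, `patient_id`, and logical `nv`.
#' @param spec a [split_spec()].
#' @param seed integer seed for the randomized assignment.
#' @return list with character-vector elements `train`, `tune`, `test`
#'   (image ids), logical `warning`, and `message`.
#' @export
split_dataset <- function(items, spec = split_spec(), seed = 1L) {
  df <- .split_frame(items)
  if (nrow(df) < 3) stop("need at least 3 items to split")
  if (spec$patient_exclusive && any(is.na(df$patient_id) | df$patient_id == ""))
    stop("patient_exclusive split requires patient ids on every item")
  targets <- .apportion(nrow(df), spec$fractions)
  nv_total <- sum(df$nv)
  nv_target <- round(spec$nv_train_fraction * nv_total)

  .with_seed(seed, {
    assign_subset <- integer(nrow(df)) # 1 train, 2 tune, 3 test
    if (spec$patient_exclusive) {
      pats <- split(seq_len(nrow(df)), df$patient_id)
      pats <- pats[sample(length(pats))]
      nv_per <- vapply(pats, function(ix) sum(df$nv[ix]), numeric(1))
      sizes <- integer(3)
      nv_train <- 0
      # NV-owning patients first, largest NV load first: push into training
      # until the NV target is met, then fall through to deficit filling
      ord <- order(-nv_per)
      for (gi in ord) {
        ix <- pats[[gi]]
        if (nv_per[gi] > 0 && nv_train < nv_target) s <- 1L
        else s <- which.max(targets - sizes)
        assign_subset[ix] <- s
        sizes[s] <- sizes[s] + length(ix)
        if (s == 1L) nv_train <- nv_train + nv_per[gi]
      }
    } else {
      nv_idx <- sample(which(df$nv))
      other_idx <- sample(which(!df$nv))
      sizes <- integer(3)
      n_nv_train <- min(nv_target, targets[1], length(nv_idx))
      take <- seq_len(n_nv_train)
      assign_subset[nv_idx[take]] <- 1L
      sizes[1] <- n_nv_train
      rest_nv <- nv_idx[-take]
      for (i in rest_nv) {
        s <- 1L + which.max((targets - sizes)[2:3])
        assign_subset[i] <- s
        sizes[s] <- sizes[s] + 1L
      }
      for (i in other_idx) {
        s <- which.max(targets - sizes)
        assign_subset[i] <- s
        sizes[s] <- sizes[s] + 1L
      }
      nv_train <- n_nv_train
    }
    warn <- abs(nv_train - nv_target) > 1
    msg <- if (warn)
      sprintf("NV stratification infeasible: %d of %d NV images in training (target %d)",
              nv_train, nv_total, nv_target)
    else ""
    list(train = df$image_id[assign_subset == 1L],
         tune = df$image_id[assign_subset == 2L],
         test = df$image_id[assign_subset == 3L],
         warning = warn, message = msg)
  })
}

.split_frame <- function(items) {
  if (is.data.frame(items)) {
    stopifnot(all(c("image_id", "patient_id", "nv") %in% names(items)))
    return(items)
  }
  stopifnot(is.list(items), length(items) > 0)
  data.frame(
    image_id = vapply(items, function(x) x$image_id, character(1)),
    patient_id = vapply(items, function(x) x$patient_id %||% "", character(1)),
    nv = vapply(items, function(x) any(x$mask == .ALL_LABELS[["NV"]]), logical(1)),
    stringsAsFactors = FALSE)
}
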