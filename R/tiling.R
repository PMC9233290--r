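#' Tiling configuration
#'
#' Parameters of patch sampling (training) and overlapping-tile inference:
#' training patches of `patch_size` pixels are sampled on a sliding-window
#' grid with the given `stride`; full-resolution inference runs the predictor
#' on `tile_size` tiles and discards a `margin`-pixel band at every tile edge
#' (where segmentation quality degrades), stepping tiles by
#' `tile_size - 2 * margin` so the retained interiors abut seamlessly.
#' `head_weights` carries the per-head loss weights of a multi-kernel output
#' layer; prediction fusion itself uses the unweighted mean (see
#' [fuse_heads()]).
#'
#' @param patch_size training patch edge, pixels (default 256).
#' @param tile_size inference tile edge, pixels (default 1024).
#' @param margin pixels cropped from each tile edge (default `tile_size / 8`;
#'   must be below `tile_size / 2`).
#' @param stride sliding-window step for patch sampling (default
#'   `patch_size`, i.e. non-overlapping).
#' @param head_weights positive per-head loss weights (default three heads at
#'   0.33).
#' @return a `tile_config` object.
#' @export
tile_config <- function(patch_size = 256, tile_size = 1024,
                        margin = tile_size / 8, stride = patch_size,
                        head_weights = c(0.33, 0.33, 0.33)) {
  stopifnot(patch_size >= 1, tile_size >= 1, margin >= 0,
            margin < tile_size / 2, stride >= 1, stride <= patch_size,
            all(head_weights > 0))
  structure(list(patch_size = as.integer(patch_size),
                 tile_size = as.integer(tile_size),
                 margin = as.integer(margin), stride = as.integer(stride),
                 head_weights = head_weights),
            class = "tile_config")
}

#' Augmentation parameters
#'
#' @param flip_horizontal,flip_vertical flip probabilities in \[0, 1\].
#' @param shift_max maximum absolute translation in pixels (zero-filled).
#' @param gamma_range positive `c(min, max)` range of the gamma exponent
#'   applied to the image only (1 leaves the image unchanged).
#' @return an `augment_params` object.
#' @export
augment_params <- function(flip_horizontal = 0.5, flip_vertical = 0.5,
                           shift_max = 16, gamma_range = c(0.8, 1.2)) {
  stopifnot(flip_horizontal >= 0, flip_horizontal <= 1,
            flip_vertical >= 0, flip_vertical <= 1, shift_max >= 0,
            length(gamma_range) == 2, all(gamma_range > 0),
            gamma_range[1] <= gamma_range[2])
  structure(list(flip_horizontal = flip_horizontal,
                 flip_vertical = flip_vertical,
                 shift_max = as.integer(shift_max), gamma_range = gamma_range),
            class = "augment_params")
}

#' Sample training patches on a sliding-window grid
#'
#' Crops aligned image/mask patches at every grid origin. Origins step by
#' `cfg$stride` along each axis; a final origin flush with the image edge is
#' added when the stride does not divide evenly, so the grid always reaches
#' the image boundary. Origins are reported 0-based (row, col).
#'
#' @param img an `annotated_image` (or a list with `image` and `mask`).
#' @param cfg a [tile_config()].
#' @return list of patches, each a list with `image`, `mask`, `origin`.
#' @export
sample_patches <- function(img, cfg) {
  p <- cfg$patch_size
  H <- nrow(img$mask); W <- ncol(img$mask)
  if (p > H || p > W)
    stop("patch_size ", p, " exceeds image dimensions ", H, "x", W)
  orig_r <- unique(c(seq(0L, H - p, by = cfg$stride), H - p))
  orig_c <- unique(c(seq(0L, W - p, by = cfg$stride), W - p))
  out <- vector("list", length(orig_r) * length(orig_c))
  i <- 0L
  for (r in orig_r) for (cc in orig_c) {
    i <- i + 1L
    out[[i]] <- list(image = img$image[r + seq_len(p), cc + seq_len(p), , drop = FALSE],
                     mask = img$mask[r + seq_len(p), cc + seq_len(p), drop = FALSE],
                     origin = c(row = r, col = cc))
  }
  out
}

#' Flip an image or mask along one axis
#' @param x matrix or H x W x C array.
#' @param axis `"horizontal"` (reverse columns) or `"vertical"` (reverse rows).
#' @return flipped object; applying the same flip twice is the identity.
#' @export
flip_patch <- function(x, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  if (length(dim(x)) == 3) {
    if (axis == "horizontal") x[, rev(seq_len(ncol(x))), , drop = FALSE]
    else x[rev(seq_len(nrow(x))), , , drop = FALSE]
  } else {
    if (axis == "horizontal") x[, rev(seq_len(ncol(x))), drop = FALSE]
    else x[rev(seq_len(nrow(x))), , drop = FALSE]
  }
}

#' Translate an image or mask, filling vacated pixels
#' @param x matrix or H x W x C array.
#' @param dy,dx integer shift in rows / columns (positive = down / right).
#' @param fill fill value for vacated pixels (0 = background / black).
#' @return shifted object of identical shape.
#' @export
shift_patch <- function(x, dy, dx, fill = 0) {
  d <- dim(x)
  H <- d[1]; W <- d[2]
  out <- x
  out[] <- as.vector(fill, mode = storage.mode(x))
  src_r <- seq_len(H) - dy; src_c <- seq_len(W) - dx
  ok_r <- src_r >= 1 & src_r <= H; ok_c <- src_c >= 1 & src_c <= W
  if (any(ok_r) && any(ok_c)) {
    if (length(d) == 3)
      out[which(ok_r), which(ok_c), ] <- x[src_r[ok_r], src_c[ok_c], , drop = FALSE]
    else
      out[which(ok_r), which(ok_c)] <- x[src_r[ok_r], src_c[ok_c], drop = FALSE]
  }
  out
}

#' Randomly augment an image/mask patch pair
#'
#' Applies, under a seeded stream: horizontal and vertical flips (each with
#' its configured probability), a uniform random translation of up to
#' `shift_max` pixels (identical for image and mask, zero-filled), and a
#' gamma adjustment drawn from `gamma_range` applied to the image only.
#'
#' @param patch H x W x 3 image array in \[0, 1\].
#' @param mask_patch integer mask matrix of matching shape.
#' @param params an [augment_params()].
#' @param seed integer seed.
#' @return list with `image`, `mask`, and `ops` (the transforms applied).
#' @export
augment_patch <- function(patch, mask_patch, params, seed = NULL) {
  stopifnot(inherits(params, "augment_params"))
  .check_same_shape(patch, mask_patch, c("patch", "mask_patch"))
  .with_seed(seed, {
    ops <- list()
    if (runif(1) < params$flip_horizontal) {
      patch <- flip_patch(patch, "horizontal")
      mask_patch <- flip_patch(mask_patch, "horizontal")
      ops$flip_horizontal <- TRUE
    }
    if (runif(1) < params$flip_vertical) {
      patch <- flip_patch(patch, "vertical")
      mask_patch <- flip_patch(mask_patch, "vertical")
      ops$flip_vertical <- TRUE
    }
    if (params$shift_max > 0) {
      sh <- sample(seq(-params$shift_max, params$shift_max), 2, replace = TRUE)
      patch <- shift_patch(patch, sh[1], sh[2])
      mask_patch <- shift_patch(mask_patch, sh[1], sh[2])
      ops$shift <- sh
    }
    g <- runif(1, params$gamma_range[1], params$gamma_range[2])
    patch <- patch^g
    ops$gamma <- g
    list(image = patch, mask = mask_patch, ops = ops)
  })
}

#' Fuse multi-head probability maps into a label mask
#'
#' A predictor may expose several output heads (e.g. parallel 1x1, 3x3 and
#' 5x5 output kernels), each emitting a per-pixel class probability map. The
#' final per-pixel class is the argmax of the unweighted mean of the head
#' probability vectors; ties break to the lowest class index.
#'
#' @param head_probs list of H x W x N probability arrays (or a single
#'   array), each pixel's probabilities nonnegative and summing to 1 within
#'   1e-6.
#' @return integer matrix of 0-based class labels (channel `k` of the
#'   probability maps corresponds to label value `k - 1`).
#' @export
fuse_heads <- function(head_probs) {
  if (is.array(head_probs) && length(dim(head_probs)) == 3)
    head_probs <- list(head_probs)
  stopifnot(is.list(head_probs), length(head_probs) >= 1)
  d <- dim(head_probs[[1]])
  if (length(d) != 3) stop("each head must be an H x W x N array")
  for (h in head_probs) {
    if (!identical(dim(h), d)) stop("head shapes differ")
    if (any(h < -1e-9)) stop("head probabilities must be nonnegative")
  }
  mean_map <- Reduce(`+`, head_probs) / length(head_probs)
  flat <- matrix(mean_map, nrow = d[1] * d[2], ncol = d[3])
  sums <- rowSums(flat) / 1 # per-pixel mass averaged over heads
  if (any(abs(sums - 1) > 1e-6))
    stop("per-pixel class probabilities must sum to 1 (max deviation ",
         format(max(abs(sums - 1))), ")")
  cls <- max.col(flat, ties.method = "first") - 1L
  matrix(as.integer(cls), d[1], d[2])
}

#' Overlapping-tile full-resolution inference
#'
#' Runs a fixed-size predictor over a large image with overlapping tiles and
#' stitches a full-resolution label mask, discarding a `margin`-pixel band at
#' each tile edge where predictions are least reliable. Tiles step by
#' `tile_size - 2 * margin`, so retained interiors tile the image seamlessly;
#' at the image boundary, tiles are shifted inward (never padded) and the
#' retained region is extended to the image edge. Every output pixel is
#' written exactly once, and each comes from a tile in which it lies at least
#' `margin` pixels from the tile edge, except where the image boundary forces
#' otherwise.
#'
#' For any pixelwise predictor (output at a pixel depending only on that
#' pixel's value) the result equals running the predictor on the whole image
#' at once -- the correctness property of the stitching.
#'
#' @param image H x W x 3 array.
#' @param predictor function taking an H' x W' x 3 crop and returning a list
#'   of probability-map heads (or one array), see [fuse_heads()].
#' @param cfg a [tile_config()]; `tile_size` must not exceed either image
#'   dimension.
#' @return integer label matrix of the full image size.
#' @export
tiled_predict <- function(image, predictor, cfg) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  Tt <- cfg$tile_size; m <- cfg$margin
  if (Tt > H || Tt > W)
    stop("tile_size ", Tt, " exceeds image dimensions ", H, "x", W,
         "; choose a smaller tile")
  step <- Tt - 2L * m
  starts <- function(D) {
    s <- seq(1L, D - Tt + 1L, by = step)
    if (s[length(s)] + Tt - 1L < D) s <- c(s, D - Tt + 1L)
    s
  }
  sr <- starts(H); sc <- starts(W)
  out <- matrix(NA_integer_, H, W)
  prev_hi_r <- 0L
  for (i in seq_along(sr)) {
    a <- sr[i]
    lo_r <- if (i == 1L) 1L else max(a + m, prev_hi_r + 1L)
    hi_r <- if (i == length(sr)) H else a + Tt - 1L - m
    prev_hi_c <- 0L
    for (j in seq_along(sc)) {
      b <- sc[j]
      lo_c <- if (j == 1L) 1L else max(b + m, prev_hi_c + 1L)
      hi_c <- if (j == length(sc)) W else b + Tt - 1L - m
      crop <- image[a:(a + Tt - 1L), b:(b + Tt - 1L), , drop = FALSE]
      heads <- predictor(crop)
      labels <- tryCatch(fuse_heads(heads), error = function(e)
        stop("predictor output invalid at tile (row=", a, ", col=", b, "): ",
             conditionMessage(e)))
      if (!all(dim(labels) == c(Tt, Tt)))
        stop("predictor output shape mismatch at tile (row=", a, ", col=", b,
             "): got ", paste(dim(labels), collapse = "x"),
             ", expected ", Tt, "x", Tt)
      out[lo_r:hi_r, lo_c:hi_c] <-
        labels[(lo_r - a + 1L):(hi_r - a + 1L), (lo_c - b + 1L):(hi_c - b + 1L)]
      prev_hi_c <- hi_c
    }
    prev_hi_r <- hi_r
  }
  stopifnot(!anyNA(out))
  out
}

#' Run a predictor on a whole image at once
#'
#' Reference (un-tiled) prediction path: apply the predictor to the full
#' image and fuse its heads. Used as the oracle against which
#' [tiled_predict()] stitching is verified.
#'
#' @inheritParams tiled_predict
#' @return integer label matrix.
#' @export
predict_labels <- function(image, predictor) {
  fuse_heads(predictor(image))
}

#' Reference color-threshold segmenter
#'
#' A trained network is out of scope here; this pixelwise stand-in assigns
#' each pixel soft class probabilities by a softmax over negative squared
#' distances between the pixel's color and each class's reference color. It
#' honours the predictor contract (list of per-pixel probability heads) and,
#' being strictly pixelwise, is also the translation-invariant oracle for
#' stitching tests. On images produced by [superimpose_mask()] with the
#' default palette it recovers the lesion labels essentially exactly.
#'
#' @param colors K x 3 matrix of reference RGB colors, rows named by class in
#'   label-code order (default [class_palette()], so channel `k` maps to
#'   label `k - 1`).
#' @param aux_colors optional matrix of additional reference colors whose
#'   probability mass is folded into an existing class channel; row names
#'   name the target class. The default maps shaded natural retina tones to
#'   `BACKGROUND` and the natural optic-disc tone to `OPTIC_DISC`, so the
#'   predictor behaves sensibly on raw (not only presegmented) renders.
#' @param heads number of identical-contract output heads to emit (default 3;
#'   heads differ by sharpness, exercising the fusion rule).
#' @param sharpness base inverse-temperature of the softmax.
#' @return a predictor `function(crop) -> list of H x W x K arrays`.
#' @export
palette_predictor <- function(colors = class_palette(),
                              aux_colors = .default_aux_colors(),
                              heads = 3, sharpness = 50) {
  colors <- as.matrix(colors)
  K <- nrow(colors)
  all_colors <- colors
  target <- seq_len(K)
  if (!is.null(aux_colors) && nrow(aux_colors) > 0) {
    aux_colors <- as.matrix(aux_colors)
    tgt <- match(rownames(aux_colors), rownames(colors))
    if (anyNA(tgt)) stop("aux_colors row names must name classes in colors")
    all_colors <- rbind(colors, aux_colors)
    target <- c(target, tgt)
  }
  sh <- sharpness * seq(0.5, 1.5, length.out = heads)
  function(crop) {
    d <- dim(crop)
    flat <- matrix(crop, nrow = d[1] * d[2], ncol = 3)
    d2 <- outer(rowSums(flat^2), rep(1, nrow(all_colors))) -
      2 * flat %*% t(all_colors) +
      outer(rep(1, nrow(flat)), rowSums(all_colors^2))
    lapply(sh, function(s) {
      logit <- -s * d2
      logit <- logit - apply(logit, 1, max)
      p <- exp(logit)
      p <- p / rowSums(p)
      folded <- matrix(0, nrow(p), K)
      for (j in seq_along(target))
        folded[, target[j]] <- folded[, target[j]] + p[, j]
      array(folded, c(d[1], d[2], K))
    })
  }
}

# natural (unannotated) tones of the synthetic render, folded into
# background / optic disc so raw images do not light up as lesions
.default_aux_colors <- function() {
  base <- c(0.48, 0.20, 0.08)
  m <- rbind(BACKGROUND = base, BACKGROUND = base * 0.85,
             BACKGROUND = base * 0.7, OPTIC_DISC = c(0.95, 0.85, 0.55))
  m
}
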