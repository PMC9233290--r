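# Independent oracles, deliberately written with different algorithms than
# the package internals (queue-based flood fill vs union-find; explicit
# pixel-set intersections vs labeled-matrix tabulation).

# flood-fill connected components over same-valued non-zero, non-optic-disc
# pixels; returns list of components: list(cls_code, pixels)
oracle_components <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  m <- mask
  m[m == 1L] <- 0L # optic disc is not a lesion
  seen <- matrix(FALSE, H, W)
  if (connectivity == 8) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1); dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dr <- c(-1, 1, 0, 0); dc <- c(0, 0, -1, 1)
  }
  comps <- list()
  for (start in which(m > 0L)) {
    if (seen[start]) next
    v <- m[start]
    queue <- start
    seen[start] <- TRUE
    pix <- integer(0)
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      pix <- c(pix, cur)
      r0 <- (cur - 1L) %% H + 1L; c0 <- (cur - 1L) %/% H + 1L
      for (k in seq_along(dr)) {
        rr <- r0 + dr[k]; cc <- c0 + dc[k]
        if (rr < 1 || rr > H || cc < 1 || cc > W) next
        li <- (cc - 1L) * H + rr
        if (!seen[li] && m[li] == v) {
          seen[li] <- TRUE
          queue <- c(queue, li)
        }
      }
    }
    comps[[length(comps) + 1L]] <- list(cls_code = v, pixels = sort(pix))
  }
  comps
}

# exhaustive pixel-set matching oracle: per class, tp/fp over predicted
# components and fn over reference components by explicit intersection
oracle_match <- function(pred, ref, connectivity = 8) {
  pc <- oracle_components(pred, connectivity)
  rf <- oracle_components(ref, connectivity)
  out <- data.frame(cls = lesion_classes(), tp = 0L, fp = 0L, fn = 0L)
  for (i in seq_along(lesion_classes())) {
    code <- LBL[[lesion_classes()[i]]]
    pcs <- Filter(function(x) x$cls_code == code, pc)
    rcs <- Filter(function(x) x$cls_code == code, rf)
    ref_pix <- unlist(lapply(rcs, `[[`, "pixels"))
    pred_pix <- unlist(lapply(pcs, `[[`, "pixels"))
    tp <- sum(vapply(pcs, function(x) any(x$pixels %in% ref_pix), logical(1)))
    fn <- sum(!vapply(rcs, function(x) any(x$pixels %in% pred_pix), logical(1)))
    out$tp[i] <- tp
    out$fp[i] <- length(pcs) - tp
    out$fn[i] <- fn
  }
  out
}

# adjusted-precision oracle: relabel every reference lesion to one class,
# then any-class overlap is same-class overlap
oracle_adjusted <- function(pred, ref, connectivity = 8) {
  pc <- oracle_components(pred, connectivity)
  ref_pix <- which(ref >= 2L)
  out <- setNames(rep(NA_real_, 7), lesion_classes())
  for (cls in lesion_classes()) {
    pcs <- Filter(function(x) x$cls_code == LBL[[cls]], pc)
    if (!length(pcs)) next
    tp <- sum(vapply(pcs, function(x) any(x$pixels %in% ref_pix), logical(1)))
    out[cls] <- tp / length(pcs)
  }
  out
}

# confusion-attribution oracle by per-component explicit counting
oracle_confusion <- function(pred, ref, connectivity = 8) {
  pc <- oracle_components(pred, connectivity)
  cols <- c(lesion_classes(), "BG")
  out <- matrix(0L, 7, 8, dimnames = list(lesion_classes(), cols))
  for (comp in pc) {
    pcls <- names(LBL)[match(comp$cls_code, LBL)]
    rvals <- ref[comp$pixels]
    rvals[rvals == 1L] <- 0L
    if (any(rvals == comp$cls_code)) {
      out[pcls, pcls] <- out[pcls, pcls] + 1L
    } else if (all(rvals == 0L)) {
      out[pcls, "BG"] <- out[pcls, "BG"] + 1L
    } else {
      cnt <- table(factor(names(LBL)[match(rvals[rvals > 0L], LBL)],
                          levels = lesion_classes()))
      out[pcls, names(cnt)[which.max(cnt)]] <-
        out[pcls, names(cnt)[which.max(cnt)]] + 1L
    }
  }
  out
}

# textbook quadratic weighted kappa, written as explicit double loops
oracle_qwk <- function(conf) {
  k <- nrow(conf); n <- sum(conf)
  num <- den <- 0
  for (i in 1:k) for (j in 1:k) {
    w <- (i - j)^2 / (k - 1)^2
    e <- sum(conf[i, ]) * sum(conf[, j]) / n
    num <- num + w * conf[i, j]
    den <- den + w * e
  }
  1 - num / den
}

# Mann-Whitney AUC per class, averaged (midranks)
oracle_macro_auc <- function(scores, ref) {
  lv <- sort(unique(ref))
  mean(vapply(lv, function(l) {
    s <- scores[, l + 1]
    pos <- s[ref == l]; neg <- s[ref != l]
    u <- 0
    for (p in pos) u <- u + sum(p > neg) + 0.5 * sum(p == neg)
    u / (length(pos) * length(neg))
  }, numeric(1)))
}

# ICC(2,1) oracle via R's aov decomposition rather than hand mean squares
oracle_icc21 <- function(counts) {
  n <- nrow(counts); k <- ncol(counts)
  df <- data.frame(y = as.vector(counts),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  av <- anova(stats::lm(y ~ subj + rater, data = df))
  msr <- av["subj", "Mean Sq"]; msc <- av["rater", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}
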