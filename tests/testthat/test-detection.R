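test_that("one shared pixel makes a true positive; disjoint makes fp+fn", {
  pred <- make_mask(10, 10, MA = c(rc(10, 2, 2), rc(10, 2, 3)))
  ref <- make_mask(10, 10, MA = c(rc(10, 2, 3), rc(10, 2, 4)))
  cts <- match_lesions(pred, ref)
  expect_equal(unlist(cts[cts$cls == "MA", c("tp", "fp", "fn")]),
               c(tp = 1L, fp = 0L, fn = 0L))

  pred2 <- make_mask(10, 10, MA = rc(10, 2, 2))
  ref2 <- make_mask(10, 10, MA = rc(10, 8, 8))
  cts2 <- match_lesions(pred2, ref2)
  expect_equal(unlist(cts2[cts2$cls == "MA", c("tp", "fp", "fn")]),
               c(tp = 0L, fp = 1L, fn = 1L))
})

test_that("overlap across classes does not match; shapes must agree", {
  pred <- make_mask(8, 8, MA = rc(8, 3, 3))
  ref <- make_mask(8, 8, HEM = rc(8, 3, 3))
  cts <- match_lesions(pred, ref)
  expect_equal(sum(cts$tp), 0L)
  expect_equal(cts[cts$cls == "MA", "fp"], 1L)
  expect_equal(cts[cts$cls == "HEM", "fn"], 1L)
  expect_error(match_lesions(pred, matrix(0L, 9, 8)), "identical dimensions")
})

test_that("one-to-many: one prediction covering k references detects all k", {
  # one long predicted HEM stripe over two disjoint reference HEMs
  pred <- make_mask(10, 12, HEM = rc(10, 5, 2:11))
  ref <- make_mask(10, 12, HEM = c(rc(10, 5, 2:3), rc(10, 5, 9:10)))
  cts <- match_lesions(pred, ref)
  row <- cts[cts$cls == "HEM", ]
  expect_equal(unlist(row[c("tp", "fp", "fn")]), c(tp = 1L, fp = 0L, fn = 0L))
  m <- detection_metrics(cts)
  expect_equal(m$recall[m$cls == "HEM"], 1)
  expect_equal(m$precision[m$cls == "HEM"], 1)
})

test_that("detection_metrics computes the stated formulas and mean", {
  cts <- data.frame(cls = lesion_classes(),
                    tp = c(1L, rep(5L, 6)), fp = c(1L, rep(0L, 6)),
                    fn = c(3L, rep(0L, 6)))
  m <- detection_metrics(cts)
  expect_equal(m$precision[1], 0.5)
  expect_equal(m$recall[1], 0.25)
  expect_equal(m$f1[1], 1 / 3)
  expect_equal(m$f1[m$cls == "Mean"], (1 / 3 + 6) / 7)

  # published per-class recall row reproduces its printed mean
  expect_equal(round(metric_mean(c(0.67, 0.74, 0.46, 0.61, 0.84, 0.67, 0.77)), 2),
               0.68)
})

test_that("undefined precision is excluded from the mean and flagged", {
  cts <- data.frame(cls = lesion_classes(), tp = 0L, fp = 0L, fn = 1L)
  cts$tp[1] <- 4L; cts$fp[1] <- 4L; cts$fn[1] <- 0L
  m <- detection_metrics(cts)
  expect_true(all(is.na(m$precision[2:7])))
  expect_equal(m$precision[m$cls == "Mean"], 0.5)
  expect_setequal(attr(m, "undefined"), lesion_classes()[-1])
})

test_that("matching equals the exhaustive pixel-set oracle on random pairs", {
  set.seed(202)
  for (i in 1:30) {
    conn <- sample(c(4, 8), 1)
    pred <- random_mask(40, 40, dens = runif(1, 0.03, 0.25),
                        classes = c("MA", "HEM", "IRMA", "NV"))
    ref <- random_mask(40, 40, dens = runif(1, 0.03, 0.25),
                       classes = c("MA", "HEM", "IRMA", "NV"))
    got <- match_lesions(pred, ref, conn)
    want <- oracle_match(pred, ref, conn)
    expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
  }
})

test_that("adjusted precision: cross-class overlap counts, and bounds hold", {
  pred <- make_mask(8, 8, MA = rc(8, 3, 3:5))
  ref <- make_mask(8, 8, HEM = rc(8, 3, 3:5))
  std <- detection_metrics(match_lesions(pred, ref))
  expect_equal(std$precision[std$cls == "MA"], 0)
  expect_equal(adjusted_precision(pred, ref)[["MA"]], 1)

  # identical masks: adjusted equals standard (both 1 for classes present)
  m <- random_mask(30, 30, classes = c("MA", "CWS"))
  ap <- adjusted_precision(m, m)
  expect_true(all(ap[!is.na(ap)] == 1))

  # random pairs: equals relabeling oracle, and >= standard precision
  set.seed(303)
  for (i in 1:15) {
    pred <- random_mask(40, 40, classes = c("MA", "HEM", "NV"))
    ref <- random_mask(40, 40, classes = c("MA", "HEM", "NV"))
    ap <- adjusted_precision(pred, ref)
    expect_equal(unclass(ap)[1:7], oracle_adjusted(pred, ref),
                 ignore_attr = TRUE)
    std <- detection_metrics(match_lesions(pred, ref))
    sp <- setNames(std$precision[1:7], std$cls[1:7])
    ok <- !is.na(ap) & !is.na(sp)
    expect_true(all(ap[ok] >= sp[ok] - 1e-12))
  }
})

test_that("image-level detection follows the presence/absence truth table", {
  # 3 predicted MA against 1 reference MA is one image-level tp
  pred <- make_mask(12, 12, MA = c(rc(12, 2, 2), rc(12, 6, 6), rc(12, 10, 10)))
  ref <- make_mask(12, 12, MA = rc(12, 4, 4))
  res <- image_level_detection(list(pred), list(ref))
  expect_equal(res$counts[res$counts$cls == "MA", "tp"], 1L)

  # empty pair contributes nothing anywhere
  res0 <- image_level_detection(list(matrix(0L, 5, 5)), list(matrix(0L, 5, 5)))
  expect_equal(sum(res0$counts[, c("tp", "fp", "fn")]), 0L)

  # 50 random pairs against an explicit truth table
  set.seed(404)
  preds <- replicate(50, random_mask(15, 15, dens = runif(1, 0, 0.2)),
                     simplify = FALSE)
  refs <- replicate(50, random_mask(15, 15, dens = runif(1, 0, 0.2)),
                    simplify = FALSE)
  res <- image_level_detection(preds, refs)
  for (cls in lesion_classes()) {
    code <- LBL[[cls]]
    p <- vapply(preds, function(m) any(m == code), logical(1))
    r <- vapply(refs, function(m) any(m == code), logical(1))
    row <- res$counts[res$counts$cls == cls, ]
    expect_equal(unlist(row[c("tp", "fp", "fn")]),
                 c(tp = sum(p & r), fp = sum(p & !r), fn = sum(!p & r)))
  }
})

test_that("fp_confusion attributes components to overlap or background", {
  # predicted IRMA fully inside reference NV
  pred <- make_mask(10, 10, IRMA = rc(10, 5, 4:6))
  ref <- make_mask(10, 10, NV = rc(10, 5, 3:7))
  conf <- fp_confusion(pred, ref)
  expect_equal(conf["IRMA", "NV"], 1L)
  expect_equal(sum(conf), 1L)

  # predicted MA on pure background (optic disc counts as background)
  pred2 <- make_mask(10, 10, MA = rc(10, 2, 2))
  ref2 <- make_mask(10, 10, OPTIC_DISC = rc(10, 2, 2))
  conf2 <- fp_confusion(pred2, ref2)
  expect_equal(conf2["MA", "BG"], 1L)

  # random masks: equals oracle; row sums equal predicted component counts
  set.seed(505)
  for (i in 1:15) {
    pred <- random_mask(40, 40, classes = c("MA", "HEM", "IRMA", "NV"))
    ref <- random_mask(40, 40, classes = c("MA", "HEM", "IRMA", "NV"))
    conf <- fp_confusion(pred, ref)
    expect_identical(conf, oracle_confusion(pred, ref))
    n_comp <- vapply(lesion_classes(), function(cls) {
      sum(vapply(extract_components(pred), function(x) x$cls == cls, logical(1)))
    }, integer(1))
    expect_equal(rowSums(conf), as.numeric(n_comp), ignore_attr = TRUE)
    # diagonal equals lesion-level tp
    cts <- match_lesions(pred, ref)
    expect_equal(unname(diag(conf)), cts$tp)
  }
})

test_that("image_fp_cooccurrence breaks false-positive images down by content", {
  # predicted NV on an image whose reference only has MA
  pred <- make_mask(10, 10, NV = rc(10, 5, 5))
  ref <- make_mask(10, 10, MA = rc(10, 2, 2))
  tab <- image_fp_cooccurrence(list(pred), list(ref))
  expect_equal(tab["NV", "MA"], 1L)
  expect_equal(tab["NV", "NA"], 0L)

  # prediction on an empty reference lands in the NA column
  tab2 <- image_fp_cooccurrence(list(pred), list(matrix(0L, 10, 10)))
  expect_equal(tab2["NV", "NA"], 1L)

  # perfect predictions: nothing off the TP column
  set.seed(606)
  masks <- replicate(10, random_mask(15, 15), simplify = FALSE)
  tab3 <- image_fp_cooccurrence(masks, masks)
  expect_equal(sum(tab3[, setdiff(colnames(tab3), "TP")]), 0L)

  # set-enumeration oracle on a random batch
  preds <- replicate(30, random_mask(15, 15, dens = runif(1, 0, 0.2)),
                     simplify = FALSE)
  refs <- replicate(30, random_mask(15, 15, dens = runif(1, 0, 0.2)),
                    simplify = FALSE)
  tab4 <- image_fp_cooccurrence(preds, refs)
  for (cls in lesion_classes()) {
    code <- LBL[[cls]]
    for (i in seq_along(preds)) {
      p <- any(preds[[i]] == code); r <- any(refs[[i]] == code)
      if (p && !r) {
        present <- lesion_classes()[vapply(lesion_classes(), function(d)
          any(refs[[i]] == LBL[[d]]), logical(1))]
        if (!length(present)) {
          expect_gte(tab4[cls, "NA"], 1L)
        } else {
          expect_true(all(tab4[cls, present] >= 1L))
        }
      }
    }
  }
})

test_that("monotonicity: extra predictions/references never reduce tallies", {
  set.seed(707)
  for (i in 1:10) {
    pred <- random_mask(25, 25)
    ref <- random_mask(25, 25)
    base <- match_lesions(pred, ref)
    free <- which(pred == 0L)
    pred2 <- pred
    pred2[sample(free, 1)] <- LBL[["MA"]]
    more_pred <- match_lesions(pred2, ref)
    expect_gte(sum(more_pred$tp + more_pred$fp), sum(base$tp + base$fp))
    ref2 <- ref
    ref2[sample(which(ref == 0L), 1)] <- LBL[["MA"]]
    more_ref <- match_lesions(pred, ref2)
    expect_gte(sum(more_ref$tp + more_ref$fn), sum(base$tp + base$fn))
  }
})

test_that("perfect prediction is a fixed point of every metric", {
  set.seed(808)
  m <- random_mask(40, 40, classes = c("MA", "HEM", "CWS", "NV"))
  mt <- detection_metrics(match_lesions(m, m))
  present <- lesion_classes()[vapply(lesion_classes(), function(cls)
    any(m == LBL[[cls]]), logical(1))]
  rows <- mt[mt$cls %in% present, ]
  expect_true(all(rows$precision == 1 & rows$recall == 1 & rows$f1 == 1))
  conf <- fp_confusion(m, m)
  expect_equal(sum(conf) - sum(diag(conf)), 0L)
})

test_that("relative improvement reproduces published comparisons", {
  expect_equal(relative_improvement(0.74, 0.68), 8.8)
  expect_equal(relative_improvement(0.67, 0.40), 67.5)
  expect_equal(relative_improvement(5, 5), 0)
  expect_error(relative_improvement(1, 0), "positive")
})
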