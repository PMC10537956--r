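sch <- default_class_schema()

test_that("confusion matrix counts truth rows against prediction columns", {
  gt <- label_mask(matrix(2L, 10, 10), 1L)
  cm <- confusion_matrix(gt, gt, sch)
  expect_equal(unclass(cm)["glomeruli", "glomeruli"], 100,
               ignore_attr = TRUE)
  expect_equal(sum(cm), 100)

  pred <- label_mask(matrix(4L, 10, 10), 1L)
  cm2 <- confusion_matrix(gt, pred, sch)
  expect_equal(unclass(cm2)["glomeruli",
                            "distal tubules/collecting ducts"], 100,
               ignore_attr = TRUE)
  expect_equal(sum(diag(cm2)), 0)

  # unannotated truth is excluded from the totals
  lab <- matrix(2L, 10, 10); lab[1:40] <- unannotated_id()
  cm3 <- confusion_matrix(label_mask(lab, 1L), pred, sch)
  expect_equal(sum(cm3), 60)

  expect_error(confusion_matrix(gt, label_mask(matrix(2L, 5, 5), 1L), sch),
               "differ in size")
})

test_that("matrix counts equal brute-force per-pixel tallies", {
  for (seed in c(1, 8, 23)) {
    gt <- random_mask(32, 32, seed, p_unannotated = 0.2)
    pred <- random_mask(32, 32, seed + 100)
    cm <- unclass(confusion_matrix(gt, pred, sch))
    brute <- matrix(0L, 10, 10)
    for (i in 1:32) for (j in 1:32) {
      g <- gt$labels[i, j]
      if (g == unannotated_id()) next
      p <- pred$labels[i, j]
      brute[g + 1L, p + 1L] <- brute[g + 1L, p + 1L] + 1L
    }
    expect_equal(cm, brute, ignore_attr = TRUE)
    # one-vs-rest TP/FP/FN/TN against brute-force pixel counting
    met <- class_metrics(confusion_matrix(gt, pred, sch))
    for (k in 0:9) {
      gv <- gt$labels[gt$labels != unannotated_id()]
      pv <- pred$labels[gt$labels != unannotated_id()]
      expect_equal(met$tp[k + 1], sum(gv == k & pv == k), ignore_attr = TRUE)
      expect_equal(met$fp[k + 1], sum(gv != k & pv == k), ignore_attr = TRUE)
      expect_equal(met$fn[k + 1], sum(gv == k & pv != k), ignore_attr = TRUE)
      expect_equal(met$tn[k + 1], sum(gv != k & pv != k), ignore_attr = TRUE)
    }
  }
})

test_that("full-resolution truth aligns to an 8x prediction both ways", {
  sec <- generate_section(synthetic_section_spec(128, 128, seed = 4,
                                                 injury_fraction = 0.2), sch)
  pred <- downsample_mask(sec$mask, 8L, sch)
  cm_down <- confusion_matrix(sec$mask, pred, sch)
  expect_equal(sum(cm_down), 16 * 16)     # evaluated on the 8x grid
  expect_equal(sum(diag(cm_down)), sum(cm_down))  # self-agreement
  cm_up <- confusion_matrix(sec$mask, pred, sch, align = "upsample_pred")
  expect_equal(sum(cm_up), 128 * 128)
})

test_that("row normalization yields percentages with undefined empty rows", {
  m <- matrix(0, 10, 10)
  m[9, 9] <- 85; m[9, 4] <- 15   # 85% of necrosis truth correctly labelled
  pct <- row_normalize(m)
  expect_equal(pct[9, 9], 85)
  expect_true(all(is.na(pct[1, ])))
  rs <- rowSums(pct, na.rm = FALSE)
  expect_equal(rs[9], 100)

  set.seed(2)
  for (i in 1:5) {
    rm_ <- matrix(rpois(100, 3), 10, 10)
    pct <- row_normalize(rm_)
    defined <- rowSums(rm_) > 0
    expect_true(all(abs(rowSums(pct[defined, , drop = FALSE]) - 100) < 1e-6))
  }

  ident <- row_normalize(diag(10) * 7)
  expect_true(all(diag(ident) == 100))
})

test_that("published precision/recall pairs reproduce the published F1", {
  expect_equal(round(f1_score(0.94, 0.85), 2), 0.89)  # tubular necrosis
  expect_equal(round(f1_score(0.87, 0.70), 2), 0.78)  # intratubular casts
  expect_gte(f1_score(0.99, 0.94), 0.95)              # glomeruli
  expect_gte(f1_score(0.95, 0.88), 0.90)              # proximal tubules
})

test_that("the two F1 formulas agree exactly on integer counts", {
  set.seed(5)
  for (i in 1:10) {
    cm <- matrix(sample(0:50, 16, replace = TRUE), 4, 4)
    dimnames(cm) <- list(letters[1:4], letters[1:4])
    met <- class_metrics(cm)
    with_pr <- f1_score(met$precision, met$recall)
    ok <- !is.na(with_pr) & !is.na(met$f1)
    expect_equal(met$f1[ok], with_pr[ok], tolerance = 1e-12)
  }
})

test_that("zero denominators give undefined metrics, not NaN", {
  cm <- matrix(0, 10, 10)
  cm[4, 4] <- 50; cm[4, 5] <- 10   # only proximal truth, predicted 4 or 5
  met <- class_metrics(cm)
  # class absent from truth and prediction: recall undefined, specificity 1
  expect_true(is.na(met$recall[3]))
  expect_equal(met$specificity[3], 1, ignore_attr = TRUE)
  expect_true(is.na(met$precision[3]))
  expect_false(any(is.nan(met$f1)))
})

test_that("permuting class order permutes counts and metrics consistently", {
  gt <- random_mask(16, 16, 42)
  pred <- random_mask(16, 16, 43)
  cm <- unclass(confusion_matrix(gt, pred, sch))
  perm <- c(1, 3, 2, 5, 4, 7, 6, 9, 8, 10)
  met <- class_metrics(cm)
  met_p <- class_metrics(cm[perm, perm])
  expect_equal(met_p$f1, met$f1[perm], ignore_attr = TRUE)
  expect_equal(met_p$precision, met$precision[perm], ignore_attr = TRUE)
})

test_that("macro and weighted summaries aggregate as documented", {
  cm <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  cm[1, 1] <- 80; cm[1, 2] <- 20   # class a: recall 0.8
  cm[2, 2] <- 100                  # class b: recall 1.0
  met <- class_metrics(cm)
  s <- macro_summary(met, cm)
  expect_equal(s["macro", "recall"], 0.9)
  # equal pixel counts: weighted equals macro
  expect_equal(s["weighted", "recall"], 0.9)
  # unequal pixels: weighted shifts toward the bigger class
  cm2 <- cm; cm2[2, 2] <- 300
  s2 <- macro_summary(class_metrics(cm2), cm2)
  expect_gt(s2["weighted", "recall"], s2["macro", "recall"])
  expect_error(macro_summary(class_metrics(matrix(0, 2, 2)),
                             matrix(0, 2, 2)), "undefined")
})
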