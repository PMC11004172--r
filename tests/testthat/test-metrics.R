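test_that("stratified splitting is deterministic and balanced", {
  mf <- manifest_241()
  s1 <- split_cohort(mf, seed = 5)
  s2 <- split_cohort(mf, seed = 5)
  expect_identical(s1, s2)
  # folds partition the training set with near-equal sizes per stratum
  ids <- names(s1$assignments)
  expect_length(intersect(ids, s1$test_ids), 0)
  expect_setequal(c(ids, s1$test_ids), mf$sample_id)
  for (dx in diagnosis_levels()) {
    sub <- s1$assignments[ids %in% mf$sample_id[mf$diagnosis == dx]]
    sizes <- table(factor(sub, levels = 1:5))
    expect_lte(max(sizes) - min(sizes), 1)
  }
})

test_that("a 241-patient cohort splits into 185 training and 56 test", {
  mf <- manifest_241()
  s <- split_cohort(mf, n_test = 56, seed = 1)
  expect_length(s$test_ids, 56)
  expect_length(s$assignments, 185)
})

test_that("10 samples across 5 folds gives folds of size 2", {
  mf <- data.frame(sample_id = sprintf("s%02d", 1:10),
                   fcs_path = "x", label_path = "y",
                   diagnosis = rep("Normal", 10))
  s <- split_cohort(mf, test_fraction = 0, seed = 2)
  expect_equal(as.integer(table(s$assignments)), rep(2L, 5))
})

test_that("strata smaller than the fold count are rejected", {
  mf <- data.frame(sample_id = sprintf("s%02d", 1:12),
                   fcs_path = "x", label_path = "y",
                   diagnosis = c(rep("Normal", 9), rep("AML", 3)))
  expect_error(split_cohort(mf, seed = 1),
               class = "ef_stratification_error")
})

test_that("one-vs-rest confusion counts match the published worked example", {
  # 56-patient test set: 10 true AML, 8 caught, 3 false alarms among 46
  y_true <- c(rep("AML", 10), rep("Normal", 46))
  y_pred <- c(rep("AML", 8), rep("Normal", 2),
              rep("AML", 3), rep("Normal", 43))
  cc <- confusion_counts(y_true, y_pred, "AML")
  expect_equal(unname(cc), c(8, 3, 2, 43))
  expect_error(confusion_counts(y_true, c(y_pred[-1], "ALL?"), "AML"),
               class = "ef_unknown_label")
})

test_that("confusion counts match a brute-force double loop", {
  set.seed(12)
  for (rep in 1:20) {
    t <- sample(diagnosis_levels(), 60, replace = TRUE)
    p <- sample(diagnosis_levels(), 60, replace = TRUE)
    for (cl in diagnosis_levels()) {
      tp <- 0; fp <- 0; fn <- 0; tn <- 0
      for (i in 1:60) {
        if (t[i] == cl && p[i] == cl) tp <- tp + 1
        if (t[i] != cl && p[i] == cl) fp <- fp + 1
        if (t[i] == cl && p[i] != cl) fn <- fn + 1
        if (t[i] != cl && p[i] != cl) tn <- tn + 1
      }
      expect_equal(unname(confusion_counts(t, p, cl)), c(tp, fp, fn, tn))
    }
  }
})

test_that("metrics formulas handle the published rows and degenerate cases", {
  m <- metrics_from_counts(8, 3, 2, 43)
  expect_equal(round(100 * m[["accuracy"]], 1), 91.1)
  expect_equal(round(100 * m[["sensitivity"]], 1), 80.0)
  expect_equal(round(100 * m[["specificity"]], 1), 93.5)
  expect_equal(round(100 * m[["f1"]], 1), 76.2)
  m2 <- metrics_from_counts(10, 0, 1, 45)
  expect_equal(m2[["specificity"]], 1)
  expect_equal(round(100 * m2[["f1"]], 1), 95.2)
  m3 <- metrics_from_counts(0, 0, 0, 10)
  expect_true(is.na(m3[["sensitivity"]]))
  expect_equal(m3[["specificity"]], 1)
  expect_false(any(is.nan(m3)))
  expect_error(metrics_from_counts(0, 0, 0, 0),
               class = "ef_degenerate_counts")
})

test_that("F1 equals the harmonic mean of precision and recall", {
  set.seed(13)
  for (rep in 1:25) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1)
    fn <- sample(0:20, 1); tn <- sample(1:20, 1)
    m <- metrics_from_counts(tp, fp, fn, tn)
    if (tp + fp > 0 && tp + fn > 0 && tp > 0) {
      prec <- tp / (tp + fp); rec <- tp / (tp + fn)
      expect_equal(m[["f1"]], 2 * prec * rec / (prec + rec))
    }
    for (v in m[!is.na(m)]) expect_true(v >= 0 && v <= 1)
  }
})

test_that("metrics reports are internally consistent", {
  set.seed(14)
  t <- sample(diagnosis_levels(), 56, replace = TRUE)
  p <- sample(diagnosis_levels(), 56, replace = TRUE)
  rep_ <- metrics_report(t, p)
  df <- rep_$per_class
  expect_equal(df$class, diagnosis_levels())
  # every class row uses all 56 samples; TP+FN = support
  expect_true(all(df$tp + df$fp + df$fn + df$tn == 56))
  expect_true(all(df$tp + df$fn == df$support))
  # confusion-matrix row sums = true-class counts
  expect_equal(unname(rowSums(rep_$confusion)),
               unname(as.integer(table(factor(t, diagnosis_levels())))))
  # report metrics equal metrics_from_counts applied to its own counts
  for (i in 1:5) {
    m <- metrics_from_counts(df$tp[i], df$fp[i], df$fn[i], df$tn[i])
    expect_equal(df$f1[i], m[["f1"]])
    expect_equal(df$accuracy[i], m[["accuracy"]])
  }
  # perfect prediction: all F1 = 1
  perfect <- metrics_report(t, t)
  expect_true(all(perfect$per_class$f1[perfect$per_class$support > 0] == 1))
})

test_that("train/test overlap hard-fails", {
  expect_error(
    metrics_report(c("AML", "Normal"), c("AML", "Normal"),
                   sample_ids = c("a", "b"), train_ids = c("b", "c")),
    class = "ef_leakage_error")
})

test_that("cross_validate sees every training sample exactly once", {
  mf <- manifest_241()
  s <- split_cohort(mf, seed = 3)
  seen <- character(0)
  res <- cross_validate(s,
    fit_fn = function(train_ids) train_ids,
    score_fn = function(model, val_ids) {
      expect_length(intersect(model, val_ids), 0)
      seen <<- c(seen, val_ids)
      1
    })
  expect_equal(nrow(res), 5)
  expect_setequal(seen, names(s$assignments))
  expect_equal(anyDuplicated(seen), 0)
})

test_that("report files are written with fractions retained", {
  t <- rep(diagnosis_levels(), 4)
  p <- t; p[1] <- "AML"
  stem <- file.path(withr::local_tempdir(), "rep")
  rp <- metrics_report(t, p)
  write_report(rp, stem)
  expect_true(file.exists(paste0(stem, "_per_class.csv")))
  expect_true(file.exists(paste0(stem, ".json")))
  back <- read.csv(paste0(stem, "_per_class.csv"))
  expect_equal(back$tp + back$fn, rp$per_class$support)
})
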