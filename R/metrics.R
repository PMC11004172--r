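# Cohort splitting, five-fold cross-validation and one-vs-rest diagnostic
# metrics (accuracy, sensitivity, specificity, F1 per diagnosis group).

# largest-remainder apportionment of n_total across strata of sizes ns
apportion <- function(ns, n_total) {
  quota <- ns / sum(ns) * n_total
  base <- floor(quota)
  rem <- n_total - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Split a cohort into test set and cross-validation folds
#'
#' Holds out a stratified test set (20% by default), then assigns the
#' remaining training samples to `k` stratified folds whose sizes differ by
#' at most one within each diagnosis stratum. Deterministic given `seed`.
#'
#' @param manifest Manifest data.frame with `sample_id` and `diagnosis`.
#' @param test_fraction Held-out fraction (ignored when `n_test` given).
#' @param n_test Optional exact test-set size (apportioned across strata by
#'   largest remainder).
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @param stratify Stratify by diagnosis (default).
#' @return A `fold_split`: list with `test_ids`, `assignments` (named fold
#'   index per training sample), `k`, `seed`, `stratified`.
#' @export
split_cohort <- function(manifest, test_fraction = 0.2, n_test = NULL,
                         k = 5L, seed = 1L, stratify = TRUE) {
  ids <- manifest$sample_id
  dx <- if (stratify) manifest$diagnosis else rep("all", length(ids))
  set.seed(seed)
  strata <- split(ids, dx)
  ns <- lengths(strata)
  ntest_k <- if (is.null(n_test)) {
    vapply(ns, function(n) as.integer(round(n * test_fraction)), integer(1))
  } else {
    stats::setNames(apportion(ns, n_test), names(ns))
  }
  test_ids <- character(0)
  assignments <- integer(0)
  for (s in names(strata)) {
    pool <- sample(strata[[s]])
    nt <- ntest_k[[s]]
    if (length(pool) - nt < k)
      stop_stratification(sprintf(
        "stratum '%s' leaves %d training samples for %d folds",
        s, length(pool) - nt, k))
    test_ids <- c(test_ids, if (nt > 0) pool[seq_len(nt)] else character(0))
    train <- if (nt > 0) pool[-seq_len(nt)] else pool
    folds <- rep(seq_len(k), length.out = length(train))
    assignments <- c(assignments, stats::setNames(folds, train))
  }
  structure(list(test_ids = sort(test_ids),
                 assignments = assignments[order(names(assignments))],
                 k = as.integer(k), seed = as.integer(seed),
                 stratified = stratify),
            class = "fold_split")
}

#' One-vs-rest confusion counts
#'
#' @param y_true,y_pred Aligned diagnosis vectors.
#' @param target_class The positive class.
#' @return Named integer vector `(tp, fp, fn, tn)`.
#' @export
confusion_counts <- function(y_true, y_pred, target_class) {
  if (length(y_true) != length(y_pred))
    stop_alignment("prediction vector must align to truth")
  vocab <- diagnosis_levels()
  bad <- setdiff(unique(c(y_true, y_pred, target_class)), vocab)
  if (length(bad))
    stop_unknown_label(paste0("unknown diagnosis label(s): ",
                              paste(bad, collapse = ", ")))
  tpos <- y_true == target_class
  ppos <- y_pred == target_class
  c(tp = sum(tpos & ppos), fp = sum(!tpos & ppos),
    fn = sum(tpos & !ppos), tn = sum(!tpos & !ppos))
}

#' Diagnostic metrics from one-vs-rest counts
#'
#' accuracy = (TP+TN)/n, sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' F1 = 2TP/(2TP+FP+FN). A metric whose denominator is zero is returned as
#' `NA` (not applicable), never `NaN`.
#'
#' @param tp,fp,fn,tn Non-negative integer counts (not all zero).
#' @return Named numeric vector `(accuracy, sensitivity, specificity, f1)`
#'   on the 0..1 scale.
#' @export
metrics_from_counts <- function(tp, fp, fn, tn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn); tn <- unname(tn)
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_config("counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop_degenerate_counts("all four confusion counts are zero")
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  c(accuracy = (tp + tn) / n,
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    f1 = safe_div(2 * tp, 2 * tp + fp + fn))
}

# round half-up to one decimal, in percent (display convention of the
# report tables)
pct1 <- function(x) floor(x * 1000 + 0.5) / 10

#' Build a metrics report from predictions
#'
#' Per-class one-vs-rest confusion counts and metrics in the fixed group
#' order (Normal, AML, B-ALL, Complex, Other), plus the full 5 x 5 confusion
#' matrix. Supplying `train_ids` triggers a hard leakage check against the
#' evaluated sample ids.
#'
#' @param y_true,y_pred Aligned diagnosis vectors for the test samples.
#' @param sample_ids Optional ids of the evaluated samples.
#' @param train_ids Optional ids used in training; any overlap with
#'   `sample_ids` raises a leakage error.
#' @return A `metrics_report`: list with `per_class` data.frame and
#'   `confusion` matrix.
#' @export
metrics_report <- function(y_true, y_pred, sample_ids = NULL,
                           train_ids = NULL) {
  if (!is.null(train_ids) && !is.null(sample_ids)) {
    overlap <- intersect(train_ids, sample_ids)
    if (length(overlap))
      stop_leakage(paste0("train/test overlap: ",
                          paste(utils::head(overlap, 5), collapse = ", ")))
  }
  lv <- diagnosis_levels()
  conf <- table(factor(y_true, levels = lv), factor(y_pred, levels = lv))
  rows <- lapply(lv, function(cl) {
    cc <- confusion_counts(y_true, y_pred, cl)
    m <- metrics_from_counts(cc["tp"], cc["fp"], cc["fn"], cc["tn"])
    data.frame(class = cl, tp = cc[["tp"]], fp = cc[["fp"]],
               fn = cc[["fn"]], tn = cc[["tn"]],
               support = cc[["tp"]] + cc[["fn"]],
               accuracy = m[["accuracy"]], sensitivity = m[["sensitivity"]],
               specificity = m[["specificity"]], f1 = m[["f1"]])
  })
  structure(list(per_class = do.call(rbind, rows),
                 confusion = unclass(conf), n = length(y_true)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  df <- x$per_class
  fmt_frac <- function(num, den) sprintf("%s%% (%d/%d)",
                                         format(pct1(num / den), nsmall = 1),
                                         num, den)
  show <- data.frame(
    Disease = df$class,
    F1 = ifelse(is.na(df$f1), "n/a",
                paste0(format(pct1(df$f1), nsmall = 1), "%")),
    Accuracy = fmt_frac(df$tp + df$tn, x$n),
    Sensitivity = ifelse(df$tp + df$fn > 0,
                         fmt_frac(df$tp, df$tp + df$fn), "n/a"),
    Specificity = ifelse(df$tn + df$fp > 0,
                         fmt_frac(df$tn, df$tn + df$fp), "n/a"))
  print(show, row.names = FALSE)
  invisible(x)
}

#' Write a metrics report to disk
#'
#' Emits `<stem>_per_class.csv` (fractions retained alongside the rounded
#' percentages), `<stem>_confusion.csv`, and `<stem>.json`.
#'
#' @param report A [metrics_report()].
#' @param stem Output path stem.
#' @return The JSON path, invisibly.
#' @export
write_report <- function(report, stem) {
  df <- report$per_class
  df$f1_pct <- pct1(df$f1); df$accuracy_pct <- pct1(df$accuracy)
  df$sensitivity_pct <- pct1(df$sensitivity)
  df$specificity_pct <- pct1(df$specificity)
  utils::write.csv(df, paste0(stem, "_per_class.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame.matrix(report$confusion),
                   paste0(stem, "_confusion.csv"))
  jsonlite::write_json(list(n = report$n, per_class = df,
                            confusion = report$confusion),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(stem, ".json"))
}

#' Evaluate trained models on a held-out test set
#'
#' Runs the appropriate input pipeline per sample (density image for Phase I
#' models; per-event gating + composition for Phase III models) and returns
#' the full metrics report. Training/test overlap hard-fails.
#'
#' @param model Trained `patient_classifier`.
#' @param manifest Manifest data.frame or path.
#' @param test_ids Sample ids to evaluate.
#' @param train_ids Ids used in training (leakage check).
#' @param event_model Trained `event_classifier`, required for composition
#'   models unless `use_manual_labels` is `TRUE`.
#' @param use_manual_labels Use sidecar labels instead of the Phase II model.
#' @return List: `report` ([metrics_report()]), `y_true`, `y_pred`.
#' @export
evaluate_pipeline <- function(model, manifest, test_ids,
                              train_ids = NULL, event_model = NULL,
                              use_manual_labels = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  sel <- manifest[manifest$sample_id %in% test_ids, , drop = FALSE]
  if (!nrow(sel)) stop_config("no manifest rows match test_ids")
  if (model$input_mode != "density_image" && !use_manual_labels &&
      is.null(event_model))
    stop_dependency("composition models need an event_model or manual labels")
  preds <- character(nrow(sel))
  for (i in seq_len(nrow(sel))) {
    em <- read_fcs(sel$fcs_path[i])
    if (model$input_mode == "density_image") {
      di <- render_density_image(em, pairs = model$config$pairs,
                                 bins = model$config$bins)
      preds[i] <- predict_patient(model, di)$label
    } else {
      labels <- if (use_manual_labels)
        read_label_sidecar(sel$label_path[i], n_events(em))
      else classify_events(event_model, em)$labels
      comp <- composition_vector(labels, sel$sample_id[i])
      feats <- if (model$input_mode == "composition+summaries")
        composition_features(comp, channel_summaries(em, labels))
      else composition_features(comp)
      preds[i] <- predict_patient(model, feats)$label
    }
  }
  rep <- metrics_report(sel$diagnosis, preds, sample_ids = sel$sample_id,
                        train_ids = train_ids)
  list(report = rep, y_true = sel$diagnosis, y_pred = preds,
       sample_ids = sel$sample_id)
}

#' Published reference test-set counts
#'
#' One-vs-rest confusion counts on a 56-patient ALOT test set, as reported
#' for a published three-phase deep-learning screening workflow: Phase I
#' (diagnosis from raw event data), Phase III from cell composition alone,
#' and Phase III from composition plus the 12 channels. Counts are derived
#' from the printed sensitivity and specificity fractions; the printed F1
#' column is retained for comparison. These rows are worked examples for
#' [metrics_from_counts()].
#'
#' @return data.frame with columns `phase`, `class`, `tp`, `fn`, `fp`, `tn`,
#'   `f1_printed`.
#' @export
reference_test_counts <- function() {
  rows <- list(
    # phase, class, tp, fn, fp, tn, printed F1 (%)
    list("I", "Normal", 9, 4, 8, 35, 60.0),
    list("I", "AML", 8, 2, 3, 43, 76.2),
    list("I", "B-ALL", 10, 1, 2, 43, 87.0),
    list("I", "Complex", 6, 8, 7, 35, 44.4),
    list("I", "Other", 3, 5, 0, 48, 54.6),
    list("III-composition", "Normal", 10, 3, 8, 35, 64.5),
    list("III-composition", "AML", 9, 1, 5, 41, 75.0),
    list("III-composition", "B-ALL", 10, 1, 0, 45, 95.2),
    list("III-composition", "Complex", 5, 9, 1, 41, 50.0),
    list("III-composition", "Other", 6, 2, 2, 46, 75.0),
    list("III-channels", "Normal", 9, 4, 8, 35, 60.0),
    list("III-channels", "AML", 9, 1, 2, 44, 85.7),
    list("III-channels", "B-ALL", 10, 1, 0, 45, 95.2),
    list("III-channels", "Complex", 5, 9, 5, 37, 41.7),
    list("III-channels", "Other", 6, 2, 2, 46, 75.0)
  )
  do.call(rbind, lapply(rows, function(r)
    data.frame(phase = r[[1]], class = r[[2]], tp = r[[3]], fn = r[[4]],
               fp = r[[5]], tn = r[[6]], f1_printed = r[[7]])))
}

#' Generic k-fold cross-validation driver
#'
#' Trains and scores a model once per fold; each training sample is
#' validated exactly once.
#'
#' @param split A [split_cohort()] result.
#' @param fit_fn `function(train_ids)` returning a fitted object.
#' @param score_fn `function(model, val_ids)` returning validation accuracy.
#' @return data.frame with one row per fold (`fold`, `n_val`, `accuracy`).
#' @export
cross_validate <- function(split, fit_fn, score_fn) {
  ids <- names(split$assignments)
  out <- lapply(seq_len(split$k), function(f) {
    val <- ids[split$assignments == f]
    model <- fit_fn(setdiff(ids, val))
    data.frame(fold = f, n_val = length(val),
               accuracy = score_fn(model, val))
  })
  do.call(rbind, out)
}
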