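#' Classification task specification
#'
#' The three binary tasks over the six histology labels:
#' * Task I uses the full data; healthy gray and white matter form the
#'   non-pathological class and all other labels the pathological class
#'   (whether edematous white matter counts as pathological is
#'   configurable, default yes).
#' * Task II focuses on white matter only: healthy white matter vs white
#'   matter with any tumor infiltration.
#' * Task III keeps only healthy white matter and the highest infiltration
#'   grade (> 60%).
#'
#' @param task `"I"`, `"II"` or `"III"`, or `"custom"` with explicit sets.
#' @param wme_positive For Task I, is edematous white matter pathological?
#' @param included,positives For `task = "custom"`: label sets with
#'   `positives` a non-empty strict subset of `included`.
#' @return An object of class `task_spec`.
#' @export
task_spec <- function(task = c("I", "II", "III", "custom"),
                      wme_positive = TRUE,
                      included = NULL, positives = NULL) {
  task <- match.arg(task)
  if (task == "I") {
    included <- tissue_labels()
    positives <- c("WM0_30", "WM30_60", "WM60plus", if (wme_positive) "WME")
  } else if (task == "II") {
    included <- c("WM0", "WM0_30", "WM30_60", "WM60plus")
    positives <- c("WM0_30", "WM30_60", "WM60plus")
  } else if (task == "III") {
    included <- c("WM0", "WM60plus")
    positives <- "WM60plus"
  }
  if (is.null(included) || is.null(positives) ||
      !length(setdiff(included, positives)) || !length(positives) ||
      !all(positives %in% included)) {
    stopf("'positives' must be a non-empty strict subset of 'included'")
  }
  structure(list(task = task, included = included, positives = positives),
            class = "task_spec")
}

#' Map histology labels onto a binary task
#'
#' @param labels Vector of tissue labels.
#' @param task A [task_spec()].
#' @return List with `included` (logical inclusion mask over `labels`) and
#'   `positive` (logical pathological-class indicator for the included
#'   rows). Errors when either class is empty after masking.
#' @export
assign_task_labels <- function(labels, task) {
  stopifnot(inherits(task, "task_spec"))
  labels <- as.character(labels)
  included <- labels %in% task$included
  positive <- labels[included] %in% task$positives
  if (!any(positive) || all(positive)) {
    stopf("task %s leaves an empty class after masking", task$task)
  }
  list(included = included, positive = positive)
}

#' Diagnostic metrics from contingency counts
#'
#' Sensitivity `100 * tp / (tp + fn)`, specificity `100 * tn / (tn + fp)`,
#' balanced accuracy (their arithmetic mean) and overall accuracy
#' `100 * (tp + tn) / total`, as exact ratios with integer-rounded
#' (half away from zero) companions. Metrics with a zero denominator are
#' flagged not computable (`NA`).
#'
#' @param tp,fp,tn,fn Non-negative contingency counts.
#' @return List of class `diagnostic_metrics` with raw and rounded values.
#' @export
compute_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("contingency counts must be non-negative integers")
  }
  if (sum(counts) == 0) stopf("empty contingency table")
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  bal <- if (!is.na(sens) && !is.na(spec)) (sens + spec) / 2 else NA_real_
  acc <- 100 * (tp + tn) / sum(counts)
  structure(
    list(
      counts = counts,
      sensitivity = sens, specificity = spec,
      balanced_accuracy = bal, accuracy = acc,
      sensitivity_rounded = round_half_out(sens),
      specificity_rounded = round_half_out(spec),
      balanced_accuracy_rounded = round_half_out(bal),
      accuracy_rounded = round_half_out(acc)
    ),
    class = "diagnostic_metrics"
  )
}

#' Balanced accuracy from a sensitivity/specificity pair
#'
#' @param sensitivity,specificity Percentages.
#' @return Integer-rounded balanced accuracy (raw value as attribute).
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  raw <- (sensitivity + specificity) / 2
  structure(round_half_out(raw), raw = raw)
}

#' Patient-level contingency from predicted vs true outcomes
#'
#' Compares per-patient residual-tumor calls (`"residual"` / `"clear"`)
#' against the histopathological truth (a patient has residual tumor when
#' at least one tissue sample is infiltrated) and tabulates tp/fp/tn/fn,
#' with `"residual"` the positive class.
#'
#' @param predicted,truth Named (by patient) or aligned character vectors
#'   with values `"residual"` or `"clear"`.
#' @return [compute_metrics()] output for the resulting counts.
#' @export
contingency_from_outcomes <- function(predicted, truth) {
  if (!is.null(names(predicted)) && !is.null(names(truth))) {
    if (!setequal(names(predicted), names(truth))) {
      stopf("predicted and truth cover different patient sets")
    }
    truth <- truth[names(predicted)]
  } else if (length(predicted) != length(truth)) {
    stopf("predicted and truth differ in length")
  }
  ok <- c("residual", "clear")
  if (!all(predicted %in% ok) || !all(truth %in% ok)) {
    stopf("outcomes must be 'residual' or 'clear'")
  }
  compute_metrics(
    tp = sum(predicted == "residual" & truth == "residual"),
    fp = sum(predicted == "residual" & truth == "clear"),
    tn = sum(predicted == "clear" & truth == "clear"),
    fn = sum(predicted == "clear" & truth == "residual")
  )
}

fold_confusion <- function(pred, truth) {
  c(tp = sum(pred & truth), fp = sum(pred & !truth),
    tn = sum(!pred & !truth), fn = sum(!pred & truth))
}

#' Leave-one-patient-out linear SVM evaluation
#'
#' One cross-validation fold per patient: a linear-kernel support vector
#' machine (regularization cost 0.1) is fit on all other patients'
#' feature rows and evaluated on the held-out patient, preventing
#' within-patient leakage. Features are standardized with training-fold
#' statistics (recorded in the report). Folds whose training data contain
#' a single class are skipped with a warning and recorded. Overall
#' performance is the mean per-fold sensitivity and specificity (over the
#' folds where each is defined), with balanced accuracy computed from the
#' two means.
#'
#' @param features Numeric matrix or data.frame of feature rows (e.g. the
#'   fitted `mu`, `I_db`, `r2` per patch).
#' @param positive Logical vector: pathological class indicator.
#' @param patient_ids Patient identity per row (fold unit).
#' @param cost SVM regularization cost.
#' @param standardize Standardize features with train-fold statistics?
#' @return An `eval_report`: per-fold table, mean sensitivity/specificity,
#'   balanced accuracy (raw + integer-rounded), skipped folds and settings.
#' @export
loo_svm_evaluate <- function(features, positive, patient_ids, cost = 0.1,
                             standardize = TRUE) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  positive <- as.logical(positive)
  stopifnot(nrow(x) == length(positive),
            nrow(x) == length(patient_ids))
  patients <- unique(patient_ids)
  if (length(patients) < 2L) stopf("need at least 2 patients")
  folds <- list(); skipped <- character()
  for (p in patients) {
    test <- patient_ids == p
    ytr <- positive[!test]
    if (length(unique(ytr)) < 2L) {
      warning(sprintf("fold %s skipped: single-class training data", p))
      skipped <- c(skipped, p)
      next
    }
    xtr <- x[!test, , drop = FALSE]
    xte <- x[test, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(xtr)
      sd <- apply(xtr, 2, stats::sd)
      sd[!is.finite(sd) | sd == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, mu, "-"), 2, sd, "/")
      xte <- sweep(sweep(xte, 2, mu, "-"), 2, sd, "/")
    }
    fit <- e1071::svm(xtr, factor(ytr, levels = c(FALSE, TRUE)),
                      kernel = "linear", cost = cost, scale = FALSE)
    pred <- as.logical(stats::predict(fit, xte))
    cm <- fold_confusion(pred, positive[test])
    sens <- if (cm["tp"] + cm["fn"] > 0) {
      100 * cm["tp"] / (cm["tp"] + cm["fn"])
    } else NA_real_
    spec <- if (cm["tn"] + cm["fp"] > 0) {
      100 * cm["tn"] / (cm["tn"] + cm["fp"])
    } else NA_real_
    folds[[length(folds) + 1L]] <- data.frame(
      patient_id = p, n_test = sum(test),
      tp = cm[["tp"]], fp = cm[["fp"]], tn = cm[["tn"]], fn = cm[["fn"]],
      sensitivity = unname(sens), specificity = unname(spec)
    )
  }
  if (!length(folds)) stopf("no evaluable folds")
  folds <- do.call(rbind, folds)
  mean_sens <- mean(folds$sensitivity, na.rm = TRUE)
  mean_spec <- mean(folds$specificity, na.rm = TRUE)
  bal <- (mean_sens + mean_spec) / 2
  structure(
    list(
      folds = folds,
      mean_sensitivity = mean_sens,
      mean_specificity = mean_spec,
      balanced_accuracy = bal,
      balanced_accuracy_rounded = round_half_out(bal),
      skipped_folds = skipped,
      settings = list(model = "linear_svm", cost = cost,
                      standardize = standardize,
                      aggregation = "mean_of_folds")
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %s: %d folds (%d skipped)  sens %.1f%%  spec %.1f%%  bal acc %.1f%%\n",
    x$settings$model, nrow(x$folds), length(x$skipped_folds),
    x$mean_sensitivity, x$mean_specificity, x$balanced_accuracy
  ))
  invisible(x)
}

#' Visual-vs-histology agreement matrix
#'
#' Joint count matrix of the five visual classes against the six histology
#' labels, both axes ordered benign to malignant (visual:
#' [visual_classes()]; histology: GM0, WM0, WME, then infiltration grades).
#'
#' @param visual Vector of visual classes.
#' @param histology Equal-length vector of tissue labels.
#' @return 5 x 6 count matrix.
#' @export
agreement_heatmap <- function(visual, histology) {
  if (length(visual) != length(histology)) {
    stopf("'visual' and 'histology' differ in length")
  }
  histo_order <- c("GM0", "WM0", "WME", "WM0_30", "WM30_60", "WM60plus")
  tab <- table(
    factor(visual, levels = visual_classes()),
    factor(histology, levels = histo_order)
  )
  m <- matrix(as.integer(tab), nrow = length(visual_classes()),
              dimnames = list(visual = visual_classes(),
                              histology = histo_order))
  m
}
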