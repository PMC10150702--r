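test_that("task specifications mask the intended label sets", {
  labels <- c("GM0", "WM0", "WM0_30", "WM30_60", "WM60plus", "WME",
              "WM0", "WM60plus")
  t1 <- assign_task_labels(labels, task_spec("I"))
  expect_true(all(t1$included))
  expect_identical(sum(t1$positive), 5L)   # infiltrated grades + edema

  t1b <- assign_task_labels(labels, task_spec("I", wme_positive = FALSE))
  expect_identical(sum(t1b$positive), 4L)

  t3 <- assign_task_labels(labels, task_spec("III"))
  expect_identical(labels[t3$included], c("WM0", "WM60plus", "WM0",
                                          "WM60plus"))
  expect_identical(t3$positive, c(FALSE, TRUE, FALSE, TRUE))

  expect_error(assign_task_labels(rep("WM0", 10), task_spec("II")),
               "empty class")
  expect_error(task_spec("custom", included = c("WM0"),
                         positives = c("WM0")), "strict subset")
})

test_that("diagnostic metrics reproduce the printed operating points", {
  # observer operating points
  expect_identical(as.numeric(balanced_accuracy(75, 89)), 82)
  expect_identical(as.numeric(balanced_accuracy(91, 83)), 87)
  # optical-property SVM, task II
  expect_identical(as.numeric(balanced_accuracy(81, 89)), 85)
  # network classifiers, task III
  expect_identical(as.numeric(balanced_accuracy(87, 79)), 83)
  expect_identical(as.numeric(balanced_accuracy(90, 84)), 87)

  perfect <- compute_metrics(tp = 7, fp = 0, tn = 9, fn = 0)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$balanced_accuracy, 100)

  m <- compute_metrics(tp = 1, fp = 2, tn = 3, fn = 2)
  expect_equal(m$balanced_accuracy, (100 / 3 + 60) / 2)
  none <- compute_metrics(tp = 0, fp = 1, tn = 3, fn = 0)
  expect_true(is.na(none$sensitivity))
  expect_error(compute_metrics(-1, 0, 1, 0), "non-negative")
})

test_that("rounding is half away from zero", {
  expect_identical(round_half_out(c(81.5, 84.5, 41.67, 66.67, -2.5)),
                   c(82, 85, 42, 67, -3))
})

test_that("patient-outcome contingencies give the clinical sensitivities", {
  # fluorescence guidance: 5 concerns confirmed, 7 missed, 9 correct clears
  fna <- contingency_from_outcomes(
    predicted = c(rep("residual", 5), rep("clear", 16)),
    truth = c(rep("residual", 12), rep("clear", 9))
  )
  expect_identical(fna$counts, c(tp = 5L, fp = 0L, tn = 9L, fn = 7L))
  expect_identical(fna$sensitivity_rounded, 42)
  expect_identical(fna$accuracy_rounded, 67)

  # early post-operative MRI: 9 detections, 3 missed, 9 correct clears
  mri <- contingency_from_outcomes(
    predicted = c(rep("residual", 9), rep("clear", 12)),
    truth = c(rep("residual", 12), rep("clear", 9))
  )
  expect_identical(mri$sensitivity_rounded, 75)

  all_right <- contingency_from_outcomes(
    predicted = c(a = "residual", b = "clear"),
    truth = c(b = "clear", a = "residual")
  )
  expect_equal(all_right$accuracy, 100)

  expect_error(contingency_from_outcomes(c(a = "clear"), c(b = "clear")),
               "patient sets")
  expect_error(contingency_from_outcomes("yes", "clear"), "outcomes")
})

test_that("leave-one-patient-out SVM separates constructed clusters", {
  set.seed(123)
  n <- 240
  pid <- sprintf("p%02d", rep_len(1:8, n))
  pos <- rep(c(FALSE, TRUE), each = n / 2)
  x <- cbind(mu = ifelse(pos, 2.5, 6) + rnorm(n, 0, 0.3),
             I_db = ifelse(pos, 49, 68) + rnorm(n, 0, 1.5),
             r2 = ifelse(pos, 0.95, 0.99) + rnorm(n, 0, 0.01))
  rep_sep <- loo_svm_evaluate(x, pos, pid)
  expect_identical(nrow(rep_sep$folds), 8L)
  expect_gte(rep_sep$balanced_accuracy, 95)

  # label shuffling destroys the signal
  set.seed(124)
  rep_null <- loo_svm_evaluate(x, sample(pos), pid)
  expect_gt(rep_null$balanced_accuracy, 35)
  expect_lt(rep_null$balanced_accuracy, 65)
})

test_that("single-class training folds are skipped with a warning", {
  set.seed(9)
  # patient p1 holds every positive: leaving anyone else out is fine, but
  # leaving out p1 gives a single-class training set... construct inverse:
  # all positives sit in p1, so every *other* fold trains on p1 + negatives
  # while the p1 fold trains on negatives only.
  x <- matrix(rnorm(60), ncol = 2)
  pos <- rep(c(TRUE, FALSE), c(10, 20))
  pid <- rep(c("p1", "p2", "p3"), each = 10)
  expect_warning(rep_ <- loo_svm_evaluate(x, pos, pid), "single-class")
  expect_identical(rep_$skipped_folds, "p1")
  expect_identical(nrow(rep_$folds), 2L)
})

test_that("fold aggregation is the mean of per-fold rates", {
  set.seed(55)
  x <- cbind(rnorm(40, rep(c(0, 3), each = 20)), rnorm(40))
  pos <- rep(c(FALSE, TRUE), each = 20)
  pid <- rep(c("a", "b", "c", "d"), times = 10)
  rep_ <- loo_svm_evaluate(x, pos, pid)
  expect_equal(rep_$mean_sensitivity,
               mean(rep_$folds$sensitivity, na.rm = TRUE))
  expect_equal(rep_$balanced_accuracy,
               (rep_$mean_sensitivity + rep_$mean_specificity) / 2)
  expect_true(rep_$settings$standardize)
})

test_that("agreement heatmap counts pairs on ordered axes", {
  single <- agreement_heatmap("tumorous", "WM60plus")
  expect_identical(sum(single), 1L)
  expect_identical(single["tumorous", "WM60plus"], 1L)

  empty <- agreement_heatmap(character(0), character(0))
  expect_identical(sum(empty), 0L)
  expect_identical(dim(empty), c(5L, 6L))

  expect_error(agreement_heatmap("tumorous", c("WM0", "WM0")), "length")

  # a concordant cohort concentrates mass along the diagonal band
  histo <- c("WM0", "WM0", "GM0", "WME", "WM0_30", "WM30_60", "WM60plus",
             "WM60plus")
  vis <- c("white_matter", "white_matter", "rather_tumorous",
           "rather_not_tumorous", "rather_tumorous", "rather_tumorous",
           "tumorous", "tumorous")
  m <- agreement_heatmap(vis, histo)
  expect_identical(sum(m), 8L)
  vi <- match(vis, visual_classes())
  hi <- match(histo, colnames(m))
  expect_gt(cor(vi, hi, method = "spearman"), 0)
})
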