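test_that("confusion-matrix metrics match hand arithmetic", {
  perfect <- compute_metrics(diag(c(10, 10, 10)))
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$per_class$precision == 1) &&
                all(perfect$per_class$recall == 1) &&
                all(perfect$per_class$f1 == 1))

  m <- matrix(c(8, 2, 0, 1, 9, 0, 0, 0, 10), nrow = 3, byrow = TRUE)
  got <- compute_metrics(m)
  expect_equal(got$per_class$precision[1], 8 / 9, tolerance = 1e-12)
  expect_equal(got$per_class$recall[1], 0.8, tolerance = 1e-12)
  expect_equal(got$per_class$f1[1],
               2 * (8 / 9) * 0.8 / (8 / 9 + 0.8), tolerance = 1e-12)
  expect_equal(got$accuracy, 27 / 30)

  # degenerate one-class-only prediction: balanced truth, everything called
  # class 1 -> accuracy 1/3, class-1 recall 1 and precision 1/3
  onecol <- matrix(c(10, 0, 0, 10, 0, 0, 10, 0, 0), nrow = 3, byrow = TRUE)
  deg <- compute_metrics(onecol)
  expect_equal(deg$accuracy, 1 / 3)
  expect_equal(deg$per_class$recall[1], 1)
  expect_equal(deg$per_class$precision[1], 1 / 3)
  expect_equal(deg$per_class$precision[2:3], c(0, 0))  # never predicted
  expect_match(deg$notes, "no predictions")
  expect_error(compute_metrics(matrix(-1, 2, 2)), "nonnegative")
})

test_that("stratified folds partition all windows with balanced classes", {
  labels <- factor(rep(behavior_labels(), times = c(40, 37, 23)),
                   levels = behavior_labels())
  folds <- make_folds(labels, k = 5, seed = 2)
  expect_length(folds, 100)
  expect_setequal(unique(folds), 1:5)
  per_fold <- table(labels, folds)
  expect_true(all(abs(per_fold - rowMeans(per_fold)) <= 1))
  expect_error(make_folds(factor(rep("EATING", 3)), k = 5), "at least 5")
})

test_that("cross-validation predicts every window exactly once and keeps counts consistent", {
  herd <- test_herd(4, 60, seed = 10)
  w <- segment_windows_multi(herd, 10)
  rep <- cross_validate(w, "fod", "tdsf", "dt", k = 5, seed = 3)
  expect_equal(sum(rep$total_confusion), length(w))
  expect_false(anyNA(rep$predicted))
  expect_setequal(unique(rep$folds), 1:5)
  # totals match metrics recomputed from the concatenated predictions
  cm2 <- as.matrix(table(rep$truth, rep$predicted))
  expect_equal(unname(as.matrix(rep$total_confusion)), unname(cm2))
  # row sums equal per-class truth counts
  expect_equal(unname(rowSums(rep$total_confusion)),
               unname(as.vector(table(rep$truth))))
  # accuracy identities
  expect_equal(rep$overall_accuracy,
               sum(diag(rep$total_confusion)) / sum(rep$total_confusion))
  expect_equal(rep$accuracy_mean, mean(rep$per_fold_accuracy))
  pc <- rep$per_class
  expect_true(all(pc$precision >= 0 & pc$precision <= 1 &
                    pc$recall >= 0 & pc$recall <= 1))
  idx <- pc$precision + pc$recall > 0
  expect_equal(pc$f1[idx],
               2 * pc$precision[idx] * pc$recall[idx] /
                 (pc$precision[idx] + pc$recall[idx]))
})

test_that("the pipeline comparison shares folds across cells and fills the grid", {
  herd <- test_herd(3, 45, seed = 14)
  cmp <- run_comparison(herd, window_seconds = 10,
                        preprocessing_methods = c("none", "ls", "hpf"),
                        schemes = c("fdf", "tdsf"),
                        algorithms = c("knn", "dt"), k = 5, seed = 4)
  expect_length(cmp$reports, 3 * 2 * 2)
  expect_equal(dim(cmp$summary), c(6, 3))  # pipeline column + 2 algorithms
  expect_equal(dim(cmp$accuracy), c(6, 2))
  expect_true(all(cmp$accuracy >= 0 & cmp$accuracy <= 1))
  # paired comparison: identical fold assignment everywhere
  fold_sets <- lapply(cmp$reports, `[[`, "folds")
  for (f in fold_sets) expect_identical(f, fold_sets[[1]])
})

test_that("the full preprocessing x scheme x algorithm grid has the expected shape", {
  herd <- test_herd(3, 45, seed = 14)
  cmp <- run_comparison(herd, window_seconds = 10, k = 5, seed = 1)
  expect_length(cmp$reports, 32)
  expect_equal(dim(cmp$accuracy), c(8, 4))
  expect_equal(rownames(cmp$accuracy),
               c("NONE_FDF", "NONE_TDSF", "FOD_FDF", "FOD_TDSF",
                 "LS_FDF", "LS_TDSF", "HPF_FDF", "HPF_TDSF"))
  expect_equal(colnames(cmp$accuracy), c("KNN", "SVM", "DT", "XGB"))
  expect_true(all(cmp$accuracy >= 0 & cmp$accuracy <= 1))
})

test_that("the window-size sweep reports one row per size with sane bookkeeping", {
  herd <- test_herd(3, 60, seed = 16)
  sw <- window_size_sweep(herd, sizes = c(5, 15), preprocessing = "ls",
                          scheme = "tdsf", algorithm = "dt", seed = 5)
  expect_equal(nrow(sw), 2)
  expect_equal(sw$window_seconds, c(5, 15))
  # shrinking the window cannot reduce the number of usable windows
  expect_gte(sw$n_windows[1], sw$n_windows[2])
  expect_true(all(sw$accuracy_mean >= 0 & sw$accuracy_mean <= 1))
  expect_true(all(sw$time_per_1k_samples_s > 0))
})
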