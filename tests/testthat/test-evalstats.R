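test_that("confusion construction counts true/predicted pairs exactly", {
  classes <- synth_classes()
  perfect <- rep(classes, each = 3)
  cm <- confusion_from_predictions(perfect, perfect, classes)
  expect_equal(unname(diag(cm)), c(3L, 3L, 3L))
  expect_equal(sum(cm), 9L)
  empty <- confusion_from_predictions(character(0), character(0), classes)
  expect_true(all(empty == 0L))
  err <- expect_error(
    confusion_from_predictions("adenocarcinoma", "mystery", classes),
    class = "cytopipe_data_error")
  expect_match(conditionMessage(err), "mystery")
})

test_that("confusion counts match a double-loop oracle on random labels", {
  set.seed(31)
  classes <- letters[1:4]
  for (rep in 1:5) {
    truth <- sample(classes, 200, TRUE)
    pred <- sample(classes, 200, TRUE)
    cm <- confusion_from_predictions(truth, pred, classes)
    for (i in seq_along(classes)) {
      for (j in seq_along(classes)) {
        expect_equal(cm[i, j],
                     sum(truth == classes[i] & pred == classes[j]))
      }
    }
  }
})

test_that("the printed hold-out confusion counts reproduce the reported metrics", {
  cm <- as_confusion_matrix(
    rbind(c(450, 0, 0),
          c(0, 450, 0),
          c(2, 0, 448)),
    c("adenocarcinoma", "neuroendocrine", "squamous"))
  met <- metrics_from_confusion(cm)
  pc <- met$per_class
  expect_equal(pc$precision[pc$class == "adenocarcinoma"], 450 / 452)
  expect_equal(pc$recall[pc$class == "adenocarcinoma"], 1)
  expect_equal(pc$f1[pc$class == "adenocarcinoma"], 900 / 902)
  expect_equal(pc$recall[pc$class == "squamous"], 448 / 450)
  expect_equal(pc$f1[pc$class == "squamous"], 896 / 898)
  expect_equal(met$accuracy, 1348 / 1350)
})

test_that("identity confusion gives unit metrics; 0/0 cells are undefined markers", {
  met <- metrics_from_confusion(as_confusion_matrix(diag(5L)))
  expect_true(all(met$per_class$precision == 1))
  expect_true(all(met$per_class$f1 == 1))
  expect_equal(met$accuracy, 1)
  # a class never predicted nor present -> undefined, not zero
  cm <- as_confusion_matrix(rbind(c(3, 0, 0), c(1, 2, 0), c(0, 0, 0)))
  met2 <- metrics_from_confusion(cm)
  expect_true(is.na(met2$per_class$recall[3]))
  expect_error(metrics_from_confusion(as_confusion_matrix(matrix(0, 2, 2))),
               class = "cytopipe_input_error")
})

test_that("metrics match the per-definition oracle on random matrices", {
  set.seed(32)
  for (rep in 1:200) {
    cm <- as_confusion_matrix(matrix(rpois(9, 20), 3, 3))
    met <- metrics_from_confusion(cm)
    orc <- oracle_metrics(unclass(cm))
    expect_equal(met$accuracy, orc$accuracy)
    expect_equal(met$per_class$precision, orc$precision)
    expect_equal(met$per_class$recall, orc$recall)
    expect_equal(met$per_class$f1, orc$f1)
  }
})

test_that("micro accuracy equals fraction-correct from the raw labels", {
  set.seed(33)
  classes <- synth_classes()
  for (rep in 1:30) {
    truth <- sample(classes, 120, TRUE)
    pred <- sample(classes, 120, TRUE)
    met <- metrics_from_confusion(confusion_from_predictions(truth, pred, classes))
    expect_equal(met$accuracy, mean(truth == pred))
  }
})

test_that("macro recall equals accuracy on balanced supports", {
  cm <- as_confusion_matrix(rbind(c(90, 5, 5), c(10, 80, 10), c(0, 20, 80)))
  met <- metrics_from_confusion(cm)
  expect_equal(met$macro_recall, met$accuracy)   # all supports are 100
})

test_that("fold summaries reproduce the cross-validation statistics", {
  vals <- c(99.47, 99.73, 99.80, 99.60, 99.87)
  s <- summarize_folds(vals)
  expect_equal(s$mean, 99.694)
  expect_equal(round(s$sd, 2), 0.16)
  expect_equal(round(s$se, 4), 0.0716)
  expect_equal(round(s$ci_low, 2), 99.55)
  expect_equal(round(s$ci_high, 2), 99.83)
  expect_equal(round(100 * s$cov / 100, 4), round(s$sd / s$mean, 4))
  # identical values collapse
  s0 <- summarize_folds(rep(98.5, 5))
  expect_equal(s0$sd, 0); expect_equal(s0$se, 0)
  expect_equal(s0$ci_low, s0$mean); expect_equal(s0$ci_high, s0$mean)
  expect_error(summarize_folds(1), class = "cytopipe_stats_error")
})

test_that("fold summary matches a two-pass variance oracle and is permutation-invariant", {
  set.seed(34)
  for (rep in 1:10) {
    vals <- runif(5, 90, 100)
    s <- summarize_folds(vals)
    m <- sum(vals) / 5
    v <- sum((vals - m)^2) / 4
    expect_equal(s$mean, m)
    expect_equal(s$sd, sqrt(v))
    expect_equal(s$se, sqrt(v / 5))
    sp <- summarize_folds(sample(vals))
    expect_equal(glance(sp), glance(s))
  }
})

test_that("cross-validation driver works with oracle and constant predictors", {
  m <- stratified_kfold(fake_manifest(c(15, 15, 15)), split_config(k = 5, seed = 6))
  # memorising predictor: looks labels up by path
  lookup <- stats::setNames(m$label, m$path)
  cv1 <- run_cross_validation(m,
    fit_fun = function(train) lookup,
    predict_fun = function(fit, test) unname(fit[test$path]))
  expect_true(all(cv1$per_fold$accuracy == 100))
  expect_equal(cv1$summaries$accuracy$sd, 0)
  # constant predictor on balanced folds
  cv2 <- run_cross_validation(m,
    fit_fun = function(train) "adenocarcinoma",
    predict_fun = function(fit, test) rep(fit, nrow(test)))
  expect_equal(cv2$per_fold$accuracy, rep(100 / 3, 5), tolerance = 1e-9)
  # summary internally consistent with its own per-fold values
  expect_equal(cv1$summaries$f1$se, cv1$summaries$f1$sd / sqrt(5))
  expect_error(run_cross_validation(fake_manifest(c(3, 3, 3)),
                                    function(x) x, function(f, x) x$label),
               class = "cytopipe_data_error")
})

test_that("external-test arithmetic reproduces per-class percentages", {
  rows <- tibble::tibble(
    class = c("adenocarcinoma", "neuroendocrine", "squamous"),
    n_tested = c(100, 100, 100),
    n_correct = c(97, 99, 98),
    n_misclassified = c(3, 1, 2))
  rep_tab <- external_test_report(rows)
  expect_equal(rep_tab$accuracy_pct[1:3], c(97, 99, 98))
  expect_equal(rep_tab$accuracy_pct[rep_tab$class == "overall"], 98)
  expect_equal(external_test_report(
    tibble::tibble(class = "x", n_tested = 100, n_correct = 100))$accuracy_pct[1],
    100)
  expect_error(external_test_report(
    tibble::tibble(class = "x", n_tested = 0, n_correct = 0)),
    class = "cytopipe_input_error")
})

test_that("tidiers expose metrics as tibbles", {
  met <- metrics_from_confusion(as_confusion_matrix(diag(3L) * 10L))
  expect_s3_class(tidy(met), "tbl_df")
  expect_equal(nrow(glance(met)), 1L)
  s <- summarize_folds(c(1, 2, 3))
  expect_equal(nrow(tidy(s)), 3L)
  expect_named(glance(s), c("mean", "sd", "se", "cov", "ci_low", "ci_high", "n"))
})
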