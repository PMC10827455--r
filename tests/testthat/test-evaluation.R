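# brute-force oracles, deliberately naive
brute_confusion <- function(truth, pred) {
  m <- matrix(0L, 2, 2, dimnames = list(true = c("benign", "malignant"),
                                        predicted = c("benign", "malignant")))
  for (i in seq_along(truth)) m[truth[i], pred[i]] <- m[truth[i], pred[i]] + 1L
  m
}

brute_auc <- function(scores, truth, positive = "malignant") {
  pos <- scores[truth == positive]
  neg <- scores[truth != positive]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

test_that("confusion counts agree with brute-force tallying", {
  set.seed(10)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    truth <- sample(c("benign", "malignant"), n, TRUE)
    pred <- sample(c("benign", "malignant"), n, TRUE)
    expect_identical(confusion_matrix(truth, pred), brute_confusion(truth, pred))
  }
  expect_error(confusion_matrix(c("benign"), c("benign", "malignant")), "equal length")
})

test_that("the published misclassification example reduces to its accuracy", {
  # 459 samples, 10 off-diagonal -> accuracy 449/459
  cm <- matrix(c(150L, 4L, 6L, 299L), 2, 2,
               dimnames = list(true = c("benign", "malignant"),
                               predicted = c("benign", "malignant")))
  expect_equal(sum(cm), 459L)
  expect_equal(sum(cm) - sum(diag(cm)), 10L)
  expect_equal(classification_metrics(cm)$accuracy, 449 / 459)
})

test_that("metrics match a brute-force recomputation from label pairs", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(30:80, 1)
    truth <- sample(c("benign", "malignant"), n, TRUE, prob = c(0.4, 0.6))
    pred <- sample(c("benign", "malignant"), n, TRUE)
    met <- classification_metrics(confusion_matrix(truth, pred))
    expect_equal(met$accuracy, mean(truth == pred))
    for (cls in c("benign", "malignant")) {
      tp <- sum(truth == cls & pred == cls)
      prec <- tp / sum(pred == cls)
      rec <- tp / sum(truth == cls)
      f1 <- if (tp == 0) 0 else 2 * prec * rec / (prec + rec)
      expect_equal(met[[paste0("f1_", cls)]], f1)
    }
  }
  # all-correct predictions give perfect metrics
  perfect <- classification_metrics(diag(c(5L, 7L)))
  expect_equal(unlist(perfect), c(accuracy = 1, f1_benign = 1,
                                  f1_malignant = 1, macro_f1 = 1))
  # degenerate matrix: one class never predicted correctly
  degen <- matrix(c(0L, 0L, 5L, 5L), 2, 2)
  expect_warning(met <- classification_metrics(degen), "benign")
  expect_equal(met$f1_benign, 0)
})

test_that("AUC equals exhaustive pair enumeration and handles ties", {
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(20:200, 1)
    truth <- sample(c("benign", "malignant"), n, TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c("benign", "malignant")
    scores <- round(runif(n), 2)  # rounding forces ties
    got <- roc_auc(scores, truth)
    expect_equal(got$auc_per_class[["malignant"]], brute_auc(scores, truth))
    expect_equal(got$auc_per_class[["benign"]], brute_auc(1 - scores, truth, "benign"))
    # two-class complementarity up to the shared tie handling
    expect_equal(got$auc_per_class[["benign"]] +
                   brute_auc(scores, truth, "benign"), 1)
    # every curve runs from (0,0) to (1,1)
    for (cls in c("benign", "malignant")) {
      pts <- dplyr::filter(got$roc_points, class == cls)
      expect_equal(unlist(pts[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
      expect_equal(unlist(pts[nrow(pts), c("fpr", "tpr")]), c(fpr = 1, tpr = 1))
    }
  }
})

test_that("AUC has its analytic fixed points and invariances", {
  truth <- rep(c("benign", "malignant"), each = 10)
  sep <- c(runif(10, 0, 0.4), runif(10, 0.6, 1))
  expect_equal(roc_auc(sep, truth)$auc_per_class[["malignant"]], 1)
  # label-independent scores at large n sit near 1/2
  set.seed(13)
  n <- 10000
  truth2 <- sample(c("benign", "malignant"), n, TRUE)
  expect_lt(abs(roc_auc(runif(n), truth2)$auc_per_class[["malignant"]] - 0.5), 0.02)
  # invariance under strictly monotone transforms of the scores
  s <- runif(200)
  t2 <- sample(c("benign", "malignant"), 200, TRUE)
  expect_equal(roc_auc(s, t2)$auc_per_class,
               roc_auc(s^3, t2)$auc_per_class)
  expect_warning(und <- roc_auc(runif(5), rep("benign", 5)), "single-class")
  expect_true(is.nan(und$auc_per_class[["malignant"]]))
})

test_that("AUC agrees with an established reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  truth <- sample(c("benign", "malignant"), 120, TRUE)
  scores <- round(runif(120), 2)
  ours <- roc_auc(scores, truth)$auc_per_class[["malignant"]]
  ref <- as.numeric(pROC::auc(pROC::roc(response = truth, predictor = scores,
                                        levels = c("benign", "malignant"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref)
})

test_that("the magnification table projects the per-tier reports", {
  set.seed(15)
  reports <- lapply(c("40", "100", "200", "400"), function(mg) {
    truth <- sample(c("benign", "malignant"), 30, TRUE)
    scores <- runif(30)
    eval_report(truth, ifelse(scores > 0.5, "malignant", "benign"),
                scores, magnification = mg)
  })
  tab <- magnification_report(reports)
  expect_equal(nrow(tab), 4L)
  for (i in seq_along(reports)) {
    expect_equal(tab$accuracy[i], reports[[i]]$metrics$accuracy)
    expect_equal(tab$auc_malignant[i], reports[[i]]$auc_per_class[["malignant"]])
  }
  expect_warning(magnification_report(reports[1:3]), "missing")
  # identical inputs give zero between-tier variance
  same <- lapply(c("40", "100"), function(mg)
    eval_report(rep(c("benign", "malignant"), 5),
                rep(c("benign", "malignant"), 5), magnification = mg))
  tab2 <- magnification_report(same, expected_tiers = c("40", "100"))
  expect_equal(stats::var(tab2$accuracy), 0)
})
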