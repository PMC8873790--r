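random_confusion <- function(seed) {
  set.seed(seed)
  matrix(rpois(16, lambda = sample(3:20, 1)), 4, 4)
}

test_that("confusion and overall accuracy handle the base cases", {
  y <- rep(0:3, each = 5)
  perfect <- confusion_and_gaa(y, y)
  expect_equal(perfect$gaa, 1)
  expect_true(all(perfect$confusion[upper.tri(perfect$confusion)] == 0))
  expect_equal(perfect$per_class_accuracy, rep(1, 4), ignore_attr = TRUE)
  constant <- confusion_and_gaa(y, rep(0L, 20))
  expect_equal(constant$gaa, 0.25)
  expect_error(confusion_and_gaa(integer(0), integer(0)), "empty")
})

test_that("overall accuracy is the count-weighted mean of class accuracies", {
  for (seed in 1:20) {
    set.seed(seed)
    y <- sample(0:3, 60, replace = TRUE)
    p <- sample(0:3, 60, replace = TRUE)
    r <- confusion_and_gaa(y, p)
    w <- rowSums(r$confusion)
    pc <- ifelse(is.na(r$per_class_accuracy), 0, r$per_class_accuracy)
    expect_equal(sum(w * pc) / sum(w), r$gaa, tolerance = 1e-12)
  }
})

test_that("kappa equals the closed-form oracle and its fixed points", {
  expect_equal(cohens_kappa(diag(c(3, 5, 7, 9))), 1)
  # independence: table equal to outer product of its marginals
  rowm <- c(2, 4, 6, 8); colm <- c(5, 5, 5, 5)
  indep <- outer(rowm, colm) / sum(rowm)
  expect_equal(cohens_kappa(indep), 0, tolerance = 1e-12)
  for (seed in 1:30) {
    cm <- random_confusion(seed)
    expect_equal(cohens_kappa(cm), oracle_kappa(cm), tolerance = 1e-12)
  }
  # kappa = 1 iff the table is diagonal
  cm <- diag(c(4, 4, 4, 4)); cm[1, 2] <- 1
  expect_lt(cohens_kappa(cm), 1)
  expect_warning(k <- cohens_kappa(matrix(c(10, 0, 0, 0), 2, 2)),
                 "degenerate")
  expect_equal(k, 0)
})

test_that("macro precision/recall/F1 match per-class hand computation", {
  perfect <- diag(c(5, 5, 5, 5))
  pr <- macro_prf1(perfect)
  expect_equal(c(pr$precision, pr$recall, pr$f1), c(1, 1, 1))
  for (seed in 1:30) {
    cm <- random_confusion(seed)
    got <- suppressWarnings(macro_prf1(cm))
    want <- oracle_prf1(cm)
    expect_equal(got$precision, want$precision, tolerance = 1e-12)
    expect_equal(got$recall, want$recall, tolerance = 1e-12)
    expect_equal(got$f1, want$f1, tolerance = 1e-12)
  }
  # a never-predicted class contributes precision 0
  cm <- matrix(c(5, 0, 5, 5, 0, 0, 0, 0, 5), 3, 3, byrow = TRUE)
  cm <- rbind(cbind(cm, 0), 0); cm[4, 1] <- 3
  expect_warning(pr0 <- macro_prf1(cm), "empty denominator")
  expect_equal(pr0$per_class$precision[4], 0)
})

test_that("micro ROC/AUC matches the exhaustive threshold sweep", {
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(5:9, 1)
    y <- sample(0:3, n, replace = TRUE)
    if (length(unique(y)) < 2) next
    p <- matrix(runif(n * 4), n, 4)
    p <- p / rowSums(p)
    got <- multiclass_roc_auc(y, p)
    expect_equal(got$auc, oracle_micro_auc(y, p), tolerance = 1e-12)
    expect_equal(got$roc_points$fpr[1], 0)
    expect_equal(tail(got$roc_points$tpr, 1), 1)
  }
})

test_that("ROC fixed points: perfect scores give 1, uniform scores 0.5", {
  y <- rep(0:3, each = 3)
  onehot <- matrix(0, 12, 4); onehot[cbind(1:12, y + 1)] <- 1
  expect_equal(multiclass_roc_auc(y, onehot)$auc, 1)
  expect_equal(multiclass_roc_auc(y, matrix(0.25, 12, 4))$auc, 0.5)
  expect_error(multiclass_roc_auc(rep(0L, 5), matrix(0.25, 5, 4)),
               "two classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(72)
  y <- sample(0:3, 30, replace = TRUE)
  p <- matrix(runif(30 * 4), 30, 4); p <- p / rowSums(p)
  a1 <- multiclass_roc_auc(y, p)$auc
  a2 <- multiclass_roc_auc(y, exp(3 * p))$auc
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("micro AUC agrees with an established ROC implementation", {
  set.seed(73)
  y <- sample(0:3, 40, replace = TRUE)
  p <- matrix(runif(40 * 4), 40, 4); p <- p / rowSums(p)
  truth <- c(sapply(0:3, function(c) as.numeric(y == c)))
  ref <- as.numeric(pROC::auc(pROC::roc(truth, c(p), quiet = TRUE,
                                        direction = "<")))
  expect_equal(multiclass_roc_auc(y, p)$auc, ref, tolerance = 1e-10)
})

test_that("evaluate_predictions assembles a coherent report", {
  set.seed(74)
  y <- sample(0:3, 50, replace = TRUE)
  p <- matrix(runif(50 * 4), 50, 4); p <- p / rowSums(p)
  pred <- max.col(p) - 1L
  r <- suppressWarnings(evaluate_predictions(y, pred, p))
  expect_s3_class(r, "eval_report")
  expect_equal(sum(r$confusion), 50)
  expect_equal(r$gaa, mean(y == pred))
  expect_equal(r$kappa, oracle_kappa(r$confusion), tolerance = 1e-12)
  expect_true(r$auc >= 0 && r$auc <= 1)
})
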