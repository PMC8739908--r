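test_that("RBF kernel follows its closed form", {
  x <- c(1, 2, 3)
  expect_equal(rbf_kernel(x, x, 2), 1)
  # ||x-y||^2 = 2 sigma^2  ->  exp(-1)
  y <- x + sqrt(2) * 1.5 / sqrt(3)
  expect_equal(rbf_kernel(x, y, 1.5), exp(-1))
  set.seed(1)
  for (i in 1:5) {
    a <- rnorm(4); b <- rnorm(4)
    expect_equal(rbf_kernel(a, b, 0.8), rbf_kernel(b, a, 0.8))
  }
  expect_error(rbf_kernel(1:2, 1:3, 1), "equal length")
  expect_error(rbf_kernel(1:2, 1:2, 0), "positive")
})

test_that("separable clusters are classified perfectly by every model", {
  set.seed(2)
  f <- data.frame(a = c(rnorm(40, 0, 0.3), rnorm(40, 5, 0.3)),
                  b = c(rnorm(40, 0, 0.3), rnorm(40, 5, 0.3)),
                  label = rep(c("u", "v"), each = 40))
  for (kind in c("svm_rbf", "lda", "qda", "knn", "mlp")) {
    clf <- train_beat_classifier(f, classifier_spec(kind, seed = 3))
    expect_equal(clf$metrics$accuracy, 1)
  }
})

test_that("shuffled labels give chance-level held-out accuracy", {
  accs <- vapply(1:8, function(s) {
    set.seed(s)
    f <- data.frame(a = rnorm(200), b = rnorm(200),
                    label = sample(rep(c("x", "y"), 100)))
    train_beat_classifier(f, classifier_spec("svm_rbf",
                                             seed = s))$metrics$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("training is deterministic under a fixed seed", {
  set.seed(4)
  f <- data.frame(a = rnorm(60), b = rnorm(60),
                  label = rep(c("u", "v"), 30))
  c1 <- train_beat_classifier(f, classifier_spec("svm_rbf", seed = 9))
  c2 <- train_beat_classifier(f, classifier_spec("svm_rbf", seed = 9))
  expect_identical(c1$idx_train, c2$idx_train)
  expect_identical(as.character(c1$test_pred),
                   as.character(c2$test_pred))
})

test_that("SVM decision values equal the explicit dual expansion", {
  set.seed(5)
  X <- rbind(matrix(rnorm(20, 0, 1), ncol = 2),
             matrix(rnorm(20, 3, 1), ncol = 2))
  y <- factor(rep(c("a", "b"), each = 10))
  sigma <- 1.5
  m <- e1071::svm(X, y, kernel = "radial", gamma = 1 / (2 * sigma^2),
                  cost = 1, scale = FALSE)
  dv <- attr(stats::predict(m, X, decision.values = TRUE),
             "decision.values")
  manual <- vapply(seq_len(nrow(X)), function(i)
    sum(m$coefs * vapply(seq_len(nrow(m$SV)), function(j)
      rbf_kernel(m$SV[j, ], X[i, ], sigma), numeric(1))) - m$rho,
    numeric(1))
  expect_equal(manual, as.vector(dv), tolerance = 1e-10)
})

test_that("detection metrics follow Se, +P and failure-rate arithmetic", {
  m <- detection_metrics(confusion_counts(tp = 9, fp = 1, fn = 1))
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$positive_predictivity, 0.9)
  expect_equal(m$failure_rate, 2 / 9)
  perfect <- detection_metrics(confusion_counts(tp = 10))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$positive_predictivity, 1)
  expect_equal(perfect$failure_rate, 0)
  none <- detection_metrics(confusion_counts(tp = 0, fp = 2, fn = 3))
  expect_equal(none$sensitivity, 0)
  expect_equal(none$positive_predictivity, 0)
  expect_true(is.na(none$failure_rate))
})

test_that("classification metrics follow the accuracy/recall/precision/F1 forms", {
  m <- classification_metrics(list(
    pos = confusion_counts(tp = 50, fp = 5, fn = 5, tn = 40)))
  expect_equal(m$accuracy, 0.9)
  expect_equal(m$recall, 50 / 55)
  expect_equal(m$precision, 50 / 55)
  expect_equal(m$f1, 50 / 55)   # recall == precision -> F1 equals both
  truth <- factor(c("a", "a", "b", "b", "b", "c"))
  pred <- factor(c("a", "b", "b", "b", "c", "c"))
  m2 <- classification_metrics(truth, pred)
  expect_equal(m2$accuracy, 4 / 6)
  expect_equal(m2$per_class$recall[m2$per_class$class == "b"], 2 / 3)
})

test_that("F1 lies between precision and recall whenever defined", {
  set.seed(6)
  for (i in 1:25) {
    cc <- confusion_counts(tp = sample(1:20, 1), fp = sample(0:10, 1),
                           fn = sample(0:10, 1), tn = sample(0:20, 1))
    m <- classification_metrics(list(x = cc))
    if (!is.na(m$f1)) {
      expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
      expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
    }
  }
})

test_that("degenerate training inputs are rejected", {
  f <- data.frame(a = rnorm(10), label = rep("only", 10))
  expect_error(train_beat_classifier(f), "2 classes")
  f2 <- data.frame(a = rnorm(3), label = c("u", "u", "v"))
  expect_error(train_beat_classifier(f2), "at least 2 rows")
})
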