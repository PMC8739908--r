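#' Gaussian radial basis kernel
#'
#' `K(x, y) = exp(-||x - y||^2 / (2 sigma^2))`.
#'
#' @param x,y numeric vectors of equal length.
#' @param sigma kernel width (> 0).
#' @return similarity in (0, 1].
#' @export
rbf_kernel <- function(x, y, sigma) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (sigma <= 0) stop("'sigma' must be positive")
  exp(-sum((x - y)^2) / (2 * sigma^2))
}

#' Classifier specification
#'
#' @param kind `"svm_rbf"`, `"mlp"`, `"knn"`, `"lda"` or `"qda"`.
#' @param svm_sigma RBF width; `NULL` (default) uses the median pairwise
#'   distance of the training features.
#' @param svm_C box constraint of the SVM dual (default 1).
#' @param knn_k neighbours for KNN (default 3).
#' @param mlp_hidden hidden layer size for the MLP (default 32).
#' @param seed RNG seed controlling the train/test split and any
#'   stochastic fitting.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("svm_rbf", "mlp", "knn", "lda",
                                     "qda"),
                            svm_sigma = NULL, svm_C = 1, knn_k = 3L,
                            mlp_hidden = 32L, seed = 1L) {
  kind <- match.arg(kind)
  if (!is.null(svm_sigma) && svm_sigma <= 0) stop("'svm_sigma' must be > 0")
  if (svm_C <= 0) stop("'svm_C' must be > 0")
  if (knn_k < 1) stop("'knn_k' must be >= 1")
  structure(list(kind = kind, svm_sigma = svm_sigma, svm_C = svm_C,
                 knn_k = as.integer(knn_k),
                 mlp_hidden = as.integer(mlp_hidden),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

feature_matrix <- function(features) {
  stopifnot(is.data.frame(features), "label" %in% names(features))
  num <- features[setdiff(names(features), "label")]
  num <- num[vapply(num, is.numeric, logical(1))]
  X <- as.matrix(num)
  X[is.na(X)] <- 0  # absent waves (e.g. no P in PVC) encode as zero
  list(X = X, y = factor(features$label))
}

#' Train a beat classifier with a stratified held-out split
#'
#' Splits the feature rows `split` / `1 - split` per class (seeded,
#' stratified), standardises the training features, fits the requested
#' model and evaluates on the held-out rows.  SVM uses the radial kernel
#' dual with box constraint `svm_C` (one-vs-one for more than two
#' classes); LDA/QDA, KNN and a single-hidden-layer MLP are the
#' alternatives.
#'
#' @param features data.frame from [extract_features()] including a
#'   `label` column; every class must have at least 2 rows.
#' @param spec a [classifier_spec()].
#' @param split training fraction in (0, 1), default 0.7.
#' @return An object of class `beat_classifier` with the fitted model,
#'   the held-out predictions, and `metrics` (see
#'   [classification_metrics()]).
#' @export
train_beat_classifier <- function(features, spec = classifier_spec(),
                                  split = 0.7) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (!(split > 0 && split < 1)) stop("'split' must be in (0, 1)")
  fm <- feature_matrix(features)
  X <- fm$X; y <- fm$y
  if (nlevels(droplevels(y)) < 2) stop("need at least 2 classes")
  if (any(table(y)[table(y) > 0] < 2))
    stop("every class needs at least 2 rows")
  idx_train <- with_seed(spec$seed, {
    unlist(lapply(levels(y), function(lv) {
      rows <- which(y == lv)
      sample(rows, max(1L, round(split * length(rows))))
    }))
  })
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_len(nrow(X)), idx_train)
  if (!length(idx_test)) stop("held-out set is empty; lower 'split'")
  ctr <- colMeans(X[idx_train, , drop = FALSE])
  scl <- apply(X[idx_train, , drop = FALSE], 2, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  std <- function(M) sweep(sweep(M, 2, ctr), 2, scl, "/")
  Xtr <- std(X[idx_train, , drop = FALSE])
  Xte <- std(X[idx_test, , drop = FALSE])
  ytr <- droplevels(y[idx_train]); yte <- y[idx_test]

  sigma <- spec$svm_sigma
  if (spec$kind == "svm_rbf" && is.null(sigma)) {
    dd <- stats::dist(Xtr[sample.int(nrow(Xtr),
                                     min(nrow(Xtr), 500L)), ,
                          drop = FALSE])
    sigma <- stats::median(dd)
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  }
  model <- with_seed(spec$seed, switch(spec$kind,
    svm_rbf = e1071::svm(Xtr, ytr, kernel = "radial",
                         gamma = 1 / (2 * sigma^2), cost = spec$svm_C,
                         scale = FALSE),
    lda = MASS::lda(Xtr, ytr),
    qda = MASS::qda(Xtr, ytr),
    knn = list(X = Xtr, y = ytr, k = spec$knn_k),
    mlp = nnet::nnet(Xtr, nnet::class.ind(ytr),
                     size = spec$mlp_hidden, decay = 1e-3,
                     maxit = 400, trace = FALSE, MaxNWts = 20000,
                     softmax = TRUE)))
  obj <- structure(list(kind = spec$kind, model = model, spec = spec,
                        sigma = sigma, center = ctr, scale = scl,
                        levels = levels(ytr),
                        idx_train = idx_train, idx_test = idx_test),
                   class = "beat_classifier")
  pred <- predict(obj, X[idx_test, , drop = FALSE])
  obj$test_truth <- yte
  obj$test_pred <- pred
  obj$metrics <- classification_metrics(yte, pred)
  obj
}

#' Predict beat classes
#'
#' @param object a `beat_classifier`.
#' @param newdata numeric matrix or feature data.frame (raw scale; the
#'   training standardisation is applied internally).
#' @param ... unused.
#' @return factor of predicted class labels.
#' @export
predict.beat_classifier <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    if (!"label" %in% names(newdata)) newdata$label <- NA_character_
    newdata <- feature_matrix(newdata)$X
  }
  M <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  out <- switch(object$kind,
    svm_rbf = as.character(stats::predict(object$model, M)),
    lda = as.character(stats::predict(object$model, M)$class),
    qda = as.character(stats::predict(object$model, M)$class),
    knn = as.character(class::knn(object$model$X, M, object$model$y,
                                  k = object$model$k)),
    mlp = {
      pr <- stats::predict(object$model, M)
      colnames(pr)[max.col(pr)]
    })
  factor(out, levels = object$levels)
}

#' @export
print.beat_classifier <- function(x, ...) {
  cat(sprintf("<beat_classifier> %s on %d train / %d test rows; ",
              x$kind, length(x$idx_train), length(x$idx_test)))
  cat(sprintf("held-out accuracy %.3f\n", x$metrics$accuracy))
  invisible(x)
}

#' Peak-detection quality metrics
#'
#' Sensitivity `Se = TP / (FN + TP)`, positive predictivity
#' `+P = TP / (FP + TP)` and failure rate `Frr = (FN + FP) / TP`.
#' Ratios with a zero denominator are returned as `NA` (undefined), not
#' coerced to 0.
#'
#' @param counts a [confusion_counts()].
#' @return list with `sensitivity`, `positive_predictivity`,
#'   `failure_rate`.
#' @export
detection_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  list(
    sensitivity = if (tp + fn > 0) tp / (fn + tp) else NA_real_,
    positive_predictivity = if (tp + fp > 0) tp / (fp + tp) else NA_real_,
    failure_rate = if (tp > 0) (fn + fp) / tp else NA_real_)
}

#' Classification quality metrics
#'
#' Overall accuracy `(TN + TP) / (TN + TP + FN + FP)` plus per-class
#' one-vs-rest recall `TP / (TP + FN)`, precision `TP / (TP + FP)` and
#' `F1 = 2 * recall * precision / (recall + precision)`, averaged with
#' the requested scheme.  Macro averaging (the default) weighs classes
#' equally; micro averaging pools the counts first.  Undefined ratios
#' (zero denominators) are `NA` and are dropped from macro averages.
#'
#' Accepts either a pair of factors (truth, prediction) or a named list
#' of per-class [confusion_counts()].
#'
#' @param truth factor of true labels, or a named list of
#'   [confusion_counts()].
#' @param pred factor of predicted labels (when `truth` is a factor).
#' @param averaging `"macro"` or `"micro"`.
#' @return list with `accuracy`, `recall`, `precision`, `f1` and a
#'   `per_class` data.frame.
#' @export
classification_metrics <- function(truth, pred = NULL,
                                   averaging = c("macro", "micro")) {
  averaging <- match.arg(averaging)
  direct_acc <- NA_real_
  if (is.list(truth) && !is.data.frame(truth) && is.null(pred)) {
    counts <- truth
  } else {
    truth <- factor(truth); pred <- factor(pred, levels = levels(truth))
    direct_acc <- mean(as.character(pred) == as.character(truth))
    counts <- lapply(stats::setNames(nm = levels(truth)), function(lv) {
      confusion_counts(
        tp = sum(truth == lv & pred == lv),
        fp = sum(truth != lv & pred == lv),
        fn = sum(truth == lv & pred != lv),
        tn = sum(truth != lv & pred != lv))
    })
  }
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  per <- do.call(rbind, lapply(names(counts), function(lv) {
    cc <- counts[[lv]]
    rec <- safe(cc$tp, cc$tp + cc$fn)
    pre <- safe(cc$tp, cc$tp + cc$fp)
    f1 <- if (!is.na(rec) && !is.na(pre) && rec + pre > 0)
      2 * rec * pre / (rec + pre) else NA_real_
    data.frame(class = lv, tp = cc$tp, fp = cc$fp, fn = cc$fn,
               tn = cc$tn, recall = rec, precision = pre, f1 = f1)
  }))
  tot <- Reduce(`+`, lapply(counts, function(cc)
    c(tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn)))
  # label accuracy when labels are available; for bare counts, the
  # (TN + TP) / (TN + TP + FN + FP) pooled form
  acc <- if (!is.na(direct_acc)) direct_acc else
    safe(tot["tp"] + tot["tn"], sum(tot))
  if (averaging == "macro") {
    avg <- function(v) if (all(is.na(v))) NA_real_ else
      mean(v, na.rm = TRUE)
    rec <- avg(per$recall); pre <- avg(per$precision); f1 <- avg(per$f1)
  } else {
    rec <- safe(tot["tp"], tot["tp"] + tot["fn"])
    pre <- safe(tot["tp"], tot["tp"] + tot["fp"])
    f1 <- if (!is.na(rec) && !is.na(pre) && rec + pre > 0)
      2 * rec * pre / (rec + pre) else NA_real_
  }
  list(accuracy = unname(acc), recall = unname(rec),
       precision = unname(pre), f1 = unname(f1), per_class = per,
       averaging = averaging)
}
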