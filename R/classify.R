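# Five classifier families over the selected feature table, stratified
# 70/30 evaluation and 10-fold cross-validation, macro-averaged metrics
# over the six execution classes, and per-repetition probability reports
# for mixed-error feedback.

algo_ids <- c("DT", "RF", "KNN", "SVM", "MLP")

default_hyperparams <- function(algo) {
  switch(algo,
    DT = list(),  # Gini impurity, effectively unlimited depth
    RF = list(ntree = 100),
    KNN = list(k = 5),
    SVM = list(cost = 1, gamma = NULL),  # RBF kernel
    MLP = list(size = 30, decay = 1e-3, maxit = 200))
}

#' Stratified fold assignment
#'
#' @param labels class labels.
#' @param k number of folds.
#' @return integer fold id per row (uses the current RNG state; seed
#'   upstream).
#' @export
stratified_folds <- function(labels, k) {
  y <- as.factor(labels)
  if (min(table(y)) < k)
    stop(sprintf("smallest class has %d rows < k = %d folds; use a smaller k",
                 min(table(y)), k))
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

stratified_split <- function(labels, p = 0.7) {
  y <- as.factor(labels)
  train <- logical(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    ntr <- max(1L, round(p * length(idx)))
    train[idx[seq_len(ntr)]] <- TRUE
  }
  train
}

fit_algo <- function(x, y, algo, hyper) {
  hp <- utils::modifyList(default_hyperparams(algo), hyper)
  switch(algo,
    DT = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      rpart::rpart(.y ~ ., df, method = "class",
                   parms = list(split = "gini"),
                   control = rpart::rpart.control(cp = 0, minsplit = 2,
                                                  maxdepth = 30, xval = 0))
    },
    RF = randomForest::randomForest(x, y, ntree = hp$ntree),
    KNN = list(x = x, y = y, k = hp$k),  # lazy learner: store training data
    SVM = e1071::svm(x, y, kernel = "radial", cost = hp$cost,
                     gamma = if (is.null(hp$gamma)) 1 / ncol(x) else hp$gamma,
                     probability = TRUE, scale = FALSE),
    MLP = nnet::nnet(x, nnet::class.ind(y), size = hp$size, decay = hp$decay,
                     maxit = hp$maxit, softmax = TRUE, trace = FALSE,
                     MaxNWts = 1e6),
    stop("unknown algorithm id: ", algo))
}

# neighbour-vote posterior for the stored-KNN model: vote fractions over
# all six classes (class::knn reports only the winning share), ties broken
# by summed inverse distance
knn_probs <- function(fit, x) {
  cls <- levels(fit$y)
  t(apply(x, 1, function(row) {
    d <- sqrt(colSums((t(fit$x) - row)^2))
    nn <- order(d)[seq_len(fit$k)]
    votes <- table(factor(fit$y[nn], levels = cls)) / fit$k
    v <- as.numeric(votes)
    top <- which(v == max(v))
    if (length(top) > 1) {
      wt <- vapply(cls[top], function(cl)
        sum(1 / (d[nn][fit$y[nn] == cl] + 1e-12)), 0)
      v[top[which.max(wt)]] <- v[top[which.max(wt)]] + 1e-9
      v <- v / sum(v)
    }
    v
  }))
}

predict_probs <- function(model, x) {
  cls <- model$classes
  p <- switch(model$algo,
    DT = predict(model$fit, data.frame(x, check.names = FALSE), type = "prob"),
    RF = predict(model$fit, x, type = "prob"),
    KNN = knn_probs(model$fit, x),
    SVM = {
      pr <- predict(model$fit, x, probability = TRUE)
      attr(pr, "probabilities")
    },
    MLP = predict(model$fit, x))
  p <- as.matrix(p)
  if (!is.null(colnames(p))) p <- p[, cls, drop = FALSE] else colnames(p) <- cls
  p / rowSums(p)
}

#' Train one classifier on a processed feature table
#'
#' Performs the seed-controlled stratified 70/30 split, fits the requested
#' family on the training portion, and evaluates the held-out portion.
#' The optional scaler and feature selection are attached so the model can
#' later consume raw feature rows (see [predict_report()]).
#'
#' @param table a scaled, feature-selected [feature_table()].
#' @param labels class labels (defaults to the table's own).
#' @param algo one of DT, RF, KNN, SVM, MLP.
#' @param seed RNG seed controlling the split and any stochastic fitting.
#' @param hyperparams named list overriding the family defaults.
#' @param scaler,selection optional [fit_scaler()] / [select_features_rfe()]
#'   results to bundle with the model.
#' @param split training fraction.
#' @param advice_threshold probability threshold for mixed-error advice.
#' @return object of class `squat_model` with the fit, class order,
#'   held-out confusion matrix and macro metrics.
#' @export
train <- function(table, labels = table$labels, algo = "MLP", seed = 1,
                  hyperparams = list(), scaler = NULL, selection = NULL,
                  split = 0.7, advice_threshold = 0.25) {
  algo <- match.arg(algo, algo_ids)
  y <- squat_label(labels)
  if (min(table(y)) < 2) stop("every class needs >= 2 rows for stratification")
  x <- table$x
  if (!is.null(selection)) x <- x[, selection$features, drop = FALSE]
  set.seed(seed)
  tr <- stratified_split(y, split)
  fit <- fit_algo(x[tr, , drop = FALSE], y[tr], algo, hyperparams)
  model <- structure(list(algo = algo, fit = fit, classes = levels(y),
                          features = colnames(x), seed = seed,
                          scaler = scaler, selection = selection,
                          advice_threshold = advice_threshold,
                          train_rows = which(tr)),
                     class = "squat_model")
  if (any(!tr)) {
    probs <- predict_probs(model, x[!tr, , drop = FALSE])
    preds <- factor(model$classes[max.col(probs, "first")],
                    levels = model$classes)
    model$holdout_confusion <- confusion(y[!tr], preds)
    model$holdout_metrics <- macro_metrics(model$holdout_confusion)
  }
  model
}

#' @export
print.squat_model <- function(x, ...) {
  cat(sprintf("<squat_model> %s on %d features", x$algo, length(x$features)))
  if (!is.null(x$holdout_metrics))
    cat(sprintf("; held-out accuracy %.3f", x$holdout_metrics$accuracy))
  cat("\n")
  invisible(x)
}

#' Stratified k-fold cross-validation of one classifier family
#'
#' @param table a processed [feature_table()].
#' @param labels class labels (defaults to the table's own).
#' @param algo classifier family id.
#' @param k folds (every class must have at least k rows).
#' @param seed RNG seed (fold assignment and stochastic fits).
#' @param hyperparams named list overriding family defaults.
#' @return list with `folds` (per-fold macro metrics), `mean` (averaged
#'   metrics), `confusion` (pooled over folds).
#' @export
cross_validate <- function(table, labels = table$labels, algo = "MLP",
                           k = 10, seed = 1, hyperparams = list()) {
  algo <- match.arg(algo, algo_ids)
  y <- squat_label(labels)
  set.seed(seed)
  folds <- stratified_folds(y, k)
  x <- table$x
  per_fold <- list()
  pooled <- NULL
  for (f in seq_len(k)) {
    tr <- folds != f
    model <- structure(list(algo = algo, classes = levels(y),
                            fit = fit_algo(x[tr, , drop = FALSE], y[tr],
                                           algo, hyperparams)),
                       class = "squat_model")
    probs <- predict_probs(model, x[!tr, , drop = FALSE])
    preds <- factor(levels(y)[max.col(probs, "first")], levels = levels(y))
    cm <- confusion(y[!tr], preds)
    pooled <- if (is.null(pooled)) cm else pooled + unclass(cm)
    per_fold[[f]] <- macro_metrics(cm)
  }
  avg <- lapply(c(accuracy = "accuracy", specificity = "specificity",
                  sensitivity = "sensitivity", precision = "precision"),
                function(m) mean(vapply(per_fold, `[[`, 0, m)))
  class(pooled) <- c("confusion_matrix", class(pooled))
  list(folds = per_fold, mean = avg, confusion = pooled)
}

#' Classify one repetition and report mixed-error probabilities
#'
#' When the model bundles a scaler/selection, `row` is a raw named feature
#' vector (full inventory or a superset of the model's features); it is
#' scaled and subset before prediction. Advice codes are all error classes
#' (everything but CO) whose probability reaches the mixed-error
#' threshold, so combined faults (e.g. KOT together with RH) produce
#' multiple corrective advices.
#'
#' @param model a [train()] result.
#' @param row named numeric feature vector.
#' @return list with `label`, `probs` (named, sums to 1), `advice`
#'   (character vector of error-class codes).
#' @export
predict_report <- function(model, row) {
  stopifnot(inherits(model, "squat_model"))
  v <- row
  if (!is.null(model$scaler)) {
    idx <- match(names(v), model$scaler$features)
    known <- !is.na(idx)
    v <- (v[known] - model$scaler$center[idx[known]]) /
      model$scaler$scale[idx[known]]
  }
  missing <- setdiff(model$features, names(v))
  if (length(missing))
    stop("feature row is missing model feature(s): ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5))
  x <- matrix(v[model$features], 1, dimnames = list(NULL, model$features))
  p <- predict_probs(model, x)[1, ]
  label <- model$classes[which.max(p)]
  advice <- setdiff(model$classes[p >= model$advice_threshold], "CO")
  list(label = label, probs = p, advice = advice)
}

#' Confusion matrix of actual vs predicted classes
#'
#' Rows are the actual class, columns the predicted class.
#'
#' @param truths,preds equal-length label vectors.
#' @return 6 x 6 integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(truths, preds) {
  stopifnot(length(truths) == length(preds))
  y <- squat_label(truths); p <- squat_label(preds)
  cm <- table(y, p)
  cm <- matrix(as.integer(cm), nrow(cm), ncol(cm),
               dimnames = list(levels(y), levels(p)))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> N = %d (rows actual, columns predicted)\n",
              sum(x)))
  print(unclass(x))
  invisible(x)
}

#' Macro-averaged classification metrics
#'
#' One-vs-rest counts per class k: TP the diagonal entry, FN the rest of
#' row k (rows hold the actual class), FP the rest of column k, TN the
#' remainder; the four metrics are each averaged over the six classes:
#' accuracy = mean (TP+TN)/N, specificity = mean TN/(TN+FP), sensitivity =
#' mean TP/(TP+FN), precision = mean TP/(TP+FP). Classes with an empty
#' denominator are excluded from that metric's mean, with a warning.
#'
#' @param cm a [confusion()] matrix (rows actual, columns predicted).
#' @return list with `accuracy`, `specificity`, `sensitivity`,
#'   `precision` and a `per_class` data.frame of the counts.
#' @export
macro_metrics <- function(cm) {
  m <- unclass(as.matrix(cm))
  n <- sum(m)
  if (n <= 0) stop("empty confusion matrix")
  tp <- diag(m)
  fn <- rowSums(m) - tp
  fp <- colSums(m) - tp
  tn <- n - tp - fn - fp
  safe_mean <- function(num, den, what) {
    ok <- den > 0
    if (!all(ok))
      warning(sum(!ok), " class(es) with empty denominator excluded from ",
              what)
    mean(num[ok] / den[ok])
  }
  list(accuracy = mean((tp + tn) / n),
       specificity = safe_mean(tn, tn + fp, "specificity"),
       sensitivity = safe_mean(tp, tp + fn, "sensitivity"),
       precision = safe_mean(tp, tp + fp, "precision"),
       per_class = data.frame(class = rownames(m) %||% as.character(seq_along(tp)),
                              TP = tp, FN = fn, FP = fp, TN = tn))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a confusion matrix CSV
#'
#' Layout: header row and first column hold the class abbreviations; rows
#' are the actual class, columns the predicted class.
#'
#' @param path CSV path.
#' @return a `confusion_matrix`.
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  stopifnot(identical(rownames(m), squat_classes()),
            identical(colnames(m), squat_classes()), all(m >= 0))
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' @rdname read_confusion_csv
#' @param cm a `confusion_matrix`.
#' @export
write_confusion_csv <- function(cm, path) {
  df <- data.frame(class = rownames(cm), unclass(cm), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reference real-time evaluation confusion matrix
#'
#' The shipped 6 x 6 confusion matrix from a live monitoring evaluation of
#' the six-class squat classifier (319 repetitions; rows actual, columns
#' predicted), used as a fixed input for metric recomputation.
#'
#' @return a `confusion_matrix`.
#' @export
realtime_confusion <- function() {
  read_confusion_csv(system.file("extdata", "realtime_confusion.csv",
                                 package = "squatmon", mustWork = TRUE))
}
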