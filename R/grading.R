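# Pfirrmann grade prediction: a hard height rule owns grade 5; a
# class-weighted classifier on SSCC features predicts grades 1-4; evaluation
# uses the frequency-weighted mean of the per-grade accuracies.

GRADER_FAMILIES <- c("ensemble", "tree", "knn", "svm", "lda", "nnet")

#' Class training weights from class frequencies
#'
#' `tw_c = median(f) / f_c`: the grade whose frequency equals the median gets
#' weight 1, rarer grades get proportionally larger weights.
#'
#' @param f positive per-grade frequency vector (names preserved).
#' @return a `class_weights` object: list with `f` and `tw`.
#' @examples
#' class_weights(c(60, 1002, 167, 295, 21))$tw  # 2.7833 0.1667 1 0.5661 7.9524
#' @export
class_weights <- function(f) {
  if (any(f <= 0)) stop("weight error: zero class frequency", call. = FALSE)
  structure(list(f = f, tw = stats::median(f) / f), class = "class_weights")
}

#' Grade-5 height rule
#'
#' A disc strictly shorter than the threshold (default 3.0 mm) is grade 5;
#' taller discs pass through to the classifier (`NA` is returned for them).
#'
#' @param height_mm nonnegative disc height(s) in millimetres.
#' @param threshold height threshold in millimetres.
#' @return integer vector: 5 where the rule fires, `NA` otherwise.
#' @export
apply_height_rule <- function(height_mm, threshold = 3.0) {
  stopifnot(all(height_mm >= 0))
  ifelse(height_mm < threshold, 5L, NA_integer_)
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin into folds.
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.drop_constant_cols <- function(x) {
  keep <- apply(x, 2L, function(col) stats::sd(col) > 1e-10)
  if (!any(keep)) keep[1L] <- TRUE
  x[, keep, drop = FALSE]
}

# Fit one classifier family on features x (matrix), grades y (factor) with
# per-sample weights wts; returns an object .family_predict can consume.
.family_fit <- function(family, x, y, wts, seed) {
  switch(family,
    ensemble = {
      df <- data.frame(.grade = y, x)
      ranger::ranger(.grade ~ ., data = df, num.trees = 15L,
                     mtry = min(20L, ncol(x)), min.node.size = 1L,
                     case.weights = wts, seed = seed,
                     num.threads = 1L)
    },
    tree = {
      df <- data.frame(.grade = y, x)
      rpart::rpart(.grade ~ ., data = df, weights = wts, method = "class",
                   control = rpart::rpart.control(minbucket = 1L, cp = 0.005,
                                                  xval = 0L))
    },
    knn = list(x = x, y = y, k = 5L),
    svm = {
      cw <- tapply(wts, y, mean)
      e1071::svm(x, y, kernel = "radial", class.weights = cw, scale = FALSE)
    },
    lda = {
      xr <- .drop_constant_cols(x)
      list(keep = colnames(xr),
           fit = MASS::lda(xr, grouping = y,
                           prior = rep(1 / nlevels(y), nlevels(y))))
    },
    nnet = {
      nnet::nnet(x, nnet::class.ind(y), weights = wts, size = 8L,
                 decay = 0.1, maxit = 200L, MaxNWts = 20000L, trace = FALSE,
                 softmax = TRUE)
    },
    stop("unknown classifier family: ", family, call. = FALSE))
}

.family_predict <- function(family, fit, x) {
  switch(family,
    ensemble = predict(fit, data = data.frame(x))$predictions,
    tree = {
      pr <- predict(fit, newdata = data.frame(x), type = "prob")
      factor(colnames(pr)[max.col(pr, ties.method = "first")],
             levels = colnames(pr))
    },
    knn = class::knn(fit$x, x, fit$y, k = fit$k),
    svm = predict(fit, x),
    lda = predict(fit$fit, x[, fit$keep, drop = FALSE])$class,
    nnet = {
      pr <- predict(fit, x)
      factor(colnames(pr)[max.col(pr, ties.method = "first")],
             levels = colnames(pr))
    })
}

#' Train a Pfirrmann grade classifier (grades 1-4)
#'
#' Fits one of six classifier families on nucleus correlogram features with
#' per-sample class weights `tw_grade` (see [class_weights()]) and reports
#' seeded stratified k-fold cross-validated accuracy. Grade-5 samples must be
#' excluded beforehand: the height rule owns grade 5. The ensemble family is
#' the reference model (bagged decision trees: 15 learning cycles, minimum
#' leaf size 1, 20 variables sampled per split; the Gini criterion stands in
#' for twoing, which no available tree backend implements).
#'
#' @param features numeric matrix, one row per disc.
#' @param grades integer grades in 1-4 (at least two classes).
#' @param weights a [class_weights()] over the grades present; computed from
#'   the empirical frequencies when `NULL`.
#' @param family one of `"ensemble"`, `"tree"`, `"knn"`, `"svm"`, `"lda"`,
#'   `"nnet"`.
#' @param cv_folds number of cross-validation folds.
#' @param seed integer seed controlling folds and the ensemble.
#' @param height_threshold_mm grade-5 height threshold stored for prediction.
#' @return a `grading_model`: list with the fitted classifier, `family`,
#'   `cv_accuracy` (percent), `cv_predictions`, `levels`, `weights`,
#'   `height_threshold_mm`, `seed`.
#' @export
train_grader <- function(features, grades, weights = NULL,
                         family = "ensemble", cv_folds = 10L, seed = 1L,
                         height_threshold_mm = 3.0) {
  family <- match.arg(family, GRADER_FAMILIES)
  features <- as.matrix(features)
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  if (any(grades == 5L))
    stop("training error: grade-5 samples are owned by the height rule",
         call. = FALSE)
  y <- factor(grades)
  if (nlevels(y) < 2L)
    stop("training error: need at least two grade classes", call. = FALSE)
  if (is.null(weights))
    weights <- class_weights(table(y))
  tw <- weights$tw
  names(tw) <- names(weights$f)
  wts <- as.numeric(tw[as.character(y)])

  set.seed(seed)
  fold <- .stratified_folds(y, cv_folds)
  cv_pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (kf in seq_len(cv_folds)) {
    tr <- fold != kf
    if (length(unique(y[tr])) < 2L) next
    fit <- .family_fit(family, features[tr, , drop = FALSE], y[tr],
                       wts[tr], seed + kf)
    cv_pred[!tr] <- .family_predict(family, fit,
                                    features[!tr, , drop = FALSE])
  }
  cv_acc <- 100 * mean(cv_pred == y, na.rm = TRUE)
  final <- .family_fit(family, features, y, wts, seed)
  structure(list(fit = final, family = family,
                 cv_accuracy = cv_acc, cv_predictions = cv_pred,
                 levels = levels(y), weights = weights,
                 height_threshold_mm = height_threshold_mm,
                 n_features = ncol(features), seed = seed),
            class = "grading_model")
}

#' @export
print.grading_model <- function(x, ...) {
  cat(sprintf(
    "grading_model: %s on %d features, CV accuracy %.1f%%, height rule %.1f mm\n",
    x$family, x$n_features, x$cv_accuracy, x$height_threshold_mm))
  invisible(x)
}

#' Predict Pfirrmann grades
#'
#' The height rule is applied first: any disc strictly below the model's
#' height threshold is grade 5. Remaining discs get the classifier's grade
#' (1-4).
#'
#' @param model a `grading_model` from [train_grader()].
#' @param features numeric matrix of SSCC features (one row per disc).
#' @param height_mm disc heights in millimetres (same length as rows).
#' @return integer grades in 1-5.
#' @export
predict_grade <- function(model, features, height_mm) {
  features <- as.matrix(features)
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  stopifnot(nrow(features) == length(height_mm))
  out <- apply_height_rule(height_mm, model$height_threshold_mm)
  todo <- is.na(out)
  if (any(todo)) {
    cls <- .family_predict(model$family, model$fit,
                           features[todo, , drop = FALSE])
    out[todo] <- as.integer(as.character(cls))
  }
  out
}

#' Evaluate grade predictions
#'
#' Builds the 5x5 confusion matrix (rows = true grade), the per-grade
#' accuracies (diagonal over row sum, percent), and the frequency-weighted
#' mean accuracy `sum(f_c * acc_c) / sum(f_c)`. With `f` equal to the
#' empirical class counts this equals the plain accuracy.
#'
#' @param truth,predicted integer grade vectors in 1-5.
#' @param f per-grade frequency weights; defaults to the empirical counts.
#' @return an `eval_report`: list with `confusion`, `class_accuracy`,
#'   `weighted_mean_accuracy`, `f`.
#' @export
evaluate_grading <- function(truth, predicted, f = NULL) {
  if (length(truth) != length(predicted))
    stop("truth and predicted lengths differ", call. = FALSE)
  lev <- 1:5
  confusion <- table(factor(truth, levels = lev),
                     factor(predicted, levels = lev))
  dimnames(confusion) <- list(true = lev, predicted = lev)
  rs <- rowSums(confusion)
  acc <- ifelse(rs > 0, 100 * diag(confusion) / rs, NA_real_)
  if (is.null(f)) f <- as.numeric(rs)
  structure(list(confusion = unclass(confusion),
                 class_accuracy = setNames(as.numeric(acc), lev),
                 weighted_mean_accuracy =
                   weighted_mean_accuracy(acc, f),
                 f = f),
            class = "eval_report")
}

#' Frequency-weighted mean of per-class accuracies
#'
#' `sum(f_c * acc_c) / sum(f_c)` over the classes with nonzero weight;
#' classes with `NA` accuracy and zero weight are dropped.
#'
#' @param acc per-class accuracies (percent).
#' @param f per-class frequencies.
#' @return the weighted mean accuracy (percent).
#' @examples
#' weighted_mean_accuracy(c(68.3, 92.6, 79.0, 82.7, 76.2),
#'                        c(60, 1002, 167, 295, 21)) # 88.1 at 1 decimal
#' @export
weighted_mean_accuracy <- function(acc, f) {
  keep <- f > 0 & !is.na(acc)
  sum(f[keep] * acc[keep]) / sum(f[keep])
}

#' @export
print.eval_report <- function(x, ...) {
  cat("confusion matrix (rows = true grade):\n")
  print(x$confusion)
  cat("per-grade accuracy (%):",
      paste(sprintf("%.1f", x$class_accuracy), collapse = " "), "\n")
  cat(sprintf("weighted mean accuracy: %.1f%%\n", x$weighted_mean_accuracy))
  invisible(x)
}

#' Serialize an evaluation report to JSON (and the confusion matrix to CSV)
#'
#' @param report an `eval_report`.
#' @param json_path optional JSON output path.
#' @param confusion_csv optional CSV output path for the confusion matrix.
#' @return the JSON string, invisibly.
#' @export
eval_report_json <- function(report, json_path = NULL, confusion_csv = NULL) {
  obj <- list(confusion = report$confusion,
              class_accuracy = report$class_accuracy,
              weighted_mean_accuracy = report$weighted_mean_accuracy,
              f = report$f)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(json_path)) writeLines(js, json_path)
  if (!is.null(confusion_csv))
    utils::write.csv(report$confusion, confusion_csv)
  invisible(js)
}
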