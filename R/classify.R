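# Foreground/background voxel classifier: a soft-margin SVM with a
# radial-basis kernel at the LIBSVM defaults (cost 1, gamma = 1/dimension),
# on per-feature standardized inputs.

#' Train the foreground/background classifier
#'
#' Fits an RBF-kernel support vector machine (via LIBSVM through e1071) on
#' balanced foreground and background feature matrices. Features are
#' standardized (center/scale fitted on the training data and stored for
#' prediction); hyperparameters are the toolkit defaults: `cost = 1`,
#' `gamma = 1/ncol`. Training is deterministic for fixed inputs.
#'
#' @param fg_features,bg_features numeric matrices (rows = samples) with the
#'   same number of columns.
#' @param seed RNG seed (kept for interface stability; the fit itself is
#'   deterministic).
#' @return object of class `st_classifier` with fields `model`, `center`,
#'   `scale`, `dimension` and `training_accuracy`.
#' @export
train_classifier <- function(fg_features, bg_features, seed = 1L) {
  fg_features <- as.matrix(fg_features)
  bg_features <- as.matrix(bg_features)
  if (nrow(fg_features) == 0 || nrow(bg_features) == 0)
    stop("both classes must be non-empty")
  if (ncol(fg_features) != ncol(bg_features))
    stop("feature dimension mismatch between classes")
  x <- rbind(fg_features, bg_features)
  y <- factor(c(rep("fg", nrow(fg_features)), rep("bg", nrow(bg_features))),
              levels = c("bg", "fg"))
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  model <- with_seed(seed, e1071::svm(
    x = xs, y = y, type = "C-classification", kernel = "radial",
    cost = 1, gamma = 1 / ncol(xs), scale = FALSE))
  acc <- mean(stats::predict(model, xs) == y)
  structure(list(model = model, center = ctr, scale = scl,
                 dimension = ncol(xs), training_accuracy = acc,
                 seed = as.integer(seed)),
            class = "st_classifier")
}

#' Predict foreground membership for feature vectors
#'
#' @param object an `st_classifier`.
#' @param features numeric matrix, one row per voxel, `object$dimension`
#'   columns.
#' @param ... unused.
#' @return logical vector, `TRUE` = foreground.
#' @export
predict.st_classifier <- function(object, features, ...) {
  features <- matrix(as.numeric(features), ncol = object$dimension)
  xs <- scale(features, center = object$center, scale = object$scale)
  as.character(stats::predict(object$model, xs)) == "fg"
}

#' @export
print.st_classifier <- function(x, ...) {
  cat(sprintf(
    "<st_classifier> RBF SVM, %d features, %d SVs, training accuracy %.1f%%\n",
    x$dimension, nrow(x$model$SV), 100 * x$training_accuracy))
  invisible(x)
}
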