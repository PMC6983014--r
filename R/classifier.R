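#' Train a one-against-all linear-kernel SVM
#'
#' Fits one binary soft-margin SVM per class (that class versus all others)
#' on feature columns standardized by training statistics, so validation
#' rows never leak into the scaling. The underlying binary solver is
#' `e1071::svm` (libsvm) with deterministic settings; this module owns the
#' one-against-all assembly, the standardization, and the decision rule.
#'
#' @param x numeric matrix, samples x features (already restricted to the
#'   feature subset under evaluation).
#' @param y class ids, one per row; at least 2 classes with at least 2 rows
#'   each.
#' @param C soft-margin cost, default 1.
#' @param kernel `"linear"` (default) or `"radial"`.
#' @param gamma RBF bandwidth, only used for the radial kernel; default
#'   `1/ncol(x)`.
#' @return An object of class `har_oaa`: per-class binary models with
#'   orientation signs, the training mean/scale, and the class id list.
#' @export
train_oaa_linear <- function(x, y, C = 1, kernel = c("linear", "radial"),
                             gamma = NULL) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("y length must equal the number of rows")
  if (anyNA(x) || any(!is.finite(x))) stop("training rows contain non-finite values")
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("training data must contain at least 2 classes")
  counts <- table(y)
  small <- names(counts)[counts < 2L]
  if (length(small))
    stop("classes with fewer than 2 training rows: ",
         paste(small, collapse = ", "))
  if (nrow(unique(x)) == 1L)
    stop("degenerate training data: all rows identical")
  center <- colMeans(x)
  scale_ <- apply(x, 2L, stats::sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  xs <- scale(x, center = center, scale = scale_)
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  models <- vector("list", length(classes))
  signs <- numeric(length(classes))
  for (i in seq_along(classes)) {
    yk <- factor(ifelse(y == classes[i], "pos", "neg"),
                 levels = c("pos", "neg"))
    fit <- e1071::svm(xs, yk, kernel = kernel, cost = C, gamma = gamma,
                      scale = FALSE, probability = FALSE)
    dv <- attr(stats::predict(fit, xs, decision.values = TRUE),
               "decision.values")[, 1L]
    # orient the decision value so positive means "this class"
    signs[i] <- if (mean(dv[yk == "pos"]) >= mean(dv[yk == "neg"])) 1 else -1
    models[[i]] <- fit
  }
  structure(list(models = models, signs = signs, classes = classes,
                 center = center, scale = scale_, C = C, kernel = kernel,
                 gamma = gamma, n_features = ncol(x)),
            class = "har_oaa")
}

#' @export
print.har_oaa <- function(x, ...) {
  cat(sprintf(
    "har_oaa: %d one-against-all %s-kernel SVMs (C = %g) on %d features\n",
    length(x$classes), x$kernel, x$C, x$n_features))
  invisible(x)
}

.oaa_decision <- function(object, newdata) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop(sprintf("dimension mismatch: model expects %d features, got %d",
                 object$n_features, ncol(newdata)))
  if (anyNA(newdata) || any(!is.finite(newdata)))
    stop("prediction rows contain non-finite values")
  xs <- scale(newdata, center = object$center, scale = object$scale)
  dec <- sapply(seq_along(object$models), function(i) {
    dv <- attr(stats::predict(object$models[[i]], xs,
                              decision.values = TRUE),
               "decision.values")[, 1L]
    object$signs[i] * dv
  })
  matrix(dec, nrow = nrow(xs),
         dimnames = list(NULL, as.character(object$classes)))
}

#' Predict activity labels with a one-against-all model
#'
#' Each row gets the class whose binary decision value is largest; exact
#' ties break to the lowest class id.
#'
#' @param object a `har_oaa` model.
#' @param newdata numeric matrix with the model's feature count.
#' @param ... unused.
#' @return integer vector of predicted class ids.
#' @export
predict.har_oaa <- function(object, newdata, ...) {
  dec <- .oaa_decision(object, newdata)
  object$classes[apply(dec, 1L, which.max)]  # which.max: lowest index on ties
}

#' Build a confusion matrix with recall/precision margins
#'
#' @param actual,predicted parallel label vectors.
#' @param classes optional class id ordering; default the sorted union.
#' @return An object of class `har_confusion`: `counts` (K x K, rows =
#'   actual, columns = predicted), `recall`, `precision` (0 where a margin
#'   is empty), and overall `accuracy` (trace / total).
#' @export
confusion_matrix <- function(actual, predicted, classes = NULL) {
  if (length(actual) != length(predicted))
    stop("actual and predicted lengths differ")
  if (!length(actual)) stop("empty test set")
  if (is.null(classes)) classes <- sort(unique(c(actual, predicted)))
  counts <- table(factor(actual, levels = classes),
                  factor(predicted, levels = classes))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(actual = as.character(classes),
                                   predicted = as.character(classes)))
  rs <- rowSums(counts)
  cs <- colSums(counts)
  dg <- diag(counts)
  structure(list(
    counts = counts,
    classes = classes,
    recall = ifelse(rs > 0, dg / rs, 0),
    precision = ifelse(cs > 0, dg / cs, 0),
    accuracy = sum(dg) / sum(counts)),
    class = "har_confusion")
}

#' Evaluate a one-against-all model on labeled rows
#'
#' @param model a `har_oaa` model.
#' @param x numeric matrix of test rows.
#' @param y true class ids.
#' @return a [confusion_matrix()] over the union of model and test classes.
#' @export
evaluate_oaa <- function(model, x, y) {
  stopifnot(inherits(model, "har_oaa"))
  if (!length(y)) stop("empty test set")
  pred <- stats::predict(model, x)
  confusion_matrix(y, pred, classes = sort(unique(c(model$classes, y))))
}

#' @export
print.har_confusion <- function(x, ...) {
  m <- cbind(x$counts, Recall = sprintf("%.2f%%", 100 * x$recall))
  m <- rbind(m, Precision = c(sprintf("%.2f%%", 100 * x$precision),
                              sprintf("%.2f%%", 100 * x$accuracy)))
  cat("confusion matrix (rows = actual, columns = predicted):\n")
  print(m, quote = FALSE)
  invisible(x)
}

#' Write a confusion matrix (with margins) to CSV
#'
#' @param cm a `har_confusion`.
#' @param path output CSV path.
#' @export
write_confusion_csv <- function(cm, path) {
  stopifnot(inherits(cm, "har_confusion"))
  d <- as.data.frame(cm$counts)
  d$recall <- cm$recall
  d <- rbind(d, precision = c(cm$precision, cm$accuracy))
  utils::write.csv(d, path, row.names = TRUE)
  invisible(path)
}
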