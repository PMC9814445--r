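## R interface to the compiled gradient-boosted tree learner.

#' Fit a gradient-boosted decision tree classifier
#'
#' Newton boosting on logistic loss with exact greedy splits, no sampling,
#' hence fully deterministic. Importance is total split gain per feature.
#'
#' @param x numeric matrix (samples x features) with column names.
#' @param y binary labels (0/1, logical, or 2-level factor; the second level
#'   is the positive class).
#' @param n_trees,max_depth,learning_rate boosting hyperparameters.
#' @param lambda L2 regularisation on leaf weights.
#' @param min_leaf minimum samples per leaf.
#' @return a `gbdt_model`.
#' @export
gbdt_fit <- function(x, y, n_trees = 150, max_depth = 2,
                     learning_rate = 0.1, lambda = 1, min_leaf = 5) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- as_binary(y)
  if (length(unique(y)) < 2)
    stop("both classes must be present", call. = FALSE)
  fit <- .gbdt_train_cpp(x, as.numeric(y), as.integer(n_trees),
                         as.integer(max_depth), learning_rate, lambda,
                         as.integer(min_leaf))
  structure(list(trees = fit$trees, base = fit$base,
                 importance = setNames(fit$importance, colnames(x)),
                 features = colnames(x),
                 params = list(n_trees = n_trees, max_depth = max_depth,
                               learning_rate = learning_rate,
                               lambda = lambda, min_leaf = min_leaf)),
            class = "gbdt_model")
}

as_binary <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2) stop("factor labels must have 2 levels",
                              call. = FALSE)
    return(as.integer(y) - 1L)
  }
  if (is.logical(y)) return(as.integer(y))
  if (!all(y %in% c(0, 1))) stop("labels must be binary", call. = FALSE)
  as.integer(y)
}

#' Predict from a gbdt model
#'
#' @param object a `gbdt_model`.
#' @param newdata samples x features matrix; columns are matched by name to
#'   the training features.
#' @param type `"prob"` (default) for positive-class probability, `"score"`
#'   for the raw additive score (log-odds).
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.gbdt_model <- function(object, newdata,
                               type = c("prob", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    missing <- setdiff(object$features, colnames(newdata))
    if (length(missing))
      stop("newdata lacks feature(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    newdata <- newdata[, object$features, drop = FALSE]
  } else if (ncol(newdata) != length(object$features)) {
    stop("newdata has wrong number of columns", call. = FALSE)
  }
  score <- .gbdt_predict_cpp(object$trees, object$base, newdata)
  if (type == "score") score else plogis(score)
}

#' @export
print.gbdt_model <- function(x, ...) {
  cat(sprintf("gbdt_model: %d trees, depth %d, lr %.3g, %d features (%d used)\n",
              length(x$trees), x$params$max_depth,
              x$params$learning_rate, length(x$features),
              sum(x$importance > 0)))
  invisible(x)
}
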