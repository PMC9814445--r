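## Two-layer stacked screening model: gradient-boosted layer-1 classifiers
## (HN: HCC vs normal, HL: HCC vs liver disease) combined by an L2-penalised
## logistic regression on their out-of-fold outputs, producing the tumor
## score h = w'x + b (t-score).

#' Training configuration
#'
#' @param folds number of cross-validation folds.
#' @param grid data.frame of gradient-boosting hyperparameter combinations
#'   (`n_trees`, `max_depth`, `learning_rate`); the default is a small grid
#'   of implementer-chosen values.
#' @param rfe_step_frac fraction of remaining features eliminated per
#'   recursive-feature-elimination step (at least 1 feature per step); 0
#'   approximates the classical step-1 elimination.
#' @param lambda_grid L2 penalties searched for the logistic combiner.
#' @param repeats repetitions of the fivefold cross-validation when building
#'   out-of-fold layer-1 outputs (predictions averaged over repeats).
#' @param seed integer seed for fold assignment.
#' @return a `train_config` list.
#' @export
train_config <- function(folds = 5,
                         grid = expand.grid(n_trees = c(100, 300),
                                            max_depth = c(2, 3),
                                            learning_rate = c(0.05, 0.1)),
                         rfe_step_frac = 0.1,
                         lambda_grid = 10^seq(-3, 2, length.out = 11),
                         repeats = 1, seed = 1) {
  check_count(folds, "folds", 2L)
  check_count(repeats, "repeats", 1L)
  structure(list(folds = as.integer(folds), grid = grid,
                 rfe_step_frac = rfe_step_frac, lambda_grid = lambda_grid,
                 repeats = as.integer(repeats), seed = seed),
            class = "train_config")
}

## Stratified fold assignment, deterministic under seed.
cv_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

## Pooled out-of-fold AUC for one hyperparameter setting.
cv_auc <- function(x, y, folds, n_trees, max_depth, learning_rate) {
  oof <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) next
    fit <- gbdt_fit(x[tr, , drop = FALSE], y[tr], n_trees = n_trees,
                    max_depth = max_depth, learning_rate = learning_rate)
    oof[!tr] <- predict(fit, x[!tr, , drop = FALSE])
  }
  ok <- !is.na(oof)
  auc_rank(oof[ok], y[ok])
}

## Grid search over the boosting hyperparameters; first maximum wins
## (deterministic).
grid_search_gbdt <- function(x, y, config, folds) {
  g <- config$grid
  scores <- vapply(seq_len(nrow(g)), function(i)
    cv_auc(x, y, folds, g$n_trees[i], g$max_depth[i], g$learning_rate[i]),
    numeric(1))
  best <- which.max(scores)
  list(params = g[best, , drop = FALSE], cv_auc = scores[best],
       all_scores = scores)
}

## Recursive feature elimination with cross-validated AUC. Elimination uses
## fixed mid-grid boosting parameters; scanning from the full set down, the
## first (largest) feature set achieving the maximum CV AUC is kept.
rfecv_gbdt <- function(x, y, config, folds,
                       n_trees = 100, max_depth = 2, learning_rate = 0.1) {
  feats <- colnames(x)
  history <- list()
  while (length(feats) >= 1) {
    xs <- x[, feats, drop = FALSE]
    score <- cv_auc(xs, y, folds, n_trees, max_depth, learning_rate)
    history[[length(history) + 1L]] <- list(features = feats,
                                            cv_auc = score)
    if (length(feats) == 1L) break
    fit <- gbdt_fit(xs, y, n_trees = n_trees, max_depth = max_depth,
                    learning_rate = learning_rate)
    drop_n <- max(1L, floor(config$rfe_step_frac * length(feats)))
    ## ties broken by column order (stable): later duplicates dropped first
    imp <- fit$importance[feats]
    keep_order <- order(imp, decreasing = TRUE)
    feats <- feats[sort(keep_order[seq_len(length(feats) - drop_n)])]
  }
  scores <- vapply(history, `[[`, numeric(1), "cv_auc")
  best <- which.max(scores)   # first max = largest feature set on ties
  list(features = history[[best]]$features, cv_auc = scores[best],
       n_evaluated = length(history))
}

#' Train the HCC-versus-normal layer-1 model
#'
#' Features are chosen by recursive feature elimination with cross-validated
#' AUC; boosting hyperparameters by cross-validated grid search on the
#' selected features; the final model is refit on all samples.
#'
#' @param x samples x features matrix (named columns).
#' @param y binary labels, positive = HCC.
#' @param config a [train_config()].
#' @return a `layer_one_model` (kind `"HN"`).
#' @export
train_hn <- function(x, y, config = train_config()) {
  y <- as_binary(y)
  if (length(unique(y)) < 2) stop("both classes must be present",
                                  call. = FALSE)
  x <- as.matrix(x)
  folds <- cv_folds(y, config$folds, derive_seed(config$seed, 11L))
  sel <- rfecv_gbdt(x, y, config, folds)
  xs <- x[, sel$features, drop = FALSE]
  gs <- grid_search_gbdt(xs, y, config, folds)
  fit <- gbdt_fit(xs, y, n_trees = gs$params$n_trees,
                  max_depth = gs$params$max_depth,
                  learning_rate = gs$params$learning_rate)
  structure(list(kind = "HN", features = sel$features, model = fit,
                 cv_auc = gs$cv_auc, grid = gs$params,
                 rfe_cv_auc = sel$cv_auc),
            class = "layer_one_model")
}

#' Train the HCC-versus-liver-disease layer-1 model
#'
#' An initial fit on all features identifies those with importance greater
#' than zero; hyperparameters are then grid-searched on that subset and the
#' final model refit.
#'
#' @inheritParams train_hn
#' @return a `layer_one_model` (kind `"HL"`).
#' @export
train_hl <- function(x, y, config = train_config()) {
  y <- as_binary(y)
  if (length(unique(y)) < 2) stop("both classes must be present",
                                  call. = FALSE)
  x <- as.matrix(x)
  folds <- cv_folds(y, config$folds, derive_seed(config$seed, 13L))
  fit0 <- gbdt_fit(x, y, n_trees = 100, max_depth = 2, learning_rate = 0.1)
  feats <- names(fit0$importance)[fit0$importance > 0]
  if (length(feats) == 0L) feats <- colnames(x)  # degenerate: keep all
  xs <- x[, feats, drop = FALSE]
  gs <- grid_search_gbdt(xs, y, config, folds)
  fit <- gbdt_fit(xs, y, n_trees = gs$params$n_trees,
                  max_depth = gs$params$max_depth,
                  learning_rate = gs$params$learning_rate)
  structure(list(kind = "HL", features = feats, model = fit,
                 cv_auc = gs$cv_auc, grid = gs$params),
            class = "layer_one_model")
}

#' @export
predict.layer_one_model <- function(object, newdata, ...) {
  predict(object$model, as.matrix(newdata)[, object$features,
                                           drop = FALSE], ...)
}

#' @export
print.layer_one_model <- function(x, ...) {
  cat(sprintf("%s model: %d features, CV AUC %.3f\n", x$kind,
              length(x$features), x$cv_auc))
  invisible(x)
}

## Ridge (L2) logistic regression by IRLS; intercept unpenalised.
ridge_logistic <- function(x, y, lambda, max_iter = 50, tol = 1e-9) {
  x <- cbind(1, as.matrix(x))
  beta <- rep(0, ncol(x))
  pen <- diag(c(0, rep(lambda, ncol(x) - 1L)), ncol(x))
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new <- solve(crossprod(x, w * x) + pen, crossprod(x, w * z))
    if (max(abs(new - beta)) < tol) { beta <- drop(new); break }
    beta <- drop(new)
  }
  list(b = beta[1], w = beta[-1])
}

#' Train the logistic stacking layer
#'
#' Fits an L2-penalised logistic regression on the layer-1 out-of-fold
#' outputs, selecting the penalty from `lambda_grid` by cross-validated AUC.
#' The input must be genuine out-of-fold predictions: the matrix must carry
#' `attr(x, "oof") = TRUE` (as produced by [run_full_training()]'s internal
#' out-of-fold loop), otherwise an error is raised unless
#' `allow_in_fold = TRUE`.
#'
#' @param oof samples x 2 matrix of layer-1 outputs (columns `hn`, `hl`).
#' @param y binary labels (HCC vs non-HCC).
#' @param config a [train_config()].
#' @param allow_in_fold override the leakage guard (testing only).
#' @return a `stack_model`: `w` (length 2), `b`, `lambda`, `threshold`
#'   (set by [run_full_training()]; `NA` here), plus layer-1 slots unset.
#' @export
train_stack <- function(oof, y, config = train_config(),
                        allow_in_fold = FALSE) {
  if (!isTRUE(attr(oof, "oof")) && !allow_in_fold)
    stop("layer-1 predictions are not flagged out-of-fold; ",
         "refusing to train a leaky stacker (see 'allow_in_fold')",
         call. = FALSE)
  y <- as_binary(y)
  oof <- as.matrix(oof)
  stopifnot(ncol(oof) == 2)
  folds <- cv_folds(y, config$folds, derive_seed(config$seed, 17L))
  scores <- vapply(config$lambda_grid, function(l) {
    pred <- rep(NA_real_, length(y))
    for (f in sort(unique(folds))) {
      tr <- folds != f
      fit <- ridge_logistic(oof[tr, , drop = FALSE], y[tr], l)
      pred[!tr] <- drop(oof[!tr, , drop = FALSE] %*% fit$w) + fit$b
    }
    auc_rank(pred, y)
  }, numeric(1))
  lambda <- config$lambda_grid[which.max(scores)]
  fit <- ridge_logistic(oof, y, lambda)
  structure(list(hn = NULL, hl = NULL, w = setNames(fit$w, c("hn", "hl")),
                 b = fit$b, lambda = lambda, threshold = NA_real_,
                 lambda_cv_auc = scores),
            class = "stack_model")
}

#' Tumor score (t-score)
#'
#' h = w . (HN(sample), HL(sample)) + b. Accepts either a feature matrix
#' (layer-1 models must be attached to the stack, as after
#' [run_full_training()]) or a precomputed 2-column layer-1 output matrix.
#'
#' @param model a `stack_model`.
#' @param x samples x features matrix, or samples x 2 layer-1 output matrix
#'   when `layer1 = TRUE`.
#' @param layer1 set `TRUE` when `x` already holds layer-1 outputs.
#' @return numeric vector of t-scores.
#' @export
t_score <- function(model, x, layer1 = FALSE) {
  stopifnot(inherits(model, "stack_model"))
  x <- as.matrix(x)
  l1 <- if (layer1) {
    stopifnot(ncol(x) == 2)
    x
  } else {
    if (is.null(model$hn) || is.null(model$hl))
      stop("stack model has no fitted layer-1 models", call. = FALSE)
    cbind(hn = predict(model$hn, x), hl = predict(model$hl, x))
  }
  drop(l1 %*% model$w) + model$b
}

#' Final class assignment
#'
#' @param model a `stack_model` (supplies the default threshold).
#' @param h t-scores.
#' @param threshold decision threshold; HCC iff `h >= threshold` (boundary
#'   counts as HCC).
#' @return character vector `"HCC"` / `"non-HCC"`.
#' @export
predict_class <- function(model, h, threshold = model$threshold) {
  if (is.na(threshold)) stop("no decision threshold set", call. = FALSE)
  ifelse(h >= threshold, "HCC", "non-HCC")
}

## Threshold maximising Youden's J (sens + spec - 1) on scores; first
## maximum at the highest threshold (deterministic).
youden_threshold <- function(scores, y) {
  rc <- roc_curve(scores, y)
  j <- rc$sensitivity + rc$specificity - 1
  rc$threshold[which.max(j)]
}

#' End-to-end training of the stacked screening model
#'
#' Trains the HN and HL layer-1 models on the cohort's training split,
#' builds out-of-fold layer-1 predictions over the whole training set
#' (each sample predicted by models fitted without it, using the
#' full-training-set feature selections and hyperparameters), fits the
#' logistic stacker on them, sets the decision threshold by Youden's J on
#' the out-of-fold t-scores, and evaluates on the untouched test split.
#'
#' @param cohort a `cohort` object from [simulate_cohort()], or a list with
#'   `samples` (`id`, `class`, `stage`, `split`, optionally `afp`, `pivka`)
#'   and `beta` (markers x samples).
#' @param config a [train_config()].
#' @return list: `model` (stack with layer-1 models attached), `markers`
#'   (deduplicated union of layer-1 features), `oof` (out-of-fold layer-1
#'   outputs), `folds`, `train_report`, `test_report`.
#' @export
run_full_training <- function(cohort, config = train_config()) {
  s <- cohort$samples
  if (!all(c("normal", "liver", "hcc") %in% s$class))
    stop("cohort must contain normal, liver and hcc samples",
         call. = FALSE)
  x_all <- t(cohort$beta)
  tr <- s$split == "train"
  xtr <- x_all[tr, , drop = FALSE]
  cls <- s$class[tr]
  y_hcc <- as.integer(cls == "hcc")

  hn_rows <- cls %in% c("hcc", "normal")
  hl_rows <- cls %in% c("hcc", "liver")
  hn <- train_hn(xtr[hn_rows, , drop = FALSE],
                 cls[hn_rows] == "hcc", config)
  hl <- train_hl(xtr[hl_rows, , drop = FALSE],
                 cls[hl_rows] == "hcc", config)

  ## Out-of-fold layer-1 outputs over the whole training split.
  n_tr <- nrow(xtr)
  oof_acc <- matrix(0, n_tr, 2, dimnames = list(s$id[tr], c("hn", "hl")))
  folds_used <- vector("list", config$repeats)
  for (r in seq_len(config$repeats)) {
    folds <- cv_folds(cls, config$folds,
                      derive_seed(config$seed, 100L + r))
    folds_used[[r]] <- folds
    for (f in seq_len(config$folds)) {
      in_f <- folds == f
      sub <- !in_f
      fit_hn <- gbdt_fit(
        xtr[sub & hn_rows, hn$features, drop = FALSE],
        cls[sub & hn_rows] == "hcc",
        n_trees = hn$grid$n_trees, max_depth = hn$grid$max_depth,
        learning_rate = hn$grid$learning_rate)
      fit_hl <- gbdt_fit(
        xtr[sub & hl_rows, hl$features, drop = FALSE],
        cls[sub & hl_rows] == "hcc",
        n_trees = hl$grid$n_trees, max_depth = hl$grid$max_depth,
        learning_rate = hl$grid$learning_rate)
      oof_acc[in_f, 1] <- oof_acc[in_f, 1] +
        predict(fit_hn, xtr[in_f, hn$features, drop = FALSE])
      oof_acc[in_f, 2] <- oof_acc[in_f, 2] +
        predict(fit_hl, xtr[in_f, hl$features, drop = FALSE])
    }
  }
  oof <- oof_acc / config$repeats
  attr(oof, "oof") <- TRUE

  stack <- train_stack(oof, y_hcc, config)
  stack$hn <- hn
  stack$hl <- hl
  h_tr <- t_score(stack, oof, layer1 = TRUE)
  stack$threshold <- youden_threshold(h_tr, y_hcc)

  markers <- sort(union(hn$features, hl$features))

  report <- function(x, samp) {
    h <- t_score(stack, x)
    y <- as.integer(samp$class == "hcc")
    pred <- predict_class(stack, h)
    cm <- confusion_counts(
      tp = sum(pred == "HCC" & y == 1), fp = sum(pred == "HCC" & y == 0),
      tn = sum(pred == "non-HCC" & y == 0),
      fn = sum(pred == "non-HCC" & y == 1))
    list(h = setNames(h, samp$id), auc = roc_auc(h, y),
         confusion = cm, metrics = confusion_metrics(cm),
         by_stage = subgroup_positive_rates(
           (pred == "HCC")[y == 1], samp$stage[y == 1]))
  }
  train_report <- list(
    oof_auc = roc_auc(h_tr, y_hcc),
    threshold = stack$threshold,
    h = setNames(h_tr, s$id[tr]))
  test <- s$split == "test"
  test_report <- if (any(test))
    report(x_all[test, , drop = FALSE], s[test, , drop = FALSE]) else NULL

  list(model = stack, markers = markers, n_markers = length(markers),
       oof = oof, folds = folds_used, train_report = train_report,
       test_report = test_report,
       train_ids = s$id[tr], test_ids = s$id[test])
}

#' @export
print.stack_model <- function(x, ...) {
  cat(sprintf("stack_model: h = %.3f*hn + %.3f*hl + %.3f (lambda %.3g, threshold %s)\n",
              x$w[1], x$w[2], x$b, x$lambda,
              if (is.na(x$threshold)) "unset" else
                sprintf("%.3f", x$threshold)))
  invisible(x)
}
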