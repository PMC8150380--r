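MODEL_FAMILIES <- c("GBM", "XGB", "GLM", "RF", "SVM", "NN")

#' Default hyperparameter grids per model family
#'
#' Grids are kept small (at most a handful of configurations per family)
#' so that the resampling protocols stay desk-scale; every entry is a list
#' of scalar hyperparameters understood by the family's backend.
#'
#' @param family one of `"GBM"`, `"XGB"`, `"GLM"`, `"RF"`, `"SVM"`, `"NN"`.
#' @param p number of features (used for RF's `mtry` candidates).
#' @return list of hyperparameter configurations.
#' @export
default_grid <- function(family, p = 10) {
  switch(family,
    # classic gradient boosting parameterization: shallow trees, small
    # learning rate, no column subsampling
    GBM = list(list(max_depth = 2, eta = 0.1, nrounds = 150, colsample_bytree = 1, lambda = 0),
               list(max_depth = 3, eta = 0.1, nrounds = 150, colsample_bytree = 1, lambda = 0),
               list(max_depth = 3, eta = 0.05, nrounds = 300, colsample_bytree = 1, lambda = 0)),
    XGB = list(list(max_depth = 3, eta = 0.3, nrounds = 100, colsample_bytree = 0.8, lambda = 1),
               list(max_depth = 6, eta = 0.3, nrounds = 100, colsample_bytree = 0.8, lambda = 1),
               list(max_depth = 6, eta = 0.1, nrounds = 200, colsample_bytree = 0.8, lambda = 1)),
    GLM = list(list()),
    RF = list(list(ntree = 300, mtry = max(1, floor(sqrt(p)))),
              list(ntree = 300, mtry = max(1, floor(p / 3)))),
    SVM = list(list(cost = 1), list(cost = 10)),
    NN = list(list(size = 3, decay = 0.1), list(size = 5, decay = 0.01)),
    stop(sprintf("unknown model family '%s'", family))
  )
}

fit_backend <- function(family, X, y, pars, seed) {
  local_seed(seed, switch(family,
    GBM = ,
    XGB = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = pars$max_depth,
                    eta = pars$eta, colsample_bytree = pars$colsample_bytree,
                    lambda = pars$lambda, nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
      nrounds = pars$nrounds, verbose = 0),
    GLM = suppressWarnings(glm(y ~ ., data = data.frame(y = y, X, check.names = FALSE),
                               family = binomial())),
    RF = randomForest::randomForest(x = X, y = factor(y, levels = c(0, 1)),
                                    ntree = pars$ntree, mtry = pars$mtry),
    SVM = e1071::svm(x = X, y = factor(y, levels = c(0, 1)), kernel = "radial",
                     cost = pars$cost, probability = TRUE),
    NN = nnet::nnet(x = X, y = y, size = pars$size, decay = pars$decay,
                    maxit = 300, trace = FALSE, entropy = TRUE),
    stop(sprintf("unknown model family '%s'", family))
  ))
}

predict_backend <- function(family, fit, X) {
  switch(family,
    GBM = ,
    XGB = predict(fit, xgboost::xgb.DMatrix(X, nthread = 1)),
    GLM = unname(predict(fit, newdata = data.frame(X, check.names = FALSE), type = "response")),
    RF = unname(predict(fit, X, type = "prob")[, "1"]),
    SVM = {
      pr <- attr(predict(fit, X, probability = TRUE), "probabilities")
      unname(pr[, "1"])
    },
    NN = as.vector(predict(fit, X, type = "raw"))
  )
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Fit an essentiality classifier
#'
#' One contract over six model families (GBM, XGB, GLM, RF, SVM, NN):
#' inner stratified cross-validated grid search maximizing ROC-AUC over the
#' family's hyperparameter grid, then a refit on the full input. All
#' randomness (folds, backend fitting) flows from `seed`, so GLM, GBM, XGB
#' and RF fits are exactly reproducible.
#'
#' @param X standardized numeric matrix (genes x features), typically
#'   restricted to the selected features.
#' @param y binary labels (both classes required); see [roc_auc()] for the
#'   accepted encodings.
#' @param family model family name.
#' @param grid hyperparameter grid (list of lists); defaults to
#'   [default_grid()]. A single-configuration grid skips the inner CV.
#' @param cv_folds inner CV folds for tuning.
#' @param seed integer seed.
#' @return object of class `"ess_model"` with elements `family`, `fit`,
#'   `features` (required column order), `hyperparameters`, `cv_auc`
#'   (inner-CV ROC-AUC per configuration), `seed`.
#' @export
ess_fit <- function(X, y, family = "XGB", grid = NULL, cv_folds = 3, seed = 1) {
  family <- match.arg(family, MODEL_FAMILIES)
  X <- as.matrix(X)
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2) stop("ess_fit needs both classes present in y")
  if (is.null(grid)) grid <- default_grid(family, p = ncol(X))
  cv_auc <- rep(NA_real_, length(grid))
  best <- 1L
  if (length(grid) > 1) {
    fold <- local_seed(seed, stratified_folds(y, cv_folds))
    for (g in seq_along(grid)) {
      scores <- numeric(length(y))
      for (k in seq_len(cv_folds)) {
        tr <- fold != k
        fit_k <- fit_backend(family, X[tr, , drop = FALSE], y[tr], grid[[g]],
                             seed = seed + k)
        scores[!tr] <- predict_backend(family, fit_k, X[!tr, , drop = FALSE])
      }
      cv_auc[g] <- roc_auc(scores, y)
    }
    best <- which.max(cv_auc)
  }
  fit <- fit_backend(family, X, y, grid[[best]], seed = seed)
  structure(list(family = family, fit = fit, features = colnames(X),
                 hyperparameters = grid[[best]], cv_auc = cv_auc, seed = seed,
                 n_train = nrow(X), prevalence = mean(y)),
            class = "ess_model")
}

#' Predict essentiality probabilities
#'
#' @param object an `ess_model`.
#' @param newdata matrix with exactly the model's feature columns; a
#'   mismatch is an error naming the missing/extra features.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]` (named by rownames
#'   of `newdata` when present).
#' @export
predict.ess_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata)) || !identical(colnames(newdata), object$features)) {
    missing <- setdiff(object$features, colnames(newdata))
    extra <- setdiff(colnames(newdata), object$features)
    if (length(missing) || length(extra))
      stop(sprintf("feature mismatch: missing [%s], extra [%s]",
                   paste(missing, collapse = ","), paste(extra, collapse = ",")))
    newdata <- newdata[, object$features, drop = FALSE]  # same set, wrong order
  }
  p <- predict_backend(object$family, object$fit, newdata)
  p <- pmin(pmax(p, 0), 1)
  names(p) <- rownames(newdata)
  p
}

#' @export
print.ess_model <- function(x, ...) {
  cat(sprintf("ess_model [%s]: %d features, trained on %d genes (prevalence %.3f)\n",
              x$family, length(x$features), x$n_train, x$prevalence))
  if (any(!is.na(x$cv_auc)))
    cat(sprintf("  inner-CV ROC-AUC: best %.3f over %d configurations\n",
                max(x$cv_auc, na.rm = TRUE), length(x$cv_auc)))
  invisible(x)
}

#' @export
summary.ess_model <- function(object, ...) {
  print(object)
  cat("  hyperparameters:", paste(names(object$hyperparameters),
                                  unlist(object$hyperparameters),
                                  sep = "=", collapse = ", "), "\n")
  invisible(object)
}

#' @export
coef.ess_model <- function(object, ...) {
  if (object$family != "GLM") return(NULL)
  coef(object$fit)
}
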