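#' Elastic-net feature selection
#'
#' Cross-validated penalized logistic regression over a grid of mixing
#' parameters; the selected set is the features with nonzero coefficients
#' at the `(alpha, lambda)` pair minimizing cross-validated binomial
#' deviance. Fold assignment is fixed across the alpha grid so the
#' comparison is paired, and the whole search is deterministic given
#' `seed`.
#'
#' @param X standardized numeric matrix (genes x features).
#' @param y binary response (0/1 or coercible; both classes required).
#' @param alpha_grid mixing parameters between ridge (0) and lasso (1).
#' @param cv_folds number of CV folds.
#' @param seed integer seed for fold assignment.
#' @param lambda optional fixed lambda sequence passed to glmnet (mainly
#'   for exploring the shrinkage limits; default lets glmnet choose).
#' @return character vector of selected feature names (may be empty), with
#'   attributes `alpha` and `lambda` recording the chosen penalty.
#' @export
elasticnet_select <- function(X, y, alpha_grid = seq(0.1, 0.9, by = 0.1),
                              cv_folds = 5, seed = 1, lambda = NULL) {
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2) stop("elastic net needs both classes in y")
  if (min(table(y)) < cv_folds) stop("fewer members in a class than cv_folds")
  local_seed(seed, {
    foldid <- integer(length(y))
    for (cl in c(0, 1)) {
      idx <- which(y == cl)
      foldid[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
    }
    fits <- lapply(alpha_grid, function(a)
      glmnet::cv.glmnet(X, y, family = "binomial", alpha = a, foldid = foldid,
                        lambda = lambda, standardize = FALSE))
    best_dev <- vapply(fits, function(f) min(f$cvm), numeric(1))
    fit <- fits[[which.min(best_dev)]]
    beta <- as.matrix(coef(fit, s = "lambda.min"))[-1, 1]
    out <- names(beta)[beta != 0]
    attr(out, "alpha") <- alpha_grid[which.min(best_dev)]
    attr(out, "lambda") <- fit$lambda.min
    out
  })
}

#' Sparse partial least squares fit for a univariate response
#'
#' Iteratively extracts `K` sparse direction vectors. Per component, the
#' covariance vector `Z = X' y_res` is soft-thresholded at a fraction
#' `eta` of its largest absolute entry — `w_j = sign(Z_j) (|Z_j| -
#' eta * max|Z|)+` — then normalized; the score `t = X w` deflates both `X`
#' and `y` by their regression on `t`. A feature is selected when it has a
#' nonzero weight in any component. With `eta = 0`, `K = 1` the direction
#' is exactly the normalized `X' y`.
#'
#' @param X standardized matrix (genes x features).
#' @param y numeric response; binary labels are encoded +1/-1 and centered.
#' @param K number of components (`>= 1`, at most `min(dim(X))`).
#' @param eta sparsity parameter in `[0, 1)`.
#' @return list of class `"spls_fit"`: `W` (features x K weight matrix),
#'   `selected` (feature names), `K`, `eta`.
#' @export
spls_fit <- function(X, y, K = 4, eta = 0.7) {
  if (eta < 0 || eta >= 1) stop("eta must lie in [0, 1)")
  if (K < 1) stop("K must be >= 1")
  if (K > min(dim(X))) stop("K exceeds the rank bound min(n, p)")
  if (is.factor(y) || is.logical(y) || all(y %in% c(0, 1)))
    y <- ifelse(as_binary_labels(y) == 1, 1, -1)
  y <- y - mean(y)
  Xd <- X
  W <- matrix(0, ncol(X), K, dimnames = list(colnames(X), NULL))
  for (k in seq_len(K)) {
    Z <- drop(crossprod(Xd, y))
    thr <- eta * max(abs(Z))
    w <- sign(Z) * pmax(abs(Z) - thr, 0)
    if (all(w == 0)) break
    w <- w / sqrt(sum(w^2))
    W[, k] <- w
    t_k <- drop(Xd %*% w)
    tt <- sum(t_k^2)
    if (tt <= .Machine$double.eps) break
    Xd <- Xd - tcrossprod(t_k, drop(crossprod(Xd, t_k)) / tt)
    y <- y - t_k * sum(t_k * y) / tt
  }
  structure(list(W = W, selected = rownames(W)[rowSums(W != 0) > 0],
                 K = K, eta = eta), class = "spls_fit")
}

#' Ensemble sparse PLS selection over subsamples
#'
#' Runs [spls_fit()] on `B` stratified row subsamples and selects the
#' features whose selection frequency reaches `freq_threshold`.
#'
#' @inheritParams spls_fit
#' @param B number of subsample replicates (`>= 1`).
#' @param subsample_frac fraction of rows per replicate (stratified by
#'   class when `y` is binary).
#' @param freq_threshold minimum selection frequency in `[0, 1]`; 0 gives
#'   the union over replicates.
#' @param seed integer seed.
#' @return list of class `"ensemble_spls"`: `selected`, `frequencies`
#'   (named vector over all features), and the settings.
#' @export
ensemble_spls_select <- function(X, y, B = 100, subsample_frac = 0.8, K = 4,
                                 eta = 0.7, freq_threshold = 0.5, seed = 1) {
  if (B < 1) stop("B must be >= 1")
  binary <- is.factor(y) || is.logical(y) || all(y %in% c(0, 1))
  strata <- if (binary) as_binary_labels(y) else rep(0L, length(y))
  local_seed(seed, {
    counts <- setNames(numeric(ncol(X)), colnames(X))
    for (b in seq_len(B)) {
      idx <- unlist(lapply(unique(strata), function(cl) {
        pool <- which(strata == cl)
        sample(pool, max(2, round(subsample_frac * length(pool))))
      }))
      fit <- spls_fit(X[idx, , drop = FALSE], y[idx], K = K, eta = eta)
      counts[fit$selected] <- counts[fit$selected] + 1
    }
    freq <- counts / B
    structure(list(selected = names(freq)[freq >= freq_threshold],
                   frequencies = freq, B = B, subsample_frac = subsample_frac,
                   K = K, eta = eta, freq_threshold = freq_threshold),
              class = "ensemble_spls")
  })
}

#' Consensus of two selected feature sets
#'
#' Intersection of the elastic-net and ensemble-SPLS selections; an empty
#' consensus is a warning, not an error.
#'
#' @param en_set,spls_set character vectors of feature names.
#' @return character vector (intersection).
#' @export
consensus_select <- function(en_set, spls_set) {
  out <- intersect(en_set, spls_set)
  if (!length(out)) warning("consensus feature set is empty")
  out
}

#' Run the full consensus feature selection
#'
#' Convenience wrapper: elastic net and ensemble SPLS on the same data,
#' intersected.
#'
#' @inheritParams elasticnet_select
#' @param en_args,spls_args argument lists forwarded to
#'   [elasticnet_select()] and [ensemble_spls_select()].
#' @return list of class `"selection_result"`: `elasticnet_set`,
#'   `spls_set`, `consensus_set`, `spls_frequencies`, `settings`.
#' @export
select_features <- function(X, y, seed = 1, en_args = list(), spls_args = list()) {
  en <- do.call(elasticnet_select, c(list(X = X, y = y, seed = seed), en_args))
  sp <- do.call(ensemble_spls_select, c(list(X = X, y = y, seed = seed + 1L), spls_args))
  structure(list(elasticnet_set = as.character(en), spls_set = sp$selected,
                 consensus_set = consensus_select(as.character(en), sp$selected),
                 spls_frequencies = sp$frequencies,
                 settings = list(elasticnet = attributes(en),
                                 spls = sp[c("B", "subsample_frac", "K", "eta", "freq_threshold")],
                                 seed = seed)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: elastic net %d, ensemble SPLS %d, consensus %d features\n",
              length(x$elasticnet_set), length(x$spls_set), length(x$consensus_set)))
  invisible(x)
}

#' Permutation importance of each feature for a fitted model
#'
#' Drop in held-out ROC-AUC when a feature column is shuffled, averaged
#' over `n_perm` shuffles and rescaled so the most important feature scores
#' 100 (negative drops floor at 0). A uniform importance contract across
#' heterogeneous model families.
#'
#' @param model an [ess_fit()] model.
#' @param X held-out feature matrix (model's feature order).
#' @param y held-out binary labels.
#' @param n_perm shuffles per feature.
#' @param seed integer seed.
#' @return named numeric vector in `[0, 100]`.
#' @export
permutation_importance <- function(model, X, y, n_perm = 5, seed = 1) {
  base <- roc_auc(predict(model, X), y)
  local_seed(seed, {
    drop <- vapply(colnames(X), function(f) {
      mean(vapply(seq_len(n_perm), function(i) {
        Xp <- X
        Xp[, f] <- sample(Xp[, f])
        base - roc_auc(predict(model, Xp), y)
      }, numeric(1)))
    }, numeric(1))
    drop <- pmax(drop, 0)
    if (max(drop) > 0) drop <- drop / max(drop) * 100
    drop
  })
}

#' Median feature importance across models
#'
#' Ranks features by the exact median of their per-model importances, ties
#' broken lexicographically by feature name. Importances are expected on a
#' common `[0, 100]` scale (as produced by [permutation_importance()],
#' where each model's top feature scores 100).
#'
#' @param per_model_importances named list of named numeric vectors (one
#'   per model family), each on the `[0, 100]` scale.
#' @return data.frame of class `"importance_ranking"`: `feature`, one
#'   column per model, `median`, ordered by descending median.
#' @export
median_importance <- function(per_model_importances) {
  if (!length(per_model_importances)) stop("need at least one model's importances")
  bad <- vapply(per_model_importances, function(v) any(v < 0 | v > 100), logical(1))
  if (any(bad)) stop("importances must lie on the [0, 100] scale")
  scaled <- per_model_importances
  feats <- sort(unique(unlist(lapply(scaled, names))))
  m <- vapply(scaled, function(v) unname(v[feats]), numeric(length(feats)))
  m <- matrix(m, nrow = length(feats),
              dimnames = list(feats, names(per_model_importances)))
  med <- apply(m, 1, median, na.rm = TRUE)
  out <- data.frame(feature = feats, m, median = med, check.names = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$median, out$feature), ]
  rownames(out) <- NULL
  class(out) <- c("importance_ranking", "data.frame")
  out
}
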