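stratified_split <- function(y, frac) {
  train <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_tr <- round(frac * length(idx))
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

#' Within-species evaluation over a grid of training fractions
#'
#' For each training fraction: a stratified random split, feature
#' selection on the training portion only (no leakage into the test set),
#' a fit of every requested family, and ROC-AUC / PR-AUC on the held-out
#' portion. A permutation-null background model runs alongside each split
#' as a negative control: labels are shuffled across the whole labeled set
#' and the identical split/fit/evaluate path is applied, so its ROC-AUC is
#' centred at 0.5 by construction. Splits yielding fewer than 2 members of
#' either class are skipped with a warning.
#'
#' @param X standardized feature matrix of the labeled genes.
#' @param y binary labels.
#' @param families model family names.
#' @param fractions training fractions (default 0.1-0.9 by 0.1).
#' @param repeats independent splits per fraction.
#' @param seed integer master seed; per-split seeds derive from it.
#' @param select logical: run consensus feature selection inside each
#'   training split. When `FALSE`, `features` (or all columns) are used.
#' @param features fixed feature set used when `select = FALSE`.
#' @param grids optional named list of hyperparameter grids per family.
#' @param en_args,spls_args forwarded to [select_features()].
#' @param background run the permuted-label control (first family).
#' @return data.frame of class `"ess_eval"`, one row per (family, fraction,
#'   repeat), with `roc_auc`, `pr_auc`, `n_train`, `n_test`, `n_features`;
#'   background rows carry family `"background"`.
#' @export
subsample_grid <- function(X, y, families = MODEL_FAMILIES,
                           fractions = seq(0.1, 0.9, by = 0.1), repeats = 5,
                           seed = 1, select = TRUE, features = NULL,
                           grids = NULL, en_args = list(), spls_args = list(),
                           background = TRUE) {
  y <- as_binary_labels(y)
  rows <- list()
  for (f in fractions) for (r in seq_len(repeats)) {
    split_seed <- derive_seed(seed, sprintf("grid_%g_%d", f, r))
    tr <- local_seed(split_seed, stratified_split(y, f))
    te <- setdiff(seq_along(y), tr)
    if (min(table(y[tr])) < 2 || min(table(y[te])) < 2) {
      warning(sprintf("fraction %g repeat %d: a class has < 2 members; skipped", f, r))
      next
    }
    feats <- if (select) {
      sel <- select_features(X[tr, , drop = FALSE], y[tr], seed = split_seed,
                             en_args = en_args, spls_args = spls_args)
      if (length(sel$consensus_set)) sel$consensus_set else sel$elasticnet_set
    } else if (!is.null(features)) features else colnames(X)
    Xtr <- X[tr, feats, drop = FALSE]
    Xte <- X[te, feats, drop = FALSE]
    for (fam in families) {
      m <- ess_fit(Xtr, y[tr], family = fam, grid = grids[[fam]],
                   seed = split_seed)
      p <- predict(m, Xte)
      rows[[length(rows) + 1]] <- data.frame(
        family = fam, fraction = f, replicate = r, seed = split_seed,
        n_train = length(tr), n_test = length(te),
        roc_auc = roc_auc(p, y[te]), pr_auc = pr_auc(p, y[te]),
        n_features = length(feats), stringsAsFactors = FALSE)
    }
    if (background) {
      # permutation null: labels shuffled across the whole labeled set,
      # then the identical split/fit/evaluate path
      y_perm <- local_seed(split_seed + 1L, sample(y))
      if (length(unique(y_perm[tr])) == 2 && length(unique(y_perm[te])) == 2) {
        m0 <- ess_fit(Xtr, y_perm[tr], family = families[1],
                      grid = grids[[families[1]]], seed = split_seed)
        p0 <- predict(m0, Xte)
        rows[[length(rows) + 1]] <- data.frame(
          family = "background", fraction = f, replicate = r, seed = split_seed,
          n_train = length(tr), n_test = length(te),
          roc_auc = roc_auc(p0, y_perm[te]), pr_auc = pr_auc(p0, y_perm[te]),
          n_features = length(feats), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ess_eval", "data.frame")
  out
}

#' Bootstrap evaluation with 90/10 stratified resampling
#'
#' `B` stratified train/test splits (default 90% training) on a fixed
#' feature set, reporting per-replicate ROC-AUC and PR-AUC. Following the
#' protocol's order, features are selected before the bootstrap and
#' hyperparameters are tuned once on the full labeled set, then reused for
#' every replicate refit. Per-replicate seeds derive from the master seed.
#'
#' @inheritParams subsample_grid
#' @param B number of bootstrap replicates (protocol default 1000;
#'   reducible for desk-scale runs).
#' @param train_frac training fraction per replicate.
#' @param features feature set to use (default: all columns of `X`).
#' @param background include a permuted-label control per replicate
#'   (first family).
#' @return `"ess_eval"` data.frame, one row per (family, replicate).
#' @export
bootstrap_evaluate <- function(X, y, families = c("GBM", "XGB", "RF"), B = 1000,
                               train_frac = 0.9, seed = 1, features = NULL,
                               grids = NULL, background = FALSE) {
  y <- as_binary_labels(y)
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  tuned <- lapply(setNames(families, families), function(fam) {
    m <- ess_fit(X, y, family = fam, grid = grids[[fam]], seed = seed)
    list(grid = list(m$hyperparameters))
  })
  rows <- list()
  for (b in seq_len(B)) {
    rep_seed <- derive_seed(seed, sprintf("boot_%d", b))
    tr <- local_seed(rep_seed, stratified_split(y, train_frac))
    te <- setdiff(seq_along(y), tr)
    if (min(table(y[tr])) < 2 || min(table(y[te])) < 1) {
      warning(sprintf("replicate %d: degenerate split; skipped", b))
      next
    }
    for (fam in families) {
      m <- ess_fit(X[tr, , drop = FALSE], y[tr], family = fam,
                   grid = tuned[[fam]]$grid, seed = rep_seed)
      p <- predict(m, X[te, , drop = FALSE])
      rows[[length(rows) + 1]] <- data.frame(
        family = fam, fraction = train_frac, replicate = b, seed = rep_seed,
        n_train = length(tr), n_test = length(te),
        roc_auc = roc_auc(p, y[te]), pr_auc = pr_auc(p, y[te]),
        n_features = ncol(X), stringsAsFactors = FALSE)
    }
    if (background) {
      y_perm <- local_seed(rep_seed + 1L, sample(y))
      if (length(unique(y_perm[tr])) == 2 && length(unique(y_perm[te])) == 2) {
        m0 <- ess_fit(X[tr, , drop = FALSE], y_perm[tr], family = families[1],
                      grid = tuned[[families[1]]]$grid, seed = rep_seed)
        p0 <- predict(m0, X[te, , drop = FALSE])
        rows[[length(rows) + 1]] <- data.frame(
          family = "background", fraction = train_frac, replicate = b,
          seed = rep_seed, n_train = length(tr), n_test = length(te),
          roc_auc = roc_auc(p0, y_perm[te]), pr_auc = pr_auc(p0, y_perm[te]),
          n_features = ncol(X), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ess_eval", "data.frame")
  out
}

#' @export
summary.ess_eval <- function(object, ...) {
  agg <- function(metric) {
    do.call(rbind, lapply(split(object[[metric]], object$family), function(v)
      data.frame(median = median(v), q05 = unname(quantile(v, 0.05)),
                 q95 = unname(quantile(v, 0.95)))))
  }
  roc <- agg("roc_auc"); pr <- agg("pr_auc")
  out <- data.frame(family = rownames(roc),
                    roc_median = roc$median, roc_q05 = roc$q05, roc_q95 = roc$q95,
                    pr_median = pr$median, pr_q05 = pr$q05, pr_q95 = pr$q95,
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' @export
print.ess_eval <- function(x, ...) {
  cat(sprintf("ess_eval: %d rows (%s)\n", nrow(x),
              paste(unique(x$family), collapse = ", ")))
  print(summary(x))
  invisible(x)
}

# Distinct k-mers of each sequence as integer codes, for the clustering
# prescreen.
kmer_sets <- function(seqs, k = 4) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(integer(0))
    aa <- match(strsplit(s, "")[[1]], AA_STANDARD20) - 1L
    aa[is.na(aa)] <- 0L
    idx <- seq_len(n - k + 1)
    code <- aa[idx]
    for (j in seq_len(k - 1)) code <- code * 20L + aa[idx + j]
    unique(code)
  })
}

pair_identity <- function(seq_a, seq_b) {
  submat <- matrix(-1, 20, 20, dimnames = list(AA_STANDARD20, AA_STANDARD20))
  diag(submat) <- 1
  pa <- Biostrings::pairwiseAlignment(Biostrings::AAString(seq_a),
                                      Biostrings::AAString(seq_b),
                                      type = "global", substitutionMatrix = submat,
                                      gapOpening = 0, gapExtension = 2)
  # matches over the full alignment length, terminal gaps included
  Biostrings::nmatch(pa) / nchar(as.character(Biostrings::alignedPattern(pa)))
}

#' Greedy non-redundant protein set (centroid clustering)
#'
#' The overfitting control: sequences are processed in descending length;
#' each joins the first existing centroid whose global-alignment identity
#' (match +1, mismatch -1, linear gap -2; identity = matches / alignment
#' length) exceeds `identity_threshold`, otherwise it founds a new
#' centroid. Only centroid gene ids are returned. A k-mer count prescreen
#' (shared distinct 4-mers) limits alignments to plausible candidate
#' centroids, the same design as UCLUST/USEARCH-style greedy clustering.
#'
#' @param proteins named character vector (gene id to protein sequence).
#' @param identity_threshold cluster when identity strictly exceeds this.
#' @param min_shared_kmers prescreen: centroids sharing fewer distinct
#'   4-mers than this are not aligned.
#' @return character vector of retained (centroid) gene ids.
#' @export
nonredundant_filter <- function(proteins, identity_threshold = 0.25,
                                min_shared_kmers = 4) {
  ord <- order(-nchar(proteins), names(proteins))
  seqs <- proteins[ord]
  km <- kmer_sets(seqs)
  all_km <- sort(unique(unlist(km)))
  # sparse k-mer incidence for the prescreen
  j <- rep.int(seq_along(seqs), lengths(km))
  i <- match(unlist(km), all_km)
  M <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(all_km), length(seqs)))
  S <- Matrix::crossprod(M)  # shared distinct k-mer counts, sparse off-diagonal
  centroids <- integer(0)
  for (s in seq_along(seqs)) {
    assigned <- FALSE
    if (length(centroids)) {
      shared <- S[centroids, s]
      for (ci in centroids[shared >= min_shared_kmers]) {
        if (pair_identity(seqs[s], seqs[ci]) > identity_threshold) {
          assigned <- TRUE
          break
        }
      }
    }
    if (!assigned) centroids <- c(centroids, s)
  }
  names(seqs)[centroids]
}
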