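#' Train on one species, rank all genes of the other
#'
#' Fits a classifier on all labeled genes of the training species
#' (restricted to the consensus feature set) and scores every gene of the
#' target species — labeled and unlabeled alike — returning genes ordered
#' by predicted essentiality probability (rank 1 = most likely essential),
#' ties broken deterministically by gene id. Using the same species as
#' source and target gives the within-species control ranking.
#'
#' @param train_table standardized `feature_table` of the training species.
#' @param train_labels `label_set` (or factor) for the training species.
#' @param features consensus feature names (present in both tables).
#' @param target_table standardized `feature_table` of the target species.
#' @param family model family (the transfer default is XGB).
#' @param grid,seed forwarded to [ess_fit()].
#' @return object of class `"ranked_prediction"`: data.frame `gene_id`,
#'   `probability`, `rank`, with attributes `target_species`,
#'   `train_species`, `family`, `model`.
#' @export
cross_predict <- function(train_table, train_labels, features, target_table,
                          family = "XGB", grid = NULL, seed = 1) {
  missing_a <- setdiff(features, train_table$feature_names)
  missing_b <- setdiff(features, target_table$feature_names)
  if (length(missing_a) || length(missing_b))
    stop(sprintf("feature mismatch: train lacks [%s], target lacks [%s]",
                 paste(missing_a, collapse = ","), paste(missing_b, collapse = ",")))
  keep <- train_labels[train_table$gene_ids] != "unlabeled"
  Xtr <- train_table$values[keep, features, drop = FALSE]
  y <- as_binary_labels(factor(as.character(train_labels[rownames(Xtr)]),
                               levels = c("essential", "non_essential")))
  model <- ess_fit(Xtr, y, family = family, grid = grid, seed = seed)
  p <- predict(model, target_table$values[, features, drop = FALSE])
  ord <- order(-p, names(p))
  out <- data.frame(gene_id = names(p)[ord], probability = unname(p[ord]),
                    rank = seq_along(p), stringsAsFactors = FALSE)
  structure(out, target_species = target_table$species,
            train_species = train_table$species, family = family,
            model = model, class = c("ranked_prediction", "data.frame"))
}

#' @export
print.ranked_prediction <- function(x, ...) {
  cat(sprintf("ranked_prediction: %d genes of species %s scored by %s trained on species %s\n",
              nrow(x), attr(x, "target_species"), attr(x, "family"),
              attr(x, "train_species")))
  print(head(as.data.frame(x), 5))
  invisible(x)
}

#' Spearman rank concordance of two gene scorings
#'
#' Tie-aware Spearman correlation (Pearson correlation of average-ranked
#' values) computed on the genes shared between the two named vectors.
#'
#' @param ranking_a,ranking_b named numeric vectors (gene to score).
#' @return rho in `[-1, 1]`; errors with fewer than 3 shared genes.
#' @export
spearman_concordance <- function(ranking_a, ranking_b) {
  shared <- intersect(names(ranking_a), names(ranking_b))
  if (length(shared) < 3) stop("need at least 3 shared genes")
  cor(rank(ranking_a[shared]), rank(ranking_b[shared]))
}

#' Cumulative lethal-phenotype ratio along a ranked gene list
#'
#' Walks the ranked list from the top (`top_down`) or the bottom
#' (`bottom_up`) and reports, at every prefix length k, the fraction of
#' phenotype-database-covered genes in the prefix that are annotated
#' lethal. Genes absent from the database count in neither numerator nor
#' denominator; prefixes with no covered gene carry `NA`. Both directions
#' end at the overall lethal prevalence among covered genes.
#'
#' @param ranked a `ranked_prediction` (or data.frame with `gene_id`,
#'   `rank`).
#' @param phenodb data.frame with `gene_id` and logical `lethal`.
#' @param direction `"top_down"` or `"bottom_up"`.
#' @return data.frame of class `"validation_curve"`: `k`, `gene_id`,
#'   `covered` (cumulative covered count), `ratio`; attribute `direction`.
#' @export
cumulative_lethal_ratio <- function(ranked, phenodb,
                                    direction = c("top_down", "bottom_up")) {
  direction <- match.arg(direction)
  if (!nrow(phenodb)) stop("phenotype database is empty")
  genes <- ranked$gene_id[order(ranked$rank)]
  if (direction == "bottom_up") genes <- rev(genes)
  lethal <- setNames(phenodb$lethal, phenodb$gene_id)
  status <- lethal[genes]                  # NA when not covered
  cov_cum <- cumsum(!is.na(status))
  let_cum <- cumsum(!is.na(status) & status %in% TRUE)
  ratio <- ifelse(cov_cum > 0, let_cum / cov_cum, NA_real_)
  structure(data.frame(k = seq_along(genes), gene_id = genes,
                       covered = cov_cum, ratio = ratio,
                       row.names = NULL, stringsAsFactors = FALSE),
            direction = direction, class = c("validation_curve", "data.frame"))
}

#' @export
print.validation_curve <- function(x, ...) {
  cat(sprintf("validation_curve (%s): %d genes, %d covered, final lethal ratio %.4f\n",
              attr(x, "direction"), nrow(x), x$covered[nrow(x)], x$ratio[nrow(x)]))
  invisible(x)
}
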