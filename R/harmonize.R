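#' Restrict two feature tables to their shared features
#'
#' Keeps the name-intersection of the two tables' feature sets, in the
#' first table's column order, so both matrices become column-comparable.
#'
#' @param table_a,table_b `feature_table` objects.
#' @return list with elements `a`, `b` (restricted tables) and `features`.
#' @export
intersect_features <- function(table_a, table_b) {
  shared <- intersect(table_a$feature_names, table_b$feature_names)
  if (!length(shared)) stop("no shared features between the two species")
  restrict <- function(tb) feature_table(tb$values[, shared, drop = FALSE],
                                         species = tb$species,
                                         provenance = tb$provenance[shared])
  list(a = restrict(table_a), b = restrict(table_b), features = shared)
}

#' Z-score a feature table within species
#'
#' Per feature: `(x - mean) / sd`, with mean and sd computed within the
#' table (species). Zero-variance features are dropped with a message.
#'
#' @param table a `feature_table`.
#' @return standardized `feature_table` with a `scaling` attribute
#'   (data.frame of per-feature mean and sd).
#' @export
standardize <- function(table) {
  if (nrow(table$values) < 2) stop("standardization needs at least 2 genes")
  mu <- colMeans(table$values)
  sig <- apply(table$values, 2, sd)
  keep <- sig > 0
  if (any(!keep))
    message(sprintf("standardize: dropping %d constant feature(s): %s",
                    sum(!keep), paste(head(names(sig)[!keep], 5), collapse = ", ")))
  z <- sweep(sweep(table$values[, keep, drop = FALSE], 2, mu[keep]), 2, sig[keep], "/")
  out <- feature_table(z, species = table$species, provenance = table$provenance[keep])
  attr(out, "scaling") <- data.frame(feature = names(mu)[keep], mean = mu[keep],
                                     sd = sig[keep], row.names = NULL)
  out
}

#' Harmonize two species' feature tables
#'
#' Intersects the feature sets, removes features constant in either
#' species from both, and z-scores each table within its own species.
#' Per-species standardization (no pooled scaling) is what makes a model
#' trained on one species' standardized features applicable to the other.
#'
#' @param table_a,table_b `feature_table` objects.
#' @return list of class `"harmonized_pair"`: standardized tables `a`,
#'   `b`, the shared `features`, and per-species `scaling` data.frames.
#' @export
harmonize <- function(table_a, table_b) {
  pair <- intersect_features(table_a, table_b)
  ok_a <- apply(pair$a$values, 2, sd) > 0
  ok_b <- apply(pair$b$values, 2, sd) > 0
  keep <- pair$features[ok_a & ok_b]
  if (!length(keep)) stop("no non-constant shared features")
  za <- standardize(feature_table(pair$a$values[, keep, drop = FALSE],
                                  species = pair$a$species, provenance = pair$a$provenance[keep]))
  zb <- standardize(feature_table(pair$b$values[, keep, drop = FALSE],
                                  species = pair$b$species, provenance = pair$b$provenance[keep]))
  structure(list(a = za, b = zb, features = keep,
                 scaling = list(a = attr(za, "scaling"), b = attr(zb, "scaling"))),
            class = "harmonized_pair")
}

#' @export
print.harmonized_pair <- function(x, ...) {
  cat(sprintf("harmonized_pair: %d shared standardized features; species %s (%d genes) / %s (%d genes)\n",
              length(x$features), x$a$species, nrow(x$a$values),
              x$b$species, nrow(x$b$values)))
  invisible(x)
}

#' Assign essentiality labels from reference probabilities
#'
#' Genes with reference probability above `hi` are labelled `essential`,
#' below `lo` `non_essential`, otherwise `unlabeled`. Only the two extreme
#' classes are used for training; unlabeled genes are still scored at
#' prediction time.
#'
#' @param ref_probs named numeric vector of probabilities in `[0,1]`.
#' @param hi,lo thresholds; `hi` must exceed `lo`. Defaults 0.7 / 0.1.
#' @return object of class `"label_set"`: a named factor with levels
#'   `essential`, `non_essential`, `unlabeled` and attributes `hi`, `lo`.
#' @export
assign_labels <- function(ref_probs, hi = 0.7, lo = 0.1) {
  if (hi <= lo) stop("hi threshold must exceed lo threshold")
  if (any(ref_probs < 0 | ref_probs > 1)) stop("reference probabilities must lie in [0,1]")
  cls <- ifelse(ref_probs > hi, "essential",
                ifelse(ref_probs < lo, "non_essential", "unlabeled"))
  out <- factor(cls, levels = c("essential", "non_essential", "unlabeled"))
  names(out) <- names(ref_probs)
  structure(out, hi = hi, lo = lo, class = c("label_set", "factor"))
}

#' @export
print.label_set <- function(x, ...) {
  tab <- table(unclass(x))
  cat(sprintf("label_set (hi > %g, lo < %g): %s essential, %s non-essential, %s unlabeled\n",
              attr(x, "hi"), attr(x, "lo"),
              sum(x == "essential"), sum(x == "non_essential"), sum(x == "unlabeled")))
  invisible(x)
}

# Binary 0/1 response for the labeled subset of a label_set.
labeled_response <- function(labels) {
  keep <- labels != "unlabeled"
  y <- as.integer(labels[keep] == "essential")
  names(y) <- names(labels)[keep]
  y
}
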