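# Shared fixtures. Worlds are cached per configuration for the session so
# expensive generations run once across test files.

.world_cache <- new.env(parent = emptyenv())

cached_world <- function(seed = 1, ...) {
  key <- paste0("w_", seed, "_", paste(unlist(list(...)), collapse = "_"))
  if (is.null(.world_cache[[key]]))
    .world_cache[[key]] <- generate_world(world_config(seed = seed, ...))
  .world_cache[[key]]
}

# The default study-scale world (3000 genes/species, 120 shared features,
# 20 informative).
default_world <- function(seed = 1) cached_world(seed = seed)

# A reduced world for fast protocol tests.
small_world <- function(seed = 1) {
  cached_world(seed = seed, n_genes_a = 700, n_genes_b = 700,
               n_shared_features = 40, n_private_features_per_species = 4,
               n_informative = 10)
}

# Standardized labeled design matrix + 0/1 response for one species.
labeled_xy <- function(world, species = "A", hi = 0.7, lo = 0.1) {
  sp <- world$species[[species]]
  lab <- assign_labels(sp$ref_probs, hi = hi, lo = lo)
  keep <- names(lab)[lab != "unlabeled"]
  X <- standardize(sp$features)$values[keep, , drop = FALSE]
  list(X = X, y = as.integer(lab[keep] == "essential"), labels = lab)
}

# Consensus feature selection on the labeled genes of species A of the
# default world with the given seed, cached for the session.
cached_selection <- function(seed = 1) {
  key <- paste0("sel_", seed)
  if (is.null(.world_cache[[key]])) {
    d <- labeled_xy(default_world(seed), "A")
    .world_cache[[key]] <- select_features(d$X, d$y, seed = seed)
  }
  .world_cache[[key]]
}

# Bootstrap evaluation (both boosting families + permuted-label control)
# on the consensus features of the default seed-1 world, cached.
cached_bootstrap <- function() {
  if (is.null(.world_cache$boot)) {
    d <- labeled_xy(default_world(1), "A")
    feats <- cached_selection(1)$consensus_set
    .world_cache$boot <- bootstrap_evaluate(d$X, d$y, families = c("GBM", "XGB"),
                                            B = 50, seed = 17, features = feats,
                                            background = TRUE)
  }
  .world_cache$boot
}

# Tiny deterministic feature tables for harmonization tests.
toy_table <- function(values, species = "S", genes = NULL, feats = NULL) {
  if (is.null(genes)) genes <- rownames(values)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(feats)) feats <- colnames(values)
  if (is.null(feats)) feats <- sprintf("f%d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, feats)
  feature_table(values, species = species)
}
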