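#' Pipeline run configuration
#'
#' Bundles every stage's settings: the synthetic-world configuration (or
#' paths to real inputs prepared with the `read_*` functions), label
#' thresholds, selection hyperparameters, model families, the evaluation
#' grid, bootstrap size and the master seed. Per-stage seeds derive from
#' the master seed by stage-name hashing, so adding a stage never perturbs
#' another stage's stream.
#'
#' @param world an [world_config()] for the simulate stage.
#' @param hi,lo label thresholds on the reference probabilities.
#' @param families model families for the evaluation stage.
#' @param transfer_family family used for cross-species transfer.
#' @param fractions,repeats subsample-grid settings.
#' @param bootstrap_B bootstrap replicates (0 skips the bootstrap).
#' @param bootstrap_families families evaluated in the bootstrap.
#' @param en_args,spls_args selection hyperparameters
#'   (see [elasticnet_select()], [ensemble_spls_select()]).
#' @param grid_select when `TRUE`, the subsample grid re-runs consensus
#'   feature selection inside every training split (the leakage-free
#'   protocol; slower); when `FALSE` (default) the grid reuses the
#'   pipeline's stage-level consensus features.
#' @param grids optional named list of per-family hyperparameter grids.
#' @param bin_size landscape density bin (bp).
#' @param seed master seed.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(world = world_config(), hi = 0.7, lo = 0.1,
                       families = MODEL_FAMILIES, transfer_family = "XGB",
                       fractions = seq(0.1, 0.9, by = 0.1), repeats = 5,
                       bootstrap_B = 1000, bootstrap_families = c("GBM", "XGB", "RF"),
                       en_args = list(), spls_args = list(), grids = NULL,
                       grid_select = FALSE, bin_size = 1e6, seed = 1L) {
  stopifnot(hi > lo)
  structure(list(world = world, hi = hi, lo = lo, families = families,
                 transfer_family = transfer_family, fractions = fractions,
                 repeats = repeats, bootstrap_B = bootstrap_B,
                 bootstrap_families = bootstrap_families,
                 en_args = en_args, spls_args = spls_args, grids = grids,
                 grid_select = isTRUE(grid_select), bin_size = bin_size,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' A small demonstration configuration
#'
#' A reduced world (800 genes, 40 shared features, 10 informative) and a
#' light evaluation protocol, sized so the full pipeline completes in well
#' under a minute while still exhibiting the planted cross-species signal.
#'
#' @param seed master seed.
#' @return a [run_config()].
#' @export
demo_config <- function(seed = 1L) {
  run_config(world = world_config(n_genes_a = 800, n_genes_b = 800,
                                  n_shared_features = 40,
                                  n_private_features_per_species = 4,
                                  n_informative = 10, seed = seed),
             families = c("XGB", "GLM"), fractions = c(0.3, 0.6, 0.9),
             repeats = 1, bootstrap_B = 10, bootstrap_families = "XGB",
             en_args = list(alpha_grid = c(0.3, 0.7), cv_folds = 3),
             spls_args = list(B = 25),
             seed = seed)
}

run_selection_for_species <- function(H, side, lab, cfg, seed) {
  tb <- H[[side]]
  keep <- names(lab)[lab != "unlabeled"]
  X <- tb$values[keep, , drop = FALSE]
  y <- as_binary_labels(factor(as.character(lab[keep]),
                               levels = c("essential", "non_essential")))
  select_features(X, y, seed = seed, en_args = cfg$en_args, spls_args = cfg$spls_args)
}

#' Run the full cross-species pipeline
#'
#' Executes simulate, featurize, harmonize, select, evaluate (grid and
#' bootstrap), transfer in both directions, validate and landscape, and
#' writes each stage's outputs plus a `manifest.json` (configuration echo,
#' derived stage seeds, output checksums) under `out_dir`. The run is
#' deterministic given the master seed. A stage failure aborts with the
#' stage named; earlier outputs are retained.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @param skip_bootstrap omit the bootstrap stage only.
#' @return (invisibly) list of class `"ess_run"` with the in-memory stage
#'   results: `world`, `harmonized`, `labels`, `selection`, `features`,
#'   `grid_eval`, `bootstrap_eval`, `transfer`, `curves`, `tracks`,
#'   `het_summaries`, `out_dir`.
#' @export
run_all <- function(config = run_config(), out_dir = tempfile("crossess_run_"),
                    skip_bootstrap = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }
  seeds <- sapply(c("simulate", "select", "evaluate", "bootstrap", "transfer"),
                  function(s) derive_seed(config$seed, s))

  world <- stage("simulate", {
    w <- generate_world(config$world)
    write_world(w, file.path(out_dir, "world"))
    w
  })

  feats <- stage("featurize", {
    lapply(world$species, function(sp)
      featurize(sp$features, sp$proteins, sp$annotation, sp$chrom_lengths))
  })

  hl <- stage("harmonize", {
    H <- harmonize(feats$A, feats$B)
    labels <- lapply(world$species, function(sp)
      assign_labels(sp$ref_probs, hi = config$hi, lo = config$lo))
    list(H = H, labels = labels)
  })
  H <- hl$H; labels <- hl$labels

  sel <- stage("select", {
    sa <- run_selection_for_species(H, "a", labels$A, config, seeds[["select"]])
    sb <- run_selection_for_species(H, "b", labels$B, config, seeds[["select"]] + 1L)
    shared <- intersect(sa$consensus_set, sb$consensus_set)
    if (!length(shared)) {
      warning("cross-species consensus empty; falling back to the union of the per-species consensus sets")
      shared <- union(sa$consensus_set, sb$consensus_set)
    }
    jsonlite::write_json(list(species_a = sa$consensus_set, species_b = sb$consensus_set,
                              cross_species = shared),
                         file.path(out_dir, "selection.json"), auto_unbox = TRUE)
    list(a = sa, b = sb, features = shared)
  })

  labeled_xy <- function(side, sp_name, features = sel$features) {
    lab <- labels[[sp_name]]
    keep <- names(lab)[lab != "unlabeled"]
    list(X = H[[side]]$values[keep, features, drop = FALSE],
         y = as_binary_labels(factor(as.character(lab[keep]),
                                     levels = c("essential", "non_essential"))))
  }
  A <- labeled_xy("a", "A")

  grid_eval <- stage("evaluate", {
    A_grid <- if (isTRUE(config$grid_select)) labeled_xy("a", "A", H$features) else A
    ev <- subsample_grid(A_grid$X, A_grid$y, families = config$families,
                         fractions = config$fractions, repeats = config$repeats,
                         seed = seeds[["evaluate"]],
                         select = isTRUE(config$grid_select),
                         features = sel$features,
                         en_args = config$en_args, spls_args = config$spls_args,
                         grids = config$grids)
    write.table(ev, file.path(out_dir, "grid_eval.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ev
  })

  boot_eval <- NULL
  if (!skip_bootstrap && config$bootstrap_B > 0) {
    boot_eval <- stage("bootstrap", {
      ev <- bootstrap_evaluate(A$X, A$y, families = config$bootstrap_families,
                               B = config$bootstrap_B, seed = seeds[["bootstrap"]],
                               grids = config$grids)
      write.table(ev, file.path(out_dir, "bootstrap_eval.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      ev
    })
  }

  transfer <- stage("transfer", {
    r_ab <- cross_predict(H$a, labels$A, sel$features, H$b,
                          family = config$transfer_family,
                          grid = config$grids[[config$transfer_family]],
                          seed = seeds[["transfer"]])
    r_ba <- cross_predict(H$b, labels$B, sel$features, H$a,
                          family = config$transfer_family,
                          grid = config$grids[[config$transfer_family]],
                          seed = seeds[["transfer"]] + 1L)
    write.table(as.data.frame(r_ab), file.path(out_dir, "ranked_b_from_a.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(r_ba), file.path(out_dir, "ranked_a_from_b.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(b_from_a = r_ab, a_from_b = r_ba)
  })

  curves <- stage("validate", {
    cv <- list(
      b_from_a_top = cumulative_lethal_ratio(transfer$b_from_a, world$species$B$phenotypes, "top_down"),
      b_from_a_bottom = cumulative_lethal_ratio(transfer$b_from_a, world$species$B$phenotypes, "bottom_up"),
      a_from_b_top = cumulative_lethal_ratio(transfer$a_from_b, world$species$A$phenotypes, "top_down"),
      a_from_b_bottom = cumulative_lethal_ratio(transfer$a_from_b, world$species$A$phenotypes, "bottom_up"))
    long <- do.call(rbind, lapply(names(cv), function(nm)
      cbind(curve = nm, as.data.frame(cv[[nm]]))))
    write.table(long, file.path(out_dir, "curves.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cv
  })

  land <- stage("landscape", {
    tr_b <- probability_track(transfer$b_from_a, world$species$B$annotation,
                              world$species$B$chrom_lengths, bin_size = config$bin_size)
    tr_a <- probability_track(transfer$a_from_b, world$species$A$annotation,
                              world$species$A$chrom_lengths, bin_size = config$bin_size)
    write_bedgraph(tr_b, file.path(out_dir, "track_b.bedgraph"))
    write_bedgraph(tr_a, file.path(out_dir, "track_a.bedgraph"))
    list(tracks = list(A = tr_a, B = tr_b),
         het = list(A = heterochromatin_summary(tr_a, world$species$A$het),
                    B = heterochromatin_summary(tr_b, world$species$B$het)))
  })

  declass <- function(x) if (is.list(x)) lapply(unclass(x), declass) else x
  manifest <- list(config = declass(config),
                   stage_seeds = as.list(seeds),
                   checksums = as.list(tools::md5sum(
                     file.path(out_dir, c("ranked_b_from_a.tsv", "ranked_a_from_b.tsv",
                                          "curves.tsv", "grid_eval.tsv")))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(structure(list(world = world, harmonized = H, labels = labels,
                           selection = sel, features = sel$features,
                           grid_eval = grid_eval, bootstrap_eval = boot_eval,
                           transfer = transfer, curves = curves,
                           tracks = land$tracks, het_summaries = land$het,
                           out_dir = out_dir),
                      class = "ess_run"))
}

#' @export
print.ess_run <- function(x, ...) {
  cat("crossess pipeline run\n")
  cat(sprintf("  output: %s\n", x$out_dir))
  cat(sprintf("  cross-species features: %d\n", length(x$features)))
  med <- summary(x$grid_eval)
  best <- med[which.max(med$roc_median), ]
  cat(sprintf("  best grid family: %s (median ROC-AUC %.3f)\n", best$family, best$roc_median))
  invisible(x)
}
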