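#' Configuration for the synthetic twin-species generator
#'
#' Returns a validated configuration list for [generate_world()]. The
#' defaults describe the study conditions the package is developed against:
#' two species of 3000 genes sharing 120 named features of which 20 carry
#' essentiality signal, strong class imbalance (5% essential), essential
#' genes depleted from heterochromatic chromosome arms, and a noisy,
#' incomplete lethal-phenotype database.
#'
#' @param n_genes_a,n_genes_b number of genes per species.
#' @param n_shared_features number of feature columns present in both
#'   species' tables under the same names.
#' @param n_private_features_per_species extra noise columns unique to each
#'   species (always uninformative).
#' @param n_informative how many shared features carry signal; must not
#'   exceed `n_shared_features`.
#' @param effect_size magnitude of each informative feature's coefficient in
#'   the latent essentiality score (unitless; features are standard normal).
#' @param coef_jitter_sd sd of the species-specific multiplicative Gaussian
#'   perturbation of the shared coefficients (`coef = base * (1 + N(0, sd))`).
#'   Shared coefficients are jittered, not resampled, so cross-species
#'   transfer is learnable by construction; very large values decorrelate
#'   the two species' coefficient vectors and destroy transferability.
#' @param noise_sd sd of the Gaussian noise added to the latent score.
#' @param essential_prevalence fraction of genes that are truly essential.
#' @param n_chromosomes,chrom_length_bp genome layout (equal-length
#'   chromosomes).
#' @param het_fraction fraction of each chromosome marked heterochromatic
#'   (split between the two chromosome ends, mimicking heterochromatic
#'   arms/telomeric blocks).
#' @param het_depletion multiplier in `[0,1]` on the probability that an
#'   essential gene stays inside heterochromatin: an essential gene first
#'   placed inside a heterochromatic block is re-drawn into euchromatin with
#'   probability `1 - het_depletion` (0 = fully depleted, 1 = no depletion).
#' @param phen_coverage fraction of genes covered by the phenotype database.
#' @param p_lethal_given_essential,p_lethal_given_nonessential class-
#'   conditional probabilities that a covered gene is annotated lethal; the
#'   first must exceed the second.
#' @param near_dup_fraction fraction of proteins generated as mutated copies
#'   of another protein (>25% identity), exercising the redundancy filter.
#' @param seed integer seed; one RNG stream drives the whole world.
#'
#' @return a list of class `"ess_config"`.
#' @seealso [generate_world()]
#' @export
world_config <- function(n_genes_a = 3000, n_genes_b = 3000,
                         n_shared_features = 120,
                         n_private_features_per_species = 10,
                         n_informative = 20,
                         effect_size = 1.0,
                         coef_jitter_sd = 0.3,
                         noise_sd = 0.5,
                         essential_prevalence = 0.05,
                         n_chromosomes = 5,
                         chrom_length_bp = 2e7,
                         het_fraction = 0.2,
                         het_depletion = 0.2,
                         phen_coverage = 0.6,
                         p_lethal_given_essential = 0.9,
                         p_lethal_given_nonessential = 0.02,
                         near_dup_fraction = 0.05,
                         seed = 1L) {
  cfg <- list(n_genes_a = as.integer(n_genes_a), n_genes_b = as.integer(n_genes_b),
              n_shared_features = as.integer(n_shared_features),
              n_private_features_per_species = as.integer(n_private_features_per_species),
              n_informative = as.integer(n_informative),
              effect_size = effect_size, coef_jitter_sd = coef_jitter_sd,
              noise_sd = noise_sd, essential_prevalence = essential_prevalence,
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.numeric(chrom_length_bp),
              het_fraction = het_fraction, het_depletion = het_depletion,
              phen_coverage = phen_coverage,
              p_lethal_given_essential = p_lethal_given_essential,
              p_lethal_given_nonessential = p_lethal_given_nonessential,
              near_dup_fraction = near_dup_fraction,
              seed = as.integer(seed))
  fracs <- c("essential_prevalence", "het_fraction", "het_depletion",
             "phen_coverage", "p_lethal_given_essential",
             "p_lethal_given_nonessential", "near_dup_fraction")
  for (f in fracs) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(sprintf("'%s' must lie in [0, 1]", f))
  }
  if (cfg$n_informative > cfg$n_shared_features)
    stop("n_informative must not exceed n_shared_features")
  if (cfg$p_lethal_given_essential <= cfg$p_lethal_given_nonessential)
    stop("p_lethal_given_essential must exceed p_lethal_given_nonessential")
  if (cfg$n_genes_a < 2 || cfg$n_genes_b < 2) stop("need at least 2 genes per species")
  structure(cfg, class = "ess_config")
}

AA_STANDARD20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Rank-based rescaling of latent scores to reference probabilities:
# top `prev` fraction is mapped into (0.7, 1], the bottom 85% into [0, 0.1),
# the remainder linearly into [0.1, 0.7]. Monotone in the latent score, so
# any monotone link (e.g. logistic) gives the same result; the fixed 0.7/0.1
# thresholds downstream then carve out non-empty label classes by design.
rescale_ref_probs <- function(latent, prev) {
  n <- length(latent)
  m_hi <- round(prev * n)
  m_lo <- min(floor(0.85 * n), n - m_hi)
  m_mid <- n - m_hi - m_lo
  r <- rank(latent, ties.method = "first")
  p <- numeric(n)
  lo <- r <= m_lo
  p[lo] <- 0.1 * (r[lo] - 1) / max(m_lo, 1)
  mid <- r > m_lo & r <= m_lo + m_mid
  if (m_mid > 0)
    p[mid] <- 0.1 + 0.6 * (r[mid] - m_lo) / (m_mid + 1)
  hi <- r > m_lo + m_mid
  p[hi] <- 0.7 + 0.3 * (r[hi] - m_lo - m_mid) / max(m_hi, 1)
  p
}

random_protein <- function(len) paste(sample(AA_STANDARD20, len, replace = TRUE), collapse = "")

mutate_protein <- function(seq, rate = 0.1) {
  aa <- strsplit(seq, "")[[1]]
  hit <- runif(length(aa)) < rate
  aa[hit] <- sample(AA_STANDARD20, sum(hit), replace = TRUE)
  paste(aa, collapse = "")
}

generate_species <- function(cfg, species, n_genes, beta_shared, informative,
                             shared_names) {
  priv_names <- sprintf("%s_private_%02d", tolower(species), seq_len(cfg$n_private_features_per_species))
  p_all <- cfg$n_shared_features + cfg$n_private_features_per_species
  X <- matrix(rnorm(n_genes * p_all), n_genes, p_all,
              dimnames = list(sprintf("%s_g%05d", species, seq_len(n_genes)),
                              c(shared_names, priv_names)))
  gene_ids <- rownames(X)

  # multiplicative jitter: species coefficients stay proportional to the
  # shared base effects (so a zero effect size is a true null) while large
  # jitter decorrelates the two species' coefficient vectors
  coefs <- beta_shared * (1 + rnorm(length(beta_shared), sd = cfg$coef_jitter_sd))
  latent <- as.vector(X[, informative, drop = FALSE] %*% coefs) +
    rnorm(n_genes, sd = cfg$noise_sd)
  ref_probs <- setNames(rescale_ref_probs(latent, cfg$essential_prevalence), gene_ids)
  m_hi <- round(cfg$essential_prevalence * n_genes)
  essential <- setNames(rank(latent, ties.method = "first") > n_genes - m_hi, gene_ids)

  # heterochromatin: two blocks per chromosome, one at each end (0-based BED)
  L <- cfg$chrom_length_bp
  half <- floor(L * cfg$het_fraction / 2)
  chroms <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
  het <- do.call(rbind, lapply(chroms, function(ch)
    data.frame(chrom = ch, start = c(0, L - half), end = c(half, L),
               stringsAsFactors = FALSE)))
  in_het <- function(mid) mid <= half | mid > L - half  # 1-based midpoint

  gene_len <- sample(2000:8000, n_genes, replace = TRUE)
  chrom <- sample(chroms, n_genes, replace = TRUE)
  start <- floor(runif(n_genes, 1, L - gene_len))
  mid <- start + gene_len / 2
  # essential genes inside heterochromatin are re-drawn into euchromatin
  # with probability 1 - het_depletion
  redraw <- essential & in_het(mid) & (runif(n_genes) < 1 - cfg$het_depletion)
  if (any(redraw)) {
    n_r <- sum(redraw)
    eu_start <- half + 1
    eu_end <- L - half - gene_len[redraw]
    start[redraw] <- floor(runif(n_r, eu_start, pmax(eu_start + 1, eu_end)))
  }
  end <- start + gene_len - 1
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  genes <- data.frame(gene_id = gene_ids, chrom = chrom, start = start,
                      end = end, strand = strand, stringsAsFactors = FALSE)

  # exon structure: 1-6 exons tiled left-to-right inside the gene span
  n_ex <- sample(1:6, n_genes, replace = TRUE)
  exons <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    k <- n_ex[i]
    bounds <- floor(seq(start[i], end[i], length.out = 2 * k + 1))
    data.frame(gene_id = gene_ids[i],
               start = bounds[seq(1, 2 * k, by = 2)],
               end = bounds[seq(2, 2 * k + 1, by = 2)],
               stringsAsFactors = FALSE)
  }))

  prot_len <- sample(80:200, n_genes, replace = TRUE)
  proteins <- vapply(prot_len, random_protein, character(1))
  n_dup <- floor(cfg$near_dup_fraction * n_genes)
  if (n_dup > 0 && n_genes > 2 * n_dup) {
    dup_idx <- sample(seq_len(n_genes), n_dup)
    # sources drawn from non-duplicated genes so every planted pair survives
    src_idx <- sample(setdiff(seq_len(n_genes), dup_idx), n_dup, replace = TRUE)
    proteins[dup_idx] <- vapply(proteins[src_idx], mutate_protein, character(1))
  }
  names(proteins) <- gene_ids

  list(species = species,
       features = feature_table(X, species = species,
                                provenance = setNames(c(rep("synthetic_shared", length(shared_names)),
                                                        rep("synthetic_private", length(priv_names))),
                                                      c(shared_names, priv_names))),
       ref_probs = ref_probs,
       annotation = list(genes = genes, exons = exons),
       chrom_lengths = setNames(rep(L, cfg$n_chromosomes), chroms),
       proteins = proteins,
       het = het,
       truth = list(essential = essential, coefficients = setNames(coefs, informative),
                    latent = setNames(latent, gene_ids)))
}

#' Generate a synthetic twin-species world
#'
#' Simulates two species whose per-gene feature tables share a subset of
#' informative columns. For each species the latent essentiality score is
#' the dot product of the shared informative features with species-specific
#' coefficients (shared base coefficients plus Gaussian jitter) plus noise;
#' reference probabilities are a monotone rank-based rescaling of the latent
#' score such that the top `essential_prevalence` fraction of genes exceeds
#' 0.7 and the bottom ~85% falls below 0.1. Gene coordinates are uniform on
#' equal-length chromosomes, with essential genes re-drawn out of
#' heterochromatic blocks with probability `1 - het_depletion`. Proteins are
#' random sequences with a configurable fraction of near-duplicate pairs.
#' A noisy, incomplete phenotype database is attached per species.
#'
#' The whole world is generated from a single RNG stream, so the same
#' configuration always yields a bit-identical world.
#'
#' @param config an [world_config()] object.
#' @return an object of class `"ess_world"`: a list with `config`, a
#'   `species` list (elements `A` and `B`, each holding `features`,
#'   `ref_probs`, `annotation`, `proteins`, `het`, `phenotypes`, `truth`)
#'   and a `truth` element recording shared informative feature names and
#'   base coefficients.
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "ess_config"))
  local_seed(config$seed, {
    shared_names <- sprintf("shared_%03d", seq_len(config$n_shared_features))
    informative <- sort(sample(shared_names, config$n_informative))
    beta <- setNames(sample(c(-1, 1), config$n_informative, replace = TRUE) * config$effect_size,
                     informative)
    A <- generate_species(config, "A", config$n_genes_a, beta, informative, shared_names)
    B <- generate_species(config, "B", config$n_genes_b, beta, informative, shared_names)
    world <- structure(list(config = config,
                            species = list(A = A, B = B),
                            truth = list(informative = informative,
                                         base_coefficients = beta,
                                         shared_features = shared_names)),
                       class = "ess_world")
    world$species$A$phenotypes <- generate_phenotype_db(world, "A", .seeded = FALSE)
    world$species$B$phenotypes <- generate_phenotype_db(world, "B", .seeded = FALSE)
    world
  })
}

#' Generate a noisy, incomplete phenotype database for one species
#'
#' Each gene enters the database with probability `phen_coverage`; a covered
#' gene is annotated lethal with probability `p_lethal_given_essential` or
#' `p_lethal_given_nonessential` according to its true class. Emulates an
#' independent functional-genomics resource (RNAi screen collections) used
#' only for validation, never training.
#'
#' @param world an `ess_world`.
#' @param species `"A"` or `"B"`.
#' @param seed seed for standalone calls; by default derived from the world
#'   seed and the species tag.
#' @param .seeded internal; set `FALSE` when already inside the world's RNG
#'   stream.
#' @return data.frame with columns `gene_id`, `lethal` (logical).
#' @export
generate_phenotype_db <- function(world, species, seed = NULL, .seeded = TRUE) {
  sp <- world$species[[species]]
  cfg <- world$config
  gen <- function() {
    ids <- names(sp$truth$essential)
    covered <- runif(length(ids)) < cfg$phen_coverage
    ids <- ids[covered]
    ess <- sp$truth$essential[ids]
    p <- ifelse(ess, cfg$p_lethal_given_essential, cfg$p_lethal_given_nonessential)
    data.frame(gene_id = ids, lethal = runif(length(ids)) < p,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  if (.seeded) {
    if (is.null(seed)) seed <- derive_seed(cfg$seed, paste0("phenotypes_", species))
    local_seed(seed, gen())
  } else gen()
}

#' @export
print.ess_world <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic twin-species world\n")
  for (s in names(x$species)) {
    sp <- x$species[[s]]
    cat(sprintf("  species %s: %d genes, %d features, %d essential, %d phenotype-covered\n",
                s, nrow(sp$features$values), ncol(sp$features$values),
                sum(sp$truth$essential), nrow(sp$phenotypes)))
  }
  cat(sprintf("  shared features: %d (%d informative); seed %d\n",
              cfg$n_shared_features, cfg$n_informative, cfg$seed))
  invisible(x)
}

#' Write a world to disk in standard formats
#'
#' Writes one directory per species containing `features.tsv`,
#' `ref_probs.tsv`, `genes.gff3`, `proteins.fasta`, `het.bed`,
#' `phenotypes.tsv` and `truth.json`, plus a top-level `manifest.json`
#' echoing the configuration.
#'
#' @param world an `ess_world`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(world$species)) {
    sp <- world$species[[s]]
    sdir <- file.path(dir, sprintf("species_%s", s))
    dir.create(sdir, showWarnings = FALSE)
    write_feature_table(sp$features, file.path(sdir, "features.tsv"))
    write.table(data.frame(gene_id = names(sp$ref_probs), ref_prob = unname(sp$ref_probs)),
                file.path(sdir, "ref_probs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    write_gff3(sp$annotation, file.path(sdir, "genes.gff3"))
    write_fasta(sp$proteins, file.path(sdir, "proteins.fasta"))
    write.table(sp$het, file.path(sdir, "het.bed"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    write.table(sp$phenotypes, file.path(sdir, "phenotypes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(essential = names(sp$truth$essential)[sp$truth$essential],
                              coefficients = as.list(sp$truth$coefficients)),
                         file.path(sdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(list(config = unclass(world$config),
                            informative = world$truth$informative),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
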