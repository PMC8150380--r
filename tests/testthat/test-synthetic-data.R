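test_that("world generation is bit-identical under a fixed seed", {
  cfg <- world_config(n_genes_a = 300, n_genes_b = 300, n_shared_features = 20,
                      n_informative = 5, seed = 7)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1, w2)
})

test_that("reference probabilities respect the prevalence and label thresholds", {
  cfg <- world_config(n_genes_a = 2000, n_genes_b = 200, n_shared_features = 40,
                      n_informative = 20, effect_size = 1.0, noise_sd = 0.5,
                      essential_prevalence = 0.04, seed = 1)
  w <- generate_world(cfg)
  p <- w$species$A$ref_probs
  expect_lte(abs(sum(p > 0.7) - 0.04 * 2000), 1)
  # bottom ~85% of genes fall below the lower labelling threshold
  expect_lte(abs(sum(p < 0.1) - floor(0.85 * 2000)), 1)
  # essential flags are exactly the high-probability genes
  expect_setequal(names(p)[p > 0.7],
                  names(which(w$species$A$truth$essential)))
})

test_that("empirical essential prevalence is within one gene of the target", {
  for (s in 1:3) {
    w <- cached_world(seed = s + 100, n_genes_a = 500, n_genes_b = 500,
                      n_shared_features = 20, n_informative = 5)
    for (sp in c("A", "B"))
      expect_lte(abs(sum(w$species[[sp]]$truth$essential) - 0.05 * 500), 1)
  }
})

test_that("effect_size = 0 yields features unrelated to the labels", {
  w <- cached_world(seed = 9, n_genes_a = 800, n_genes_b = 100,
                    n_shared_features = 20, n_informative = 10, effect_size = 0)
  d <- labeled_xy(w, "A")
  tr <- withr::with_seed(2, crossess:::stratified_split(d$y, 0.6))
  te <- setdiff(seq_along(d$y), tr)
  m <- ess_fit(d$X[tr, ], d$y[tr], family = "GLM", seed = 1)
  auc <- roc_auc(predict(m, d$X[te, ]), d$y[te])
  expect_lt(abs(auc - 0.5), 0.15)
})

test_that("heterochromatin depletion controls essential-gene placement", {
  in_het <- function(w, sp) {
    s <- w$species[[sp]]
    g <- s$annotation$genes
    mid <- (g$start + g$end) / 2
    ins <- vapply(seq_len(nrow(g)), function(i) {
      h <- s$het[s$het$chrom == g$chrom[i], ]
      any(mid[i] > h$start & mid[i] <= h$end)
    }, logical(1))
    setNames(ins, g$gene_id)
  }
  w0 <- cached_world(seed = 21, n_genes_a = 1500, n_genes_b = 100,
                     n_shared_features = 20, n_informative = 5, het_depletion = 0)
  ins0 <- in_het(w0, "A")
  ess0 <- w0$species$A$truth$essential[names(ins0)]
  expect_equal(sum(ins0 & ess0), 0)

  w1 <- cached_world(seed = 22, n_genes_a = 1500, n_genes_b = 100,
                     n_shared_features = 20, n_informative = 5, het_depletion = 1)
  ins1 <- in_het(w1, "A")
  ess1 <- w1$species$A$truth$essential[names(ins1)]
  # no depletion: essential density inside vs outside differs only by noise
  expect_gt(suppressWarnings(stats::fisher.test(table(ins1, ess1)))$p.value, 0.01)
})

test_that("phenotype database honours its degenerate parameter limits", {
  w <- cached_world(seed = 31, n_genes_a = 400, n_genes_b = 100,
                    n_shared_features = 20, n_informative = 5)
  w_perfect <- w
  w_perfect$config$phen_coverage <- 1
  w_perfect$config$p_lethal_given_essential <- 1
  w_perfect$config$p_lethal_given_nonessential <- 0
  db <- generate_phenotype_db(w_perfect, "A", seed = 5)
  expect_setequal(db$gene_id[db$lethal],
                  names(which(w$species$A$truth$essential)))
  expect_equal(nrow(db), 400)

  w_empty <- w
  w_empty$config$phen_coverage <- 0
  expect_equal(nrow(generate_phenotype_db(w_empty, "A", seed = 5)), 0)
})

test_that("lethal prevalence matches the class-conditional mixture", {
  w <- cached_world(seed = 41, n_genes_a = 4000, n_genes_b = 100,
                    n_shared_features = 20, n_informative = 5)
  db <- generate_phenotype_db(w, "A", seed = 11)
  cfg <- w$config
  pi_e <- mean(w$species$A$truth$essential)
  expected <- pi_e * cfg$p_lethal_given_essential +
    (1 - pi_e) * cfg$p_lethal_given_nonessential
  expect_lt(abs(mean(db$lethal) - expected), 3 * sqrt(expected * (1 - expected) / nrow(db)))
  expect_lt(abs(nrow(db) / 4000 - cfg$phen_coverage), 0.05)
})

test_that("invalid generator configurations are rejected", {
  expect_error(world_config(n_informative = 30, n_shared_features = 20),
               "n_informative")
  expect_error(world_config(p_lethal_given_essential = 0.1,
                            p_lethal_given_nonessential = 0.5),
               "exceed")
  expect_error(world_config(het_fraction = 1.5), "\\[0, 1\\]")
})

test_that("worlds round-trip to disk in standard formats", {
  w <- cached_world(seed = 51, n_genes_a = 60, n_genes_b = 60,
                    n_shared_features = 10, n_informative = 3)
  dir <- withr::local_tempdir()
  write_world(w, dir)
  ft <- read_feature_table(file.path(dir, "species_A", "features.tsv"), species = "A")
  expect_equal(ft$values, w$species$A$features$values)
  ann <- read_gff3(file.path(dir, "species_A", "genes.gff3"))
  expect_setequal(ann$genes$gene_id, w$species$A$annotation$genes$gene_id)
  g0 <- w$species$A$annotation$genes
  expect_equal(ann$genes$start[match(g0$gene_id, ann$genes$gene_id)], g0$start)
  prot <- read_fasta(file.path(dir, "species_A", "proteins.fasta"))
  expect_identical(prot[names(w$species$A$proteins)], w$species$A$proteins)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$config$seed, 51)
})
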