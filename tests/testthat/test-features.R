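test_that("gc_content follows the N-exclusion rule", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATNGC"), 0.5)   # N out of both numerator and denominator
  expect_error(gc_content(""), "non-empty")
  expect_error(gc_content("NNN"), "undefined")
  expect_error(gc_content("ATXG"), "unexpected")
})

test_that("amino-acid composition is a normalized 20-vector", {
  expect_equal(unname(aa_composition("SSSS")["AAC_S"]), 1.0)
  comp <- aa_composition("SASA")
  expect_equal(unname(comp["AAC_S"]), 0.5)
  expect_equal(unname(comp["AAC_A"]), 0.5)
  set.seed(4)
  rnd <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 60, TRUE), collapse = "")
  expect_equal(sum(aa_composition(rnd)), 1.0)
  expect_length(aa_composition(rnd), 20)
  expect_error(aa_composition(""), "non-empty")
})

test_that("autocorrelation matches its defining formula", {
  # homopolymer: AC(d) = P(A)^2 at every lag
  scale <- crossess:::KYTE_DOOLITTLE
  pA <- unname((scale - mean(scale)) / sd(scale))[1]
  ac <- autocorrelation(strrep("A", 30))
  expect_equal(unname(ac), rep(pA^2, 3), tolerance = 1e-12)
  # alternating residues with opposite standardized property signs:
  # lag 2 pairs like residues (positive product), lag 1 unlike (negative)
  alt <- paste(rep(c("I", "R"), 20), collapse = "")  # hydropathy 4.5 / -4.5
  ac2 <- autocorrelation(alt, max_lag = 2)
  expect_gt(ac2["AC_2"], ac2["AC_1"])
  expect_lt(ac2["AC_1"], 0)
  expect_error(autocorrelation("IKL", max_lag = 3), "shorter")
})

test_that("exon features count and sum 1-based inclusive lengths", {
  ann <- list(genes = data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                                 start = c(1, 100, 500), end = c(10, 300, 600),
                                 strand = "+"),
              exons = data.frame(gene_id = c("g1", "g2", "g2"),
                                 start = c(1, 100, 200), end = c(10, 150, 260)))
  ef <- exon_features(ann)
  expect_equal(ef$exons, c(1L, 2L, 0L))
  expect_equal(ef$exons_total_length, c(10, 112, 0))
})

test_that("distance from the chromosome centre is the scaled midpoint offset", {
  genes <- data.frame(gene_id = c("mid", "edge", "quarter"), chrom = "c",
                      start = c(49, 1, 20), end = c(51, 1, 30))
  d <- distance_from_centre(genes, c(c = 100))
  expect_equal(unname(d["mid"]), 0)
  expect_gt(d["edge"], 0.97)
  expect_equal(unname(d["quarter"]), 0.5)  # midpoint 25 on length 100
  expect_error(distance_from_centre(genes, c(c = -5)), "positive")
})

test_that("peak overlap counting respects the half-open BED convention", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 100, end = 200)
  peaks <- data.frame(chrom = "chr1", start = c(149, 299), end = c(160, 400))
  expect_equal(unname(count_peak_overlaps(genes, peaks)), 1L)
  # peak starting exactly at the gene end in 0-based coords does not overlap
  abut <- data.frame(chrom = "chr1", start = 200, end = 250)
  expect_equal(unname(count_peak_overlaps(genes, abut)), 0L)
  # but a peak ending at the gene start does cover base 100
  touch <- data.frame(chrom = "chr1", start = 99, end = 100)
  expect_equal(unname(count_peak_overlaps(genes, touch)), 1L)
  expect_equal(unname(count_peak_overlaps(genes, peaks[0, ])), 0L)
})

test_that("peak overlap counts agree with a brute-force intersector", {
  set.seed(11)
  for (rep in 1:20) {
    genes <- data.frame(gene_id = sprintf("g%d", 1:15),
                        chrom = sample(c("c1", "c2"), 15, TRUE),
                        start = sample(1:500, 15))
    genes$end <- genes$start + sample(1:100, 15)
    peaks <- data.frame(chrom = sample(c("c1", "c2"), 25, TRUE),
                        start = sample(0:550, 25))
    peaks$end <- peaks$start + sample(1:80, 25)
    expect_equal(unname(count_peak_overlaps(genes, peaks)),
                 brute_peak_overlaps(genes, peaks))
  }
})

test_that("centralities match brute force on canonical small graphs", {
  # path a-b-c
  adj <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  adj["a", "b"] <- adj["b", "a"] <- adj["b", "c"] <- adj["c", "b"] <- 1
  cen <- graph_centralities(adj_to_igraph(adj))
  expect_equal(cen$betweenness[cen$node == "b"], 1)
  expect_equal(cen$betweenness[cen$node == "a"], 0)
  # complete graph K4
  k4 <- matrix(1, 4, 4) - diag(4)
  dimnames(k4) <- list(letters[1:4], letters[1:4])
  cen4 <- graph_centralities(adj_to_igraph(k4))
  expect_equal(cen4$betweenness, rep(0, 4))
  expect_equal(cen4$degree, rep(3, 4))
  # isolate
  iso <- matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  ceni <- graph_centralities(adj_to_igraph(iso))
  expect_equal(ceni$degree, c(0, 0))
  expect_equal(ceni$closeness, c(0, 0))
})

test_that("self-loops are dropped before computing centralities", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "a", "b"), to = c("a", "b", "c")), directed = FALSE)
  cen <- graph_centralities(g)
  expect_equal(cen$degree[cen$node == "a"], 1)
})

test_that("ortholog group sizes use the largest containing group", {
  groups <- list(OG1 = c("g1", "g2", "g3", "g4", "g5", "g6", "g7"),
                 OG2 = c("g1", "g8"), OG3 = "g9")
  expect_message(sizes <- ortholog_group_sizes(groups, c("g1", "g8", "g9", "g10")),
                 "multiple groups")
  expect_equal(unname(sizes), c(7L, 2L, 1L, 0L))
})

test_that("EST hit counting filters at the e-value cutoff inclusively", {
  hits <- data.frame(qseqid = sprintf("est%d", 1:5),
                     sseqid = c("g1", "g1", "g1", "g1", "g2"),
                     evalue = c(1e-20, 1e-20, 1e-20, 1e-5, 1e-10))
  cnt <- est_hit_counts(hits, c("g1", "g2", "g3"))
  expect_equal(unname(cnt), c(3L, 1L, 0L))  # 1e-10 boundary counted, 1e-5 not
  expect_equal(unname(est_hit_counts(hits[0, ], c("g1", "g2"))), c(0L, 0L))
})

test_that("featurize derives sequence and annotation columns for a species", {
  w <- cached_world(seed = 61, n_genes_a = 50, n_genes_b = 50,
                    n_shared_features = 8, n_informative = 3)
  sp <- w$species$A
  ft <- featurize(sp$features, sp$proteins, sp$annotation, sp$chrom_lengths)
  expect_true(all(c("AAC_S", "AC_1", "exons", "exons_total_length", "distance") %in%
                  ft$feature_names))
  expect_equal(nrow(ft$values), 50)
  expect_true(all(is.finite(ft$values)))
  # composition block rows sum to one
  aac_cols <- grep("^AAC_", ft$feature_names, value = TRUE)
  expect_equal(unname(rowSums(ft$values[, aac_cols])), rep(1, 50))
})
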