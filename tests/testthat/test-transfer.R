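xgb_quick <- list(list(max_depth = 3, eta = 0.3, nrounds = 60,
                       colsample_bytree = 0.8, lambda = 1))

test_that("spearman concordance matches the rank formula and its limits", {
  a <- c(g1 = 1, g2 = 2, g3 = 3, g4 = 4)
  expect_equal(spearman_concordance(a, a), 1)
  expect_equal(spearman_concordance(a, -a), -1)
  b <- c(g1 = 1, g2 = 3, g3 = 2, g4 = 4)
  expect_equal(spearman_concordance(a, b), 0.8)  # 1 - 6*2/(4*15)
  expect_error(spearman_concordance(a[1:2], b[1:2]), "at least 3")
  # computed on the name intersection only
  expect_equal(spearman_concordance(c(a, g9 = 99), b), 0.8)
})

test_that("cumulative lethal ratios reproduce the worked toy example", {
  ranked <- data.frame(gene_id = c("g1", "g2", "g3", "g4"), rank = 1:4)
  db <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   lethal = c(TRUE, FALSE, TRUE, FALSE))
  top <- cumulative_lethal_ratio(ranked, db, "top_down")
  expect_equal(top$ratio, c(1, 0.5, 2 / 3, 0.5))
  bottom <- cumulative_lethal_ratio(ranked, db, "bottom_up")
  expect_equal(bottom$ratio, c(0, 0.5, 1 / 3, 0.5))
  expect_equal(top$ratio[4], bottom$ratio[4])
  expect_error(cumulative_lethal_ratio(ranked, db[0, ], "top_down"), "empty")
})

test_that("uncovered genes are skipped and leading gaps carried as missing", {
  ranked <- data.frame(gene_id = sprintf("g%d", 1:5), rank = 1:5)
  db <- data.frame(gene_id = c("g3", "g5"), lethal = c(TRUE, FALSE))
  top <- cumulative_lethal_ratio(ranked, db, "top_down")
  expect_true(all(is.na(top$ratio[1:2])))
  expect_equal(top$ratio[3:5], c(1, 1, 0.5))
  expect_equal(top$covered, c(0, 0, 1, 1, 2))
})

test_that("curve endpoints equal prevalence in both directions on random instances", {
  set.seed(19)
  for (i in 1:60) {
    n <- sample(10:60, 1)
    ranked <- data.frame(gene_id = sprintf("g%d", 1:n), rank = sample(n))
    covered <- sample(n, max(2, rbinom(1, n, 0.6)))
    db <- data.frame(gene_id = sprintf("g%d", covered),
                     lethal = as.logical(rbinom(length(covered), 1, 0.3)))
    top <- cumulative_lethal_ratio(ranked, db, "top_down")
    bottom <- cumulative_lethal_ratio(ranked, db, "bottom_up")
    expect_identical(top$ratio[n], bottom$ratio[n])
    expect_identical(top$ratio[n], mean(db$lethal))
  }
})

test_that("a perfect ranking gives a non-increasing top-down curve from 1", {
  ranked <- data.frame(gene_id = sprintf("g%d", 1:20), rank = 1:20)
  db <- data.frame(gene_id = sprintf("g%d", 1:20),
                   lethal = c(rep(TRUE, 6), rep(FALSE, 14)))
  top <- cumulative_lethal_ratio(ranked, db, "top_down")
  expect_equal(top$ratio[1], 1)
  expect_true(all(diff(top$ratio) <= 1e-12))
  bottom <- cumulative_lethal_ratio(ranked, db, "bottom_up")
  expect_equal(bottom$ratio[1], 0)
})

test_that("cross-species prediction ranks target essentials highly", {
  w <- small_world(seed = 5)
  H <- harmonize(w$species$A$features, w$species$B$features)
  lab_a <- assign_labels(w$species$A$ref_probs)
  r <- cross_predict(H$a, lab_a, w$truth$informative, H$b,
                     grid = xgb_quick, seed = 3)
  expect_equal(r$rank, seq_len(nrow(r)))
  expect_true(all(diff(r$probability) <= 0))
  truth_b <- w$species$B$truth$essential
  auc <- roc_auc(setNames(r$probability, r$gene_id)[names(truth_b)], truth_b)
  expect_gt(auc, 0.8)
  expect_error(cross_predict(H$a, lab_a, c(w$truth$informative, "no_such"),
                             H$b), "feature mismatch")
})

test_that("self-transfer reproduces the within-species ranking (control mode)", {
  w <- small_world(seed = 5)
  H <- harmonize(w$species$A$features, w$species$A$features)
  lab_a <- assign_labels(w$species$A$ref_probs)
  r1 <- cross_predict(H$a, lab_a, w$truth$informative, H$a,
                      grid = xgb_quick, seed = 3)
  r2 <- cross_predict(H$b, lab_a, w$truth$informative, H$b,
                      grid = xgb_quick, seed = 3)
  expect_equal(r1$gene_id, r2$gene_id)
  expect_equal(r1$probability, r2$probability)
})

test_that("destroying coefficient sharing destroys transferability", {
  w_far <- cached_world(seed = 6, n_genes_a = 700, n_genes_b = 700,
                        n_shared_features = 40, n_private_features_per_species = 4,
                        n_informative = 10, coef_jitter_sd = 3.0)
  H <- harmonize(w_far$species$A$features, w_far$species$B$features)
  lab_a <- assign_labels(w_far$species$A$ref_probs)
  r <- cross_predict(H$a, lab_a, w_far$truth$informative, H$b,
                     grid = xgb_quick, seed = 3)
  truth_b <- w_far$species$B$truth$essential
  auc <- roc_auc(setNames(r$probability, r$gene_id)[names(truth_b)], truth_b)
  expect_lt(auc, 0.68)
})

test_that("top-ranked genes are lethal-enriched and bottom-ranked depleted", {
  seeds <- 1:3
  top_ratio <- bottom_ratio <- prev <- numeric(0)
  for (s in seeds) {
    w <- default_world(seed = s)
    H <- harmonize(w$species$A$features, w$species$B$features)
    lab_a <- assign_labels(w$species$A$ref_probs)
    r <- cross_predict(H$a, lab_a, w$truth$informative, H$b,
                       grid = xgb_quick, seed = s)
    db <- w$species$B$phenotypes
    top <- cumulative_lethal_ratio(r, db, "top_down")
    bottom <- cumulative_lethal_ratio(r, db, "bottom_up")
    top_ratio <- c(top_ratio, top$ratio[500])
    bottom_ratio <- c(bottom_ratio, bottom$ratio[500])
    prev <- c(prev, mean(db$lethal))
  }
  expect_gte(mean(top_ratio), 3 * mean(prev))
  expect_lte(mean(bottom_ratio), mean(prev) / 2)
})
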