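# Planted single/multi-feature designs used across the selection tests.
planted_design <- function(n = 500, p_noise = 20, effects = 2.0, seed = 1) {
  withr::with_seed(seed, {
    p_inf <- length(effects)
    X <- matrix(rnorm(n * (p_inf + p_noise)), n,
                dimnames = list(NULL, c(sprintf("inf%d", seq_len(p_inf)),
                                        sprintf("noise%d", seq_len(p_noise)))))
    eta <- X[, seq_len(p_inf), drop = FALSE] %*% effects
    y <- rbinom(n, 1, stats::plogis(drop(eta)))
    list(X = X, y = y, informative = sprintf("inf%d", seq_len(p_inf)))
  })
}

test_that("elastic net recovers a strong planted feature among noise", {
  d <- planted_design(n = 500, p_noise = 20, effects = 2.0, seed = 3)
  sel <- elasticnet_select(d$X, d$y, seed = 1)
  expect_true("inf1" %in% sel)
  expect_error(elasticnet_select(d$X, rep(1, nrow(d$X)), seed = 1), "both classes")
})

test_that("full shrinkage empties the elastic-net selection", {
  d <- planted_design(n = 200, p_noise = 5, effects = 1.5, seed = 4)
  sel <- elasticnet_select(d$X, d$y, alpha_grid = 0.5, seed = 1,
                           lambda = c(1e4, 5e3))
  expect_length(sel, 0)
})

test_that("a duplicated informative column is still selected (grouping property)", {
  d <- planted_design(n = 400, p_noise = 10, effects = 2.0, seed = 5)
  X2 <- cbind(d$X, inf1_copy = d$X[, "inf1"])
  sel <- elasticnet_select(X2, d$y, seed = 2)
  expect_true(any(c("inf1", "inf1_copy") %in% sel))
})

test_that("spls direction with eta = 0, K = 1 is the normalized X'y", {
  set.seed(9)
  X <- scale(matrix(rnorm(200 * 12), 200, 12))
  colnames(X) <- sprintf("f%02d", 1:12)
  y <- rnorm(200)
  fit <- spls_fit(X, y, K = 1, eta = 0)
  z <- drop(crossprod(X, y - mean(y)))
  expect_equal(unname(fit$W[, 1]), unname(z / sqrt(sum(z^2))), tolerance = 1e-10)
})

test_that("eta near one keeps only the dominant covariance feature", {
  set.seed(10)
  X <- scale(matrix(rnorm(300 * 8), 300, 8))
  colnames(X) <- sprintf("f%d", 1:8)
  y <- X[, "f3"] * 2 + rnorm(300, sd = 0.5)
  fit <- spls_fit(X, y, K = 1, eta = 0.999)
  expect_equal(fit$selected, "f3")
})

test_that("spls rejects invalid sparsity and component counts", {
  X <- scale(matrix(rnorm(40), 10, 4, dimnames = list(NULL, letters[1:4])))
  y <- rnorm(10)
  expect_error(spls_fit(X, y, eta = 1), "eta")
  expect_error(spls_fit(X, y, K = 0), "K must be")
  expect_error(spls_fit(X, y, K = 5), "rank")
})

test_that("spls recovers planted informative features", {
  d <- planted_design(n = 500, p_noise = 20,
                      effects = c(1.5, 1.5, 1.5, 1.5, 1.5), seed = 6)
  fit <- spls_fit(scale(d$X), d$y, K = 2, eta = 0.7)
  expect_true(all(d$informative %in% fit$selected))
})

test_that("ensemble spls frequencies separate planted from noise features", {
  d <- planted_design(n = 500, p_noise = 20,
                      effects = c(1.5, 1.5, 1.5, 1.5, 1.5), seed = 7)
  ens <- ensemble_spls_select(scale(d$X), d$y, B = 50, seed = 8)
  expect_true(all(ens$frequencies[d$informative] >= 0.9))
  noise <- setdiff(colnames(d$X), d$informative)
  expect_true(all(ens$frequencies[noise] <= 0.35))
  expect_setequal(ens$selected, d$informative)
})

test_that("frequency-threshold limits give the union and the empty set", {
  d <- planted_design(n = 150, p_noise = 5, effects = 1.0, seed = 11)
  X <- scale(d$X)
  union_sel <- ensemble_spls_select(X, d$y, B = 10, freq_threshold = 0, seed = 1)
  expect_setequal(union_sel$selected,
                  names(union_sel$frequencies)[union_sel$frequencies > 0])
  none <- ensemble_spls_select(X, d$y, B = 10, freq_threshold = 1.01, seed = 1)
  expect_length(none$selected, 0)
  expect_error(ensemble_spls_select(X, d$y, B = 0), "B must be")
})

test_that("consensus is the plain intersection with a warning when empty", {
  expect_setequal(consensus_select(c("a", "b", "c"), c("b", "c", "d")), c("b", "c"))
  expect_warning(out <- consensus_select("a", "b"), "empty")
  expect_length(out, 0)
  expect_setequal(consensus_select(c("a", "b"), c("a", "b")), c("a", "b"))
})

test_that("median importance ranks by exact median with lexicographic ties", {
  imp <- list(m1 = c(f = 100, g = 10, h = 0),
              m2 = c(f = 60, g = 50, h = 0),
              m3 = c(f = 80, g = 80, h = 0))
  rk <- median_importance(imp)
  expect_equal(rk$median[rk$feature == "f"], 80)
  expect_equal(rk$feature[1], "f")
  expect_equal(rk$feature[nrow(rk)], "h")  # all-zero feature ranks last
  single <- median_importance(imp["m1"])
  expect_equal(single$feature, c("f", "g", "h"))
  # equal medians fall back to lexicographic feature order
  tied <- median_importance(list(m = c(b = 50, a = 50)))
  expect_equal(tied$feature, c("a", "b"))
  expect_error(median_importance(list(m = c(a = 120))), "scale")
})

test_that("permutation importance singles out the informative feature", {
  d <- planted_design(n = 400, p_noise = 4, effects = 2.5, seed = 12)
  m <- ess_fit(d$X[1:300, ], d$y[1:300], family = "GLM", seed = 1)
  imp <- permutation_importance(m, d$X[301:400, ], d$y[301:400], seed = 2)
  expect_equal(names(which.max(imp)), "inf1")
  expect_equal(max(imp), 100)
})
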