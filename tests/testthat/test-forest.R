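planted_data <- function(n = 100, p = 5, seed = 1, sd = 0.5) {
  leafdrought:::with_seed(seed, {
    x <- as.data.frame(matrix(rnorm(n * p), n, p))
    names(x) <- paste0("v", seq_len(p))
    list(x = x, y = 2 * x$v1 + rnorm(n, sd = sd))
  })
}

test_that("forest fit: planted linear signal gives high OOB R^2", {
  d <- planted_data()
  # mtry = p so the single informative predictor is available at every
  # split; the default p/3 dilutes a lone linear signal
  fit <- fit_forest(d$x, d$y, ntree = 300, seed = 1, mtry = 5)
  expect_gt(fit$r2, 0.8)
})

test_that("forest fit: constant response yields non-positive R^2", {
  d <- planted_data()
  fit <- suppressWarnings(fit_forest(d$x, rep(1, nrow(d$x)), ntree = 50,
                                     seed = 1))
  expect_lte(fit$r2, 0)
})

test_that("forest fit is deterministic for a fixed seed", {
  d <- planted_data(n = 40)
  f1 <- fit_forest(d$x, d$y, ntree = 100, seed = 5)
  f2 <- fit_forest(d$x, d$y, ntree = 100, seed = 5)
  expect_identical(f1$oob_mse, f2$oob_mse)
  expect_identical(permutation_importance(f1, seed = 3),
                   permutation_importance(f2, seed = 3))
  expect_error(fit_forest(d$x[1:5, ], d$y[1:5]), "at least 10")
})

test_that("planted predictor dominates pure-noise predictors", {
  for (s in 1:5) {
    d <- planted_data(n = 80, seed = s)
    imp <- permutation_importance(fit_forest(d$x, d$y, ntree = 300, seed = s))
    expect_equal(names(which.max(imp)), "v1")
    expect_true(all(imp["v1"] > abs(imp[c("v2", "v3", "v4", "v5")])))
  }
})

test_that("permutation importance matches a brute-force reimplementation", {
  # tiny instance: 3 trees, 10 rows, manual tree traversal via getTree
  d <- planted_data(n = 10, p = 3, seed = 2)
  fit <- fit_forest(d$x, d$y, ntree = 3, seed = 4)
  mine <- permutation_importance(fit, seed = 99)
  brute <- brute_force_incmse(fit, seed = 99)
  expect_equal(mine, brute, tolerance = 1e-10)
  # a second configuration, more trees
  d2 <- planted_data(n = 16, p = 4, seed = 6)
  fit2 <- fit_forest(d2$x, d2$y, ntree = 7, seed = 8)
  expect_equal(permutation_importance(fit2, seed = 13),
               brute_force_incmse(fit2, seed = 13), tolerance = 1e-10)
})

test_that("importance agrees with randomForest's own measure on rankings", {
  # independent route: randomForest's unscaled permutation importance
  # (mean raw OOB-MSE increase) must rank the planted predictor first,
  # like the package's percentage-based loop
  d <- planted_data(n = 80, seed = 11)
  fit <- fit_forest(d$x, d$y, ntree = 300, seed = 11, importance = TRUE)
  ref <- randomForest::importance(fit$forest, type = 1, scale = FALSE)[, 1]
  mine <- permutation_importance(fit, seed = 11)
  expect_equal(names(which.max(mine)), names(which.max(ref)))
  expect_gt(cor(mine, ref[names(mine)], method = "spearman"), 0.6)
})

test_that("importance ranking is invariant to positive affine rescaling", {
  d <- planted_data(n = 60, seed = 3)
  f1 <- fit_forest(d$x, d$y, ntree = 200, seed = 7)
  xs <- d$x
  xs$v1 <- 100 + 50 * xs$v1   # splits are rank-based
  f2 <- fit_forest(xs, d$y, ntree = 200, seed = 7)
  i1 <- permutation_importance(f1, seed = 21)
  i2 <- permutation_importance(f2, seed = 21)
  expect_equal(order(-i1), order(-i2))
})

test_that("backward selection is the identity at full target count", {
  d <- planted_data(n = 30, p = 4, seed = 5)
  sel <- backward_select(d$x, d$y, target_count = 4, ntree = 50, seed = 1)
  expect_equal(sel$retained, names(d$x))
  expect_equal(sel$drop_order, character(0))
  expect_error(backward_select(d$x, d$y, target_count = 5), "exceeds")
})

test_that("backward selection keeps planted signals, logs drops, reproduces", {
  leafdrought:::with_seed(31, {
    n <- 60
    x <- as.data.frame(matrix(rnorm(n * 10), n, 10))
    names(x) <- c(paste0("sig", 1:3), paste0("noise", 1:7))
    y <- 2 * x$sig1 + 1.5 * x$sig2 + x$sig3 + rnorm(n, sd = 0.5)
  })
  sel <- backward_select(x, y, target_count = 5, ntree = 200, seed = 2)
  expect_true(all(paste0("sig", 1:3) %in% sel$retained))
  expect_equal(length(sel$drop_order), 5)
  sel2 <- backward_select(x, y, target_count = 5, ntree = 200, seed = 2)
  expect_identical(sel$retained, sel2$retained)
})

test_that("permutation p-values respect the plus-one lower bound", {
  d <- planted_data(n = 25, p = 3, seed = 9)
  r <- importance_significance(d$x, d$y, n_perm = 20, ntree = 50, seed = 3)
  expect_true(all(r$importance$p_value >= 1 / 21))
  expect_true(all(r$importance$p_value <= 1))
  expect_equal(r$importance$predictor, names(d$x))
  expect_error(importance_significance(d$x, d$y, n_perm = 5), ">= 20")
  # strong planted signal is flagged
  expect_lt(r$importance$p_value[1], 0.05)
})

test_that("model significance attains its bound on planted signal", {
  d <- planted_data(n = 40, seed = 12)
  m <- model_significance(d$x, d$y, n_perm = 99, ntree = 100, seed = 4)
  expect_equal(m$p, 0.01)             # 1/(99 + 1): minimum attainable
  expect_gt(m$r2, 0.3)
  m2 <- model_significance(d$x, d$y, n_perm = 99, ntree = 100, seed = 4)
  expect_identical(m$p, m2$p)
})

test_that("feature matrix screening drops constant columns", {
  tab <- generate_trait_table(default_experiment_config(), 3)
  const <- data.frame(treatment = rep(c("CK", "T1", "T2", "T3"), each = 12),
                      period = rep(rep(paste0("S", 1:4), each = 3), 4),
                      replicate = rep(1:3, 16), trait = "flat", value = 1)
  tab2 <- assemble_trait_records(tab, const)
  expect_warning(fm <- feature_matrix(tab2, "astar"), "constant")
  expect_false("flat" %in% names(fm$predictors))
  expect_equal(nrow(fm$predictors), 48)
  expect_equal(length(fm$response), 48)
})
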