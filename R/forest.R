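# Permutation-tested random-forest importance of leaf color parameters.
#
# The forest learner is the randomForest package; everything the analysis
# actually specifies - the %IncMSE permutation loop, the per-predictor
# and whole-model permutation tests, and backward predictor selection -
# is implemented here. n = 48 observations (4 x 4 x 3) is small for ~14
# predictors, so importance results should be read with the
# seed-sensitivity diagnostics in mind (see `importance_over_seeds`).

#' Build a feature matrix from a long trait table
#'
#' One row per (treatment, period, replicate) observation; the response
#' is one color parameter and the predictors default to every other
#' trait. Constant predictor columns are screened out with a warning.
#'
#' @param table Long trait table.
#' @param response Response trait name (e.g. `"astar"`).
#' @param predictors Optional predictor trait names.
#' @param screen Drop constant predictor columns (default TRUE).
#' @return List with `predictors` (data frame), `response` (numeric),
#'   `keys` (treatment/period/replicate).
#' @export
feature_matrix <- function(table, response, predictors = NULL, screen = TRUE) {
  if (is.null(predictors))
    predictors <- setdiff(unique(table$trait), response)
  wide <- trait_wide(table, c(response, predictors))
  keys <- wide[c("treatment", "period", "replicate")]
  y <- wide[[response]]
  if (is.null(y)) stop("response trait not found: ", response)
  x <- wide[intersect(predictors, names(wide))]
  if (screen) {
    keep <- vapply(x, function(v) stats::sd(v) > 0, TRUE)
    if (any(!keep))
      warning("dropping constant predictor(s): ",
              paste(names(x)[!keep], collapse = ", "))
    x <- x[keep]
  }
  list(predictors = x, response = y, keys = keys)
}

#' Fit a random-forest regression ensemble with out-of-bag R^2
#'
#' Bootstrap-resampled regression-tree ensemble (ntree trees) with
#' in-bag bookkeeping retained so that permutation importance can be
#' computed tree-wise on the out-of-bag samples. Deterministic for a
#' fixed seed.
#'
#' @param predictors Data frame of numeric predictors.
#' @param response Numeric response (>= 10 observations).
#' @param ntree Number of trees (default 500).
#' @param seed Integer seed.
#' @param ... Passed to [randomForest::randomForest()].
#' @return Object of class `rf_fit`: `forest`, `predictors`, `response`,
#'   `oob_mse`, `r2` (1 - OOB-MSE / var(response)), `ntree`, `seed`.
#' @export
fit_forest <- function(predictors, response, ntree = 500L, seed = 1L, ...) {
  predictors <- as.data.frame(predictors)
  if (nrow(predictors) < 10L) stop("need at least 10 observations")
  stopifnot(length(response) == nrow(predictors))
  rf <- with_seed(seed,
    randomForest::randomForest(x = predictors, y = response, ntree = ntree,
                               keep.forest = TRUE, keep.inbag = TRUE, ...))
  oob <- rf$predicted
  mse <- mean((response - oob)^2, na.rm = TRUE)
  vy <- mean((response - mean(response))^2)
  r2 <- if (vy > 0) 1 - mse / vy else 0
  structure(list(forest = rf, predictors = predictors, response = response,
                 oob_mse = mse, r2 = r2, ntree = as.integer(ntree),
                 seed = as.integer(seed)),
            class = "rf_fit")
}

#' @export
print.rf_fit <- function(x, ...) {
  cat(sprintf("Random forest: %d trees, %d predictors, n = %d\n",
              x$ntree, ncol(x$predictors), nrow(x$predictors)))
  cat(sprintf("  OOB MSE = %.4g, variance explained R^2 = %.3f\n",
              x$oob_mse, x$r2))
  invisible(x)
}

#' Permutation importance (%IncMSE)
#'
#' For each predictor, its column is permuted and every tree is re-scored
#' on its own out-of-bag samples; the importance is the mean percentage
#' increase in per-tree OOB MSE, 100 * mean_t (MSE_perm,t - MSE_t) /
#' MSE_t. One permutation is drawn per predictor (from `seed`), shared
#' across trees and evaluated tree-wise, so one prediction pass per
#' predictor suffices.
#'
#' @param fit An [fit_forest()] object.
#' @param seed Permutation seed (default derived from the fit's seed).
#' @return Named numeric vector of %IncMSE values.
#' @export
permutation_importance <- function(fit,
                                   seed = substream_seed(fit$seed, "perm")) {
  stopifnot(inherits(fit, "rf_fit"))
  rf <- fit$forest
  x <- fit$predictors
  y <- fit$response
  n <- nrow(x)
  ind <- stats::predict(rf, x, predict.all = TRUE)$individual
  oob <- rf$inbag == 0
  n_oob <- colSums(oob)
  base <- colSums((y - ind)^2 * oob) / pmax(n_oob, 1L)
  ok <- n_oob > 0 & base > 0
  perms <- with_seed(seed,
    replicate(ncol(x), sample.int(n), simplify = FALSE))
  inc <- vapply(seq_along(x), function(j) {
    xp <- x
    xp[[j]] <- x[[j]][perms[[j]]]
    indj <- stats::predict(rf, xp, predict.all = TRUE)$individual
    msej <- colSums((y - indj)^2 * oob) / pmax(n_oob, 1L)
    100 * mean((msej[ok] - base[ok]) / base[ok])
  }, 0)
  stats::setNames(inc, names(x))
}

#' Per-predictor permutation significance of %IncMSE
#'
#' The null distribution of each predictor's importance is obtained by
#' refitting the forest on response-permuted data `n_perm` times;
#' p = (1 + #\{null >= observed\}) / (n_perm + 1), so p can never be
#' exactly zero.
#'
#' @param predictors Data frame of predictors.
#' @param response Numeric response.
#' @param n_perm Number of response permutations (>= 20, default 100).
#' @param ntree Trees per forest (default 500).
#' @param seed Master seed.
#' @return Object of class `rf_importance`: data frame `importance`
#'   (predictor, inc_mse, p_value), plus `r2`, `n_perm`, `ntree`, `seed`.
#' @export
importance_significance <- function(predictors, response, n_perm = 100L,
                                    ntree = 500L, seed = 1L) {
  if (n_perm < 20L) stop("n_perm must be >= 20")
  fit <- fit_forest(predictors, response, ntree = ntree,
                    seed = substream_seed(seed, "obs"))
  obs <- permutation_importance(fit)
  null <- matrix(NA_real_, n_perm, length(obs),
                 dimnames = list(NULL, names(obs)))
  for (b in seq_len(n_perm)) {
    yb <- with_seed(substream_seed(seed, paste0("shuffle", b)),
                    sample(response))
    fb <- fit_forest(predictors, yb, ntree = ntree,
                     seed = substream_seed(seed, paste0("nullfit", b)))
    null[b, ] <- permutation_importance(fb)
  }
  p <- (1 + colSums(null >= rep(obs, each = n_perm))) / (n_perm + 1)
  structure(list(
    importance = data.frame(predictor = names(obs), inc_mse = unname(obs),
                            p_value = unname(p), stringsAsFactors = FALSE),
    r2 = fit$r2, n_perm = as.integer(n_perm), ntree = as.integer(ntree),
    seed = as.integer(seed), null = null
  ), class = "rf_importance")
}

#' @export
print.rf_importance <- function(x, ...) {
  cat(sprintf("Permutation importance (%d trees, %d response permutations)\n",
              x$ntree, x$n_perm))
  cat(sprintf("  model variance explained R^2 = %.3f\n", x$r2))
  imp <- x$importance[order(-x$importance$inc_mse), ]
  imp$sig <- ifelse(imp$p_value < 0.01, "**",
                    ifelse(imp$p_value < 0.05, "*", ""))
  print(imp, row.names = FALSE)
  cat("note: n is small relative to the predictor count; rankings are\n")
  cat("seed-sensitive (see importance_over_seeds)\n")
  invisible(x)
}

#' @export
plot.rf_importance <- function(x, ...) {
  imp <- x$importance[order(x$importance$inc_mse), ]
  graphics::dotchart(imp$inc_mse, labels = imp$predictor,
                     xlab = "%IncMSE", ...)
  invisible(x)
}

#' Whole-model permutation significance of the OOB R^2
#'
#' Refits the forest on permuted responses and compares the observed
#' out-of-bag R^2 against the null distribution;
#' p = (1 + #\{null >= observed\}) / (n_perm + 1).
#'
#' @inheritParams importance_significance
#' @param n_perm Number of permutations (default 99, giving a minimum
#'   attainable p of 0.01).
#' @return List with `r2`, `p`, `null_r2`, `n_perm`.
#' @export
model_significance <- function(predictors, response, n_perm = 99L,
                               ntree = 500L, seed = 1L) {
  fit <- fit_forest(predictors, response, ntree = ntree,
                    seed = substream_seed(seed, "obs"))
  null_r2 <- vapply(seq_len(n_perm), function(b) {
    yb <- with_seed(substream_seed(seed, paste0("shuffle", b)),
                    sample(response))
    fit_forest(predictors, yb, ntree = ntree,
               seed = substream_seed(seed, paste0("nullfit", b)))$r2
  }, 0)
  list(r2 = fit$r2, p = (1 + sum(null_r2 >= fit$r2)) / (n_perm + 1),
       null_r2 = null_r2, n_perm = as.integer(n_perm))
}

#' Backward predictor selection by lowest %IncMSE
#'
#' Iteratively refits the forest and drops the predictor with the lowest
#' permutation importance until `target_count` remain. The drop criterion
#' (lowest %IncMSE, refit each step) is this package's concrete choice
#' for the named procedure.
#'
#' @inheritParams importance_significance
#' @param target_count Number of predictors to retain (default 14).
#' @return List with `predictors` (reduced data frame), `retained`,
#'   `drop_order` (first dropped first), `importance` (final fit's).
#' @export
backward_select <- function(predictors, response, target_count = 14L,
                            ntree = 500L, seed = 1L) {
  predictors <- as.data.frame(predictors)
  if (target_count > ncol(predictors))
    stop("target_count exceeds the number of candidate predictors")
  dropped <- character()
  step <- 0L
  while (ncol(predictors) > target_count) {
    step <- step + 1L
    fit <- fit_forest(predictors, response, ntree = ntree,
                      seed = substream_seed(seed, paste0("step", step)))
    imp <- permutation_importance(fit)
    worst <- names(imp)[which.min(imp)]
    dropped <- c(dropped, worst)
    predictors <- predictors[setdiff(names(predictors), worst)]
  }
  fit <- fit_forest(predictors, response, ntree = ntree,
                    seed = substream_seed(seed, "final"))
  list(predictors = predictors, retained = names(predictors),
       drop_order = dropped, importance = permutation_importance(fit))
}

#' Importance averaged over seeds (stability diagnostic)
#'
#' With 48 observations importance rankings move between seeds; this
#' recomputes %IncMSE over `n_seeds` forests and returns the per-seed
#' matrix and the mean.
#'
#' @inheritParams importance_significance
#' @param n_seeds Number of seeds (default 20).
#' @return List with `mean` (named vector) and `per_seed` (matrix).
#' @export
importance_over_seeds <- function(predictors, response, n_seeds = 20L,
                                  ntree = 500L, seed = 1L) {
  per <- t(vapply(seq_len(n_seeds), function(s) {
    fit <- fit_forest(predictors, response, ntree = ntree,
                      seed = substream_seed(seed, paste0("seed", s)))
    permutation_importance(fit)
  }, numeric(ncol(predictors))))
  list(mean = colMeans(per), per_seed = per)
}
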