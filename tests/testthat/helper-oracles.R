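# Independent oracles used across the suite.

# Construct raw triples with exact mean m and standard error s (n = 3):
# {m - s*sqrt(3), m, m + s*sqrt(3)} has sd = s*sqrt(3), SE = s.
triples_from_summary <- function(means, ses) {
  mapply(function(m, s) c(m - s * sqrt(3), m, m + s * sqrt(3)),
         means, ses, SIMPLIFY = FALSE)
}

# Manual traversal of one randomForest tree (independent of predict()).
predict_tree_manual <- function(rf, t, x) {
  tree <- randomForest::getTree(rf, t, labelVar = FALSE)
  xm <- as.matrix(x)
  apply(xm, 1L, function(row) {
    node <- 1L
    while (tree[node, "status"] != -1L) {
      v <- tree[node, "split var"]
      node <- if (row[v] <= tree[node, "split point"])
        tree[node, "left daughter"] else tree[node, "right daughter"]
    }
    tree[node, "prediction"]
  })
}

# Brute-force permute-and-score %IncMSE: walks every tree by hand on its
# out-of-bag rows, using the same per-predictor permutations as the
# package implementation (shared permutation, tree-wise OOB scoring).
brute_force_incmse <- function(fit, seed) {
  rf <- fit$forest
  x <- fit$predictors
  y <- fit$response
  n <- nrow(x)
  perms <- leafdrought:::with_seed(
    seed, replicate(ncol(x), sample.int(n), simplify = FALSE))
  ntree <- rf$ntree
  base <- numeric(ntree)
  oob_rows <- vector("list", ntree)
  for (t in seq_len(ntree)) {
    rows <- which(rf$inbag[, t] == 0)
    oob_rows[[t]] <- rows
    pred <- predict_tree_manual(rf, t, x[rows, , drop = FALSE])
    base[t] <- mean((y[rows] - pred)^2)
  }
  ok <- lengths(oob_rows) > 0 & base > 0
  out <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    xp <- x
    xp[[j]] <- x[[j]][perms[[j]]]
    pct <- numeric(ntree)
    for (t in seq_len(ntree)) {
      rows <- oob_rows[[t]]
      pred <- predict_tree_manual(rf, t, xp[rows, , drop = FALSE])
      msej <- mean((y[rows] - pred)^2)
      pct[t] <- 100 * (msej - base[t]) / base[t]
    }
    out[j] <- mean(pct[ok])
  }
  stats::setNames(out, names(x))
}

# Smallest number of distinct letters admitting a valid display for a
# significance matrix (TRUE = significantly different), by enumeration.
minimal_letter_count <- function(sig) {
  k <- nrow(sig)
  for (L in 1:k) {
    subsets <- lapply(1:(2^L - 1), function(m) which(bitwAnd(m, 2^(0:(L - 1))) > 0))
    idx <- rep(1L, k)
    repeat {
      assign_ok <- TRUE
      for (i in 1:(k - 1)) for (j in (i + 1):k) {
        share <- length(intersect(subsets[[idx[i]]], subsets[[idx[j]]])) > 0
        if (share == sig[i, j]) { assign_ok <- FALSE; break }
      }
      if (assign_ok) return(L)
      pos <- 1L
      while (pos <= k) {
        idx[pos] <- idx[pos] + 1L
        if (idx[pos] <= length(subsets)) break
        idx[pos] <- 1L
        pos <- pos + 1L
      }
      if (pos > k) break
    }
  }
  NA_integer_
}

# A tiny single-trait experiment config for generator tests.
mini_config <- function(mean, se, replicates = 3L, trait = "x") {
  cfg <- list(
    treatments = c(CK = "100% FC"),
    periods = "S1",
    replicates = as.integer(replicates),
    se_n = 3L,
    cell_means = data.frame(treatment = "CK", period = "S1", trait = trait,
                            mean = mean, se = se, units = "u",
                            stringsAsFactors = FALSE),
    schema = "leafdrought-config-1"
  )
  class(cfg) <- "experiment_config"
  cfg
}
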