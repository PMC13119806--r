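# One-way inference layer matching the experiment's reporting style:
# one-way ANOVA within each factorial axis, Duncan's multiple range test
# at alpha = 0.05, and compact letter displays (lowercase across
# treatments within a period, uppercase across periods within a
# treatment). No multiplicity correction is applied across traits, and no
# two-way model is fitted - the reports this mirrors use neither.

#' One-way analysis of variance from raw group values
#'
#' Classical between/within decomposition. When the within-group variance
#' is exactly zero but group means differ, the F statistic is reported as
#' `Inf` with p = 0 rather than failing.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each with
#'   >= 2 values).
#' @return Object of class `anova_result`: list with `F`, `df_between`,
#'   `df_within`, `p`, `msw`, `means`, `n`.
#' @examples
#' anova_oneway(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 7)))
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) < 2L)) stop("every group needs at least 2 values")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  ni <- lengths(groups)
  mi <- vapply(groups, mean, 0)
  grand <- sum(ni * mi) / sum(ni)
  ssb <- sum(ni * (mi - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- length(groups) - 1L
  dfw <- sum(ni) - length(groups)
  msb <- ssb / dfb
  msw <- ssw / dfw
  if (msw == 0) {
    f <- if (ssb > 0) Inf else 0
    p <- if (ssb > 0) 0 else 1
  } else {
    f <- msb / msw
    p <- stats::pf(f, dfb, dfw, lower.tail = FALSE)
  }
  structure(list(F = f, df_between = dfb, df_within = dfw, p = p,
                 msw = msw, means = mi, n = ni),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' One-way ANOVA from group summaries (mean, SE, n)
#'
#' Reconstructs the classical decomposition from sufficient statistics,
#' e.g. from a published means +/- SE table: the within-group variance of
#' group i is n_i * SE_i^2, so MSW is the df-weighted mean of those and
#' the result is identical to [anova_oneway()] applied to any raw data
#' sharing the summaries.
#'
#' @param summary Data frame with columns `mean`, `se`, `n` (and
#'   optionally `label`).
#' @return An `anova_result` (see [anova_oneway()]).
#' @export
anova_from_summary <- function(summary) {
  stopifnot(all(c("mean", "se", "n") %in% names(summary)))
  if (any(summary$n < 2L)) stop("every group needs n >= 2")
  ni <- summary$n
  mi <- summary$mean
  lab <- if (!is.null(summary$label)) as.character(summary$label)
         else paste0("g", seq_len(nrow(summary)))
  grand <- sum(ni * mi) / sum(ni)
  ssb <- sum(ni * (mi - grand)^2)
  vi <- ni * summary$se^2                 # within-group sample variance
  ssw <- sum((ni - 1L) * vi)
  dfb <- nrow(summary) - 1L
  dfw <- sum(ni) - nrow(summary)
  msw <- ssw / dfw
  if (msw == 0) {
    f <- if (ssb > 0) Inf else 0
    p <- if (ssb > 0) 0 else 1
  } else {
    f <- (ssb / dfb) / msw
    p <- stats::pf(f, dfb, dfw, lower.tail = FALSE)
  }
  means <- stats::setNames(mi, lab)
  structure(list(F = f, df_between = dfb, df_within = dfw, p = p,
                 msw = msw, means = means, n = stats::setNames(ni, lab)),
            class = "anova_result")
}

# normalize duncan input to (means, n, msw, dfw)
.duncan_stats <- function(x) {
  if (is.data.frame(x)) {
    a <- anova_from_summary(x)
  } else if (is.list(x)) {
    a <- anova_oneway(x)
  } else stop("x must be a list of vectors or a mean/se/n data frame")
  n <- a$n
  if (length(unique(n)) > 1L) {
    warning("unequal group sizes; using the harmonic mean n")
    n_eff <- length(n) / sum(1 / n)
  } else n_eff <- n[1L]
  list(means = a$means, n_eff = n_eff, msw = a$msw, dfw = a$df_within)
}

#' Duncan's multiple range test
#'
#' Means are ranked; a comparison spanning p ranks is tested against the
#' critical range q(1 - (1-alpha)^(p-1); p, df) * sqrt(MSW/n), with the
#' studentized-range quantile taken at Duncan's protection level (this
#' reproduces the classical Duncan tables without shipping them). A pair
#' lying inside a non-significant span is itself declared non-significant
#' (the standard containment rule).
#'
#' @param x Named list of raw group vectors, or a summary data frame with
#'   columns `label`, `mean`, `se`, `n`.
#' @param alpha Familywise level per comparison family (default 0.05).
#' @return Object of class `duncan_mrt`: `means` (sorted decreasing),
#'   `significant` (logical matrix over the original labels, TRUE =
#'   significantly different), `critical_ranges`, `msw`, `dfw`, `alpha`.
#' @examples
#' an <- anatomy_reference()
#' g <- an[an$trait == "Mvt" & an$period == "S2",
#'         c("treatment", "mean", "se", "n")]
#' names(g)[1] <- "label"
#' compact_letters(duncan_mrt(g))  # a a b c
#' @export
duncan_mrt <- function(x, alpha = 0.05) {
  st <- .duncan_stats(x)
  k <- length(st$means)
  ord <- order(st$means, decreasing = TRUE)
  m <- st$means[ord]
  se_m <- sqrt(st$msw / st$n_eff)
  crit <- vapply(2:k, function(p) {
    ap <- 1 - (1 - alpha)^(p - 1)
    stats::qtukey(1 - ap, p, st$dfw) * se_m
  }, 0)
  names(crit) <- paste0("span", 2:k)
  # raw span tests in rank order
  raw <- matrix(FALSE, k, k, dimnames = list(names(m), names(m)))
  for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
    span <- j - i + 1L
    raw[i, j] <- raw[j, i] <- (m[i] - m[j]) > crit[span - 1L]
  }
  # containment: (i, j) significant only if every containing span is
  sig <- raw
  for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
    ok <- TRUE
    for (i2 in 1:i) for (j2 in j:k) if (!raw[i2, j2]) ok <- FALSE
    sig[i, j] <- sig[j, i] <- ok
  }
  # return matrices on the original label order
  lab0 <- names(st$means)
  sig <- sig[lab0, lab0, drop = FALSE]
  structure(list(means = m, significant = sig, critical_ranges = crit,
                 msw = st$msw, dfw = st$dfw, n_eff = st$n_eff,
                 alpha = alpha),
            class = "duncan_mrt")
}

#' @export
print.duncan_mrt <- function(x, ...) {
  cat(sprintf("Duncan's multiple range test (alpha = %g, df = %d)\n",
              x$alpha, x$dfw))
  lt <- compact_letters(x)
  out <- data.frame(mean = x$means, letters = lt[names(x$means)])
  print(out)
  invisible(x)
}

#' Compact letter display from a pairwise significance pattern
#'
#' Insert-and-absorb: start from one class holding every group; for each
#' significantly different pair, split every class containing both; then
#' absorb classes that are subsets of others. Groups sharing a letter are
#' pairwise non-significant; letters are assigned in descending-mean
#' order.
#'
#' @param x A `duncan_mrt` object, or a logical matrix (TRUE =
#'   significantly different) with dimnames; in the latter case `means`
#'   orders the letters.
#' @param means Optional named means for ordering when `x` is a matrix.
#' @return Named character vector of letter strings.
#' @export
compact_letters <- function(x, means = NULL) {
  if (inherits(x, "duncan_mrt")) {
    sig <- x$significant
    means <- x$means[rownames(sig)]
  } else {
    sig <- x
    if (is.null(means)) means <- stats::setNames(rev(seq_len(nrow(sig))),
                                                 rownames(sig))
    means <- means[rownames(sig)]
  }
  labs <- rownames(sig)[order(means, decreasing = TRUE)]
  sets <- list(labs)
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (j <= i) next
    g1 <- labs[i]; g2 <- labs[j]
    if (!sig[g1, g2]) next
    nxt <- list()
    for (s in sets) {
      if (all(c(g1, g2) %in% s)) {
        a <- setdiff(s, g2); b <- setdiff(s, g1)
        if (length(a)) nxt <- c(nxt, list(a))
        if (length(b)) nxt <- c(nxt, list(b))
      } else nxt <- c(nxt, list(s))
    }
    sets <- unique(nxt)
  }
  # absorb subsets
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i != j && keep[i] && keep[j] &&
        all(sets[[i]] %in% sets[[j]]) &&
        length(sets[[i]]) < length(sets[[j]])) keep[i] <- FALSE
  }
  sets <- sets[keep]
  # order classes by their highest-mean member, assign letters
  first_pos <- vapply(sets, function(s) min(match(s, labs)), 0)
  sets <- sets[order(first_pos)]
  lt <- stats::setNames(rep("", length(labs)), labs)
  for (i in seq_along(sets))
    for (g in sets[[i]]) lt[g] <- paste0(lt[g], letters[i])
  lt[rownames(sig)]
}

#' Table-style letter grid for one trait along both factorial axes
#'
#' Runs ANOVA + Duncan + compact letters independently across treatments
#' within each period (lowercase) and across periods within each
#' treatment (uppercase), reproducing the published annotation style.
#' Accepts either a long raw trait table or a mean/SE/n summary table.
#'
#' @param x Long trait table (`treatment`, `period`, `replicate`,
#'   `trait`, `value`) or a summary frame (`treatment`, `period`,
#'   `trait`, `mean`, `se`, `n`).
#' @param trait Trait name to annotate.
#' @param alpha Significance level (default 0.05).
#' @return Data frame `treatment`, `period`, `mean`, `upper`, `lower`,
#'   `label` (e.g. `"Ba"`).
#' @export
letter_matrix <- function(x, trait, alpha = 0.05) {
  d <- x[x$trait == trait, , drop = FALSE]
  if (nrow(d) == 0L) stop("trait not found: ", trait)
  raw <- "value" %in% names(d)
  trs <- unique(d$treatment); pes <- unique(d$period)
  grid <- expand.grid(treatment = trs, period = pes,
                      stringsAsFactors = FALSE)
  have <- paste(d$treatment, d$period)
  miss <- setdiff(paste(grid$treatment, grid$period), unique(have))
  if (length(miss))
    stop("missing cells for trait ", trait, ": ", paste(miss, collapse = ", "))
  groups_for <- function(sub, by) {
    if (raw) {
      g <- split(sub$value, sub[[by]])
      g[unique(sub[[by]])]
    } else {
      s <- sub[c(by, "mean", "se", "n")]
      names(s)[1L] <- "label"
      s
    }
  }
  lower <- list(); upper <- list()
  for (pe in pes) {
    g <- groups_for(d[d$period == pe, , drop = FALSE], "treatment")
    lower[[pe]] <- compact_letters(duncan_mrt(g, alpha))
  }
  for (tr in trs) {
    g <- groups_for(d[d$treatment == tr, , drop = FALSE], "period")
    upper[[tr]] <- toupper(compact_letters(duncan_mrt(g, alpha)))
  }
  mean_of <- function(tr, pe) {
    sub <- d[d$treatment == tr & d$period == pe, , drop = FALSE]
    if (raw) mean(sub$value) else sub$mean
  }
  grid$mean <- mapply(mean_of, grid$treatment, grid$period)
  grid$upper <- mapply(function(tr, pe) upper[[tr]][[pe]],
                       grid$treatment, grid$period)
  grid$lower <- mapply(function(tr, pe) lower[[pe]][[tr]],
                       grid$treatment, grid$period)
  grid$label <- paste0(grid$upper, grid$lower)
  grid
}

#' Pearson correlation matrix over traits
#'
#' Pairwise-complete Pearson correlations between trait columns of the
#' wide observation matrix, with two-sided p-values from the t transform
#' t = r * sqrt((m - 2) / (1 - r^2)). Constant traits yield `NA`
#' (undefined correlation) with a warning rather than an error.
#'
#' @param table Long trait table.
#' @param traits Optional subset of traits.
#' @return List with matrices `r`, `p` and `n` (pair counts).
#' @export
pearson_matrix <- function(table, traits = NULL) {
  wide <- trait_wide(table, traits)
  m <- as.matrix(wide[, setdiff(names(wide),
                                c("treatment", "period", "replicate")),
                      drop = FALSE])
  if (ncol(m) < 2L) stop("need at least two traits")
  if (nrow(m) < 3L) stop("need at least 3 paired observations")
  sds <- apply(m, 2L, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE))
    warning("constant trait(s): ",
            paste(colnames(m)[which(sds == 0)], collapse = ", "),
            "; correlations undefined (NA)")
  suppressWarnings(r <- stats::cor(m, use = "pairwise.complete.obs"))
  np <- crossprod(!is.na(m))
  tt <- r * sqrt(pmax(np - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), pmax(np - 2, 1))
  diag(p) <- NA_real_
  p[is.na(r)] <- NA_real_
  list(r = r, p = p, n = np)
}

#' Percent change relative to a reference
#'
#' `type = "decrease"` reports (reference - treated) / reference * 100,
#' matching the "decreased by x%" phrasing; `type = "signed"` reports
#' (treated - reference) / reference * 100, positive for increases.
#'
#' @param reference Reference (control) value, non-zero.
#' @param treated Treated value.
#' @param type `"decrease"` or `"signed"`.
#' @return Percent change, vectorized.
#' @export
percent_change <- function(reference, treated, type = c("decrease", "signed")) {
  type <- match.arg(type)
  if (any(reference == 0)) stop("reference must be non-zero")
  if (type == "decrease") (reference - treated) / reference * 100
  else (treated - reference) / reference * 100
}
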