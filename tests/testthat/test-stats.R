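test_that("one-way ANOVA matches textbook hand computation", {
  a <- anova_oneway(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 7)))
  # SSB = 26, MSB = 13, SSW = 6, MSW = 1 -> F = 13 on (2, 6)
  expect_equal(a$F, 13)
  expect_equal(c(a$df_between, a$df_within), c(2L, 6L))
  expect_equal(a$p, 0.006591797, tolerance = 1e-6)
})

test_that("ANOVA edge cases: equal means, label symmetry, zero variance", {
  eq <- anova_oneway(list(a = c(1, 2, 3), b = c(2, 1, 3), c = c(3, 2, 1)))
  expect_lt(eq$F, 1e-10)
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 7))
  expect_equal(anova_oneway(g)$F, anova_oneway(g[c(3, 1, 2)])$F)
  degen <- anova_oneway(list(a = c(1, 1), b = c(2, 2)))
  expect_identical(degen$F, Inf)
  expect_identical(degen$p, 0)
  expect_error(anova_oneway(list(a = 1:3)), "2 groups")
  expect_error(anova_oneway(list(a = 1, b = 1:3)), "at least 2 values")
})

test_that("summary-based ANOVA equals raw ANOVA on matched statistics", {
  set.seed(42)
  for (i in 1:50) {
    k <- sample(3:6, 1)
    n <- sample(3:7, 1)
    groups <- replicate(k, rnorm(n, sd = runif(1, 0.5, 3)), simplify = FALSE)
    names(groups) <- paste0("g", 1:k)
    raw <- anova_oneway(groups)
    summ <- data.frame(label = names(groups),
                       mean = sapply(groups, mean),
                       se = sapply(groups, function(g) sd(g) / sqrt(n)),
                       n = n)
    from_sum <- anova_from_summary(summ)
    expect_equal(from_sum$F, raw$F, tolerance = 1e-10)
    expect_equal(from_sum$p, raw$p, tolerance = 1e-10)
    expect_equal(from_sum$msw, raw$msw, tolerance = 1e-10)
  }
})

test_that("published summary row reconstructs the expected F", {
  # oracle: raw triples {m - SE*sqrt(3), m, m + SE*sqrt(3)} have exactly
  # the printed mean and SE
  means <- c(14.2, 13.8, 13.1, 12.6)
  ses <- c(0.1, 0.3, 0.3, 0.3)
  raw <- anova_oneway(triples_from_summary(means, ses))
  s <- data.frame(label = c("CK", "T1", "T2", "T3"), mean = means, se = ses,
                  n = 3L)
  a <- anova_from_summary(s)
  expect_equal(a$F, raw$F, tolerance = 1e-10)
  expect_equal(a$F, 7.27, tolerance = 0.01)
  expect_lt(a$p, 0.05)
  expect_identical(anova_from_summary(data.frame(mean = c(1, 1), se = c(1, 1),
                                                 n = 3L))$F, 0)
})

test_that("Duncan's test reproduces the published letter pattern", {
  an <- anatomy_reference()
  g <- an[an$trait == "Mvt" & an$period == "S2",
          c("treatment", "mean", "se", "n")]
  names(g)[1] <- "label"
  lt <- compact_letters(duncan_mrt(g))
  expect_equal(unname(lt[c("CK", "T1", "T2", "T3")]), c("a", "a", "b", "c"))
})

test_that("Duncan limit behaviors: no separation and full separation", {
  same <- duncan_mrt(list(a = c(10, 11, 12), b = c(10.1, 11, 11.9),
                          c = c(10, 11.2, 11.8)))
  expect_false(any(same$significant))
  expect_true(all(compact_letters(same) == "a"))
  far <- duncan_mrt(list(a = c(100, 101, 102), b = c(50, 51, 52),
                         c = c(1, 2, 3)))
  expect_true(all(far$significant[upper.tri(far$significant)]))
  expect_equal(unname(compact_letters(far)[c("a", "b", "c")]),
               c("a", "b", "c"))
})

test_that("Duncan sits between Tukey HSD and unadjusted LSD", {
  set.seed(7)
  for (i in 1:20) {
    k <- sample(3:5, 1)
    groups <- replicate(k, rnorm(3, mean = runif(1, 0, 4)), simplify = FALSE)
    names(groups) <- paste0("g", 1:k)
    a <- anova_oneway(groups)
    d <- duncan_mrt(groups)
    m <- a$means
    se_m <- sqrt(a$msw / 3)
    dunc <- tukey <- lsd <- 0L
    for (g1 in 1:(k - 1)) for (g2 in (g1 + 1):k) {
      diffm <- abs(m[g1] - m[g2])
      if (d$significant[g1, g2]) dunc <- dunc + 1L
      if (diffm > qtukey(0.95, k, a$df_within) * se_m) tukey <- tukey + 1L
      if (diffm > qt(0.975, a$df_within) * sqrt(2) * se_m) lsd <- lsd + 1L
    }
    expect_gte(dunc, tukey)
    expect_lte(dunc, lsd)
  }
})

test_that("compact letters: chain, overlap, and minimality", {
  chain <- matrix(TRUE, 3, 3, dimnames = list(c("a", "b", "c"),
                                              c("a", "b", "c")))
  diag(chain) <- FALSE
  expect_equal(unname(compact_letters(chain, c(a = 3, b = 2, c = 1))),
               c("a", "b", "c"))
  # 1 ~ 2, 2 ~ 3, 1 != 3 -> a, ab, b
  ov <- matrix(FALSE, 3, 3, dimnames = list(c("x", "y", "z"),
                                            c("x", "y", "z")))
  ov["x", "z"] <- ov["z", "x"] <- TRUE
  lt <- compact_letters(ov, c(x = 3, y = 2, z = 1))
  expect_equal(unname(lt), c("a", "ab", "b"))
  expect_equal(length(unique(strsplit(paste(lt, collapse = ""), "")[[1]])),
               minimal_letter_count(ov))
})

test_that("letter displays satisfy shared-letter iff non-significant", {
  set.seed(11)
  for (i in 1:20) {
    k <- sample(3:5, 1)
    groups <- replicate(k, rnorm(3, mean = runif(1, 0, 3)), simplify = FALSE)
    names(groups) <- paste0("g", 1:k)
    d <- duncan_mrt(groups)
    lt <- compact_letters(d)
    for (g1 in 1:(k - 1)) for (g2 in (g1 + 1):k) {
      shared <- length(intersect(strsplit(lt[g1], "")[[1]],
                                 strsplit(lt[g2], "")[[1]])) > 0
      expect_equal(shared, !d$significant[g1, g2])
    }
    expect_true(all(nchar(lt) >= 1))
  }
})

test_that("letter grid reproduces published lowercase letters for Mvt", {
  an <- anatomy_reference()
  g <- letter_matrix(an, "Mvt")
  s2 <- g[g$period == "S2", ]
  expect_equal(s2$lower[match(c("CK", "T1", "T2", "T3"), s2$treatment)],
               c("a", "a", "b", "c"))
  expect_true(all(grepl("^[A-D]+[a-d]+$", g$label)))
})

test_that("letter grid on zero-noise monotone data orders strictly", {
  cfg <- default_experiment_config()
  cfg$cell_means$se <- 0
  tab <- generate_trait_table(cfg, 1)
  # Chl cell means decrease strictly CK -> T3 in S3 with zero noise
  g <- letter_matrix(tab, "Chl")
  s3 <- g[g$period == "S3", ]
  expect_equal(s3$lower[match(c("CK", "T1", "T2", "T3"), s3$treatment)],
               c("a", "b", "c", "d"))
})

test_that("letter grid is equivariant under label shuffling", {
  an <- anatomy_reference()
  g0 <- letter_matrix(an, "Xt")
  swapped <- an
  swapped$treatment[an$treatment == "CK"] <- "T3"
  swapped$treatment[an$treatment == "T3"] <- "CK"
  g1 <- letter_matrix(swapped, "Xt")
  for (pe in c("S1", "S2", "S3", "S4")) {
    expect_equal(sort(g0$lower[g0$period == pe]),
                 sort(g1$lower[g1$period == pe]))
    expect_equal(g0$lower[g0$period == pe & g0$treatment == "CK"],
                 g1$lower[g1$period == pe & g1$treatment == "T3"])
  }
})

test_that("pearson matrix: trivial values and affine invariance", {
  tab <- expand.grid(treatment = c("CK", "T1"), period = c("S1", "S2"),
                     replicate = 1:3, stringsAsFactors = FALSE)
  n <- nrow(tab)
  set.seed(3)
  x <- rnorm(n)
  long <- rbind(
    cbind(tab, trait = "x", value = x),
    cbind(tab, trait = "negx", value = -x),
    cbind(tab, trait = "z", value = rnorm(n))
  )
  pm <- pearson_matrix(long)
  expect_equal(unname(diag(pm$r)), rep(1, 3))
  expect_equal(pm$r["x", "negx"], -1)
  long2 <- long
  long2$value[long2$trait == "z"] <- 5 + 2 * long2$value[long2$trait == "z"]
  pm2 <- pearson_matrix(long2)
  expect_equal(pm2$r, pm$r, tolerance = 1e-12)
  # constant trait: undefined marker, not an error
  long3 <- long
  long3$value[long3$trait == "z"] <- 1
  expect_warning(pm3 <- pearson_matrix(long3), "constant")
  expect_true(is.na(pm3$r["x", "z"]))
})

test_that("percent change follows the reporting conventions", {
  expect_equal(percent_change(20, 20), 0)
  expect_equal(percent_change(20, 15), 25)
  expect_equal(percent_change(100, 175.7, type = "signed"), 75.7)
  expect_error(percent_change(0, 1), "non-zero")
})
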