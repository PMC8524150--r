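test_that("independent-samples t-tests match closed-form computation", {
  tt <- tTest(c(1, 2, 3), c(2, 3, 4), "student")
  expect_equal(tt$statistic, -1 / sqrt(2 / 3), tolerance = 1e-9)  # -1.2247
  expect_equal(tt$df, 4)
  expect_equal(tt$mean_diff, -1)

  set.seed(1)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(tTest(a, b, "student")$df, 38)
  expect_lte(tTest(a, b, "welch")$df, 38)

  same <- rep(3, 5)
  z <- tTest(same, same, "student")
  expect_equal(z$statistic, 0); expect_equal(z$p.value, 1)
})

test_that("Student and Welch agree for equal variances and equal n", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 3, 4, 5, 6)  # same spread, shifted
  s <- tTest(x, y, "student"); w <- tTest(x, y, "welch")
  expect_equal(s$statistic, w$statistic, tolerance = 1e-9)
  expect_equal(s$p.value, w$p.value, tolerance = 1e-9)
  expect_equal(s$df, w$df, tolerance = 1e-9)
})

test_that("Bonferroni alphas reproduce the two study families", {
  expect_equal(bonferroniAlpha(0.05, 4), 0.0125)
  expect_equal(round(bonferroniAlpha(0.05, 3), 4), 0.0167)
  expect_equal(bonferroniAlpha(0.05, 1), 0.05)
  expect_error(bonferroniAlpha(0.05, 0), "m must be")
})

test_that("mixed ANOVA reports the classical uncorrected dfs", {
  # 2 within-levels x 2 groups of 20 -> interaction df (1, 38)
  set.seed(2)
  d <- expand.grid(subject = 1:40, condition = c("SCD0", "SCD300"))
  d$species <- ifelse(d$subject <= 20, "pigeon", "human")
  d$rt2 <- rnorm(nrow(d), 800)
  a <- mixedAnova(d, "rt2", "subject", "condition", "species")
  e <- a$effects
  expect_equal(e$df_num[e$effect == "interaction"], 1)
  expect_equal(e$df_den[e$effect == "interaction"], 38)
  expect_equal(e$df_den[e$effect == "between"], 38)

  # 4 within-levels x 3 groups of 6/6/8 -> (3,51), (6,51), (2,17)
  subj <- sprintf("P%02d", 1:20)
  grp <- rep(c("GO", "STOP", "SC"), c(6, 6, 8))
  d2 <- expand.grid(subject = subj, area = c("CPi", "NMm", "NIML", "MM"))
  d2$group <- grp[match(d2$subject, subj)]
  d2$y <- rnorm(nrow(d2), 1000, 200)
  a2 <- mixedAnova(d2, "y", "subject", "area", "group")$effects
  expect_equal(unlist(a2[a2$effect == "within", c("df_num", "df_den")]),
               c(df_num = 3, df_den = 51))
  expect_equal(unlist(a2[a2$effect == "interaction", c("df_num", "df_den")]),
               c(df_num = 6, df_den = 51))
  expect_equal(unlist(a2[a2$effect == "between", c("df_num", "df_den")]),
               c(df_num = 2, df_den = 17))
  expect_true(all(a2$partial_eta_sq >= 0 & a2$partial_eta_sq <= 1))
})

test_that("the SS partition sums to the total on balanced data", {
  set.seed(3)
  d <- expand.grid(subject = 1:12, w = c("a", "b", "c"))
  d$g <- ifelse(d$subject <= 6, "g1", "g2")
  d$y <- rnorm(nrow(d), 10, 2)
  a <- mixedAnova(d, "y", "subject", "w", "g")
  ss_total <- sum((d$y - mean(d$y))^2)
  expect_equal(sum(a$ss$ss), ss_total, tolerance = 1e-8)
})

test_that("a constructed null interaction yields F ~ 0", {
  # group 2 duplicates group 1's subjects, so cell means are identical in
  # both groups: interaction SS is exactly zero, residual is not
  set.seed(10)
  base <- matrix(rnorm(12, 100, 10), nrow = 6)  # 6 subjects x 2 conditions
  d <- expand.grid(subject = 1:12, w = c("a", "b"))
  d$g <- ifelse(d$subject <= 6, "g1", "g2")
  d$y <- base[cbind((d$subject - 1) %% 6 + 1, as.integer(factor(d$w)))]
  a <- mixedAnova(d, "y", "subject", "w", "g")
  expect_lt(a$effects$F[a$effects$effect == "interaction"], 1e-20)
})

test_that("mixed ANOVA rejects incomplete within-subject data", {
  d <- expand.grid(subject = 1:6, w = c("a", "b"))
  d$g <- ifelse(d$subject <= 3, "g1", "g2")
  d$y <- rnorm(12)
  expect_error(mixedAnova(d[-1, ], "y", "subject", "w", "g"),
               "exactly one observation")
})

test_that("Greenhouse-Geisser epsilon is a valid correction factor", {
  set.seed(4)
  d <- expand.grid(subject = 1:16, w = c("a", "b", "c", "d"))
  d$g <- ifelse(d$subject <= 8, "g1", "g2")
  d$y <- rnorm(nrow(d))
  a <- mixedAnova(d, "y", "subject", "w", "g", sphericity_correction = "GG")
  eps <- a$gg_epsilon
  expect_gte(eps, 1 / 3); expect_lte(eps, 1)
  e <- a$effects
  expect_equal(e$df_num[e$effect == "within"], 3 * eps, tolerance = 1e-9)
})

test_that("pairwise comparisons are Bonferroni-multiplied and capped", {
  set.seed(5)
  d <- expand.grid(subject = 1:12, w = c("a", "b"))
  d$g <- rep(c("g1", "g2", "g3"), 4)[d$subject]
  d$y <- rnorm(nrow(d))
  pw <- pairwiseBonferroni(d, "y", "subject", "w", "g")
  expect_equal(nrow(pw), 6)  # 3 pairs x 2 within levels
  expect_true(all(pw$p_bonferroni <= 1))
  expect_equal(pw$p_bonferroni, pmin(pw$p_uncorrected * 3, 1))
  expect_true(all(pw$p_display[pw$p_bonferroni > 0.999] == "> 0.999"))
})

test_that("Spearman rho and exact p behave on the canonical cases", {
  expect_equal(spearmanTest(1:5, c(2, 4, 6, 7, 9))$rho, 1)
  expect_equal(spearmanTest(1:5, 5:1)$rho, -1)
  r3 <- spearmanTest(1:3, c(10, 20, 30))
  expect_equal(r3$p.value, 2 / 6)
  expect_equal(r3$method, "exact")
  expect_warning(rc <- spearmanTest(rep(1, 4), 1:4), "constant")
  expect_true(is.na(rc$rho))
})

test_that("exact Spearman p matches brute-force enumeration", {
  # independent brute force: all distinct n-tuples via expand.grid
  bruteP <- function(x, y) {
    n <- length(x)
    rx <- rank(x); ry <- rank(y)
    rho <- cor(rx, ry)
    grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
    ok <- rep(TRUE, nrow(grid))
    for (v in seq_len(n)) ok <- ok & (rowSums(grid == v) == 1L)
    perms <- grid[ok, , drop = FALSE]
    null_rho <- apply(perms, 1, function(p) cor(rx, ry[p]))
    mean(abs(null_rho) >= abs(rho) - 1e-12)
  }
  set.seed(6)
  for (n in 4:6) {
    x <- sample(100, n); y <- sample(100, n)
    expect_equal(spearmanTest(x, y)$p.value, bruteP(x, y))
  }
  # and against the library's exact algorithm at n = 7
  x <- sample(100, 7); y <- sample(100, 7)
  ref <- cor.test(x, y, method = "spearman")
  got <- spearmanTest(x, y)
  expect_equal(got$rho, unname(ref$estimate))
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  set.seed(7)
  x <- rnorm(15); y <- rnorm(15)
  base <- spearmanTest(x, y)$rho
  expect_equal(spearmanTest(exp(x), y)$rho, base)
  expect_equal(spearmanTest(x, y^3 + 5 * y)$rho, base)
})

test_that("the BIC Bayes factor obeys its closed form and reciprocity", {
  expect_equal(bf01Bic(100, 100)$bf01, 1)
  expect_equal(bf01Bic(100, 102)$bf01, exp(1))
  a <- runif(1, 50, 150); b <- runif(1, 50, 150)
  expect_equal(bf01Bic(a, b)$bf01 * bf01Bic(b, a)$bf01, 1, tolerance = 1e-12)
})

test_that("null 2x2 data favour the no-interaction model on average", {
  set.seed(8)
  wins <- 0
  for (i in 1:40) {
    d <- expand.grid(subject = 1:20, w = c("a", "b"))
    d$g <- ifelse(d$subject <= 10, "g1", "g2")
    d$y <- rnorm(nrow(d), 100, 10) + 5 * (d$w == "b")
    bf <- interactionBF01(d, "y", "subject", "w", "g")
    wins <- wins + (bf$bf01 > 1)
  }
  expect_gt(wins / 40, 0.7)
})
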