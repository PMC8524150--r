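## Inferential layer: t-tests, mixed-design RM-ANOVA with partial eta^2,
## Spearman correlation with exact small-n p, BIC-approximate Bayes factor.

#' Independent-samples t-test
#'
#' Student (pooled variance, df = n_a + n_b - 2) or Welch (Satterthwaite
#' df) two-sided test, via [stats::t.test()]. Two constant samples with
#' equal means return t = 0, p = 1 instead of an error.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param variant `"student"` or `"welch"`.
#' @return List of class `"sc_ttest"`: `statistic`, `df`, `p.value`,
#'   `mean_diff`, `variant`.
#' @examples
#' tTest(c(1, 2, 3), c(2, 3, 4), "student")  # t = -1.225, df = 4
#' @export
tTest <- function(a, b, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
    res <- list(statistic = 0, df = length(a) + length(b) - 2, p.value = 1,
                mean_diff = 0, variant = variant)
    class(res) <- "sc_ttest"
    return(res)
  }
  ht <- t.test(a, b, var.equal = (variant == "student"))
  res <- list(statistic = unname(ht$statistic), df = unname(ht$parameter),
              p.value = ht$p.value, mean_diff = mean(a) - mean(b),
              variant = variant)
  class(res) <- "sc_ttest"
  res
}

#' @export
print.sc_ttest <- function(x, ...) {
  cat(sprintf("%s t-test: t(%s) = %.3f, p = %.4g, mean diff = %.3f\n",
              x$variant, format(round(x$df, 3)), x$statistic, x$p.value,
              x$mean_diff))
  invisible(x)
}

#' Bonferroni-adjusted alpha level
#'
#' @param alpha Family-wise alpha (default 0.05).
#' @param m Number of comparisons in the family.
#' @return `alpha / m` (e.g. 0.0125 for the four behavioral contrasts,
#'   0.0167 for the three slope correlations).
#' @examples
#' bonferroniAlpha(0.05, 4)  # 0.0125
#' @export
bonferroniAlpha <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Mixed-design repeated-measures ANOVA
#'
#' Classical univariate mixed-model analysis with one within-subject and
#' one between-subject factor, fitted via [stats::aov()] with an
#' `Error(subject)` stratum: the between effect is tested against the
#' subjects-within-groups error, the within effect and the interaction
#' against the subject-by-within residual. Reports uncorrected degrees of
#' freedom by default (Greenhouse-Geisser epsilon is computed and can be
#' applied on request) and partial eta squared
#' `SS_effect / (SS_effect + SS_error)` per effect.
#'
#' @param data Long-format data.frame.
#' @param dv,subject,within,between Column names.
#' @param sphericity_correction `"none"` (default) or `"GG"`.
#' @return List of class `"sc_anova"`: `effects` (data.frame with `effect`,
#'   `F`, `df_num`, `df_den`, `p`, `partial_eta_sq`), `ss` (full SS table),
#'   `gg_epsilon`, `design`.
#' @export
mixedAnova <- function(data, dv, subject, within, between,
                       sphericity_correction = c("none", "GG")) {
  sphericity_correction <- match.arg(sphericity_correction)
  d <- data.frame(y = data[[dv]],
                  subj = factor(data[[subject]]),
                  w = factor(data[[within]]),
                  b = factor(data[[between]]))
  if (any(is.na(d$y))) stop("missing values in the dependent variable")
  tab <- table(d$subj, d$w)
  if (any(tab[rowSums(tab) > 0, ] != 1))
    stop("each subject needs exactly one observation per within level")
  if (any(table(unique(d[c("subj", "b")])$b) < 2))
    stop("need >= 2 subjects per between group")

  fit <- aov(y ~ b * w + Error(subj), data = d)
  sm <- summary(fit)
  btab <- as.data.frame(sm[["Error: subj"]][[1]])
  wtab <- as.data.frame(sm[["Error: Within"]][[1]])
  rn <- function(tb) trimws(rownames(tb))
  ss_err_b <- btab[rn(btab) == "Residuals", "Sum Sq"]
  ss_err_w <- wtab[rn(wtab) == "Residuals", "Sum Sq"]

  nlev <- nlevels(d$w)
  eps <- ggEpsilon(d)
  adj <- if (sphericity_correction == "GG") eps else 1

  mk <- function(tb, name, label, err_ss, err_df, scale_df = 1) {
    row <- tb[rn(tb) == name, , drop = FALSE]
    Fv <- row[["F value"]]
    df1 <- row[["Df"]] * scale_df
    df2 <- err_df * scale_df
    data.frame(effect = label, F = Fv, df_num = df1, df_den = df2,
               p = pf(Fv, df1, df2, lower.tail = FALSE),
               partial_eta_sq = row[["Sum Sq"]] / (row[["Sum Sq"]] + err_ss),
               stringsAsFactors = FALSE)
  }
  err_df_b <- btab[rn(btab) == "Residuals", "Df"]
  err_df_w <- wtab[rn(wtab) == "Residuals", "Df"]
  effects <- rbind(
    mk(btab, "b", "between", ss_err_b, err_df_b),
    mk(wtab, "w", "within", ss_err_w, err_df_w, adj),
    mk(wtab, "b:w", "interaction", ss_err_w, err_df_w, adj))

  ss <- rbind(
    data.frame(source = "between", ss = btab[rn(btab) == "b", "Sum Sq"],
               df = btab[rn(btab) == "b", "Df"]),
    data.frame(source = "subjects_within_groups", ss = ss_err_b, df = err_df_b),
    data.frame(source = "within", ss = wtab[rn(wtab) == "w", "Sum Sq"],
               df = wtab[rn(wtab) == "w", "Df"]),
    data.frame(source = "interaction", ss = wtab[rn(wtab) == "b:w", "Sum Sq"],
               df = wtab[rn(wtab) == "b:w", "Df"]),
    data.frame(source = "within_error", ss = ss_err_w, df = err_df_w))

  res <- list(effects = effects, ss = ss, gg_epsilon = eps,
              design = sprintf("%d within-levels x %d groups (N = %d)",
                               nlev, nlevels(d$b), nlevels(d$subj)))
  class(res) <- "sc_anova"
  res
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of
# the within-subject measures.
ggEpsilon <- function(d) {
  k <- nlevels(d$w)
  if (k < 3) return(1)
  wide <- tapply(d$y, list(d$subj, d$w), mean)
  groups <- tapply(as.character(d$b), d$subj, `[`, 1)[rownames(wide)]
  covs <- lapply(split(seq_len(nrow(wide)), groups), function(ix) {
    if (length(ix) < 2) return(NULL)
    (length(ix) - 1) * cov(wide[ix, , drop = FALSE])
  })
  covs <- covs[!vapply(covs, is.null, logical(1))]
  S <- Reduce(`+`, covs) / (nrow(wide) - length(covs))
  sbar <- mean(diag(S))
  mbar <- mean(S)
  num <- (k * (sbar - mbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * mbar^2)
  max(min(num / den, 1), 1 / (k - 1))
}

#' @export
print.sc_anova <- function(x, ...) {
  cat("Mixed-design repeated-measures ANOVA:", x$design, "\n")
  e <- x$effects
  for (i in seq_len(nrow(e)))
    cat(sprintf("  %-11s F(%g, %g) = %.3f, p = %.4g, pes = %.3f\n",
                e$effect[i], e$df_num[i], e$df_den[i], e$F[i], e$p[i],
                e$partial_eta_sq[i]))
  invisible(x)
}

#' Bonferroni-corrected pairwise group comparisons per within level
#'
#' For each level of the within factor, compares every pair of between
#' groups with a Student t-test and multiplies each p-value by the number
#' of comparisons in that family (pairs per level), capped at 1; capped
#' values display as "> 0.999".
#'
#' @inheritParams mixedAnova
#' @return data.frame: `within_level`, `group_a`, `group_b`, `mean_diff`,
#'   `t`, `df`, `p_uncorrected`, `p_bonferroni`, `p_display`.
#' @export
pairwiseBonferroni <- function(data, dv, subject, within, between) {
  d <- data.frame(y = data[[dv]], w = factor(data[[within]]),
                  b = factor(data[[between]]))
  out <- do.call(rbind, lapply(levels(d$w), function(wl) {
    dl <- d[d$w == wl, ]
    gs <- levels(d$b)
    pairs <- utils::combn(gs, 2)
    m <- ncol(pairs)
    do.call(rbind, lapply(seq_len(m), function(j) {
      a <- dl$y[dl$b == pairs[1, j]]
      b <- dl$y[dl$b == pairs[2, j]]
      tt <- tTest(a, b, "student")
      padj <- min(tt$p.value * m, 1)
      data.frame(within_level = wl, group_a = pairs[1, j],
                 group_b = pairs[2, j], mean_diff = tt$mean_diff,
                 t = tt$statistic, df = tt$df,
                 p_uncorrected = tt$p.value, p_bonferroni = padj,
                 p_display = if (padj > 0.999) "> 0.999"
                             else sprintf("%.3f", padj),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

permutationsOf <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutationsOf(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rho is the Pearson correlation of the (average-tie) ranks. For n <= 9
#' and untied data the two-sided p-value is exact, from full enumeration
#' of the n! rank permutations; otherwise the t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` is used. A constant input
#' yields an undefined rho with a warning.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return List of class `"sc_spearman"`: `rho`, `p.value`, `n`, `method`.
#' @examples
#' spearmanTest(1:3, c(10, 20, 30))  # rho = 1, exact p = 1/3
#' @export
spearmanTest <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  n <- length(x)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input: Spearman rho undefined")
    res <- list(rho = NA_real_, p.value = NA_real_, n = n, method = "undefined")
    class(res) <- "sc_spearman"
    return(res)
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  ties <- anyDuplicated(rx) > 0 || anyDuplicated(ry) > 0
  if (n <= 9 && !ties) {
    perms <- permutationsOf(n)
    null_rho <- apply(perms, 1, function(p) cor(rx, ry[p]))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(2 * pt(abs(tstat), n - 2, lower.tail = FALSE), 1)
    method <- "asymptotic"
  }
  res <- list(rho = rho, p.value = p, n = n, method = method)
  class(res) <- "sc_spearman"
  res
}

#' @export
print.sc_spearman <- function(x, ...) {
  cat(sprintf("Spearman correlation: rho = %.3f, p = %.4g (n = %d, %s)\n",
              x$rho, x$p.value, x$n, x$method))
  invisible(x)
}

#' BIC-approximate Bayes factor for the null
#'
#' `BF01 = exp((BIC_alt - BIC_null) / 2)`, the unit-information-prior
#' approximation to the Bayes factor favouring the null (simpler) model
#' over the alternative; values above 1 favour the null and
#' `BF01 * BF10 = 1` holds by construction.
#'
#' @param bic_null,bic_alt BIC values of the nested null and alternative
#'   models fit to the same data.
#' @return List of class `"sc_bf"`: `bf01`, `bic_null`, `bic_alt`,
#'   `method`.
#' @examples
#' bf01Bic(100, 102)$bf01  # e = 2.718...
#' @export
bf01Bic <- function(bic_null, bic_alt) {
  res <- list(bf01 = exp((bic_alt - bic_null) / 2),
              bic_null = bic_null, bic_alt = bic_alt,
              method = "BIC approximation (unit-information prior)")
  class(res) <- "sc_bf"
  res
}

#' @export
print.sc_bf <- function(x, ...) {
  cat(sprintf("BF01 = %.4f (%s)\n", x$bf01, x$method))
  invisible(x)
}

#' Bayes factor for the absence of the group-by-condition interaction
#'
#' Fits the mixed design with and without the interaction term as
#' maximum-likelihood linear mixed models (random subject intercept) and
#' converts the BIC difference into BF01 via [bf01Bic()].
#'
#' @inheritParams mixedAnova
#' @return An `"sc_bf"` result (see [bf01Bic()]).
#' @export
interactionBF01 <- function(data, dv, subject, within, between) {
  d <- data.frame(y = data[[dv]], subj = factor(data[[subject]]),
                  w = factor(data[[within]]), b = factor(data[[between]]))
  # singular random-intercept fits (variance ~ 0) are expected for some
  # inputs and do not invalidate the BIC comparison; keep them quiet
  full <- suppressMessages(
    lme4::lmer(y ~ b * w + (1 | subj), data = d, REML = FALSE))
  null <- suppressMessages(
    lme4::lmer(y ~ b + w + (1 | subj), data = d, REML = FALSE))
  bf01Bic(stats::BIC(null), stats::BIC(full))
}
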