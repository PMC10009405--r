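#' Nonparametric group comparison
#'
#' Chooses the test by the field's standard rule: two groups of a
#' continuous variable are compared with the Mann-Whitney U test
#' (tie-corrected; exact enumeration for small untied samples, normal
#' approximation with continuity correction otherwise), three or more
#' groups with the Kruskal-Wallis H test; categorical variables use
#' Fisher's exact test for two groups and the chi-squared test otherwise.
#' All p values are two-sided.
#'
#' @param values numeric vector (continuous) or vector/factor (categorical)
#' @param labels group factor, same length as `values`
#' @param type `"continuous"` or `"categorical"`; `"auto"` treats numeric
#'   input as continuous
#' @param categorical_test override for categorical data: `"auto"`
#'   (Fisher for 2 groups, chi-squared otherwise), `"fisher"` or
#'   `"chi_squared"`
#' @return list with `variable`, `groups`, `test`, `statistic`, `p_value`,
#'   `n`
#' @export
#' @examples
#' compareGroups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
compareGroups <- function(values, labels,
                          type = c("auto", "continuous", "categorical"),
                          categorical_test = c("auto", "fisher",
                                               "chi_squared")) {
  type <- match.arg(type)
  categorical_test <- match.arg(categorical_test)
  labels <- factor(labels)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- droplevels(labels[keep])
  g <- levels(labels)
  if (length(g) < 2L) stop("need >= 2 groups")
  if (type == "auto")
    type <- if (is.numeric(values)) "continuous" else "categorical"

  if (type == "continuous") {
    sizes <- table(labels)
    if (any(sizes < 2L))
      stop("rank tests need >= 2 observations per group (got ",
           paste(sizes, collapse = ", "), ")")
    if (stats::var(values) == 0)
      stop("constant variable: rank tests undefined")
    if (length(g) == 2L) {
      ht <- suppressWarnings(
        stats::wilcox.test(values[labels == g[1]], values[labels == g[2]],
                           correct = TRUE))
      test <- "mann_whitney_u"
      statistic <- unname(ht$statistic)
    } else {
      ht <- stats::kruskal.test(values, labels)
      test <- "kruskal_wallis_h"
      statistic <- unname(ht$statistic)
    }
  } else {
    tab <- table(values, labels)
    if (categorical_test == "auto")
      categorical_test <- if (length(g) == 2L) "fisher" else "chi_squared"
    if (categorical_test == "fisher") {
      ht <- stats::fisher.test(tab)
      test <- "fisher_exact"
      statistic <- NA_real_
    } else {
      ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      if (any(ht$expected < 5))
        message("chi-squared: some expected cell counts are below 5")
      test <- "chi_squared"
      statistic <- unname(ht$statistic)
    }
  }
  list(variable = deparse1(substitute(values)), groups = g, test = test,
       statistic = statistic, p_value = unname(ht$p.value),
       n = length(values))
}

#' Bonferroni-adjusted post-hoc pairwise U tests after a 3-group omnibus
#'
#' Runs the three pairwise Mann-Whitney U tests and declares significance
#' at the family alpha divided by the number of comparisons; for the
#' default family alpha of 0.05 across three groups the adjusted threshold
#' is 0.0167 (to 4 dp).
#'
#' @param values numeric vector
#' @param labels factor with exactly 3 levels
#' @param family_alpha family-wise alpha (default 0.05)
#' @return list with `adjusted_alpha` and `pairs`, a data.frame of the
#'   three comparisons (`group1`, `group2`, `U`, `p_value`, `significant`)
#' @export
posthocPairwise <- function(values, labels, family_alpha = 0.05) {
  labels <- factor(labels)
  g <- levels(droplevels(labels))
  if (length(g) != 3L)
    stop("post-hoc pairwise tests require exactly 3 groups, got ",
         length(g))
  alpha <- round(family_alpha / 3, 4)
  combos <- utils::combn(g, 2)
  pairs <- do.call(rbind, lapply(seq_len(ncol(combos)), function(i) {
    a <- combos[1, i]; b <- combos[2, i]
    ht <- suppressWarnings(
      stats::wilcox.test(values[labels == a], values[labels == b],
                         correct = TRUE))
    data.frame(group1 = a, group2 = b, U = unname(ht$statistic),
               p_value = unname(ht$p.value),
               significant = unname(ht$p.value) < alpha,
               stringsAsFactors = FALSE)
  }))
  list(adjusted_alpha = alpha, pairs = pairs)
}

#' Spearman rank correlation
#'
#' Tie-corrected rank correlation with a two-sided p value from the
#' t approximation (the convention for samples with ties).
#'
#' @param x,y paired numeric vectors, n >= 4
#' @return list with `rho`, `p_value`, `n`
#' @export
#' @examples
#' spearmanCor(1:10, (1:10)^3)$rho  # 1: invariant to monotone transforms
spearmanCor <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L) stop("need >= 4 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("constant input: rank correlation undefined")
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ht$estimate), p_value = unname(ht$p.value),
       n = length(x))
}

residualize <- function(v, Z) {
  fit <- stats::lm.fit(Z, v)
  fit$residuals
}

#' Covariate-adjusted partial correlation
#'
#' Correlation of `x` and `y` after linear removal of the covariates
#' (Pearson on the two OLS residual vectors). The p value uses the
#' t transform with `df = n - k - 2` where k is the number of covariates.
#' A rank-based variant first replaces `x`, `y` and every covariate column
#' by midranks and then residualizes, for a Spearman-flavoured partial
#' correlation.
#'
#' @param x,y numeric vectors
#' @param covariates numeric matrix or data.frame of nuisance variables
#'   (an intercept is always added)
#' @param method `"pearson"` (default) or `"spearman"` (residualized
#'   midranks)
#' @return list with `r_partial`, `p_value`, `df`, `n`
#' @export
partialCorrelation <- function(x, y, covariates,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  Zdf <- as.data.frame(covariates)
  for (nm in names(Zdf)) {
    if (!is.numeric(Zdf[[nm]])) {
      f <- factor(Zdf[[nm]])
      if (nlevels(f) != 2L)
        stop("covariate '", nm, "' is categorical with ", nlevels(f),
             " levels; only binary coding is supported")
      Zdf[[nm]] <- as.numeric(f) - 1
    }
  }
  Zc <- as.matrix(Zdf)
  storage.mode(Zc) <- "double"
  n <- length(x)
  k <- ncol(Zc)
  stopifnot(length(y) == n, nrow(Zc) == n)
  if (n <= k + 2L)
    stop("need n > number of covariates + 2 (n = ", n, ", k = ", k, ")")
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
    Zc <- apply(Zc, 2L, rank)
  }
  Z <- cbind(`(intercept)` = 1, Zc)
  qrZ <- qr(Z)
  if (qrZ$rank < ncol(Z)) {
    bad <- colnames(Z)[qrZ$pivot[seq(qrZ$rank + 1L, ncol(Z))]]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  rx <- qr.resid(qrZ, x)
  ry <- qr.resid(qrZ, y)
  # a variable fully explained by the covariates has nothing left to
  # correlate: its residual is numerical noise, so r is 0 by convention
  degenerate <- function(res, orig)
    sqrt(mean(res^2)) < 1e-10 * max(sqrt(mean(orig^2)), 1)
  r <- if (degenerate(rx, x) || degenerate(ry, y)) 0
       else stats::cor(rx, ry)
  df <- n - k - 2L
  tstat <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(r_partial = unname(r), p_value = unname(p), df = df, n = n)
}

#' Tidy group-comparison report over many variables
#'
#' Runs [compareGroups()] on each named variable of a cohort table and,
#' for 3-group comparisons of continuous variables, appends the
#' Bonferroni-adjusted post-hoc pairwise U tests.
#'
#' @param data cohort data.frame
#' @param variables character, column names to compare
#' @param group_col grouping column name (default `"group"`)
#' @param family_alpha family alpha for post-hoc adjustment
#' @return data.frame with one row per variable (plus post-hoc rows),
#'   columns `variable`, `comparison`, `test`, `statistic`, `p_value`,
#'   `adjusted_alpha`, `significant`
#' @export
groupComparisonReport <- function(data, variables, group_col = "group",
                                  family_alpha = 0.05) {
  labels <- factor(data[[group_col]])
  n_groups <- nlevels(droplevels(labels))
  rows <- list()
  for (v in variables) {
    vals <- data[[v]]
    cmp <- compareGroups(vals, labels)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, comparison = "omnibus", test = cmp$test,
      statistic = cmp$statistic, p_value = cmp$p_value,
      adjusted_alpha = family_alpha,
      significant = cmp$p_value < family_alpha, stringsAsFactors = FALSE)
    if (n_groups == 3L && is.numeric(vals) &&
        cmp$p_value < family_alpha) {
      ph <- posthocPairwise(vals, labels, family_alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v,
        comparison = paste(ph$pairs$group1, "vs", ph$pairs$group2),
        test = "mann_whitney_u", statistic = ph$pairs$U,
        p_value = ph$pairs$p_value, adjusted_alpha = ph$adjusted_alpha,
        significant = ph$pairs$significant, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
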