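test_that("Mann-Whitney U matches enumeration and handles ties symmetrically", {
  # identical samples: U sits at its null mean under midrank ties
  cmp <- compareGroups(c(rep(1, 5), rep(1, 5)) + rep(c(0, 0), each = 5) +
                         c(1:5, 1:5) * 0.1,
                       rep(c("a", "b"), each = 5))
  expect_equal(cmp$statistic, 5 * 5 / 2)
  expect_gt(cmp$p_value, 0.99)
  # exhaustive-enumeration oracle on a separable pair
  cmp2 <- compareGroups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  want <- oracle_u_exact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp2$statistic, want$U)
  expect_equal(cmp2$p_value, want$p)
  expect_equal(cmp2$test, "mann_whitney_u")
  # random small samples also match the enumeration oracle exactly
  set.seed(31)
  for (i in 1:10) {
    x <- round(rnorm(4), 2); y <- round(rnorm(5), 2)
    got <- compareGroups(c(x, y), rep(c("a", "b"), c(4, 5)))
    expect_equal(got$statistic, oracle_u_exact(x, y)$U)
  }
})

test_that("test selection follows the group-count rules", {
  set.seed(12)
  v <- rnorm(30)
  g3 <- rep(c("a", "b", "c"), each = 10)
  expect_equal(compareGroups(v, g3)$test, "kruskal_wallis_h")
  sex <- rep(c("m", "f"), 15)
  expect_equal(compareGroups(sex, rep(c("a", "b"), each = 15),
                             type = "categorical")$test, "fisher_exact")
  expect_equal(compareGroups(sex, g3, type = "categorical")$test,
               "chi_squared")
  expect_equal(compareGroups(sex, rep(c("a", "b"), each = 15),
                             type = "categorical",
                             categorical_test = "chi_squared")$test,
               "chi_squared")
  expect_error(compareGroups(c(1, 2, 3), c("a", "a", "b")), ">= 2 obs")
  expect_error(compareGroups(rep(1, 10), rep(c("a", "b"), 5)), "constant")
})

test_that("the study's sex imbalance (18/30 vs 20/63 women) is significant", {
  sex <- c(rep("female", 18), rep("male", 12),
           rep("female", 20), rep("male", 43))
  grp <- rep(c("control", "pd"), c(30, 63))
  cmp <- compareGroups(sex, grp, type = "categorical")
  expect_equal(cmp$test, "fisher_exact")
  expect_lt(cmp$p_value, 0.05)
  expect_equal(round(cmp$p_value, 3), 0.013)
})

test_that("post-hoc U tests use the Bonferroni-adjusted threshold", {
  expect_equal(posthocPairwise(rnorm(30), rep(c("a", "b", "c"), 10),
                               family_alpha = 0.05)$adjusted_alpha, 0.0167)
  expect_equal(posthocPairwise(rnorm(30), rep(c("a", "b", "c"), 10),
                               family_alpha = 0.03)$adjusted_alpha, 0.01)
  expect_error(posthocPairwise(rnorm(20), rep(c("a", "b"), 10)),
               "exactly 3 groups")
  ph <- posthocPairwise(c(rnorm(10), rnorm(10, 5), rnorm(10, 10)),
                        rep(c("a", "b", "c"), each = 10))
  expect_equal(nrow(ph$pairs), 3)
  expect_true(all(ph$pairs$significant))
})

test_that("post-hoc family-wise error is controlled under the null", {
  set.seed(77)
  g <- rep(c("a", "b", "c"), each = 15)
  hits <- vapply(1:400, function(i) {
    ph <- posthocPairwise(rnorm(45), g)
    any(ph$pairs$significant)
  }, logical(1))
  mc_se <- sqrt(0.05 * 0.95 / 400)
  expect_lte(mean(hits), 0.05 + 2 * mc_se)
})

test_that("Spearman correlation is monotone-invariant and midrank-exact", {
  expect_equal(spearmanCor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearmanCor(1:10, -(1:10))$rho, -1)
  set.seed(14)
  x <- sample(1:5, 10, TRUE); y <- sample(1:5, 10, TRUE)  # ties likely
  got <- spearmanCor(x, y)
  expect_equal(got$rho, cor(rank(x), rank(y)))  # Pearson of midranks
  expect_error(spearmanCor(rep(1, 10), 1:10), "constant")
  expect_error(spearmanCor(1:3, 1:3), ">= 4")
})

test_that("partial correlation equals Pearson on independent OLS residuals", {
  set.seed(15)
  n <- 40
  Z <- data.frame(age = runif(n, 55, 80), updrs3 = rnorm(n, 30, 8))
  x <- rnorm(n) + 0.5 * Z$age / 10
  y <- rnorm(n) + 0.3 * Z$updrs3 / 10
  got <- partialCorrelation(x, y, Z)
  rx <- resid(lm(x ~ age + updrs3, data = Z))
  ry <- resid(lm(y ~ age + updrs3, data = Z))
  expect_equal(got$r_partial, cor(rx, ry))
  expect_equal(got$df, n - 2 - 2)
  r <- got$r_partial
  expect_equal(got$p_value,
               2 * pt(-abs(r * sqrt(got$df) / sqrt(1 - r^2)), got$df))
  # covariates orthogonal to x and y leave the simple correlation intact
  Zo <- data.frame(c1 = rep(c(-1, 1), n / 2))
  x2 <- rnorm(n); y2 <- rnorm(n)
  x2 <- resid(lm(x2 ~ Zo$c1)); y2 <- resid(lm(y2 ~ Zo$c1))
  expect_equal(partialCorrelation(x2, y2, Zo)$r_partial, cor(x2, y2),
               tolerance = 1e-10)
  # y identical to a covariate partials out to ~0
  expect_lt(abs(partialCorrelation(x, Z$age, Z)$r_partial), 1e-6)
  # collinear covariates are named in the error
  Zbad <- data.frame(a = 1:n, b = 2 * (1:n))
  expect_error(partialCorrelation(x, y, Zbad), "collinear.*b")
  expect_error(partialCorrelation(x[1:4], y[1:4], Z[1:4, ]), "covariates")
})

test_that("rank-based partial correlation residualizes midranks", {
  set.seed(16)
  n <- 30
  Z <- data.frame(a = rnorm(n))
  x <- exp(rnorm(n)); y <- x^2 + rnorm(n, 0, 0.1)
  got <- partialCorrelation(x, y, Z, method = "spearman")
  rx <- resid(lm(rank(x) ~ rank(Z$a)))
  ry <- resid(lm(rank(y) ~ rank(Z$a)))
  expect_equal(got$r_partial, cor(rx, ry))
})

test_that("group comparison reports cover omnibus and post-hoc rows", {
  set.seed(18)
  d <- data.frame(group = rep(c("control", "pd_nc", "pd_mci"), each = 12),
                  v = c(rnorm(12), rnorm(12, 3), rnorm(12, 6)))
  rep3 <- groupComparisonReport(d, "v")
  expect_equal(rep3$test[1], "kruskal_wallis_h")
  expect_equal(sum(rep3$comparison != "omnibus"), 3)
  expect_true(all(rep3$p_value >= 0 & rep3$p_value <= 1))
  expect_equal(unique(rep3$adjusted_alpha[rep3$comparison != "omnibus"]),
               0.0167)
})
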