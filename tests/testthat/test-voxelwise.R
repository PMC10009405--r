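test_that("proportional scaling fixes every in-mask mean at the grand mean", {
  set.seed(21)
  st <- make_stack(matrix(runif(5 * 27, 50, 150), 5), c(3, 3, 3))
  sc <- proportionalScaling(st, 50)
  expect_equal(unname(rowMeans(stackData(sc))), rep(50, 5))
  # a volume with mean 100 is exactly halved
  st2 <- make_stack(matrix(100 + rep(c(-1, 1), length.out = 27),
                           1, 27, byrow = TRUE), c(3, 3, 3))
  exp_mean <- mean(stackData(st2)[1, ])
  sc2 <- proportionalScaling(st2, exp_mean / 2)
  expect_equal(stackData(sc2)[1, ], stackData(st2)[1, ] / 2)
  # idempotent
  expect_equal(stackData(proportionalScaling(sc, 50)), stackData(sc))
  # non-positive mean errors
  st3 <- make_stack(matrix(-1, 1, 27), c(3, 3, 3))
  expect_error(proportionalScaling(st3), "non-positive")
})

test_that("Gaussian smoothing matches the analytic separable kernel", {
  grid <- c(15L, 15L, 15L)
  delta <- array(0, dim = grid); delta[8, 8, 8] <- 1
  st <- make_stack(matrix(as.numeric(delta), 1), grid, voxel_size = 2)
  fwhm <- 6
  sm <- smoothStack(st, fwhm)
  out <- array(stackData(sm)[1, ], dim = grid)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / 2   # voxels
  r <- max(1, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma); k <- k / sum(k)
  idx <- 8 + (-r:r)
  want <- outer(outer(k, k), k)
  expect_equal(out[idx, idx, idx], want, tolerance = 1e-12)
  # total mass conserved (column-normalized kernels, no zero padding)
  expect_equal(sum(out), 1)
  # fwhm 0 is the identity
  expect_identical(stackData(smoothStack(st, 0)), stackData(st))
  expect_error(smoothStack(st, -1), "fwhm")
})

test_that("voxel-wise t-maps match per-voxel lm fits", {
  set.seed(23)
  n <- 25; grid <- c(4L, 4L, 4L)
  df <- make_covariates(n, seed = 23)
  st <- make_stack(matrix(rnorm(n * 64, 100, 10), n), grid)
  des <- designMatrix(df)
  fit <- fitVoxelGlm(st, des)
  expect_equal(fit$df, n - 7)
  sexn <- as.numeric(factor(df$sex)) - 1
  for (v in sample(64, 8)) {
    y <- stackData(st)[, v]
    m <- lm(y ~ df$isacog_magnitude + df$age + sexn + df$bdi2 +
              df$updrs3 + df$ledd)
    want <- summary(m)$coefficients["df$isacog_magnitude", "t value"]
    expect_equal(fit$t[v], want, tolerance = 1e-8)
  }
  # degenerate regressor: constant ISAcog is collinear with the intercept
  df2 <- df; df2$isacog_magnitude <- 1
  expect_error(designMatrix(df2), "rank deficient")
  # perfect fit is capped and flagged
  st3 <- make_stack(outer(df$isacog_magnitude, rep(1, 64)) * -2 + 100,
                    grid)
  expect_message(fit3 <- fitVoxelGlm(st3, des), "perfect fit")
  expect_true(all(fit3$capped))
})

test_that("design matrices validate rank and code sex as binary", {
  df <- make_covariates(12, seed = 29)
  des <- designMatrix(df)
  expect_equal(colnames(des@matrix),
               c("(intercept)", "isacog_magnitude", "age", "sex", "bdi2",
                 "updrs3", "ledd"))
  expect_true(all(des@matrix[, "sex"] %in% c(0, 1)))
  df$dup <- df$age * 2
  expect_error(designMatrix(df, covariates = c("age", "dup")),
               "collinear")
})

test_that("cluster formation respects threshold, direction and connectivity", {
  grid <- c(6L, 6L, 6L)
  tmap <- array(0, dim = grid)
  empty <- formClusters(tmap, df = 30)
  expect_equal(nrow(clusterTable(empty)), 0)

  # two voxels sharing only an edge: one 18-cluster, two 6-clusters
  tmap2 <- array(0, dim = grid)
  tmap2[2, 2, 2] <- -10; tmap2[3, 3, 2] <- -10
  c18 <- formClusters(tmap2, df = 30, connectivity = 18)
  c6 <- formClusters(tmap2, df = 30, connectivity = 6)
  expect_equal(nrow(clusterTable(c18)), 1)
  expect_equal(nrow(clusterTable(c6)), 2)
  # corner-only contact separates under 18 but not 26
  tmap3 <- array(0, dim = grid)
  tmap3[2, 2, 2] <- -10; tmap3[3, 3, 3] <- -10
  expect_equal(nrow(clusterTable(formClusters(tmap3, 30,
                                              connectivity = 26))), 1)
  expect_equal(nrow(clusterTable(formClusters(tmap3, 30,
                                              connectivity = 18))), 2)
  # positive direction ignores negative peaks
  expect_equal(nrow(clusterTable(formClusters(tmap2, 30,
                                              direction = "positive"))), 0)
  # peak location in mm respects the affine
  aff <- isacog:::defaultAffine(grid, 4)
  cl <- formClusters(tmap2, 30, connectivity = 18, affine = aff)
  tab <- clusterTable(cl)
  expect_equal(unname(c(tab$peak_x, tab$peak_y, tab$peak_z)),
               as.numeric(isacog:::voxelToMm(aff, arrayInd(which.min(tmap2),
                                                           grid))))
})

test_that("component labelling agrees exactly with a flood-fill oracle", {
  set.seed(33)
  for (i in 1:12) {
    grid <- c(7L, 6L, 5L)
    mask <- array(runif(prod(grid)) < 0.3, dim = grid)
    conn <- sample(c(6L, 18L, 26L), 1)
    got <- array(isacog:::.label_components_cpp(as.logical(mask), grid,
                                                conn), dim = grid)
    want <- oracle_flood_fill(mask, conn)
    # same partition: identical component memberships up to relabeling
    expect_equal(got > 0, want > 0)
    if (any(mask)) {
      key_got <- split(which(got > 0), got[got > 0])
      key_want <- split(which(want > 0), want[want > 0])
      norm <- function(k) unname(k[order(vapply(k, min, numeric(1)))])
      expect_identical(norm(key_got), norm(key_want))
    }
    expect_equal(isacog:::.max_component_size_cpp(as.logical(mask), grid,
                                                  conn),
                 if (any(mask)) max(tabulate(want[want > 0])) else 0L)
  }
})

test_that("permutation inference is deterministic and finds planted effects", {
  set.seed(41)
  n <- 24; grid <- c(10L, 10L, 10L)
  df <- make_covariates(n, seed = 41)
  vs <- volumeSpec(grid_shape = grid, seed = 43,
                   effect_slope = -12, noise_sd = 4)
  st <- generateVolumes(df, df$isacog_magnitude, vs)
  stackMask(st) <- computeAnalysisMask(st)
  st <- proportionalScaling(st)
  des <- designMatrix(df)
  cl1 <- suppressWarnings(clusterFwePermutation(st, des, n_perm = 150,
                                                seed = 7))
  cl2 <- suppressWarnings(clusterFwePermutation(st, des, n_perm = 150,
                                                seed = 7))
  expect_identical(clusterTable(cl1), clusterTable(cl2))
  # under the cluster-mass statistic the planted cluster's mass dwarfs
  # any permutation maximum: it reaches the minimum attainable p
  clm <- suppressWarnings(clusterFwePermutation(st, des, n_perm = 150,
                                                seed = 7,
                                                statistic = "mass"))
  expect_equal(min(clusterTable(clm)$fwe_p), 1 / 151)
  # and the extent-based significant map overlaps the planted mask
  sig <- significantMap(cl1)
  expect_gt(sum(sig & vs$effect_mask) / sum(vs$effect_mask), 0.5)
  # guard rails
  expect_error(clusterFwePermutation(st[1:5], des), ">= 7 subjects")
  expect_error(suppressWarnings(
    clusterFwePermutation(st, des, n_perm = 50)), "n_perm")
  expect_warning(clusterFwePermutation(st, des, n_perm = 150, seed = 1),
                 "resolution")
})

test_that("VOI means equal masked means and feed subgroup correlations", {
  grid <- c(4L, 4L, 4L)
  st <- make_stack(matrix(7, 3, 64), grid)
  voi <- array(FALSE, dim = grid); voi[1:2, 1, 1] <- TRUE
  expect_equal(unname(extractVoiMeans(st, voi)), rep(7, 3))
  # single voxel
  voi1 <- array(FALSE, dim = grid); voi1[2, 3, 4] <- TRUE
  set.seed(51)
  st2 <- make_stack(matrix(rnorm(3 * 64), 3), grid)
  idx <- which(as.logical(voi1))
  expect_equal(unname(extractVoiMeans(st2, voi1)),
               stackData(st2)[, idx])
  # random oracle
  voiR <- array(runif(64) < 0.4, dim = grid)
  expect_equal(unname(extractVoiMeans(st2, voiR)),
               unname(rowMeans(stackData(st2)[, as.logical(voiR)])))
  expect_error(extractVoiMeans(st2, array(FALSE, dim = grid)), "empty")

  # identical subgroup data give identical partial correlations
  df <- make_covariates(40, seed = 52)
  vm <- rnorm(40)
  glab <- rep(c("a", "b"), each = 20)
  df2 <- rbind(df[1:20, ], df[1:20, ]); vm2 <- c(vm[1:20], vm[1:20])
  tab <- subgroupVoiAnalysis(vm2, df2$isacog_magnitude,
                             df2[c("age", "bdi2")], glab)
  expect_equal(tab$r_partial[1], tab$r_partial[2])
  # undersized subgroup is skipped with a message
  expect_message(
    small <- subgroupVoiAnalysis(vm, df$isacog_magnitude,
                                 df[c("age", "bdi2")],
                                 rep(c("a", "b"), c(37, 3))),
    "skipped")
  expect_equal(small$group, "a")
})

test_that("the specificity rerun with cognition == ISAcog is identical", {
  df <- make_covariates(20, seed = 61)
  vs <- volumeSpec(grid_shape = c(8L, 8L, 8L), seed = 62,
                   effect_slope = -10, noise_sd = 4)
  st <- generateVolumes(df, df$isacog_magnitude, vs)
  stackMask(st) <- computeAnalysisMask(st)
  st <- proportionalScaling(st)
  des <- designMatrix(df)
  cl <- suppressWarnings(clusterFwePermutation(st, des, n_perm = 120,
                                               seed = 3))
  sp <- suppressWarnings(specificityCheck(st, des, df$isacog_magnitude,
                                          n_perm = 120, seed = 3))
  expect_identical(clusterTable(sp$clusters), clusterTable(cl))
})

test_that("the restricted structural mask is the union of hit atlas labels", {
  grid <- c(8L, 8L, 8L)
  atlas <- syntheticAtlas(grid)           # 8 octants
  labels <- array(0L, dim = grid)
  labels[1:2, 1:2, 1:2] <- 1L             # inside octant 1
  labels[7:8, 1:2, 1:2] <- 2L             # inside octant 2
  tab <- data.frame(cluster = 1:2, size = 8, peak_t = -5, peak_x = 0,
                    peak_y = 0, peak_z = 0, mass = 10,
                    fwe_p = c(0.01, 0.03))
  cl <- new("ClusterResult", labels = labels, table = tab, df = 20,
            threshold = 2.8, direction = "negative",
            connectivity = 18L, statistic = "extent")
  n <- 30
  set.seed(71)
  isa <- rnorm(n)
  covs <- data.frame(age = runif(n, 55, 80))
  structural <- data.frame(matrix(rnorm(n * 8, 2.5, 0.1), n, 8))
  names(structural) <- paste0("region_", 1:8)
  res <- restrictedMaskStructuralAnalysis(structural, atlas, cl, isa,
                                          covs)
  hit <- sort(unique(atlas[labels > 0]))
  expect_equal(res$labels, hit)
  expect_equal(res$mask, array(atlas %in% hit, dim = grid))
  expect_equal(nrow(res$regions), length(hit))
  # a region that is an affine function of ISAcog is flagged
  structural$region_1 <- 2.5 + 0.2 * isa
  res2 <- restrictedMaskStructuralAnalysis(structural, atlas, cl, isa,
                                           covs)
  expect_true(res2$regions$significant[res2$regions$region == 1])
  # no intersecting label -> empty report
  tab0 <- tab; tab0$fwe_p <- c(0.9, 0.9)
  cl0 <- new("ClusterResult", labels = labels, table = tab0, df = 20,
             threshold = 2.8, direction = "negative",
             connectivity = 18L, statistic = "extent")
  expect_message(res0 <- restrictedMaskStructuralAnalysis(
    structural, atlas, cl0, isa, covs), "no atlas label")
  expect_equal(nrow(res0$regions), 0)
})

test_that("the analysis mask keeps voxels above the mean-uptake fraction", {
  grid <- c(4L, 4L, 4L)
  dat <- matrix(100, 3, 64)
  dat[, 1:5] <- 2                         # below 0.2 * 50
  st <- make_stack(dat, grid)
  m <- computeAnalysisMask(st, grand_mean = 50)
  expect_equal(sum(m), 59)
  user <- array(TRUE, dim = grid); user[, , 1] <- FALSE
  m2 <- computeAnalysisMask(st, 50, user_mask = user)
  expect_true(!any(m2[, , 1]))
})
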