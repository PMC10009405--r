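test_that("cohort generation is deterministic and structurally sound", {
  spec <- cohortSpec(n_controls = 8, n_pd_nc = 8, n_pd_mci = 8, seed = 99)
  a <- generateCohort(spec)
  b <- generateCohort(spec)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$norms@entries, b$norms@entries)
  s <- a$subjects
  expect_equal(nrow(s), 24)
  items <- as.matrix(s[paste0("cfq_", 1:25)])
  expect_true(all(items >= 0 & items <= 4))
  expect_true(all(s$bdi2 >= 0))
  ctrl <- s[s$group == "control", ]
  expect_true(all(ctrl$updrs3 == 0 & ctrl$ledd == 0 &
                    ctrl$disease_duration == 0))
  expect_error(generateCohort(cohortSpec(n_controls = 0)),
               "control-referenced scoring")
  expect_error(cohortSpec(n_pd_nc = -1), "counts")
})

test_that("null effects leave groups exchangeable; planted deficits classify", {
  # all shifts zero: MCI rate in "patients" matches the controls' own rate
  zero <- list(control = setNames(numeric(5), batteryDomains()),
               pd_nc = setNames(numeric(5), batteryDomains()),
               pd_mci = setNames(numeric(5), batteryDomains()))
  coh0 <- generateCohort(cohortSpec(n_controls = 100, n_pd_nc = 100,
                                    n_pd_mci = 0, seed = 17,
                                    cognition_effects = zero,
                                    awareness_offset = c(control = 0,
                                                         pd_nc = 0,
                                                         pd_mci = 0)))
  scored0 <- classifyCohort(scoreCohort(coh0$subjects, coh0$norms))
  r_ctrl <- mean(scored0$mci_status[scored0$group == "control"] == "MCI")
  r_pat <- mean(scored0$mci_status[scored0$group == "pd_nc"] == "MCI")
  # Monte-Carlo estimate of P(>= 2 of 10 correlated z <= -1.5) under the
  # generator's variance components, via an independent direct simulation
  set.seed(18)
  layout <- batteryLayout()
  null_rate <- mean(replicate(4000, {
    g <- rnorm(1, 0, sqrt(0.3))
    u <- setNames(rnorm(5, 0, sqrt(0.2)), batteryDomains())
    z <- g + u[layout] + rnorm(10, 0, sqrt(0.5))
    sum(z <= -1.5) >= 2
  }))
  se <- sqrt(null_rate * (1 - null_rate)) * sqrt(1 / 100 + 1 / 4000)
  expect_lt(abs(r_pat - null_rate), 4 * se + 0.02)
  expect_lt(abs(r_ctrl - null_rate), 4 * se + 0.02)

  # planted -2 SD memory+executive deficits: the classified MCI fraction
  # matches the same direct Monte-Carlo oracle with the shift applied
  eff <- zero
  eff$pd_mci[c("memory", "executive")] <- -2
  coh1 <- generateCohort(cohortSpec(n_controls = 60, n_pd_nc = 0,
                                    n_pd_mci = 200, seed = 19,
                                    cognition_effects = eff))
  scored1 <- classifyCohort(scoreCohort(coh1$subjects, coh1$norms))
  got1 <- mean(scored1$mci_status[scored1$group == "pd_mci"] == "MCI")
  set.seed(20)
  shift <- ifelse(layout %in% c("memory", "executive"), -2, 0)
  oracle1 <- mean(replicate(4000, {
    g <- rnorm(1, 0, sqrt(0.3))
    u <- setNames(rnorm(5, 0, sqrt(0.2)), batteryDomains())
    z <- g + u[layout] + rnorm(10, 0, sqrt(0.5)) + shift
    sum(z <= -1.5) >= 2
  }))
  se1 <- sqrt(oracle1 * (1 - oracle1)) * sqrt(1 / 200 + 1 / 4000)
  expect_lt(abs(got1 - oracle1), 4 * se1 + 0.02)
  expect_gte(got1, 0.80)
})

test_that("the planted awareness offset surfaces as the ISAcog group mean", {
  coh <- generateCohort(cohortSpec(n_controls = 120, n_pd_nc = 120,
                                   n_pd_mci = 120, seed = 23))
  aw <- awarenessCohort(scoreCohort(coh$subjects, coh$norms))
  m <- tapply(aw$isacog_magnitude, aw$group, mean)
  expect_lt(abs(m[["control"]]), 0.25)
  expect_lt(abs(m[["pd_nc"]] - 0), 0.3)
  expect_gt(m[["pd_mci"]], 0.6)   # planted offset 1 minus shrinkage
})

test_that("volume generation is deterministic with exact noiseless structure", {
  vs <- volumeSpec(grid_shape = c(10L, 10L, 10L), seed = 5,
                   effect_slope = -2)
  isa <- c(-1, 0, 1, 2)
  a <- generateVolumes(4, isa, vs)
  b <- generateVolumes(4, isa, vs)
  expect_identical(stackData(a), stackData(b))

  # noiseless volumes are an exact affine function of isacog in the mask
  vs0 <- volumeSpec(grid_shape = c(10L, 10L, 10L), noise_sd = 0,
                    effect_slope = -2, seed = 5)
  st0 <- generateVolumes(4, isa, vs0)
  inmask <- which(as.logical(vs0$effect_mask))
  outmask <- which(!as.logical(vs0$effect_mask))
  for (i in 1:4) {
    vol <- stackData(st0)[i, ]
    expect_equal(unique(vol[inmask]), 50 - 2 * isa[i])
    expect_equal(unique(vol[outmask]), 50)
  }

  # fwhm 0: neighboring voxel noise is uncorrelated
  vsf <- volumeSpec(grid_shape = c(16L, 16L, 16L), fwhm = 0, seed = 7)
  stf <- generateVolumes(40, rnorm(40), vsf)
  arrs <- lapply(1:40, function(i) array(stackData(stf)[i, ],
                                         dim = c(16, 16, 16)))
  v1 <- sapply(arrs, function(a) a[8, 8, 8])
  v2 <- sapply(arrs, function(a) a[9, 8, 8])
  expect_lt(abs(cor(v1, v2)), 0.45)  # |r| ~ N(0, 1/sqrt(38)) under null

  # mask / grid mismatch
  vsbad <- volumeSpec(grid_shape = c(10L, 10L, 10L))
  vsbad$effect_mask <- array(TRUE, dim = c(9, 10, 10))
  expect_error(generateVolumes(2, c(0, 0), vsbad), "dimensions")
  expect_error(generateVolumes(3, c(0, 0), volumeSpec()), "one isacog")
})

test_that("effect-slope calibration hits the target voxel correlation", {
  vs <- volumeSpec(grid_shape = c(14L, 14L, 14L), seed = 31)
  set.seed(32)
  isa <- rnorm(60)
  vs$effect_slope <- calibrateEffectSlope(vs, sd(isa), target_r = 0.6)
  st <- generateVolumes(60, isa, vs)
  inmask <- which(as.logical(vs$effect_mask))
  # interior effect voxels: average |correlation| near the 0.6 target
  rs <- apply(stackData(st)[, sample(inmask, 30)], 2,
              function(v) cor(v, isa))
  expect_lt(abs(mean(-rs) - 0.6), 0.12)
})

test_that("the synthetic atlas partitions the grid", {
  at <- syntheticAtlas(c(12L, 12L, 12L))
  expect_equal(sort(unique(as.integer(at))), 1:8)
  expect_equal(dim(at), c(12L, 12L, 12L))
})
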