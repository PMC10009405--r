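#' Specification of a synthetic three-group cohort
#'
#' The generator emulates a case-control study of self-awareness of
#' cognition in Parkinson's disease: healthy controls, cognitively normal
#' patients (PD-NC) and patients with mild cognitive impairment (PD-MCI).
#' Latent cognition per domain is shifted by group (`cognition_effects`, in
#' SD units of the norm scale), and the expected subjective self-rating is
#' shifted relative to objective cognition by `awareness_offset` — the
#' planted ground truth for the ISAcog statistic, concentrated in the MCI
#' group by default.
#'
#' @param n_controls,n_pd_nc,n_pd_mci group sizes (defaults 30/40/23, the
#'   structure of the emulated study sample)
#' @param seed integer; the same seed yields a byte-identical cohort
#' @param age_range,education_range sampling ranges in years
#' @param cognition_effects named list (`control`, `pd_nc`, `pd_mci`) of
#'   named numeric(5) per-domain mean shifts in SD units
#' @param awareness_offset named numeric(3): mean shift of the subjective
#'   self-rating relative to objective cognition, in SD units (controls 0)
#' @param covariate_distributions per-group parameters for UPDRS-III,
#'   LEDD, BDI-2, disease duration (`c(mean, sd)`) and the proportion of
#'   women (`sex_prop_female`)
#' @param sex_imbalance when TRUE, uses the imbalanced sex proportions of
#'   the emulated study (60% women among controls, 32% among patients);
#'   default off (balanced)
#' @param var_general,var_domain,var_test variance components of the
#'   latent-cognition model (general factor, domain factor, test noise);
#'   they sum to 1 so control z-scores are standard normal. The defaults
#'   give between-domain test correlations of 0.3 and within-domain
#'   correlations of 0.5, typical of neuropsychological batteries
#' @return a classed list (`CohortSpec`)
#' @export
cohortSpec <- function(n_controls = 30L, n_pd_nc = 40L, n_pd_mci = 23L,
                       seed = 1L,
                       age_range = c(55, 80),
                       education_range = c(8, 18),
                       cognition_effects = defaultCognitionEffects(),
                       awareness_offset = c(control = 0, pd_nc = 0,
                                            pd_mci = 1),
                       covariate_distributions =
                         defaultCovariateDistributions(),
                       sex_imbalance = FALSE,
                       var_general = 0.3, var_domain = 0.2,
                       var_test = 0.5) {
  counts <- c(n_controls, n_pd_nc, n_pd_mci)
  if (any(counts < 0)) stop("group counts must be >= 0")
  stopifnot(length(age_range) == 2L, length(education_range) == 2L,
            all(c("control", "pd_nc", "pd_mci") %in%
                  names(cognition_effects)),
            all(c("control", "pd_nc", "pd_mci") %in%
                  names(awareness_offset)),
            abs(var_general + var_domain + var_test - 1) < 1e-8)
  if (sex_imbalance) {
    covariate_distributions$control$sex_prop_female <- 0.60
    covariate_distributions$pd_nc$sex_prop_female <- 0.32
    covariate_distributions$pd_mci$sex_prop_female <- 0.32
  }
  structure(list(n_controls = as.integer(n_controls),
                 n_pd_nc = as.integer(n_pd_nc),
                 n_pd_mci = as.integer(n_pd_mci),
                 seed = as.integer(seed), age_range = age_range,
                 education_range = education_range,
                 cognition_effects = cognition_effects,
                 awareness_offset = awareness_offset,
                 covariate_distributions = covariate_distributions,
                 var_general = var_general, var_domain = var_domain,
                 var_test = var_test),
            class = "CohortSpec")
}

#' Default per-group per-domain cognition shifts (SD units)
#'
#' Controls at 0; PD-NC subclinically lowered in attention, executive
#' functions and language; PD-MCI impaired across all five domains.
#' @return named list of named numeric(5)
#' @export
defaultCognitionEffects <- function() {
  zero <- stats::setNames(numeric(5), batteryDomains())
  pd_nc <- zero
  pd_nc[c("attention", "executive", "language")] <- -0.3
  pd_mci <- stats::setNames(rep(-2, 5), batteryDomains())
  list(control = zero, pd_nc = pd_nc, pd_mci = pd_mci)
}

#' Default covariate distribution parameters per group
#' @return named list per group with `updrs3`, `ledd`, `bdi2`,
#'   `duration` (`c(mean, sd)`) and `sex_prop_female`
#' @export
defaultCovariateDistributions <- function() {
  list(control = list(updrs3 = c(0, 0), ledd = c(0, 0), bdi2 = c(5, 3),
                      duration = c(0, 0), sex_prop_female = 0.5),
       pd_nc = list(updrs3 = c(28, 10), ledd = c(600, 250),
                    bdi2 = c(9, 4), duration = c(6, 3),
                    sex_prop_female = 0.5),
       pd_mci = list(updrs3 = c(35, 12), ledd = c(800, 300),
                     bdi2 = c(12, 4), duration = c(8, 4),
                     sex_prop_female = 0.5))
}

# Generator-truth reference parameters for the control-referenced tests
# (instruments without published norms: BNT, PANDA/MMSE subtests).
control_reference_truth <- function() {
  data.frame(
    test = c("bnt", "panda_delayed_recall", "mmse_delayed_recall",
             "panda_cubes", "mmse_pentagons"),
    source = "control_reference",
    intercept = c(13.5, 8, 2.6, 7, 8),
    age_slope = 0, edu_slope = 0,
    sd = c(1.2, 2, 0.6, 2, 1),
    direction = "higher_is_better", stringsAsFactors = FALSE)
}

# CFQ item model: discretized latent normal. The item latent is
# -subjective_cognition + N(0,1); the four cutpoints bin it into 0..4 so
# worse subjective cognition raises expected item scores while the 0-4
# ordinal structure is preserved.
cfq_cutpoints <- function() c(-0.4, 0.45, 1.2, 1.9)

#' Generate a synthetic cohort table and its norm table
#'
#' Each subject's latent cognition per domain is
#' `group shift + general factor + domain deviation`; the raw score of a
#' test is `conditional norm mean + (latent + test noise) * norm SD`
#' (error-count tests are inverted so that worse cognition means more
#' errors). CFQ items come from a discretized latent-normal model whose
#' location tracks latent cognition *plus* the group awareness offset
#' (a positive offset means the subjective self-rating is better than the
#' objective state), so the group's mean ISAcog magnitude approximately
#' equals the offset (attenuated somewhat by the ordinal item mapping). Controls' disease
#' fields (UPDRS-III, LEDD, duration) are zero.
#'
#' @param spec a [cohortSpec()]
#' @return list with `subjects` (data.frame, one row per subject: id,
#'   group, demographics, covariates, 10 raw test scores, 25 CFQ items)
#'   and `norms` (the complete generation [NormTable-class]: shipped
#'   published-norm entries plus the generator-truth control-reference
#'   entries)
#' @export
#' @examples
#' coh <- generateCohort(cohortSpec(n_controls = 5, n_pd_nc = 5,
#'                                  n_pd_mci = 5, seed = 42))
#' dim(coh$subjects)
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  if (spec$n_controls == 0L)
    stop("n_controls = 0: control-referenced scoring is impossible")
  norms <- mergeNormTables(defaultNormTable(),
                           normTable(control_reference_truth()))
  groups <- rep(c("control", "pd_nc", "pd_mci"),
                times = c(spec$n_controls, spec$n_pd_nc, spec$n_pd_mci))
  n <- length(groups)
  layout <- batteryLayout()
  doms <- batteryDomains()
  entries <- norms@entries

  with_seed(spec$seed, {
    age <- round(stats::runif(n, spec$age_range[1], spec$age_range[2]), 1)
    education <- round(stats::runif(n, spec$education_range[1],
                                    spec$education_range[2]))
    cv <- spec$covariate_distributions
    draw <- function(param, lo = 0) {
      vapply(seq_len(n), function(i) {
        p <- cv[[groups[i]]][[param]]
        max(lo, stats::rnorm(1, p[1], p[2]))
      }, numeric(1))
    }
    sex <- vapply(seq_len(n), function(i) {
      p <- cv[[groups[i]]]$sex_prop_female
      if (stats::runif(1) < p) "female" else "male"
    }, character(1))
    updrs3 <- round(draw("updrs3"), 1)
    ledd <- round(draw("ledd"))
    bdi2 <- round(draw("bdi2"))
    duration <- round(draw("duration", lo = 0), 1)
    updrs3[groups == "control"] <- 0
    ledd[groups == "control"] <- 0
    duration[groups == "control"] <- 0

    g_fac <- stats::rnorm(n, 0, sqrt(spec$var_general))
    u_dom <- matrix(stats::rnorm(n * 5, 0, sqrt(spec$var_domain)),
                    n, 5, dimnames = list(NULL, doms))
    shifts <- t(vapply(groups,
                       function(g) spec$cognition_effects[[g]][doms],
                       numeric(5)))
    latent <- shifts + g_fac + u_dom   # n x 5, SD units

    raw <- matrix(NA_real_, n, 10,
                  dimnames = list(NULL, names(layout)))
    for (tt in names(layout)) {
      e <- entries[entries$test == tt, ]
      std <- latent[, layout[[tt]]] +
        stats::rnorm(n, 0, sqrt(spec$var_test))
      mu <- e$intercept + e$age_slope * age + e$edu_slope * education
      raw[, tt] <- if (e$direction == "higher_is_worse")
        mu - std * e$sd else mu + std * e$sd
      raw[, tt] <- round(raw[, tt], 2)
    }

    overall_latent <- rowMeans(latent)
    offsets <- spec$awareness_offset[groups]
    subjective <- overall_latent + offsets +
      stats::rnorm(n, 0, sqrt(spec$var_test))
    cuts <- cfq_cutpoints()
    item_latent <- matrix(stats::rnorm(n * 25), n, 25) - subjective
    items <- matrix(findInterval(item_latent, cuts), n, 25,
                    dimnames = list(NULL, paste0("cfq_", 1:25)))
    if (any(items < 0 | items > 4)) {
      warning("CFQ items outside 0-4 were clamped")
      items[] <- pmin(pmax(items, 0L), 4L)
    }
  })

  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)), group = groups,
    age = age, sex = sex, education = education, updrs3 = updrs3,
    ledd = ledd, bdi2 = bdi2, disease_duration = duration,
    dementia = FALSE, stringsAsFactors = FALSE)
  subjects <- cbind(subjects, as.data.frame(raw), as.data.frame(items))
  list(subjects = subjects, norms = norms)
}

#' Specification of synthetic uptake volumes
#'
#' Stand-in for spatially normalized, smoothed metabolic images at desk
#' scale: a 24 x 28 x 24 grid of 4 mm voxels by default (the analysis
#' conventions — 6 mm FWHM smoothing, proportional scaling to a grand mean
#' of 50 — follow the full-resolution originals). Each subject's volume is
#' `baseline + effect_slope * isacog * effect_mask + smoothed noise`;
#' the effect mask is a midline box by default, emulating a medial
#' frontal / cingulate effect region.
#'
#' @param grid_shape integer(3) voxels in x/y/z
#' @param voxel_size mm (isotropic)
#' @param fwhm Gaussian smoothing FWHM in mm applied to the noise field
#' @param baseline_mean baseline uptake (arbitrary units)
#' @param noise_sd SD of the voxel noise before smoothing
#' @param effect_mask logical array (dim = `grid_shape`) where signal
#'   couples to ISAcog; `NULL` for the default midline box
#' @param effect_slope uptake units per ISAcog unit (negative = lower
#'   uptake with more impaired awareness, the planted direction)
#' @param seed integer RNG seed
#' @return a classed list (`VolumeSpec`)
#' @export
volumeSpec <- function(grid_shape = c(24L, 28L, 24L), voxel_size = 4,
                       fwhm = 6, baseline_mean = 50, noise_sd = 5,
                       effect_mask = NULL, effect_slope = 0, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0L),
            fwhm >= 0, voxel_size > 0, noise_sd >= 0)
  if (is.null(effect_mask)) effect_mask <- defaultEffectMask(grid_shape)
  stopifnot(is.logical(effect_mask),
            identical(dim(effect_mask), grid_shape))
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 fwhm = fwhm, baseline_mean = baseline_mean,
                 noise_sd = noise_sd, effect_mask = effect_mask,
                 effect_slope = effect_slope, seed = as.integer(seed)),
            class = "VolumeSpec")
}

#' Default midline effect mask
#'
#' A box of four midline sagittal planes spanning mid-anterior y and
#' upper z — the rough location of a medial frontal / cingulate cluster.
#'
#' @param grid integer(3)
#' @return logical array
#' @export
defaultEffectMask <- function(grid) {
  m <- array(FALSE, dim = grid)
  xc <- floor(grid[1] / 2)
  xs <- max(1, xc - 1):min(grid[1], xc + 2)
  ys <- max(1, round(0.45 * grid[2])):min(grid[2], round(0.75 * grid[2]))
  zs <- max(1, round(0.55 * grid[3])):min(grid[3], round(0.80 * grid[3]))
  m[xs, ys, zs] <- TRUE
  m
}

#' SD of the smoothed noise field at an interior voxel
#'
#' White noise of SD `noise_sd` convolved with the normalized separable
#' Gaussian kernel has SD `noise_sd * sqrt(prod_axis sum(k^2))`; used to
#' calibrate effect slopes analytically.
#'
#' @param spec a [volumeSpec()]
#' @return numeric SD in uptake units
#' @export
smoothedNoiseSd <- function(spec) {
  if (spec$fwhm <= 0) return(spec$noise_sd)
  sigma <- spec$fwhm / (2 * sqrt(2 * log(2))) / spec$voxel_size
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  spec$noise_sd * sqrt(sum(k^2))^3
}

#' Effect slope giving a target voxel-wise correlation with ISAcog
#'
#' Solves `target_r = s * sd(isa) / sqrt(s^2 * sd(isa)^2 + sd_noise^2)`
#' for the slope `s`, with `sd_noise` the smoothed-noise SD of `spec`. The
#' returned slope is negative: the planted convention is reduced uptake
#' with more impaired awareness.
#'
#' @param spec a [volumeSpec()]
#' @param isacog_sd SD of the ISAcog scores the volumes will couple to
#' @param target_r target across-subject correlation at in-mask voxels
#' @return numeric slope (uptake units per ISAcog unit, negative)
#' @export
calibrateEffectSlope <- function(spec, isacog_sd, target_r = 0.6) {
  stopifnot(target_r > 0, target_r < 1, isacog_sd > 0)
  -target_r / sqrt(1 - target_r^2) * smoothedNoiseSd(spec) / isacog_sd
}

#' Generate a subject-aligned stack of synthetic uptake volumes
#'
#' @param subjects data.frame with a `subject_id` column (one volume per
#'   row), or an integer count
#' @param isacog numeric, one ISAcog value per subject
#' @param spec a [volumeSpec()]
#' @return a [VolumeStack-class]; the stack mask is all-TRUE (compute an
#'   analysis mask with [computeAnalysisMask()])
#' @export
generateVolumes <- function(subjects, isacog, spec) {
  stopifnot(inherits(spec, "VolumeSpec"))
  ids <- if (is.data.frame(subjects)) as.character(subjects$subject_id)
         else sprintf("S%03d", seq_len(subjects))
  n <- length(ids)
  if (length(isacog) != n)
    stop("need one isacog value per subject (", n, " subjects, ",
         length(isacog), " values)")
  grid <- spec$grid_shape
  if (!identical(dim(spec$effect_mask), grid))
    stop("effect_mask dimensions do not match grid_shape")
  V <- prod(grid)
  eff <- as.numeric(spec$effect_mask)
  sigma_vox <- if (spec$fwhm > 0)
    rep(spec$fwhm / (2 * sqrt(2 * log(2))) / spec$voxel_size, 3) else NULL
  dat <- with_seed(spec$seed, {
    m <- matrix(NA_real_, n, V)
    for (i in seq_len(n)) {
      noise <- array(stats::rnorm(V, 0, spec$noise_sd), dim = grid)
      if (!is.null(sigma_vox) && spec$noise_sd > 0)
        noise <- gaussianSmooth3d(noise, sigma_vox)
      m[i, ] <- spec$baseline_mean +
        spec$effect_slope * isacog[i] * eff + as.numeric(noise)
    }
    m
  })
  new("VolumeStack", data = dat, grid = grid,
      affine = defaultAffine(grid, spec$voxel_size),
      mask = array(TRUE, dim = grid), subjectIds = ids)
}

#' Synthetic integer-labeled atlas volume
#'
#' Partitions the grid into `n_regions` rectangular parcels (2 x 2 x 2
#' octants by default), standing in for an anatomical atlas.
#'
#' @param grid integer(3)
#' @param n_per_axis parcels per axis (default 2 -> 8 regions)
#' @return integer array with labels 1..n_per_axis^3
#' @export
syntheticAtlas <- function(grid, n_per_axis = 2L) {
  cutaxis <- function(n) pmin(n_per_axis,
                              1L + (seq_len(n) - 1L) %/%
                                ceiling(n / n_per_axis))
  ix <- cutaxis(grid[1]); iy <- cutaxis(grid[2]); iz <- cutaxis(grid[3])
  lab <- array(0L, dim = grid)
  for (k in seq_len(grid[3]))
    lab[, , k] <- outer(ix, iy,
                        function(a, b) a + n_per_axis * (b - 1L)) +
      n_per_axis^2 * (iz[k] - 1L)
  storage.mode(lab) <- "integer"
  lab
}
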