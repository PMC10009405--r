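#' Read a pipeline run configuration (YAML)
#'
#' Structured-text config holding paths (subject CSV, volume directory,
#' atlas, output dir, optional norm table and structural table),
#' thresholds (MCI SD, cluster-forming p, FWE alpha, post-hoc family
#' alpha), covariate lists, permutation count, seed and flags
#' (connectivity, grand mean, cluster statistic, correlation type,
#' optional extra smoothing FWHM). Missing fields take the package
#' defaults; probability thresholds are validated to lie in (0, 1).
#'
#' @param path YAML file path
#' @return classed list (`RunConfig`) with a `config_hash` field (MD5 of
#'   the file)
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  runConfig(cfg, hash = unname(tools::md5sum(path)))
}

#' @rdname readRunConfig
#' @param cfg list of configuration fields (see [readRunConfig()])
#' @param hash optional config hash to record in outputs
#' @export
runConfig <- function(cfg = list(), hash = NA_character_) {
  def <- list(
    paths = list(subjects_csv = NULL, volume_dir = NULL, atlas = NULL,
                 structural_csv = NULL, norm_table = NULL,
                 out_dir = "isacog-out"),
    thresholds = list(mci_sd = 1.5, cluster_p = 0.005, fwe_alpha = 0.05,
                      posthoc_family_alpha = 0.05),
    covariates = c("age", "sex", "bdi2", "updrs3", "ledd"),
    control_covariates = c("age", "sex", "bdi2"),
    n_perm = 1000L, seed = 1L,
    flags = list(connectivity = 18L, grand_mean = 50,
                 statistic = "extent", correlation = "pearson",
                 smooth_fwhm = 0))
  cfg <- utils::modifyList(def, cfg)
  th <- cfg$thresholds
  for (nm in c("cluster_p", "fwe_alpha", "posthoc_family_alpha"))
    if (th[[nm]] <= 0 || th[[nm]] >= 1)
      stop("threshold '", nm, "' must lie in (0, 1)")
  if (th$mci_sd <= 0) stop("mci_sd must be > 0")
  cfg$config_hash <- hash
  structure(cfg, class = "RunConfig")
}

hash_line <- function(config) {
  paste0("# config_hash: ", config$config_hash %||% NA)
}

#' Behavioral stage: screen, score, classify, compare
#'
#' Reads (or accepts) the subject table, applies inclusion screening
#' (BDI-2 > 21 or dementia flag excludes), builds the control-reference
#' norm entries from the included controls for the tests without
#' published norms, scores the battery, classifies Level II MCI, scores
#' the CFQ and ISAcog, and writes the scored table, a group-comparison
#' report (controls vs all patients, and controls / PD-NC / PD-MCI with
#' Bonferroni-adjusted post-hoc U tests) and a cohort summary.
#'
#' @param config a [runConfig()]
#' @param subjects optional data.frame overriding
#'   `config$paths$subjects_csv`
#' @return invisible list: `subjects` (scored/classified/awareness
#'   columns appended), `comparisons_two_group`, `comparisons_three_group`,
#'   `summary`, `norms`
#' @export
runBehavioral <- function(config, subjects = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  if (is.null(subjects)) {
    if (is.null(config$paths$subjects_csv))
      stop("config has no subjects_csv and no table was supplied")
    subjects <- utils::read.csv(config$paths$subjects_csv,
                                stringsAsFactors = FALSE)
  }
  need <- c("subject_id", "group", "age", "education", "bdi2",
            batteryTests(), paste0("cfq_", 1:25))
  miss <- setdiff(need, names(subjects))
  if (length(miss))
    stop("subject table is missing column(s): ",
         paste(miss, collapse = ", "))

  scr <- lapply(seq_len(nrow(subjects)),
                function(i) screenInclusion(subjects[i, , drop = FALSE]))
  included <- vapply(scr, `[[`, logical(1), "included")
  cohort <- subjects[included, , drop = FALSE]
  if (sum(cohort$group == "control") < 2L)
    stop("fewer than 2 included controls: cannot build the control ",
         "reference")

  published <- if (!is.null(config$paths$norm_table))
    readNormTable(config$paths$norm_table) else defaultNormTable()
  ref_tests <- setdiff(batteryTests(), published@entries$test)
  norms <- if (length(ref_tests))
    mergeNormTables(published,
                    buildControlReference(
                      cohort[cohort$group == "control", , drop = FALSE],
                      ref_tests))
  else published

  scored <- scoreCohort(cohort, norms)
  scored <- classifyCohort(scored, threshold = config$thresholds$mci_sd)
  scored <- awarenessCohort(scored)
  scored$group3 <- ifelse(scored$group == "control", "control",
                          ifelse(scored$mci_status == "MCI", "pd_mci",
                                 "pd_nc"))

  vars <- c("age", "education", "updrs3", "ledd", "bdi2", "overall_z",
            "cfq_total", "isacog_magnitude")
  vars <- vars[vars %in% names(scored)]
  two <- scored
  two$group2 <- ifelse(two$group == "control", "control", "pd")
  cmp2 <- groupComparisonReport(
    two, setdiff(vars, c("updrs3", "ledd")), group_col = "group2",
    family_alpha = config$thresholds$posthoc_family_alpha)
  sex2 <- compareGroups(two$sex, two$group2, type = "categorical")
  cmp2 <- rbind(cmp2, data.frame(
    variable = "sex", comparison = "omnibus", test = sex2$test,
    statistic = sex2$statistic, p_value = sex2$p_value,
    adjusted_alpha = config$thresholds$posthoc_family_alpha,
    significant = sex2$p_value < config$thresholds$posthoc_family_alpha))
  cmp3 <- groupComparisonReport(
    scored, vars, group_col = "group3",
    family_alpha = config$thresholds$posthoc_family_alpha)
  summ <- mciSummary(scored)

  out_dir <- config$paths$out_dir
  if (!is.null(out_dir) && !is.na(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    all_out <- subjects
    all_out$included <- included
    all_out$exclusion_reason <- vapply(scr, `[[`, character(1), "reason")
    utils::write.csv(all_out, file.path(out_dir, "subjects_screened.csv"),
                     row.names = FALSE)
    utils::write.csv(scored, file.path(out_dir, "subjects_scored.csv"),
                     row.names = FALSE)
    utils::write.csv(rbind(cbind(sample = "control_vs_pd", cmp2),
                           cbind(sample = "three_group", cmp3)),
                     file.path(out_dir, "group_comparisons.csv"),
                     row.names = FALSE)
    con <- file(file.path(out_dir, "cohort_summary.txt"), "w")
    writeLines(c(hash_line(config), "",
                 "Cohort classification summary", ""), con)
    utils::capture.output(print(summ$by_group), file = con)
    writeLines("", con)
    utils::capture.output(print(summ$subtypes), file = con)
    close(con)
  }
  invisible(list(subjects = scored, comparisons_two_group = cmp2,
                 comparisons_three_group = cmp3, summary = summ,
                 norms = norms))
}

#' Imaging stage: voxel-wise ISAcog mapping per analysis group
#'
#' For each requested analysis group (all patients, PD-NC, PD-MCI,
#' controls) with enough subjects and available volumes: proportional
#' scaling, analysis masking, voxel-wise regression of uptake on ISAcog
#' with the group's covariate set, cluster-forming thresholding and
#' permutation cluster-FWE inference in both directions. Significant
#' clusters of the all-patients negative analysis become VOIs for
#' subgroup partial correlations and the cognition specificity check;
#' when an atlas and structural table are configured, the restricted-mask
#' structural analysis is run as well.
#'
#' @param config a [runConfig()]
#' @param behavioral result of [runBehavioral()]
#' @param stack optional [VolumeStack-class] overriding
#'   `config$paths$volume_dir`
#' @param atlas optional integer-label array overriding
#'   `config$paths$atlas`
#' @param structural optional data.frame overriding
#'   `config$paths$structural_csv` (columns `subject_id`,
#'   `region_<label>`)
#' @return invisible list: `cluster_tables` (per group x direction),
#'   `voi` (per-VOI subgroup partial correlations), `specificity`,
#'   `structural`
#' @export
runImaging <- function(config, behavioral, stack = NULL, atlas = NULL,
                       structural = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  subj <- behavioral$subjects
  if (is.null(stack)) {
    if (is.null(config$paths$volume_dir))
      stop("config has no volume_dir and no stack was supplied")
    have <- vapply(subj$subject_id, function(id)
      file.exists(file.path(config$paths$volume_dir,
                            paste0(id, ".nii.gz"))) ||
        file.exists(file.path(config$paths$volume_dir,
                              paste0(id, ".nii"))), logical(1))
    if (!any(have))
      stop("no volumes found for any subject; unmatched ids: ",
           paste(subj$subject_id, collapse = ", "))
    stack <- readVolumeStack(config$paths$volume_dir,
                             subj$subject_id[have])
  }
  missing_ids <- setdiff(subj$subject_id, subjectIds(stack))
  use <- subj[subj$subject_id %in% subjectIds(stack), , drop = FALSE]
  if (nrow(use) == 0L)
    stop("no overlap between subject table and volumes; unmatched ids: ",
         paste(missing_ids, collapse = ", "))
  stack <- stack[match(use$subject_id, subjectIds(stack))]

  fl <- config$flags; th <- config$thresholds
  if (fl$smooth_fwhm > 0) stack <- smoothStack(stack, fl$smooth_fwhm)
  stackMask(stack) <- computeAnalysisMask(stack, fl$grand_mean)
  stack <- proportionalScaling(stack, fl$grand_mean)

  groups <- list(all_patients = use$group != "control",
                 pd_nc = use$group3 == "pd_nc",
                 pd_mci = use$group3 == "pd_mci",
                 control = use$group == "control")
  cluster_tables <- list()
  results <- list()
  for (g in names(groups)) {
    sel <- groups[[g]]
    covs <- if (g == "control") config$control_covariates
            else config$covariates
    if (sum(sel) < max(7L, length(covs) + 3L)) {
      message("group '", g, "' skipped: n = ", sum(sel),
              " too small for permutation inference")
      next
    }
    sub_stack <- stack[sel]
    des <- designMatrix(use[sel, , drop = FALSE],
                        regressor = "isacog_magnitude",
                        covariates = covs)
    for (dirn in c("negative", "positive")) {
      cl <- clusterFwePermutation(sub_stack, des,
                                  cluster_p = th$cluster_p,
                                  n_perm = config$n_perm,
                                  seed = config$seed, direction = dirn,
                                  connectivity = fl$connectivity,
                                  statistic = fl$statistic)
      key <- paste(g, dirn, sep = ".")
      results[[key]] <- cl
      tab <- clusterTable(cl)
      if (nrow(tab))
        cluster_tables[[key]] <- cbind(group = g, direction = dirn, tab)
    }
  }

  # VOI follow-up on the significant negative all-patients clusters
  voi_tab <- NULL; spec <- NULL; struct_res <- NULL
  main <- results[["all_patients.negative"]]
  if (!is.null(main)) {
    sig <- clusterTable(main)
    sig <- sig[!is.na(sig$fwe_p) & sig$fwe_p < th$fwe_alpha, ,
               drop = FALSE]
    pats <- groups$all_patients
    if (nrow(sig)) {
      vois <- lapply(sig$cluster, function(ci) voiFromCluster(main, ci))
      names(vois) <- paste0("cluster_", sig$cluster)
      cov_df <- use[pats, config$covariates, drop = FALSE]
      voi_tab <- do.call(rbind, lapply(names(vois), function(nm) {
        vm <- extractVoiMeans(stack[pats], vois[[nm]])
        cbind(voi = nm,
              subgroupVoiAnalysis(vm, use$isacog_magnitude[pats],
                                  cov_df, use$group3[pats]))
      }))
      des_p <- designMatrix(use[pats, , drop = FALSE],
                            regressor = "isacog_magnitude",
                            covariates = config$covariates)
      spec <- specificityCheck(stack[pats], des_p,
                               use$overall_z[pats], vois = vois,
                               cluster_p = th$cluster_p,
                               n_perm = config$n_perm,
                               seed = config$seed,
                               connectivity = fl$connectivity,
                               statistic = fl$statistic)
      if (is.null(atlas) && !is.null(config$paths$atlas))
        atlas <- array(as.integer(
          round(readNiftiVolume(config$paths$atlas)$data)),
          dim = gridDim(stack))
      if (is.null(structural) && !is.null(config$paths$structural_csv))
        structural <- utils::read.csv(config$paths$structural_csv,
                                      stringsAsFactors = FALSE)
      if (!is.null(atlas) && !is.null(structural)) {
        structural <- structural[match(use$subject_id[pats],
                                       structural$subject_id), ,
                                 drop = FALSE]
        struct_res <- restrictedMaskStructuralAnalysis(
          structural, atlas, main, use$isacog_magnitude[pats],
          use[pats, config$covariates, drop = FALSE],
          alpha = th$fwe_alpha)
      }
    }
  }

  out_dir <- config$paths$out_dir
  if (!is.null(out_dir) && !is.na(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ct <- if (length(cluster_tables)) do.call(rbind, cluster_tables)
          else data.frame()
    utils::write.csv(ct, file.path(out_dir, "cluster_tables.csv"),
                     row.names = FALSE)
    for (key in names(results))
      writeNiftiVolume(clusterLabels(results[[key]]),
                       stackAffine(stack),
                       file.path(out_dir, paste0("clusters_", key,
                                                 ".nii.gz")))
    if (!is.null(voi_tab))
      utils::write.csv(voi_tab, file.path(out_dir, "voi_partial.csv"),
                       row.names = FALSE)
    if (!is.null(struct_res))
      utils::write.csv(struct_res$regions,
                       file.path(out_dir, "structural_regions.csv"),
                       row.names = FALSE)
    writeLines(c(hash_line(config),
                 paste0("# unmatched_ids: ",
                        paste(missing_ids, collapse = ","))),
               file.path(out_dir, "imaging_run.txt"))
  }
  invisible(list(results = results, cluster_tables = cluster_tables,
                 voi = voi_tab, specificity = spec,
                 structural = struct_res))
}

#' Subset a VolumeStack by subject
#'
#' @param x a [VolumeStack-class]
#' @param i subject indices (logical, integer or ids)
#' @param j,...,drop ignored
#' @export
setMethod("[", "VolumeStack", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@subjectIds)
  initialize(x, data = x@data[i, , drop = FALSE],
             subjectIds = x@subjectIds[i])
})

#' End-to-end synthetic study: tables and volumes on disk
#'
#' Generates the behavioral cohort, scores it through the full behavioral
#' pipeline, and writes the subject CSV plus per-subject NIfTI volumes,
#' an atlas and an optional structural table to `out_dir`. The
#' awareness-metabolism coupling is planted in patients only (controls'
#' volumes are pure baseline + smoothed noise), at a slope calibrated for
#' the requested voxel-wise correlation.
#'
#' @param out_dir output directory
#' @param cohort_spec a [cohortSpec()]
#' @param volume_spec a [volumeSpec()] (its `effect_slope` is overridden
#'   by calibration unless `target_r` is NULL)
#' @param target_r calibrated voxel-wise effect correlation (default 0.6;
#'   NULL keeps `volume_spec$effect_slope`)
#' @return invisible list with the generated `subjects`, `stack`,
#'   `atlas`, `structural` and the `effect_slope` used
#' @export
simulateStudy <- function(out_dir, cohort_spec = cohortSpec(),
                          volume_spec = volumeSpec(), target_r = 0.6) {
  coh <- generateCohort(cohort_spec)
  cfg <- runConfig(list(paths = list(out_dir = NA)))
  beh <- runBehavioral(cfg, subjects = coh$subjects)
  scored <- beh$subjects
  isa <- scored$isacog_magnitude
  eff_isa <- ifelse(scored$group == "control", 0, isa)
  if (!is.null(target_r))
    volume_spec$effect_slope <-
      calibrateEffectSlope(volume_spec,
                           stats::sd(eff_isa[scored$group != "control"]),
                           target_r)
  stack <- generateVolumes(scored, eff_isa, volume_spec)
  atlas <- syntheticAtlas(volume_spec$grid_shape)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(coh$subjects, file.path(out_dir, "subjects.csv"),
                   row.names = FALSE)
  writeVolumeStack(stack, file.path(out_dir, "volumes"))
  writeNiftiVolume(atlas, stackAffine(stack),
                   file.path(out_dir, "atlas.nii.gz"))
  writeNormTable(coh$norms, file.path(out_dir, "norms.csv"))
  structural <- with_seed(cohort_spec$seed + 1L, {
    labs <- sort(unique(as.integer(atlas[atlas > 0])))
    st <- data.frame(subject_id = scored$subject_id)
    for (lb in labs)
      st[[paste0("region_", lb)]] <- round(stats::rnorm(nrow(st), 2.5,
                                                        0.15), 4)
    st
  })
  utils::write.csv(structural, file.path(out_dir, "structural.csv"),
                   row.names = FALSE)
  invisible(list(subjects = coh$subjects, scored = scored, stack = stack,
                 atlas = atlas, structural = structural,
                 effect_slope = volume_spec$effect_slope))
}
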