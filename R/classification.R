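#' Level II mild-cognitive-impairment classification
#'
#' A test is impaired when its z-score lies at or below `-threshold`
#' (boundary inclusive: 1.5 SD below the norm mean counts as impaired).
#' MCI is diagnosed when at least two distinct tests are impaired, whether
#' within one domain or across domains. Subtype is `single_domain` when all
#' impaired tests fall in exactly one domain and `multiple_domain`
#' otherwise; the label is amnestic when the memory domain contains an
#' impaired test.
#'
#' @param profile a [CognitiveProfile-class]
#' @param threshold impairment cutoff in SD units (default 1.5)
#' @return an [MciLabel-class]
#' @export
#' @examples
#' norms <- defaultNormTable()
#' ctrl <- buildControlReference(
#'   data.frame(bnt = c(13, 14, 15), panda_delayed_recall = c(7, 8, 9),
#'              mmse_delayed_recall = c(2, 3, 3), panda_cubes = c(6, 7, 8),
#'              mmse_pentagons = c(7, 8, 9)),
#'   c("bnt", "panda_delayed_recall", "mmse_delayed_recall",
#'     "panda_cubes", "mmse_pentagons"))
classifyMci <- function(profile, threshold = 1.5) {
  stopifnot(is(profile, "CognitiveProfile"), threshold > 0)
  tz <- testZ(profile)
  layout <- batteryLayout()
  impaired <- names(tz)[tz <= -threshold]
  domains <- unique(unname(layout[impaired]))
  status <- if (length(impaired) >= 2L) "MCI" else "NC"
  subtype <- if (status != "MCI") "none"
             else if (length(domains) == 1L) "single_domain"
             else "multiple_domain"
  new("MciLabel", status = status, impairedTests = impaired,
      impairedDomains = domains, domainSubtype = subtype,
      amnestic = status == "MCI" && "memory" %in% domains,
      threshold = threshold)
}

#' Inclusion screening
#'
#' A subject is excluded when clinically relevant depression is present
#' (BDI-2 total above 21) or the dementia flag is set (dementia is a
#' clinical diagnosis supplied as input, not computed here). BDI-2 of
#' exactly 21 is still included.
#'
#' @param subject list or one-row data.frame with `bdi2` and optionally a
#'   logical `dementia`
#' @return list with `included` (logical) and `reason` (character, `""`
#'   when included)
#' @export
#' @examples
#' screenInclusion(list(bdi2 = 22))$included  # FALSE
#' screenInclusion(list(bdi2 = 21))$included  # TRUE
screenInclusion <- function(subject) {
  bdi2 <- subject$bdi2
  if (is.null(bdi2) || !is.finite(bdi2))
    stop("subject ", subject$subject_id %||% "?", ": missing bdi2")
  dementia <- isTRUE(subject$dementia)
  if (dementia)
    list(included = FALSE, reason = "dementia")
  else if (bdi2 > 21)
    list(included = FALSE, reason = sprintf("bdi2 %.4g > 21", bdi2))
  else
    list(included = TRUE, reason = "")
}

#' Classify a scored cohort and append label columns
#'
#' @param scored data.frame from [scoreCohort()] (must contain the
#'   `z_<test>` columns)
#' @param threshold impairment cutoff in SD units
#' @return `scored` with `mci_status`, `mci_subtype`, `amnestic`,
#'   `n_impaired_tests`, `included` and `exclusion_reason` appended
#' @export
classifyCohort <- function(scored, threshold = 1.5) {
  zc <- paste0("z_", batteryTests())
  stopifnot(all(zc %in% names(scored)))
  layout <- batteryLayout()
  out <- scored
  labels <- lapply(seq_len(nrow(scored)), function(i) {
    tz <- as.numeric(scored[i, zc])
    names(tz) <- batteryTests()
    prof <- new("CognitiveProfile",
                subjectId = as.character(scored$subject_id[i]),
                testZ = tz,
                domainZ = vapply(batteryDomains(),
                                 function(d) mean(tz[layout == d]),
                                 numeric(1)),
                overallZ = mean(tz))
    classifyMci(prof, threshold)
  })
  out$mci_status <- vapply(labels, function(l) l@status, character(1))
  out$mci_subtype <- vapply(labels, function(l) l@domainSubtype, character(1))
  out$amnestic <- vapply(labels, function(l) l@amnestic, logical(1))
  out$n_impaired_tests <- vapply(labels,
                                 function(l) length(l@impairedTests),
                                 integer(1))
  scr <- lapply(seq_len(nrow(scored)),
                function(i) screenInclusion(scored[i, , drop = FALSE]))
  out$included <- vapply(scr, `[[`, logical(1), "included")
  out$exclusion_reason <- vapply(scr, `[[`, character(1), "reason")
  out
}

#' Cohort classification summary (counts and percentages)
#'
#' @param classified data.frame from [classifyCohort()]
#' @param patient_groups group labels counted as patients
#' @return list of summary data.frames: `by_group` and `subtypes`
#' @export
mciSummary <- function(classified,
                       patient_groups = c("pd_nc", "pd_mci")) {
  pats <- classified[classified$group %in% patient_groups, , drop = FALSE]
  n <- nrow(pats)
  n_mci <- sum(pats$mci_status == "MCI")
  mci <- pats[pats$mci_status == "MCI", , drop = FALSE]
  n_sda <- sum(mci$mci_subtype == "single_domain" & mci$amnestic)
  by_group <- data.frame(
    what = c("patients", "mci", "normal_cognition"),
    n = c(n, n_mci, n - n_mci),
    percent = round(100 * c(1, n_mci / n, (n - n_mci) / n), 1))
  subtypes <- data.frame(
    what = c("single_domain_amnestic", "single_domain_other",
             "multiple_domain"),
    n = c(n_sda,
          sum(mci$mci_subtype == "single_domain") - n_sda,
          sum(mci$mci_subtype == "multiple_domain")),
    percent = if (n_mci > 0)
      round(100 * c(n_sda,
                    sum(mci$mci_subtype == "single_domain") - n_sda,
                    sum(mci$mci_subtype == "multiple_domain")) / n_mci, 0)
      else c(NA, NA, NA))
  list(by_group = by_group, subtypes = subtypes)
}
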