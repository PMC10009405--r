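#' The fixed ten-test battery and its domain layout
#'
#' Two tests per domain: attention (digit span forwards/backwards),
#' executive functions (modified Wisconsin Card Sorting Test errors,
#' alternating verbal fluency), language (Boston Naming Test, semantic
#' fluency), memory (PANDA delayed recall, MMSE delayed recall) and
#' visual-spatial abilities (PANDA cubes, MMSE pentagons).
#'
#' @return named character vector mapping each test to its domain
#' @export
#' @examples
#' batteryLayout()
batteryLayout <- function() {
  c(digit_span_forward  = "attention",
    digit_span_backward = "attention",
    mwcst_errors        = "executive",
    fluency_alternating = "executive",
    bnt                 = "language",
    fluency_semantic    = "language",
    panda_delayed_recall = "memory",
    mmse_delayed_recall  = "memory",
    panda_cubes          = "visuospatial",
    mmse_pentagons       = "visuospatial")
}

#' Battery test names
#' @return character(10)
#' @export
batteryTests <- function() names(batteryLayout())

#' Domain names in canonical order
#' @return character(5)
#' @export
batteryDomains <- function() {
  c("attention", "executive", "language", "memory", "visuospatial")
}

#' Construct a NormTable from an entries data.frame
#'
#' @param entries data.frame with columns `test`, `source`, `intercept`,
#'   `age_slope`, `edu_slope`, `sd`, `direction`. The conditional mean of a
#'   `published_norm` entry is `intercept + age_slope * age +
#'   edu_slope * education`; `control_reference` entries have zero slopes
#'   and carry the control-sample mean in `intercept`.
#' @return a [NormTable-class]
#' @export
normTable <- function(entries) {
  entries$test <- as.character(entries$test)
  entries$source <- as.character(entries$source)
  entries$direction <- as.character(entries$direction)
  new("NormTable", entries = entries)
}

#' Default published-norm entries for the tests with printed norms
#'
#' Synthetic linear-in-age/education norms for digit span (forwards and
#' backwards), mWCST errors and the two fluency tasks; the remaining five
#' battery tests (BNT, PANDA and MMSE subtests) have no published norms and
#' are scored against the study's own control sample via
#' [buildControlReference()]. mWCST errors is the only `higher_is_worse`
#' test: its z-score is sign-flipped.
#'
#' @return a [NormTable-class] with the 5 published-norm entries
#' @export
defaultNormTable <- function() {
  path <- system.file("extdata", "default_norms.csv", package = "isacog",
                      mustWork = TRUE)
  readNormTable(path)
}

#' Read / write a NormTable config file (CSV, one record per test)
#' @param path file path
#' @return `readNormTable`: a [NormTable-class]
#' @export
readNormTable <- function(path) {
  normTable(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname readNormTable
#' @param norms a [NormTable-class]
#' @export
writeNormTable <- function(norms, path) {
  utils::write.csv(norms@entries, path, row.names = FALSE)
  invisible(path)
}

norm_entry <- function(norms, test) {
  e <- norms@entries
  i <- match(test, e$test)
  if (is.na(i))
    stop("no norm entry for test '", test, "'", call. = FALSE)
  e[i, , drop = FALSE]
}

norm_mean <- function(entry, age, education) {
  entry$intercept + entry$age_slope * age + entry$edu_slope * education
}

#' Age/education-controlled z-score for one raw test result
#'
#' `z = (raw - conditional mean) / conditional SD`, then sign-flipped when
#' the test's direction is `higher_is_worse` (error counts), so that higher
#' z always means better cognition. A z of -1.5 sits exactly on the
#' Level II impairment boundary.
#'
#' @param raw raw test score
#' @param test battery test name
#' @param subject list or one-row data.frame with `age` and `education`
#' @param norms a [NormTable-class] containing an entry for `test`
#' @return numeric z-score
#' @export
#' @examples
#' norms <- defaultNormTable()
#' zScore(8.01, "digit_span_forward", list(age = 65, education = 12), norms)
zScore <- function(raw, test, subject, norms) {
  entry <- norm_entry(norms, test)
  if (!is.finite(raw)) stop("missing raw score for test '", test, "'")
  mu <- norm_mean(entry, subject$age, subject$education)
  z <- (raw - mu) / entry$sd
  if (entry$direction == "higher_is_worse") z <- -z
  unname(z)
}

#' Build control-reference norm entries from the control sample
#'
#' For tests without published norms, the reference is the mean and SD of
#' the age- and education-matched control sample itself (a single band:
#' zero age/education slopes). Controls re-scored against these entries
#' have sample mean 0 and SD 1 exactly.
#'
#' @param controls data.frame of control subjects, one column per test in
#'   `tests`
#' @param tests character, tests to reference against controls
#' @param directions named character, direction per test; defaults to
#'   `higher_is_better` for all
#' @return a [NormTable-class] with one `control_reference` entry per test
#' @export
buildControlReference <- function(controls, tests,
                                  directions = NULL) {
  stopifnot(is.data.frame(controls))
  rows <- lapply(tests, function(tt) {
    if (!tt %in% names(controls))
      stop("control table has no column '", tt, "'")
    v <- controls[[tt]]
    v <- v[is.finite(v)]
    if (length(v) < 2L)
      stop("need >= 2 controls with non-missing '", tt,
           "' to build a reference")
    s <- stats::sd(v)
    if (s <= 0 || !is.finite(s))
      stop("zero variance in controls for test '", tt, "'")
    dirn <- if (!is.null(directions) && tt %in% names(directions))
      directions[[tt]] else "higher_is_better"
    data.frame(test = tt, source = "control_reference",
               intercept = mean(v), age_slope = 0, edu_slope = 0,
               sd = s, direction = dirn, stringsAsFactors = FALSE)
  })
  normTable(do.call(rbind, rows))
}

#' Merge norm tables (later entries override earlier ones per test)
#' @param ... [NormTable-class] objects
#' @return a combined [NormTable-class]
#' @export
mergeNormTables <- function(...) {
  e <- do.call(rbind, lapply(list(...), function(x) x@entries))
  e <- e[!duplicated(e$test, fromLast = TRUE), , drop = FALSE]
  rownames(e) <- NULL
  normTable(e)
}

#' Score a subject's full battery into a CognitiveProfile
#'
#' Applies [zScore()] to all ten tests, averages the two tests per domain
#' into the five domain z-scores, and takes the overall cognition z as the
#' arithmetic mean of the ten test z-scores. Any missing test is a hard
#' error: the Level II classification requires a complete battery.
#'
#' @param subject list or one-row data.frame with `age`, `education`, a
#'   `subject_id` and one column per battery test
#' @param norms a [NormTable-class] covering all 10 tests
#' @return a [CognitiveProfile-class]
#' @export
computeProfile <- function(subject, norms) {
  layout <- batteryLayout()
  tz <- vapply(names(layout), function(tt) {
    raw <- subject[[tt]]
    if (is.null(raw) || !is.finite(raw))
      stop("subject ", subject$subject_id %||% "?",
           ": missing score for test '", tt, "'")
    zScore(raw, tt, subject, norms)
  }, numeric(1))
  dz <- vapply(batteryDomains(),
               function(d) mean(tz[layout == d]), numeric(1))
  new("CognitiveProfile",
      subjectId = as.character(subject$subject_id %||% ""),
      testZ = tz, domainZ = dz, overallZ = mean(tz))
}

#' Score a whole cohort table
#'
#' Column-appending convenience over [computeProfile()]: adds `z_<test>`,
#' `domain_<domain>` and `overall_z` columns to the cohort data.frame.
#'
#' @param cohort data.frame, one row per subject
#' @param norms a complete [NormTable-class]
#' @return the cohort with scoring columns appended
#' @export
scoreCohort <- function(cohort, norms) {
  profiles <- lapply(seq_len(nrow(cohort)),
                     function(i) computeProfile(cohort[i, , drop = FALSE],
                                                norms))
  tz <- t(vapply(profiles, testZ, numeric(10)))
  dz <- t(vapply(profiles, domainZ, numeric(5)))
  colnames(tz) <- paste0("z_", batteryTests())
  colnames(dz) <- paste0("domain_", batteryDomains())
  cbind(cohort, tz, dz,
        overall_z = vapply(profiles, overallZ, numeric(1)))
}
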