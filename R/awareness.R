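#' Cognitive Failures Questionnaire total score
#'
#' The CFQ has 25 items, each rated 0 (never) to 4 (very often); the total
#' ranges 0-100 and higher totals mean more self-reported everyday
#' cognitive failures. Missing items are a hard error (no proration:
#' prorating would silently change the 0-100 scale).
#'
#' @param items numeric vector of exactly 25 item responses, each in 0-4
#' @return integer-valued total in 0-100
#' @export
#' @examples
#' cfqTotal(rep(4, 25))  # 100
cfqTotal <- function(items) {
  if (length(items) != 25L)
    stop("CFQ requires exactly 25 items, got ", length(items))
  if (any(!is.finite(items)))
    stop("CFQ items contain missing values; proration is not supported")
  if (any(items < 0 | items > 4))
    stop("CFQ items must lie in 0-4")
  sum(items)
}

#' Direction-adjusted CFQ z-score
#'
#' Standardizes a CFQ total against the control sample's mean and SD, then
#' multiplies by -1 so that higher values mean fewer reported failures,
#' i.e. better subjective cognition — the same orientation as the objective
#' cognition z-scores.
#'
#' @param total CFQ total (0-100)
#' @param control_mean control-sample mean total
#' @param control_sd control-sample SD of totals (> 0)
#' @return adjusted z-score
#' @export
#' @examples
#' cfqZ(40, control_mean = 32, control_sd = 8)  # -1
cfqZ <- function(total, control_mean, control_sd) {
  if (!is.finite(control_sd) || control_sd <= 0)
    stop("control_sd must be > 0")
  -(total - control_mean) / control_sd
}

#' ISAcog: the objective-subjective awareness discrepancy
#'
#' The direction-adjusted CFQ z is subtracted from the overall cognition
#' z-score. On the signed scale, negative values mean the subject rates
#' their cognition better than objective testing shows — impaired
#' self-awareness. The magnitude scale is the negation (higher = more
#' impaired awareness) and is the canonical scale used in correlations and
#' imaging regressions. ISAcog is dimensional; no cutoff is applied.
#'
#' @param overall_z overall cognition z-score
#' @param cfq_z_adjusted direction-adjusted CFQ z-score
#' @param cfq_total optional CFQ total to carry along in the result
#' @return an [AwarenessScore-class]
#' @export
#' @examples
#' s <- isacogScore(overall_z = -1.2, cfq_z_adjusted = 0.3)
#' s  # signed -1.5, magnitude 1.5: impaired-awareness direction
isacogScore <- function(overall_z, cfq_z_adjusted, cfq_total = numeric(0)) {
  stopifnot(is.finite(overall_z), is.finite(cfq_z_adjusted))
  signed <- overall_z - cfq_z_adjusted
  new("AwarenessScore", cfqTotal = cfq_total,
      cfqZAdjusted = cfq_z_adjusted,
      isacogSigned = signed, isacogMagnitude = -signed)
}

#' Score awareness for a whole cohort table
#'
#' Computes per-subject CFQ totals from the `cfq_1` ... `cfq_25` columns,
#' standardizes them against the cohort's control group (rows with
#' `group == control_group`), and appends `cfq_total`, `cfq_z_adjusted`,
#' `isacog_signed` and `isacog_magnitude` columns. Requires an `overall_z`
#' column (from [scoreCohort()]).
#'
#' @param scored data.frame with `overall_z`, `group` and CFQ item columns
#' @param control_group label of the reference group (default `"control"`)
#' @return `scored` with awareness columns appended
#' @export
awarenessCohort <- function(scored, control_group = "control") {
  item_cols <- paste0("cfq_", 1:25)
  stopifnot(all(item_cols %in% names(scored)),
            "overall_z" %in% names(scored))
  totals <- apply(as.matrix(scored[item_cols]), 1L, cfqTotal)
  ctrl <- totals[scored$group == control_group]
  if (length(ctrl) < 2L)
    stop("need >= 2 subjects in group '", control_group,
         "' to standardize the CFQ")
  m <- mean(ctrl); s <- stats::sd(ctrl)
  if (s <= 0) stop("zero variance in control CFQ totals")
  out <- scored
  out$cfq_total <- totals
  out$cfq_z_adjusted <- cfqZ(totals, m, s)
  out$isacog_signed <- out$overall_z - out$cfq_z_adjusted
  out$isacog_magnitude <- -out$isacog_signed
  out
}
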