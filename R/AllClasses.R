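#' @import methods
NULL

#' NormTable: per-test scoring norms
#'
#' Holds one scoring rule per battery test. Two kinds of entries coexist:
#' `published_norm` entries model the age/education-conditional mean as a
#' linear function of age and education with a fixed residual SD (the usual
#' shape of printed norm tables once interpolated), and `control_reference`
#' entries carry the mean and SD of the study's own control sample, used for
#' instruments without published norms (Boston Naming Test and the PANDA and
#' MMSE subtests). Each entry also records the test's direction: for error
#' counts a *higher* raw score means *worse* performance and the z-score is
#' sign-flipped so that higher z always means better cognition.
#'
#' @slot entries data.frame with columns `test`, `source`
#'   (`published_norm`/`control_reference`), `intercept`, `age_slope`,
#'   `edu_slope`, `sd`, `direction` (`higher_is_better`/`higher_is_worse`).
#'   For `control_reference` entries the slopes are 0 and `intercept` is the
#'   control-sample mean.
#' @exportClass NormTable
setClass("NormTable", representation(entries = "data.frame"))

setValidity("NormTable", function(object) {
  e <- object@entries
  need <- c("test", "source", "intercept", "age_slope", "edu_slope", "sd",
            "direction")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(e$test))
    return("duplicate test entries")
  if (any(!is.finite(e$sd)) || any(e$sd <= 0))
    return("every norm SD must be finite and > 0")
  if (!all(e$source %in% c("published_norm", "control_reference")))
    return("source must be published_norm or control_reference")
  if (!all(e$direction %in% c("higher_is_better", "higher_is_worse")))
    return("direction must be higher_is_better or higher_is_worse")
  TRUE
})

#' CognitiveProfile: one subject's standardized battery
#'
#' Ten test z-scores arranged into the five cognitive domains (two tests
#' each: attention, executive, language, memory, visuospatial), the per-domain
#' mean z, and the overall cognition z-score (arithmetic mean of the ten
#' test z-scores).
#'
#' @slot subjectId character scalar
#' @slot testZ named numeric(10), names = battery tests
#' @slot domainZ named numeric(5), names = domains
#' @slot overallZ numeric scalar
#' @exportClass CognitiveProfile
setClass("CognitiveProfile",
         representation(subjectId = "character", testZ = "numeric",
                        domainZ = "numeric", overallZ = "numeric"))

setValidity("CognitiveProfile", function(object) {
  if (length(object@testZ) != 10L || is.null(names(object@testZ)))
    return("testZ must be 10 named z-scores")
  if (!all(is.finite(object@testZ)))
    return("all test z-scores must be finite")
  if (length(object@domainZ) != 5L)
    return("domainZ must cover the 5 domains")
  ok <- all.equal(unname(object@overallZ), mean(object@testZ),
                  tolerance = 1e-12)
  if (!isTRUE(ok))
    return("overallZ must equal the mean of the 10 test z-scores")
  TRUE
})

#' MciLabel: Level II classification outcome
#'
#' @slot status `"NC"` or `"MCI"`
#' @slot impairedTests character, tests with z at or below -threshold
#' @slot impairedDomains character, domains containing >= 1 impaired test
#' @slot domainSubtype `"none"`, `"single_domain"` or `"multiple_domain"`
#' @slot amnestic logical, TRUE when the memory domain is impaired
#' @slot threshold numeric, impairment cutoff in SD units (default 1.5)
#' @exportClass MciLabel
setClass("MciLabel",
         representation(status = "character", impairedTests = "character",
                        impairedDomains = "character",
                        domainSubtype = "character", amnestic = "logical",
                        threshold = "numeric"))

setValidity("MciLabel", function(object) {
  if (!object@status %in% c("NC", "MCI")) return("status must be NC or MCI")
  if ((object@status == "MCI") != (length(object@impairedTests) >= 2L))
    return("status MCI iff >= 2 impaired tests")
  if (!object@domainSubtype %in% c("none", "single_domain", "multiple_domain"))
    return("bad domainSubtype")
  TRUE
})

#' AwarenessScore: CFQ summary and the ISAcog discrepancy
#'
#' `isacogSigned` follows the subtraction convention (overall cognition z
#' minus direction-adjusted CFQ z): negative values mean subjective
#' self-rating is better than objective performance, i.e. impaired
#' self-awareness. `isacogMagnitude` is its negation, so that higher values
#' mean more impaired awareness; the magnitude scale is the canonical one
#' used in correlations and imaging regressions.
#'
#' @slot cfqTotal numeric, 0-100 questionnaire total
#' @slot cfqZAdjusted numeric, direction-adjusted CFQ z (higher = better
#'   subjective cognition)
#' @slot isacogSigned numeric, overall z minus adjusted CFQ z
#' @slot isacogMagnitude numeric, `-isacogSigned`
#' @exportClass AwarenessScore
setClass("AwarenessScore",
         representation(cfqTotal = "numeric", cfqZAdjusted = "numeric",
                        isacogSigned = "numeric", isacogMagnitude = "numeric"))

setValidity("AwarenessScore", function(object) {
  if (length(object@cfqTotal) && (object@cfqTotal < 0 || object@cfqTotal > 100))
    return("cfqTotal must lie in 0-100")
  if (length(object@isacogSigned) &&
      !isTRUE(all.equal(object@isacogMagnitude, -object@isacogSigned)))
    return("isacogMagnitude must equal -isacogSigned")
  TRUE
})

#' VolumeStack: subject-aligned 3D volumes on a common grid
#'
#' Stores n subjects' volumes as an n x V matrix (V = prod(grid)) together
#' with the shared grid dimensions, voxel-to-mm affine, a boolean analysis
#' mask on the same grid, and the subject identifiers aligned to the
#' behavioral table. Row-major storage of volumes as flattened R arrays
#' (column-major in x,y,z) keeps voxel-wise regression a single matrix
#' operation.
#'
#' @slot data numeric matrix, subjects x voxels
#' @slot grid integer(3), voxels in x/y/z
#' @slot affine numeric 4 x 4 voxel-to-mm transform
#' @slot mask logical array with dim = grid
#' @slot subjectIds character, one id per row of `data`
#' @exportClass VolumeStack
setClass("VolumeStack",
         representation(data = "matrix", grid = "integer", affine = "matrix",
                        mask = "array", subjectIds = "character"))

setValidity("VolumeStack", function(object) {
  if (length(object@grid) != 3L || any(object@grid < 1L))
    return("grid must be 3 positive extents")
  if (ncol(object@data) != prod(object@grid))
    return("data columns must equal prod(grid)")
  if (!identical(dim(object@mask), as.integer(object@grid)))
    return("mask dim must equal grid")
  if (!is.logical(object@mask)) return("mask must be logical")
  if (!identical(dim(object@affine), c(4L, 4L)))
    return("affine must be 4x4")
  if (length(object@subjectIds) != nrow(object@data))
    return("one subject id per volume")
  TRUE
})

#' DesignMatrix: regression design with a designated regressor of interest
#'
#' Full-column-rank design with an intercept, the regressor of interest
#' (ISAcog on the magnitude scale by convention) and nuisance covariates
#' (age, binary-coded sex, BDI-2, UPDRS-III, LEDD in the canonical
#' patient analysis).
#'
#' @slot matrix numeric design matrix, one row per subject
#' @slot regressor character, name of the column of interest
#' @exportClass DesignMatrix
setClass("DesignMatrix",
         representation(matrix = "matrix", regressor = "character"))

setValidity("DesignMatrix", function(object) {
  X <- object@matrix
  if (is.null(colnames(X))) return("design columns must be named")
  if (!object@regressor %in% colnames(X))
    return("regressor must be a design column")
  if (qr(X)$rank < ncol(X)) {
    qrX <- qr(X)
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    return(paste("design matrix is rank deficient; collinear column(s):",
                 paste(bad, collapse = ", ")))
  }
  TRUE
})

#' ClusterResult: supra-threshold connected components
#'
#' Connected components of the thresholded t-map under the chosen voxel
#' connectivity, with per-cluster extent, peak statistics and (after
#' permutation inference) the cluster-level family-wise-error-corrected p
#' value. The convention is that only clusters with `fwe_p < 0.05` are
#' treated as significant.
#'
#' @slot labels integer array, 0 = background, k = cluster k
#' @slot table data.frame: `cluster`, `size`, `peak_t`, `peak_x`, `peak_y`,
#'   `peak_z` (mm), `mass`, and `fwe_p` (NA before permutation inference)
#' @slot df numeric, residual degrees of freedom of the t-map
#' @slot threshold numeric, cluster-forming t threshold actually applied
#' @slot direction `"negative"` or `"positive"`
#' @slot connectivity integer, 6, 18 or 26
#' @slot statistic `"extent"` or `"mass"` (cluster summary used for FWE)
#' @exportClass ClusterResult
setClass("ClusterResult",
         representation(labels = "array", table = "data.frame", df = "numeric",
                        threshold = "numeric", direction = "character",
                        connectivity = "integer", statistic = "character"))

setValidity("ClusterResult", function(object) {
  if (!object@direction %in% c("negative", "positive"))
    return("direction must be negative or positive")
  if (!object@connectivity %in% c(6L, 18L, 26L))
    return("connectivity must be 6, 18 or 26")
  p <- object@table$fwe_p
  if (length(p) && any(!is.na(p) & (p < 0 | p > 1)))
    return("fwe_p must lie in [0, 1]")
  TRUE
})
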