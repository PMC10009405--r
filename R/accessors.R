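#' @describeIn VolumeStack-accessors subjects-by-voxels data matrix
#' @export
setGeneric("stackData", function(x) standardGeneric("stackData"))
#' @describeIn VolumeStack-accessors logical analysis mask (3D array)
#' @export
setGeneric("stackMask", function(x) standardGeneric("stackMask"))
#' @describeIn VolumeStack-accessors replace the analysis mask
#' @export
setGeneric("stackMask<-", function(x, value) standardGeneric("stackMask<-"))
#' @describeIn VolumeStack-accessors 4x4 voxel-to-mm affine
#' @export
setGeneric("stackAffine", function(x) standardGeneric("stackAffine"))
#' @describeIn VolumeStack-accessors grid dimensions (voxels in x/y/z)
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))
#' @describeIn VolumeStack-accessors number of subjects
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))
#' @describeIn VolumeStack-accessors subject identifiers
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' Accessors for VolumeStack
#'
#' @param x a [VolumeStack-class]
#' @param value replacement value
#' @name VolumeStack-accessors
#' @aliases stackData stackMask stackAffine gridDim nSubjects subjectIds
NULL

#' @rdname VolumeStack-accessors
setMethod("stackData", "VolumeStack", function(x) x@data)
#' @rdname VolumeStack-accessors
setMethod("stackMask", "VolumeStack", function(x) x@mask)
#' @rdname VolumeStack-accessors
setMethod("stackMask<-", "VolumeStack", function(x, value) {
  stopifnot(is.logical(value), identical(dim(value), dim(x@mask)))
  x@mask <- value
  validObject(x)
  x
})
#' @rdname VolumeStack-accessors
setMethod("stackAffine", "VolumeStack", function(x) x@affine)
#' @rdname VolumeStack-accessors
setMethod("gridDim", "VolumeStack", function(x) x@grid)
#' @rdname VolumeStack-accessors
setMethod("nSubjects", "VolumeStack", function(x) nrow(x@data))
#' @rdname VolumeStack-accessors
setMethod("subjectIds", "VolumeStack", function(x) x@subjectIds)

#' @describeIn CognitiveProfile-accessors the 10 named test z-scores
#' @export
setGeneric("testZ", function(x) standardGeneric("testZ"))
#' @describeIn CognitiveProfile-accessors the 5 named domain z-scores
#' @export
setGeneric("domainZ", function(x) standardGeneric("domainZ"))
#' @describeIn CognitiveProfile-accessors overall cognition z (mean of 10)
#' @export
setGeneric("overallZ", function(x) standardGeneric("overallZ"))

#' Accessors for CognitiveProfile
#'
#' @param x a [CognitiveProfile-class]
#' @name CognitiveProfile-accessors
#' @aliases testZ domainZ overallZ
NULL

#' @rdname CognitiveProfile-accessors
setMethod("testZ", "CognitiveProfile", function(x) x@testZ)
#' @rdname CognitiveProfile-accessors
setMethod("domainZ", "CognitiveProfile", function(x) x@domainZ)
#' @rdname CognitiveProfile-accessors
setMethod("overallZ", "CognitiveProfile", function(x) x@overallZ)

#' @describeIn ClusterResult-accessors per-cluster summary table
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))
#' @describeIn ClusterResult-accessors integer label volume
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @describeIn ClusterResult-accessors logical map of significant clusters
#' @param alpha family-wise alpha for significance (default 0.05)
#' @export
setGeneric("significantMap",
           function(x, alpha = 0.05) standardGeneric("significantMap"))

#' Accessors for ClusterResult
#'
#' @param x a [ClusterResult-class]
#' @name ClusterResult-accessors
#' @aliases clusterTable clusterLabels significantMap
NULL

#' @rdname ClusterResult-accessors
setMethod("clusterTable", "ClusterResult", function(x) x@table)
#' @rdname ClusterResult-accessors
setMethod("clusterLabels", "ClusterResult", function(x) x@labels)
#' @rdname ClusterResult-accessors
setMethod("significantMap", "ClusterResult", function(x, alpha = 0.05) {
  tab <- x@table
  keep <- tab$cluster[!is.na(tab$fwe_p) & tab$fwe_p < alpha]
  array(x@labels %in% keep, dim = dim(x@labels))
})

setMethod("show", "VolumeStack", function(object) {
  cat("VolumeStack:", nrow(object@data), "subjects on a",
      paste(object@grid, collapse = " x "), "grid\n")
  vs <- voxelSizes(object@affine)
  cat("  voxel size:", paste(signif(vs, 4), collapse = " x "), "mm;",
      sum(object@mask), "voxels in mask\n")
})

setMethod("show", "CognitiveProfile", function(object) {
  cat("CognitiveProfile", object@subjectId, "\n")
  print(round(object@domainZ, 3))
  cat("  overall z:", round(object@overallZ, 3), "\n")
})

setMethod("show", "MciLabel", function(object) {
  cat("MciLabel:", object@status)
  if (object@status == "MCI")
    cat(" (", object@domainSubtype,
        if (object@amnestic) ", amnestic" else ", non-amnestic", ")", sep = "")
  cat("\n  impaired tests:",
      if (length(object@impairedTests)) paste(object@impairedTests,
                                              collapse = ", ") else "none",
      "\n")
})

setMethod("show", "AwarenessScore", function(object) {
  cat("AwarenessScore: CFQ total", object@cfqTotal,
      "| adjusted CFQ z", round(object@cfqZAdjusted, 3),
      "| ISAcog signed", round(object@isacogSigned, 3),
      "(magnitude", paste0(round(object@isacogMagnitude, 3), ")"), "\n")
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult (", object@direction, " direction, t threshold ",
      signif(object@threshold, 4), ", ", object@connectivity,
      "-connectivity, ", object@statistic, " statistic)\n", sep = "")
  if (nrow(object@table) == 0L) {
    cat("  no supra-threshold clusters\n")
  } else {
    print(object@table, digits = 4)
  }
})

setMethod("show", "NormTable", function(object) {
  cat("NormTable with", nrow(object@entries), "tests (",
      sum(object@entries$source == "published_norm"), "published norm,",
      sum(object@entries$source == "control_reference"),
      "control reference)\n")
})

setMethod("show", "DesignMatrix", function(object) {
  cat("DesignMatrix:", nrow(object@matrix), "subjects x",
      ncol(object@matrix), "columns; regressor of interest:",
      object@regressor, "\n")
})
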