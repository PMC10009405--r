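# NIfTI-1 round trips via RNifti; the affine travels in the sform.

#' Write / read a subject-aligned volume stack as NIfTI-1 files
#'
#' One `<subject_id>.nii.gz` per subject plus `mask.nii.gz`, with the
#' stack affine stored in the sform.
#'
#' @param stack a [VolumeStack-class]
#' @param dir output directory (created if needed)
#' @return `writeVolumeStack`: invisible character vector of paths
#' @export
writeVolumeStack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- gridDim(stack)
  paths <- vapply(seq_len(nSubjects(stack)), function(i) {
    p <- file.path(dir, paste0(subjectIds(stack)[i], ".nii.gz"))
    writeNiftiVolume(array(stackData(stack)[i, ], dim = grid),
                     stackAffine(stack), p)
    p
  }, character(1))
  writeNiftiVolume(array(as.numeric(stackMask(stack)), dim = grid),
                   stackAffine(stack), file.path(dir, "mask.nii.gz"))
  invisible(paths)
}

#' @rdname writeVolumeStack
#' @param subject_ids subjects to read (files `<id>.nii.gz` / `<id>.nii`
#'   under `dir`)
#' @return `readVolumeStack`: a [VolumeStack-class]
#' @export
readVolumeStack <- function(dir, subject_ids) {
  vols <- lapply(subject_ids, function(id) {
    p <- file.path(dir, paste0(id, ".nii.gz"))
    if (!file.exists(p)) p <- file.path(dir, paste0(id, ".nii"))
    if (!file.exists(p)) stop("no volume for subject '", id, "' in ", dir)
    RNifti::readNifti(p)
  })
  dims <- lapply(vols, dim)
  if (length(unique(vapply(dims, paste, character(1),
                           collapse = "x"))) != 1L)
    stop("volumes do not share a grid")
  grid <- as.integer(dims[[1]])
  aff <- unclass(RNifti::xform(vols[[1]]))
  dat <- do.call(rbind, lapply(vols, as.numeric))
  maskp <- file.path(dir, "mask.nii.gz")
  mask <- if (file.exists(maskp))
    array(as.numeric(RNifti::readNifti(maskp)) > 0.5, dim = grid)
  else array(TRUE, dim = grid)
  new("VolumeStack", data = dat, grid = grid,
      affine = matrix(as.numeric(aff), 4, 4), mask = mask,
      subjectIds = as.character(subject_ids))
}

#' Write / read a single volume (t-map, mask, atlas) as NIfTI-1
#'
#' @param vol numeric/integer 3D array
#' @param affine 4x4 voxel-to-mm transform
#' @param path output `.nii` / `.nii.gz` path
#' @return `writeNiftiVolume`: invisible path;
#'   `readNiftiVolume`: list with `data` (array) and `affine`
#' @export
writeNiftiVolume <- function(vol, affine, path) {
  img <- RNifti::asNifti(vol)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeNiftiVolume
#' @export
readNiftiVolume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)),
       affine = matrix(as.numeric(unclass(RNifti::xform(img))), 4, 4))
}
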