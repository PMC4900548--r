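# Reading/writing the standard neuroimaging formats (NIfTI volumes via
# RNifti, FSL-style bval/bvec text files) and signal normalisation.

#' Read a diffusion-weighted series with its gradient table
#'
#' Reads a 4D NIfTI volume plus FSL-style whitespace-delimited `bval` and
#' `bvec` (3 x N layout) files and returns a validated [DWIVolume-class].
#'
#' @param nifti_path path to a `.nii`/`.nii.gz` 4D volume.
#' @param bval_path,bvec_path paths to the gradient text files.
#' @param big_delta,small_delta gradient timing Delta/delta in ms (not part
#'   of the FSL files; defaults match a monopolar 42.4/10 ms scheme).
#' @return a [DWIVolume-class].
#' @export
readDWI <- function(nifti_path, bval_path, bvec_path,
                    big_delta = 42.4, small_delta = 10) {
  for (f in c(nifti_path, bval_path, bvec_path))
    if (!file.exists(f)) .formatError(paste("file not found:", f))
  img <- RNifti::readNifti(nifti_path)
  data <- array(as.vector(img), dim(img))   # strip the niftiImage class
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- as.matrix(read.table(bvec_path))
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) bvecs <- t(bvecs)
  dimnames(bvecs) <- NULL
  if (length(bvals) != ncol(bvecs))
    .formatError("bval and bvec files disagree on the number of volumes")
  if (dim(data)[4] != length(bvals))
    .formatError(sprintf("volume count (%d) does not match gradient count (%d)",
                         dim(data)[4], length(bvals)))
  gt <- gradientTable(bvals, bvecs, big_delta, small_delta)
  dwiVolume(data, affine = unclass(RNifti::xform(img)), gradients = gt)
}

#' Write a diffusion-weighted series
#'
#' @param dwi a [DWIVolume-class].
#' @param nifti_path,bval_path,bvec_path output paths.
#' @return `nifti_path`, invisibly.
#' @export
writeDWI <- function(dwi, nifti_path, bval_path, bvec_path) {
  img <- RNifti::asNifti(dwi@data)
  img <- RNifti::`sform<-`(img, structure(dwi@affine, code = 2L))
  RNifti::writeNifti(img, nifti_path, datatype = "float")
  writeLines(paste(dwi@gradients@bvals, collapse = " "), bval_path)
  writeLines(apply(dwi@gradients@bvecs, 1, paste, collapse = " "), bvec_path)
  invisible(nifti_path)
}

#' Normalise signal to attenuations E(q) = S(q)/S0
#'
#' The b = 0 volumes are averaged (arithmetic mean) and each volume is
#' divided by that mean per voxel; the result is clamped to (eps, 1]
#' (attenuation above 1 is physically impossible and arises only from
#' noise) and the b = 0 channels are set identically to 1. Voxels with
#' S0 = 0 are flagged in the `"valid"` attribute and zeroed.
#'
#' @param dwi a [DWIVolume-class].
#' @param eps lower clamp for the attenuation.
#' @return 4D array of attenuations with attributes `"s0"` (mean b = 0
#'   volume) and `"valid"` (logical 3D array, S0 > 0).
#' @export
attenuation <- function(dwi, eps = 1e-6) {
  b <- dwi@gradients@bvals
  b0 <- which(b == 0)
  if (!length(b0)) .validationError("no b = 0 volume present")
  d <- dim(dwi@data)
  s0 <- apply(dwi@data[, , , b0, drop = FALSE], 1:3, mean)
  valid <- s0 > 0
  s0safe <- ifelse(valid, s0, 1)
  E <- dwi@data / as.vector(s0safe)
  E[E > 1] <- 1
  E[E < eps] <- eps
  E[, , , b0] <- 1
  E <- E * as.vector(valid)
  attr(E, "s0") <- s0
  attr(E, "valid") <- valid
  E
}

#' Read a binary ROI mask on the grid of a reference volume
#'
#' @param nifti_path path to a mask volume (nonzero = inside).
#' @param reference a [DWIVolume-class] or [GMField-class] defining the grid.
#' @return an [ROIMask-class].
#' @export
readMask <- function(nifti_path, reference) {
  img <- RNifti::readNifti(nifti_path)
  m <- as.array(img) != 0
  ref_dim <- if (is(reference, "DWIVolume")) dim(reference@data)[1:3]
             else dim(reference@weights)[1:3]
  if (!all(dim(m) == ref_dim))
    .validationError(sprintf("mask grid (%s) does not match reference (%s)",
                             paste(dim(m), collapse = "x"),
                             paste(ref_dim, collapse = "x")))
  if (!any(m)) .validationError("mask is empty")
  roiMask(m, affine = unclass(RNifti::xform(img)))
}

#' Serialise a Gaussian mixture field
#'
#' The weights go to a 4D NIfTI volume and the dictionary (orientations,
#' diffusivities, tau) to a JSON sidecar.
#'
#' @param gmf a [GMField-class].
#' @param nifti_path output weights volume; the sidecar is written next to
#'   it with extension `.json`.
#' @return `nifti_path`, invisibly.
#' @export
writeGMField <- function(gmf, nifti_path) {
  img <- RNifti::asNifti(gmf@weights)
  img <- RNifti::`sform<-`(img, structure(gmf@affine, code = 2L))
  RNifti::writeNifti(img, nifti_path, datatype = "float")
  side <- sub("\\.nii(\\.gz)?$", ".json", nifti_path)
  d <- gmf@dictionary
  jsonlite::write_json(list(axes = t(d@axes), dpar = d@dpar, dperp = d@dperp,
                            tau = d@tau, mask = which(gmf@mask)),
                       side, digits = NA, auto_unbox = TRUE)
  invisible(nifti_path)
}

#' @rdname writeGMField
#' @export
readGMField <- function(nifti_path) {
  img <- RNifti::readNifti(nifti_path)
  w <- array(as.vector(img), dim(img))
  side <- sub("\\.nii(\\.gz)?$", ".json", nifti_path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  dict <- new("DiffusionDictionary", axes = t(as.matrix(meta$axes)),
              dpar = meta$dpar, dperp = meta$dperp, tau = meta$tau)
  mask <- array(FALSE, dim(w)[1:3])
  mask[meta$mask] <- TRUE
  new("GMField", weights = w, dictionary = dict, atomAxes = dict@axes,
      affine = unclass(RNifti::xform(img)), mask = mask, axes = NULL)
}
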