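# S4 containers for the pipeline. Arrays are stored in plain slots with
# validity methods enforcing the domain invariants; accessors below avoid
# direct slot access.

.formatError <- function(msg)
  stop(errorCondition(msg, class = c("cdtmorph_format_error", "error", "condition")))

.validationError <- function(msg)
  stop(errorCondition(msg, class = c("cdtmorph_validation_error", "error", "condition")))

#' Gradient table for a diffusion acquisition
#'
#' Per-volume b-values (s/mm^2) and unit gradient directions, plus the
#' pulsed-gradient timing Delta (separation) and delta (duration) in ms,
#' from which the effective diffusion time tau = Delta - delta/3 follows.
#'
#' @slot bvals numeric vector of b-values, one per volume.
#' @slot bvecs 3 x N matrix of gradient directions (columns; unit norm for
#'   nonzero b, zero or arbitrary for b = 0 volumes).
#' @slot bigDelta,smallDelta gradient separation / duration in ms.
#' @export
setClass("GradientTable",
  representation(bvals = "numeric", bvecs = "matrix",
                 bigDelta = "numeric", smallDelta = "numeric"))

setValidity("GradientTable", function(object) {
  b <- object@bvals; g <- object@bvecs
  if (nrow(g) != 3L) return("bvecs must be a 3 x N matrix")
  if (ncol(g) != length(b)) return("bvals length must equal bvecs count")
  if (!any(b == 0)) return("at least one b = 0 volume is required")
  nz <- which(b > 0)
  if (length(nz)) {
    nrm <- sqrt(colSums(g[, nz, drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-3))
      return("nonzero-b gradient directions must have unit norm (tol 1e-3)")
  }
  if (object@bigDelta <= 0 || object@smallDelta <= 0)
    return("gradient timing must be positive")
  TRUE
})

#' @rdname GradientTable-class
#' @param bvals,bvecs,bigDelta,smallDelta see slots.
#' @export
gradientTable <- function(bvals, bvecs, bigDelta = 42.4, smallDelta = 10) {
  bvecs <- as.matrix(bvecs)
  dimnames(bvecs) <- NULL
  new("GradientTable", bvals = as.vector(bvals, "numeric"), bvecs = bvecs,
      bigDelta = bigDelta, smallDelta = smallDelta)
}

#' Diffusion-weighted 4D volume
#'
#' @slot data 4D array of nonnegative signal values S(q).
#' @slot affine 4 x 4 voxel-to-world matrix (mm).
#' @slot gradients a [GradientTable-class].
#' @export
setClass("DWIVolume",
  representation(data = "array", affine = "matrix", gradients = "GradientTable"))

setValidity("DWIVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) return("data must be a 4D array")
  if (d[4] != length(object@gradients@bvals))
    return("number of volumes must match the gradient table")
  if (!all(dim(object@affine) == c(4, 4))) return("affine must be 4 x 4")
  if (min(object@data) < 0) return("signal must be nonnegative")
  TRUE
})

#' @rdname DWIVolume-class
#' @param data,affine,gradients see slots.
#' @export
dwiVolume <- function(data, affine = diag(4), gradients) {
  new("DWIVolume", data = data, affine = affine, gradients = gradients)
}

#' Binary region-of-interest mask
#'
#' @slot mask logical 3D array.
#' @slot affine 4 x 4 voxel-to-world matrix.
#' @export
setClass("ROIMask", representation(mask = "array", affine = "matrix"))

setValidity("ROIMask", function(object) {
  if (length(dim(object@mask)) != 3L) return("mask must be a 3D array")
  if (!is.logical(object@mask)) return("mask must be logical")
  if (sum(object@mask) == 0) return("mask is empty")
  TRUE
})

#' @rdname ROIMask-class
#' @param mask,affine see slots.
#' @export
roiMask <- function(mask, affine = diag(4)) {
  storage.mode(mask) <- "logical"
  new("ROIMask", mask = mask, affine = affine)
}

#' @rdname ROIMask-class
#' @param object an `ROIMask`.
#' @export
nVoxels <- function(object) sum(object@mask)

#' Dictionary of canonical diffusion tensors
#'
#' Axially symmetric Gaussian atoms D_k = (d_par - d_perp) u_k u_k' +
#' d_perp I on a hemisphere tessellation, optionally plus one isotropic
#' atom. All mixtures of a population share one dictionary, so mixture
#' fields can be averaged weight-wise.
#'
#' @slot axes 3 x K matrix of unit principal axes.
#' @slot dpar,dperp per-atom axial / radial diffusivities (mm^2/s);
#'   equal entries denote an isotropic atom.
#' @slot tau effective diffusion time (ms).
#' @export
setClass("DiffusionDictionary",
  representation(axes = "matrix", dpar = "numeric", dperp = "numeric",
                 tau = "numeric"))

setValidity("DiffusionDictionary", function(object) {
  K <- ncol(object@axes)
  if (nrow(object@axes) != 3L) return("axes must be 3 x K")
  if (length(object@dpar) != K || length(object@dperp) != K)
    return("diffusivity vectors must have one entry per atom")
  if (any(object@dperp <= 0) || any(object@dpar < object@dperp))
    return("need dpar >= dperp > 0 for every atom")
  nrm <- sqrt(colSums(object@axes^2))
  if (any(abs(nrm - 1) > 1e-8)) return("axes must be unit vectors")
  if (object@tau <= 0) return("tau must be positive")
  aniso <- which(object@dpar > object@dperp)
  if (length(aniso) > 1) {
    dots <- abs(crossprod(object@axes[, aniso, drop = FALSE]))
    diag(dots) <- 0
    if (any(dots > 1 - 1e-9))
      return("orientations must be antipodally deduplicated")
  }
  TRUE
})

#' @rdname DiffusionDictionary-class
#' @param object a `DiffusionDictionary`.
#' @export
nAtoms <- function(object) ncol(object@axes)

#' Zero-mean Gaussian mixture (one EAP)
#'
#' P(r) = sum_k w_k N(r; 0, C_k) with explicit component covariances; the
#' weights are normalised to sum one wherever a density is evaluated.
#'
#' @slot weights nonnegative component weights.
#' @slot covariances 3 x 3 x K array of SPD component covariances (mm^2).
#' @export
setClass("GaussianMixture",
  representation(weights = "numeric", covariances = "array"))

setValidity("GaussianMixture", function(object) {
  K <- length(object@weights)
  d <- dim(object@covariances)
  if (length(d) != 3L || d[1] != 3L || d[2] != 3L || d[3] != K)
    return("covariances must be 3 x 3 x K")
  if (any(!is.finite(object@weights)) || any(object@weights < 0))
    return("weights must be finite and nonnegative")
  if (sum(object@weights) <= 0) return("at least one positive weight required")
  for (k in seq_len(K)) {
    C <- object@covariances[, , k]
    if (max(abs(C - t(C))) > 1e-10) return("component covariance not symmetric")
    if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      return("component covariance not positive definite")
  }
  TRUE
})

#' Gaussian mixture field (an EAP field)
#'
#' A 3D grid of Gaussian mixtures over a shared dictionary. `atomAxes`
#' holds the (possibly globally rotated) atom axes for this field; the
#' optional `axes` slot carries exact per-voxel PPD-reoriented axes
#' produced by [applyWarp()] with `snap = FALSE`.
#'
#' @slot weights 4D array (x, y, z, K) of nonnegative mixture weights.
#' @slot dictionary the shared [DiffusionDictionary-class].
#' @slot atomAxes 3 x K matrix of atom axes for this field.
#' @slot affine 4 x 4 voxel-to-world matrix.
#' @slot mask logical 3D tissue support.
#' @slot axes `NULL`, or a V x 3K matrix of per-voxel component axes.
#' @export
setClass("GMField",
  representation(weights = "array", dictionary = "DiffusionDictionary",
                 atomAxes = "matrix", affine = "matrix", mask = "array",
                 axes = "ANY"))

setValidity("GMField", function(object) {
  d <- dim(object@weights)
  if (length(d) != 4L) return("weights must be a 4D array")
  if (d[4] != nAtoms(object@dictionary))
    return("4th dimension must match the dictionary size")
  if (!all(dim(object@mask) == d[1:3])) return("mask grid mismatch")
  if (min(object@weights) < 0) return("weights must be nonnegative")
  if (!all(dim(object@atomAxes) == c(3, d[4]))) return("atomAxes must be 3 x K")
  TRUE
})

#' Dense deformation field T(x) = x + d(x)
#'
#' @slot disp 4D array (x, y, z, 3) of displacements in voxel units.
#' @slot affine 4 x 4 voxel-to-world matrix.
#' @export
setClass("DeformationField", representation(disp = "array", affine = "matrix"))

setValidity("DeformationField", function(object) {
  d <- dim(object@disp)
  if (length(d) != 4L || d[4] != 3L) return("disp must be (nx, ny, nz, 3)")
  if (any(!is.finite(object@disp))) return("displacements must be finite")
  TRUE
})

#' @rdname DeformationField-class
#' @param disp,affine see slots.
#' @export
deformationField <- function(disp, affine = diag(4)) {
  new("DeformationField", disp = disp, affine = affine)
}

#' @rdname DeformationField-class
#' @param dims integer grid dimensions.
#' @export
identityDeformation <- function(dims, affine = diag(4)) {
  deformationField(array(0, c(dims, 3)), affine)
}

#' Per-voxel Jacobian field of a deformation
#'
#' @slot J 4D array (x, y, z, 9); the 3 x 3 Jacobian at a voxel is stored
#'   column-major, entry (r, c) at channel 3 (c-1) + r.
#' @export
setClass("JacobianField", representation(J = "array"))

#' Cauchy deformation tensor field over an ROI
#'
#' One SPD(3) strain tensor sqrt(J J') per ROI voxel, in lower-triangular
#' order (dxx, dxy, dyy, dxz, dyz, dzz).
#'
#' @slot tensors V x 6 matrix, one row per ROI voxel.
#' @slot roi the [ROIMask-class] the rows index (in array order).
#' @slot subjectId subject identifier.
#' @export
setClass("CDTField",
  representation(tensors = "matrix", roi = "ROIMask", subjectId = "character"))

setValidity("CDTField", function(object) {
  if (nrow(object@tensors) != nVoxels(object@roi))
    return("one tensor per ROI voxel required")
  if (ncol(object@tensors) != 6L) return("tensors must have 6 columns")
  # SPD: sylvester criterion on the packed entries (cheap necessary check)
  t <- object@tensors
  if (any(t[, 1] <= 0) || any(t[, 1] * t[, 3] - t[, 2]^2 <= 0))
    return("tensors must be positive definite")
  TRUE
})

#' Principal geodesic analysis model for CDT fields
#'
#' Voxel-wise Frechet means plus an orthonormal principal basis of the
#' concatenated tangent space (dimension 6V), with per-component variances.
#'
#' @slot meanField V x 6 matrix of per-voxel Frechet mean tensors.
#' @slot components nComp x 6V matrix of orthonormal tangent directions.
#' @slot variances non-increasing per-component variances.
#' @slot center 6V tangent-coordinate centring vector.
#' @slot roi the common [ROIMask-class].
#' @slot metric `"affine"` or `"logeuclid"`.
#' @export
setClass("PGAModel",
  representation(meanField = "matrix", components = "matrix",
                 variances = "numeric", center = "numeric",
                 roi = "ROIMask", metric = "character"))

setValidity("PGAModel", function(object) {
  nc <- nrow(object@components)
  if (length(object@variances) != nc)
    return("one variance per component required")
  if (nc > 1 && any(diff(object@variances) > 1e-8 * object@variances[1]))
    return("variances must be non-increasing")
  if (nc > 0) {
    G <- tcrossprod(object@components)
    if (max(abs(G - diag(nc))) > 1e-6) return("components must be orthonormal")
  }
  TRUE
})

#' @rdname PGAModel-class
#' @param object a `PGAModel`.
#' @export
nComponents <- function(object) length(object@variances)

#' Result of the two-stage template construction
#'
#' @slot intermediate the blurred first-stage average (I-bar).
#' @slot final the sharp projected template (I-hat), a warped population
#'   member by construction.
#' @slot mStar index of the selected population member.
#' @slot TStar the selected projection deformation.
#' @slot deformations per-subject deformations from the intermediate stage.
#' @slot energyTable per-subject final projection data energies.
#' @slot trace population energy per outer iteration of stage one.
#' @slot regCount number of nonrigid registrations used.
#' @export
setClass("TemplateResult",
  representation(intermediate = "GMField", final = "GMField",
                 mStar = "integer", TStar = "DeformationField",
                 deformations = "list", energyTable = "numeric",
                 trace = "numeric", regCount = "integer"))

setValidity("TemplateResult", function(object) {
  N <- length(object@energyTable)
  if (object@mStar < 1L || object@mStar > N) return("mStar out of range")
  if (length(object@deformations) != N)
    return("one deformation per subject required")
  TRUE
})

#' Leave-one-out classification report
#'
#' @slot accuracy,sensitivity,specificity fractions from the confusion counts.
#' @slot predictions per-subject held-out predictions (1 = patient).
#' @slot labels true labels (1 = patient).
#' @slot bestR,bestG,bestNu selected grid cell (NA outside a grid search).
#' @slot confusion named counts TP, FP, TN, FN.
#' @slot valid FALSE when a fold was degenerate or nu infeasible.
#' @export
setClass("ClassifierReport",
  representation(accuracy = "numeric", sensitivity = "numeric",
                 specificity = "numeric", predictions = "integer",
                 labels = "integer", bestR = "numeric", bestG = "numeric",
                 bestNu = "numeric", confusion = "numeric", valid = "logical"))

# ---- show methods ----------------------------------------------------------

setMethod("show", "GradientTable", function(object) {
  cat("GradientTable:", length(object@bvals), "volumes,",
      sum(object@bvals > 0), "diffusion-weighted, b in {",
      paste(sort(unique(object@bvals)), collapse = ", "),
      "} s/mm^2; Delta/delta =", object@bigDelta, "/", object@smallDelta, "ms\n")
})

setMethod("show", "DWIVolume", function(object) {
  d <- dim(object@data)
  cat("DWIVolume:", paste(d[1:3], collapse = " x "), "grid,",
      d[4], "volumes\n")
})

setMethod("show", "DiffusionDictionary", function(object) {
  iso <- sum(object@dpar == object@dperp)
  cat("DiffusionDictionary:", nAtoms(object), "atoms (",
      nAtoms(object) - iso, "oriented +", iso, "isotropic ), tau =",
      signif(object@tau, 5), "ms\n")
})

setMethod("show", "GMField", function(object) {
  d <- dim(object@weights)
  cat("GMField:", paste(d[1:3], collapse = " x "), "grid,", d[4],
      "atoms,", sum(object@mask), "tissue voxels\n")
})

setMethod("show", "DeformationField", function(object) {
  d <- dim(object@disp)
  mx <- sqrt(max(rowSums(matrix(object@disp, prod(d[1:3]), 3)^2)))
  cat("DeformationField:", paste(d[1:3], collapse = " x "),
      "grid, max |d| =", signif(mx, 4), "voxels\n")
})

setMethod("show", "CDTField", function(object) {
  cat("CDTField: subject", object@subjectId, ",", nrow(object@tensors),
      "ROI voxels\n")
})

setMethod("show", "PGAModel", function(object) {
  cat("PGAModel:", nComponents(object), "components over",
      nrow(object@meanField), "voxels (", object@metric, "metric );",
      "top component carries",
      if (nComponents(object)) sprintf("%.1f%%", 100 * object@variances[1] /
                                         sum(object@variances)) else "NA",
      "of variance\n")
})

setMethod("show", "TemplateResult", function(object) {
  cat("TemplateResult:", length(object@energyTable), "subjects, m* =",
      object@mStar, ",", object@regCount, "registrations, final energy",
      signif(object@energyTable[object@mStar], 5), "\n")
})

setMethod("show", "ClassifierReport", function(object) {
  cat(sprintf(
    "ClassifierReport: accuracy %.4f, sensitivity %.4f, specificity %.4f\n",
    object@accuracy, object@sensitivity, object@specificity))
  if (!is.na(object@bestR))
    cat("  selected r =", object@bestR, ", g =", object@bestG,
        ", nu =", object@bestNu, "\n")
})
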