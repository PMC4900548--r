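# Riemannian statistics on SPD(3) fields: Cauchy deformation tensors from
# warp Jacobians, affine-invariant (default) or log-Euclidean log/exp maps,
# Frechet means, principal geodesic analysis on the concatenated tangent
# space, and a permutation-calibrated voxel-wise Hotelling test.

.metricCode <- function(metric) {
  match.arg(metric, c("affine", "logeuclid"))
  if (metric == "affine") 0L else 1L
}

.checkSPD <- function(M, name = "matrix") {
  if (!is.matrix(M) || !all(dim(M) == c(3, 3)))
    .validationError(paste(name, "must be 3 x 3"))
  if (max(abs(M - t(M))) > 1e-10)
    .validationError(paste(name, "is not symmetric"))
  if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    .validationError(paste(name, "is not positive definite"))
  invisible(M)
}

#' Cauchy deformation tensor of a Jacobian
#'
#' CDT = sqrt(J J'), the left stretch of the local deformation: identity
#' wherever the warp is locally a rigid rotation, with eigenvalues equal
#' to the singular values of J. Computed by symmetric eigendecomposition.
#'
#' @param J 3 x 3 Jacobian with det(J) > 0, or a [JacobianField-class]
#'   (then a V x 6 matrix in order dxx, dxy, dyy, dxz, dyz, dzz is
#'   returned).
#' @param variant `"left"` uses J J' (the convention of the defining work);
#'   `"right"` uses J' J.
#' @return 3 x 3 SPD matrix, or V x 6 matrix for a field input.
#' @export
cdtFromJacobian <- function(J, variant = c("left", "right")) {
  variant <- match.arg(variant)
  if (is(J, "JacobianField")) {
    d <- dim(J@J)[1:3]
    Jv <- matrix(J@J, prod(d), 9)
    if (variant == "right")
      Jv <- Jv[, c(1, 4, 7, 2, 5, 8, 3, 6, 9), drop = FALSE]
    res <- cpp_cdt_batch(Jv)
    if (res$min_det <= 0)
      .validationError("det(J) <= 0: not a valid diffeomorphism Jacobian")
    return(res$cdt)
  }
  if (det(J) <= 0) .validationError("det(J) must be positive")
  if (variant == "right") J <- t(J)
  cpp_spd_sqrtm(J %*% t(J))
}

#' Cauchy deformation tensor field of a warp over an ROI
#'
#' @param T a [DeformationField-class] (subject-to-template warp).
#' @param roi an [ROIMask-class] on the same grid.
#' @param subject_id identifier stored with the field.
#' @param variant see [cdtFromJacobian()].
#' @return a [CDTField-class].
#' @export
cdtField <- function(T, roi, subject_id = "subject",
                     variant = c("left", "right")) {
  variant <- match.arg(variant)
  dims <- dim(T@disp)[1:3]
  if (!all(dim(roi@mask) == dims)) .validationError("ROI grid mismatch")
  Jv <- matrix(jacobianField(T)@J, prod(dims), 9)[which(roi@mask), ,
                                                  drop = FALSE]
  if (variant == "right")
    Jv <- Jv[, c(1, 4, 7, 2, 5, 8, 3, 6, 9), drop = FALSE]
  res <- cpp_cdt_batch(Jv)
  if (res$min_det <= 0)
    .validationError("det(J) <= 0 inside the ROI")
  new("CDTField", tensors = res$cdt, roi = roi,
      subjectId = as.character(subject_id))
}

#' Riemannian log and exp maps on SPD(3)
#'
#' Affine-invariant metric: Log_M(X) = M^{1/2} logm(M^{-1/2} X M^{-1/2})
#' M^{1/2} and its inverse Exp_M(V) = M^{1/2} expm(M^{-1/2} V M^{-1/2})
#' M^{1/2}; log-Euclidean: logm(X) - logm(M) and expm(logm(M) + V).
#'
#' @param M SPD base point (3 x 3).
#' @param X SPD target (for the log) / `V` symmetric tangent (for the exp).
#' @param metric `"affine"` (default) or `"logeuclid"`.
#' @return symmetric 3 x 3 matrix (tangent) / SPD 3 x 3 matrix.
#' @export
spdLog <- function(M, X, metric = c("affine", "logeuclid")) {
  metric <- match.arg(metric)
  .checkSPD(M, "M"); .checkSPD(X, "X")
  if (metric == "affine") {
    Mh <- cpp_spd_sqrtm(M)
    Mih <- solve(Mh)
    Mh %*% cpp_spd_logm(Mih %*% X %*% Mih) %*% Mh
  } else {
    cpp_spd_logm(X) - cpp_spd_logm(M)
  }
}

#' @rdname spdLog
#' @param V symmetric 3 x 3 tangent matrix.
#' @export
spdExp <- function(M, V, metric = c("affine", "logeuclid")) {
  metric <- match.arg(metric)
  .checkSPD(M, "M")
  if (max(abs(V - t(V))) > 1e-10) .validationError("V is not symmetric")
  if (metric == "affine") {
    Mh <- cpp_spd_sqrtm(M)
    Mih <- solve(Mh)
    Mh %*% cpp_spd_expm(Mih %*% V %*% Mih) %*% Mh
  } else {
    cpp_spd_expm(cpp_spd_logm(M) + V)
  }
}

#' Geodesic distance on SPD(3)
#'
#' @inheritParams spdLog
#' @return nonnegative scalar ||Log_M(X)||_M.
#' @export
spdDistance <- function(M, X, metric = c("affine", "logeuclid")) {
  metric <- match.arg(metric)
  if (metric == "affine") {
    Mih <- solve(cpp_spd_sqrtm(M))
    sqrt(sum(cpp_spd_logm(Mih %*% X %*% Mih)^2))
  } else {
    sqrt(sum((cpp_spd_logm(X) - cpp_spd_logm(M))^2))
  }
}

#' Frechet mean of SPD(3) matrices
#'
#' Fixed-point iteration M <- Exp_M(mean_i Log_M(X_i)) under the
#' affine-invariant metric (the log-Euclidean mean is closed form and used
#' as initialisation).
#'
#' @param tensors list of SPD 3 x 3 matrices (N >= 1).
#' @param tol gradient-norm stopping threshold.
#' @param max_iter iteration cap; exceeding it raises an error with the
#'   residual.
#' @param metric `"affine"` or `"logeuclid"`.
#' @return SPD 3 x 3 matrix.
#' @export
frechetMean <- function(tensors, tol = 1e-10, max_iter = 100,
                        metric = c("affine", "logeuclid")) {
  metric <- match.arg(metric)
  if (!length(tensors)) .validationError("need at least one tensor")
  for (t in tensors) .checkSPD(t)
  X <- array(0, c(1, 6, length(tensors)))
  for (s in seq_along(tensors)) X[1, , s] <- .pack6(tensors[[s]])
  res <- cpp_frechet_field(X, tol, max_iter, .metricCode(metric))
  if (!res$converged)
    stop(sprintf("Frechet mean did not converge: gradient norm %.3g",
                 max(res$gnorm)))
  .unpack6(res$mean[1, ])
}

.pack6 <- function(M) c(M[1, 1], M[1, 2], M[2, 2], M[1, 3], M[2, 3], M[3, 3])

.unpack6 <- function(t) {
  M <- matrix(0, 3, 3)
  M[1, 1] <- t[1]; M[1, 2] <- M[2, 1] <- t[2]; M[2, 2] <- t[3]
  M[1, 3] <- M[3, 1] <- t[4]; M[2, 3] <- M[3, 2] <- t[5]; M[3, 3] <- t[6]
  M
}

# stack CDT fields into a V x 6 x N cube after checking a common ROI
.cdtCube <- function(fields) {
  roi <- fields[[1]]@roi
  V <- nVoxels(roi)
  for (f in fields)
    if (nVoxels(f@roi) != V || !all(f@roi@mask == roi@mask))
      .validationError("CDT fields must share one ROI")
  X <- array(0, c(V, 6, length(fields)))
  for (s in seq_along(fields)) X[, , s] <- fields[[s]]@tensors
  X
}

#' Principal geodesic analysis of CDT fields
#'
#' Computes the voxel-wise Frechet mean field, maps every subject to the
#' concatenated tangent space (whitened coordinates, off-diagonals scaled
#' by sqrt(2) so the Euclidean inner product matches the Riemannian one;
#' dimension 6V), and eigendecomposes the tangent covariance. Retains at
#' most min(N - 1, 6V) components with variance above `var_tol` of the
#' total.
#'
#' @param fields list of [CDTField-class] objects on a common ROI (N >= 2).
#' @param metric `"affine"` (default) or `"logeuclid"`; with the latter
#'   on commuting data PGA reduces to ordinary PCA of matrix logs.
#' @param var_tol relative variance threshold for retaining components.
#' @param mean_tol,mean_max_iter Frechet-mean iteration controls.
#' @return a [PGAModel-class].
#' @export
pgaFit <- function(fields, metric = c("affine", "logeuclid"),
                   var_tol = 1e-12, mean_tol = 1e-9, mean_max_iter = 60) {
  metric <- match.arg(metric)
  if (length(fields) < 2L) .validationError("need at least two subjects")
  X <- .cdtCube(fields)
  mres <- cpp_frechet_field(X, mean_tol, mean_max_iter, .metricCode(metric))
  coords <- cpp_tangent_coords(X, mres$mean, .metricCode(metric))  # N x 6V
  ctr <- colMeans(coords)
  Xc <- sweep(coords, 2, ctr)
  sv <- svd(Xc, nu = 0)
  variances <- sv$d^2 / (nrow(coords) - 1)
  keep <- which(variances > var_tol * max(sum(variances), 1e-300))
  keep <- head(keep, min(nrow(coords) - 1L, ncol(coords)))
  new("PGAModel", meanField = mres$mean,
      components = t(sv$v[, keep, drop = FALSE]),
      variances = variances[keep], center = ctr,
      roi = fields[[1]]@roi, metric = metric)
}

#' Project a CDT field on the principal geodesic basis
#'
#' @param model a [PGAModel-class].
#' @param field a [CDTField-class] on the model's ROI.
#' @param r_sel number of leading components (default all).
#' @return coefficient vector of length `r_sel`.
#' @export
pgaProject <- function(model, field, r_sel = nComponents(model)) {
  if (r_sel < 1 || r_sel > nComponents(model))
    .validationError("r_sel out of range")
  X <- array(field@tensors, c(nrow(field@tensors), 6, 1))
  coords <- cpp_tangent_coords(X, model@meanField, .metricCode(model@metric))
  as.vector((coords[1, ] - model@center) %*%
              t(model@components[seq_len(r_sel), , drop = FALSE]))
}

#' Tangent coordinates of several fields (feature matrix)
#'
#' @param model a [PGAModel-class].
#' @param fields list of [CDTField-class] objects.
#' @param r_sel number of leading components.
#' @return N x r_sel matrix of PGA coefficients.
#' @export
pgaFeatures <- function(model, fields, r_sel = nComponents(model)) {
  t(vapply(fields, pgaProject, numeric(r_sel), model = model,
           r_sel = r_sel))
}

#' Voxel-wise manifold two-sample test on CDT fields
#'
#' At every ROI voxel the two groups are compared by a Hotelling-type T^2
#' statistic in the tangent space at the pooled Frechet mean; p-values are
#' calibrated by permutation of the group labels (distribution-free), and
#' significance masks at p < 0.05 and p < 0.01 are returned uncorrected,
#' with an optional Benjamini-Hochberg adjustment alongside.
#'
#' @param groupA,groupB lists of [CDTField-class] objects on a common ROI
#'   (each group >= 2 subjects).
#' @param n_perm number of label permutations.
#' @param seed RNG seed for the permutations (mandatory).
#' @param metric `"affine"` or `"logeuclid"`.
#' @param ridge small diagonal loading of the pooled covariance.
#' @param bh also return Benjamini-Hochberg adjusted p-values.
#' @return list with `stat`, `p`, `p_bh` (optional), `mask05`, `mask01`
#'   (logical vectors over ROI voxels, array order), and `roi`.
#' @export
manifoldTTest <- function(groupA, groupB, n_perm = 1000, seed,
                          metric = c("affine", "logeuclid"),
                          ridge = 1e-10, bh = FALSE) {
  metric <- match.arg(metric)
  if (length(groupA) < 2L || length(groupB) < 2L)
    .validationError("each group needs at least 2 subjects")
  if (missing(seed)) .validationError("a permutation seed is mandatory")
  fields <- c(groupA, groupB)
  labels <- c(rep(0L, length(groupA)), rep(1L, length(groupB)))
  X <- .cdtCube(fields)
  mres <- cpp_frechet_field(X, 1e-9, 60, .metricCode(metric))
  coords <- cpp_tangent_coords(X, mres$mean, .metricCode(metric)) # N x 6V
  N <- length(fields); V <- nrow(X)
  tang <- array(0, c(V, 6, N))
  for (s in seq_len(N)) tang[, , s] <- matrix(coords[s, ], V, 6, byrow = TRUE)
  set.seed(seed)
  perms <- t(replicate(n_perm, sample(labels)))
  storage.mode(perms) <- "integer"
  res <- cpp_hotelling_perm(tang, labels, perms, ridge)
  out <- list(stat = as.vector(res$stat), p = as.vector(res$p),
              mask05 = as.vector(res$p) < 0.05,
              mask01 = as.vector(res$p) < 0.01,
              roi = fields[[1]]@roi)
  if (bh) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}
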