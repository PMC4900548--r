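# Diffeomorphic registration of Gaussian mixture fields: similarity
# pre-alignment on S0 images, greedy velocity-step minimisation of the
# voxel-wise squared mixture L2 distance plus a log-determinant volume
# penalty, PPD reorientation refreshed from the current Jacobian, warp
# application, inversion and Jacobian bookkeeping.

#' Registration configuration
#'
#' @param lam weight of the log-determinant volume penalty, in units of the
#'   initial mean per-voxel data energy (auto-scaled so the default is
#'   meaningful across dictionaries).
#' @param smooth_sigma Gaussian width (voxels) of the velocity smoothing
#'   that stands in for the inverse of L'L, fluid-registration style.
#' @param max_step per-iteration displacement cap (voxels).
#' @param n_iter maximum iterations per pyramid level.
#' @param n_levels multiresolution pyramid depth (downsampling by 2).
#' @param tol relative energy-decrease stopping threshold.
#' @param fd_step finite-difference step (voxels) for the energy gradient.
#' @param min_level_dim levels that would shrink any dimension below this
#'   are skipped.
#' @return a named list of settings.
#' @export
registrationConfig <- function(lam = 0.05, smooth_sigma = 2, max_step = 0.4,
                               n_iter = 60, n_levels = 3, tol = 1e-4,
                               fd_step = 0.25, min_level_dim = 8) {
  list(lam = lam, smooth_sigma = smooth_sigma, max_step = max_step,
       n_iter = n_iter, n_levels = n_levels, tol = tol, fd_step = fd_step,
       min_level_dim = min_level_dim)
}

.dispMat <- function(T) {
  d <- dim(T@disp)
  matrix(T@disp, prod(d[1:3]), 3)
}

#' Jacobian field of a deformation
#'
#' J = I + grad d by central differences in the interior and one-sided
#' differences at the boundary faces.
#'
#' @param T a [DeformationField-class].
#' @return a [JacobianField-class].
#' @export
jacobianField <- function(T) {
  dims <- as.integer(dim(T@disp)[1:3])
  J <- cpp_jacobian(.dispMat(T), dims)
  new("JacobianField", J = array(J, c(dims, 9)))
}

#' Jacobian determinant map
#'
#' @param x a [DeformationField-class] or [JacobianField-class].
#' @return 3D array of det(J).
#' @export
jacobianDeterminant <- function(x) {
  if (is(x, "DeformationField")) x <- jacobianField(x)
  d <- dim(x@J)[1:3]
  array(cpp_det3(matrix(x@J, prod(d), 9)), d)
}

# energy internals: moving warped by disp and reoriented by the Jacobian of
# the current total deformation, against the fixed field
.gmfEnergy <- function(moving, fixed, disp, want_grad = FALSE,
                       fd_step = 0.25, Wm = NULL, Wf = NULL, dims = NULL) {
  if (is.null(dims)) dims <- .gmfDims(fixed)
  if (is.null(Wf)) Wf <- .wmat(fixed)
  if (is.null(Wm)) Wm <- .wmat(moving)
  cp <- .covParams(fixed@dictionary)
  J <- cpp_jacobian(disp, dims)
  en <- cpp_gmf_energy(Wf, Wm, dims, fixed@atomAxes, moving@atomAxes,
                       cp$p, cp$q, disp, J, fd_step, want_grad)
  en$detv <- cpp_det3(J)
  en
}

#' Data term of the registration energy
#'
#' Sum over voxels of the squared mixture L2 distance between the
#' warped-and-PPD-reoriented moving field and the fixed field.
#'
#' @param moving,fixed [GMField-class] objects on the same grid with a
#'   shared dictionary family.
#' @param T optional [DeformationField-class] (identity when `NULL`).
#' @param per_voxel return the per-voxel squared distances instead of
#'   their sum.
#' @return scalar energy, or a 3D array when `per_voxel = TRUE`.
#' @export
dataEnergy <- function(moving, fixed, T = NULL, per_voxel = FALSE) {
  dims <- .gmfDims(fixed)
  if (!all(.gmfDims(moving) == dims))
    .validationError("moving and fixed grids differ")
  if (nAtoms(moving@dictionary) != nAtoms(fixed@dictionary))
    .validationError("dictionary size mismatch")
  disp <- if (is.null(T)) matrix(0, prod(dims), 3) else .dispMat(T)
  en <- .gmfEnergy(moving, fixed, disp)
  if (per_voxel) array(en$d2, dims) else sum(en$d2)
}

# 27-neighbourhood discrete Laplacian: mean over the 26 neighbours minus
# the centre, edge-replicated at the boundary.
.lap27 <- function(field, dims) {
  a <- array(field, c(dims, ncol(field)))
  out <- array(0, dim(a))
  n <- 0L
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    ii <- pmin(pmax(seq_len(dims[1]) + di, 1L), dims[1])
    jj <- pmin(pmax(seq_len(dims[2]) + dj, 1L), dims[2])
    kk <- pmin(pmax(seq_len(dims[3]) + dk, 1L), dims[3])
    out <- out + a[ii, jj, kk, , drop = FALSE]
    n <- n + 1L
  }
  out <- out / n - a
  matrix(out, prod(dims), ncol(field))
}

#' Smoothness penalty of a deformation
#'
#' lam * sum_x log(det J) (det J - 1) + sum_x ||L d||^2, with L the
#' 27-neighbourhood discrete Laplacian and the displacement read as a
#' single Euler step of its velocity field. The determinant term is
#' nonnegative and zero iff det J = 1 everywhere; it is infinite (the step
#' is rejected) if det J <= 0 anywhere. Note the term is not symmetric
#' under det -> 1/det: log(d)(d-1) != log(1/d)(1/d-1).
#'
#' @param T a [DeformationField-class].
#' @param config a [registrationConfig()] list (supplies `lam`).
#' @return scalar penalty.
#' @export
smoothnessPenalty <- function(T, config = registrationConfig(lam = 1)) {
  dims <- as.integer(dim(T@disp)[1:3])
  d <- .dispMat(T)
  detv <- cpp_det3(cpp_jacobian(d, dims))
  if (any(detv <= 0)) return(Inf)
  detterm <- sum(log(detv) * (detv - 1))
  vterm <- sum(.lap27(d, dims)^2)
  config$lam * detterm + vterm
}

# block-average downsampling by 2 of a V x C field
.downsample2 <- function(field, dims) {
  nd <- as.integer(ceiling(dims / 2))
  pi_ <- (seq_len(dims[1]) - 1L) %/% 2L
  pj <- (seq_len(dims[2]) - 1L) %/% 2L
  pk <- (seq_len(dims[3]) - 1L) %/% 2L
  idx <- 1L + rep(pi_, times = dims[2] * dims[3]) +
    nd[1] * (rep(rep(pj, each = dims[1]), times = dims[3]) +
             nd[2] * rep(pk, each = dims[1] * dims[2]))
  cnt <- tabulate(idx, nbins = prod(nd))
  out <- rowsum(field, idx, reorder = TRUE) / cnt
  list(field = out, dims = nd)
}

# upsample a displacement field from dims_c to dims_f (scale values by the
# grid ratio)
.upsampleDisp <- function(d, dims_c, dims_f) {
  ratio <- (dims_f) / (dims_c)
  X <- .gridCoords(dims_f)
  pts <- sweep(X, 2, ratio, "/")
  up <- cpp_sample_field(d, dims_c, pts, 1L)
  sweep(up, 2, ratio, "*")
}

# 0-based voxel coordinates, V x 3, fastest index first (matches flattening)
.gridCoords <- function(dims) {
  cbind(rep(seq_len(dims[1]) - 1, times = dims[2] * dims[3]),
        rep(rep(seq_len(dims[2]) - 1, each = dims[1]), times = dims[3]),
        rep(seq_len(dims[3]) - 1, each = dims[1] * dims[2]))
}

#' Nonrigid diffeomorphic registration of two mixture fields
#'
#' Greedy small-step minimisation of [dataEnergy()] plus the
#' log-determinant volume penalty: per iteration the voxel-wise gradient of
#' the squared mixture distance with respect to the displacement (central
#' finite differences of the warped image, reorientation refreshed from the
#' current Jacobian) is smoothed by a Gaussian kernel, capped at
#' `max_step`, and composed with the current deformation; a step is
#' accepted only if it keeps det J > 0 everywhere and decreases the total
#' energy, so the energy trace is monotone non-increasing by construction.
#' A multiresolution pyramid initialises each level from the previous one.
#'
#' @param moving,fixed similarity-aligned [GMField-class] objects on a
#'   common grid with a shared dictionary.
#' @param config a [registrationConfig()] list.
#' @return list with `deformation` (a [DeformationField-class]),
#'   `trace` (accepted total energies at the finest level), `energy`
#'   (final data energy), and `converged`.
#' @export
nonrigidRegister <- function(moving, fixed, config = registrationConfig()) {
  .cdtmorph_env$reg_count <- .cdtmorph_env$reg_count + 1L
  dims0 <- .gmfDims(fixed)
  if (!all(.gmfDims(moving) == dims0))
    .validationError("moving and fixed grids differ")
  cp <- .covParams(fixed@dictionary)
  Wf0 <- .wmat(fixed); Wm0 <- .wmat(moving)

  # pyramid (coarsest last)
  pyr <- list(list(Wf = Wf0, Wm = Wm0, dims = dims0))
  for (l in seq_len(config$n_levels - 1)) {
    prev <- pyr[[length(pyr)]]
    if (any(ceiling(prev$dims / 2) < config$min_level_dim)) break
    df <- .downsample2(prev$Wf, prev$dims)
    dm <- .downsample2(prev$Wm, prev$dims)
    pyr[[length(pyr) + 1L]] <- list(Wf = df$field, Wm = dm$field,
                                    dims = df$dims)
  }

  d <- matrix(0, prod(pyr[[length(pyr)]]$dims), 3)
  trace <- NULL
  converged <- TRUE
  final_data <- NA_real_
  for (lv in rev(seq_along(pyr))) {
    L <- pyr[[lv]]
    dims <- L$dims
    V <- prod(dims)
    if (nrow(d) != V) d <- .upsampleDisp(d, pyr[[lv + 1L]]$dims, dims)
    lam_eff <- NULL
    level_trace <- numeric(0)
    E <- Inf
    for (it in seq_len(config$n_iter)) {
      J <- cpp_jacobian(d, dims)
      en <- cpp_gmf_energy(L$Wf, L$Wm, dims, fixed@atomAxes, moving@atomAxes,
                           cp$p, cp$q, d, J, config$fd_step, TRUE)
      Edata <- sum(en$d2)
      detv <- cpp_det3(J)
      if (is.null(lam_eff)) lam_eff <- config$lam * max(Edata / V, 1e-12)
      E <- Edata + lam_eff * sum(log(detv) * (detv - 1))
      level_trace <- c(level_trace, E)
      # demons-style unit force: the gradient supplies the direction only,
      # so flat and steep regions advance at comparable rates
      f <- -en$grad
      fn <- sqrt(rowSums(f^2))
      pos <- fn > 1e-14
      f[pos, ] <- f[pos, , drop = FALSE] / fn[pos]
      f[!pos, ] <- 0
      v <- cpp_smooth3(f, dims, config$smooth_sigma)
      vmax <- sqrt(max(rowSums(v^2)))
      if (vmax < 1e-10) break
      base <- config$max_step / vmax
      accepted <- FALSE
      for (s in base * c(1, 0.5, 0.25)) {
        dtry <- cpp_compose_disp(s * v, d, dims)
        dettry <- cpp_det3(cpp_jacobian(dtry, dims))
        if (any(dettry <= 0)) next
        entry <- cpp_gmf_energy(L$Wf, L$Wm, dims, fixed@atomAxes,
                                moving@atomAxes, cp$p, cp$q, dtry,
                                cpp_jacobian(dtry, dims), config$fd_step,
                                FALSE)
        Etry <- sum(entry$d2) + lam_eff * sum(log(dettry) * (dettry - 1))
        if (Etry < E) {
          d <- dtry
          accepted <- TRUE
          Edata <- sum(entry$d2)
          break
        }
      }
      if (!accepted) {
        converged <- it > 1L || lv < length(pyr)
        break
      }
      if ((E - Etry) / max(abs(E), 1e-12) < config$tol) {
        E <- Etry
        break
      }
      E <- Etry
    }
    if (lv == 1L) {
      trace <- level_trace
      final_data <- Edata
    }
  }
  list(deformation = deformationField(array(d, c(dims0, 3)), fixed@affine),
       trace = trace, energy = final_data, converged = converged)
}

#' Warp a mixture field by a deformation
#'
#' Weight vectors are interpolated trilinearly at T(x) = x + d(x), each
#' voxel's components are PPD-reoriented by the local Jacobian of T, and
#' the weights are renormalised. With `snap = TRUE` (default) every
#' reoriented component is reassigned to the nearest dictionary
#' orientation so the result lives on the shared dictionary (needed for
#' weight-wise averaging); `snap = FALSE` keeps the exact reoriented axes
#' per voxel in the `axes` slot.
#'
#' @param img a [GMField-class].
#' @param T a [DeformationField-class] on the same grid.
#' @param snap reassign reoriented components to dictionary orientations.
#' @param min_support voxels whose interpolated weight mass falls below
#'   this are treated as background (zero weights).
#' @return a [GMField-class].
#' @export
applyWarp <- function(img, T, snap = TRUE, min_support = 0.05) {
  dims <- .gmfDims(img)
  if (!all(dim(T@disp)[1:3] == dims))
    .validationError("deformation grid mismatch")
  cp <- .covParams(img@dictionary)
  disp <- .dispMat(T)
  J <- cpp_jacobian(disp, dims)
  res <- cpp_warp_reorient(.wmat(img), dims, disp, J, img@atomAxes,
                           cp$q, snap)
  W <- res$W
  s <- rowSums(W)
  tissue <- s > min_support
  W[tissue, ] <- W[tissue, , drop = FALSE] / s[tissue]
  W[!tissue, ] <- 0
  new("GMField",
      weights = array(W, c(dims, ncol(W))), dictionary = img@dictionary,
      atomAxes = if (snap) img@atomAxes else img@atomAxes,
      affine = img@affine, mask = array(tissue, dims),
      axes = if (snap) NULL else res$axes)
}

#' Invert a deformation by fixed-point iteration
#'
#' Solves d_inv(x) = -d(x + d_inv(x)); the returned field satisfies
#' max_x |T(T^-1(x)) - x| < `tol` voxels or an error reporting the
#' residual is raised.
#'
#' @param T a [DeformationField-class] with det J > 0.
#' @param max_iter iteration cap.
#' @param tol composition residual bound (voxels).
#' @return a [DeformationField-class].
#' @export
invertDeformation <- function(T, max_iter = 50, tol = 0.1) {
  dims <- as.integer(dim(T@disp)[1:3])
  d <- .dispMat(T)
  X <- .gridCoords(dims)
  dinv <- -d
  for (it in seq_len(max_iter)) {
    samp <- cpp_sample_field(d, dims, X + dinv, 1L)
    dnew <- -samp
    delta <- max(abs(dnew - dinv))
    dinv <- dnew
    if (delta < 1e-4) break
  }
  resid <- max(sqrt(rowSums(
    (dinv + cpp_sample_field(d, dims, X + dinv, 1L))^2)))
  if (resid >= tol)
    .validationError(sprintf(
      "deformation inversion did not converge: residual %.3f voxels", resid))
  deformationField(array(dinv, c(dims, 3)), T@affine)
}

# ---- similarity (7-dof) alignment -----------------------------------------

.eulerRotation <- function(r) {
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

.similarityPoints <- function(theta, X, center) {
  R <- .eulerRotation(theta[4:6]) * exp(theta[7])
  sweep(sweep(X, 2, center) %*% t(R), 2, center + theta[1:3], "+")
}

#' Similarity (7-dof) pre-alignment of two scalar volumes
#'
#' Maximises normalised cross-correlation over 3 translations, 3 Euler
#' rotations and 1 isotropic log-scale, coarse-to-fine, typically on the
#' S0 images. The transform maps fixed-grid coordinates into the moving
#' volume, so a moving volume shifted by +3 voxels in x relative to the
#' fixed one yields translation (-3, 0, 0).
#'
#' @param moving_s0,fixed_s0 3D arrays on comparable grids.
#' @param smooth_sigma pre-smoothing width (voxels).
#' @param max_iter Nelder-Mead iteration cap per stage.
#' @return list with `rotation` (3 x 3), `translation`, `scale`, `center`,
#'   `ncc` and `converged`; class `"SimilarityTransform"`.
#' @export
similarityRegister <- function(moving_s0, fixed_s0, smooth_sigma = 1.5,
                               max_iter = 600) {
  dims <- as.integer(dim(fixed_s0))
  V <- prod(dims)
  fs <- cpp_smooth3(matrix(as.numeric(fixed_s0), V, 1), dims, smooth_sigma)
  ms <- cpp_smooth3(matrix(as.numeric(moving_s0), V, 1), dims, smooth_sigma)
  X <- .gridCoords(dims)
  center <- (dims - 1) / 2
  com <- function(v) colSums(X * as.vector(v)) / sum(v)
  t0 <- if (sum(ms) > 0 && sum(fs) > 0) com(ms) - com(fs) else c(0, 0, 0)
  obj <- function(theta) {
    pts <- .similarityPoints(theta, X, center)
    samp <- cpp_sample_field(ms, dims, pts, 0L)
    if (sd(samp) < 1e-12) return(1)
    -suppressWarnings(stats::cor(as.vector(samp), as.vector(fs)))
  }
  theta0 <- c(t0, 0, 0, 0, 0)
  fit <- tryCatch(
    optim(theta0, obj, method = "Nelder-Mead",
          control = list(maxit = max_iter,
                         parscale = c(1, 1, 1, 0.05, 0.05, 0.05, 0.05))),
    error = function(e) NULL)
  id_ncc <- -obj(rep(0, 7))
  if (is.null(fit) || -fit$value < id_ncc) {
    warning("similarity optimisation did not improve on identity")
    return(structure(list(rotation = diag(3), translation = c(0, 0, 0),
                          scale = 1, center = center, ncc = id_ncc,
                          converged = FALSE),
                     class = "SimilarityTransform"))
  }
  th <- fit$par
  structure(list(rotation = .eulerRotation(th[4:6]),
                 translation = th[1:3], scale = exp(th[7]), center = center,
                 ncc = -fit$value, converged = fit$convergence == 0),
            class = "SimilarityTransform")
}

#' Apply a similarity transform to a mixture field
#'
#' Weights are resampled at the transformed coordinates and the atom axes
#' are rotated by the transform's rotation (the PPD reorientation of a
#' similarity map reduces to its rotation, shared across voxels).
#'
#' @param gmf a [GMField-class].
#' @param trans a `"SimilarityTransform"` from [similarityRegister()].
#' @param min_support background threshold as in [applyWarp()].
#' @return a [GMField-class].
#' @export
applySimilarity <- function(gmf, trans, min_support = 0.05) {
  dims <- .gmfDims(gmf)
  X <- .gridCoords(dims)
  pts <- sweep(sweep(X, 2, trans$center) %*%
                 t(trans$rotation * trans$scale), 2,
               trans$center + trans$translation, "+")
  W <- cpp_sample_field(.wmat(gmf), dims, pts, 0L)
  s <- rowSums(W)
  tissue <- s > min_support
  W[tissue, ] <- W[tissue, , drop = FALSE] / s[tissue]
  W[!tissue, ] <- 0
  new("GMField", weights = array(W, c(dims, ncol(W))),
      dictionary = gmf@dictionary,
      atomAxes = trans$rotation %*% gmf@atomAxes,
      affine = gmf@affine, mask = array(tissue, dims), axes = NULL)
}
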