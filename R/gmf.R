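# Gaussian mixture fields: the forward attenuation model, nonnegative
# dictionary estimation, mixture densities, the closed-form L2 distance and
# PPD reorientation.

#' Construct a Gaussian mixture from dictionary weights
#'
#' @param weights nonnegative weights, one per dictionary atom.
#' @param dict a [DiffusionDictionary-class]; component covariances are
#'   2 tau D_k.
#' @param covariances alternatively, an explicit 3 x 3 x K covariance array.
#' @return a [GaussianMixture-class].
#' @export
gaussianMixture <- function(weights, dict = NULL, covariances = NULL) {
  if (is.null(covariances)) {
    if (is.null(dict)) .validationError("give a dictionary or covariances")
    covariances <- atomCovariances(dict)
  }
  new("GaussianMixture", weights = as.numeric(weights),
      covariances = covariances)
}

#' Forward attenuation model of a dictionary mixture
#'
#' E(q) = sum_k w~_k exp(-b g' D_k g) with w~ the weights normalised to
#' sum one; E = 1 at b = 0 by construction.
#'
#' @param dict a [DiffusionDictionary-class].
#' @param weights nonnegative atom weights (not all zero).
#' @param gradients a [GradientTable-class].
#' @return attenuation vector, one entry per volume, in (0, 1].
#' @export
predictAttenuation <- function(dict, weights, gradients) {
  if (all(weights == 0)) .validationError("all-zero weights: undefined voxel")
  if (any(weights < 0)) .validationError("weights must be nonnegative")
  w <- weights / sum(weights)
  as.vector(designMatrix(dict, gradients) %*% w)
}

#' Dictionary design matrix of per-atom attenuations
#'
#' A[i, k] = exp(-b_i g_i' D_k g_i); rows with b = 0 are identically 1.
#'
#' @inheritParams predictAttenuation
#' @return N_volumes x K matrix.
#' @export
designMatrix <- function(dict, gradients) {
  b <- gradients@bvals
  g <- gradients@bvecs
  # ADC per (direction, atom): dperp + (dpar - dperp) (g . u)^2
  du <- crossprod(g, dict@axes)^2                 # N x K
  adc <- sweep(du, 2, dict@dpar - dict@dperp, "*")
  adc <- sweep(adc, 2, dict@dperp, "+")
  A <- exp(-b * adc)
  A[b == 0, ] <- 1
  A
}

#' Estimate a Gaussian mixture field from diffusion data
#'
#' Per masked voxel solves min_{w >= 0} ||A w - E||^2 + ridge ||w||^2 over
#' the shared dictionary (Lawson-Hanson active set on the ridge-augmented
#' system), then rescales the weights to sum one so each voxel's EAP is a
#' probability density. Voxels where the fit returns all-zero weights fall
#' back to the isotropic atom (last atom when the dictionary has one) and
#' are counted in the `"n_fallback"` attribute.
#'
#' @param dwi a [DWIVolume-class].
#' @param dict the shared [DiffusionDictionary-class] (fixed across the
#'   population).
#' @param mask optional logical 3D array restricting the fit; default is
#'   the S0 > 0 support.
#' @param ridge ridge penalty (default 1e-3).
#' @param max_components keep only the largest `max_components` weights
#'   per voxel (renormalised); under noise the active set can spread over
#'   many near-collinear atoms, and a compact mixture both denoises and
#'   bounds the cost of the closed-form mixture distance.
#' @return a [GMField-class].
#' @export
estimateGMF <- function(dwi, dict, mask = NULL, ridge = 1e-3,
                        max_components = 6) {
  E <- attenuation(dwi)
  valid <- attr(E, "valid")
  if (is.null(mask)) mask <- valid else mask <- mask & valid
  d <- dim(dwi@data)
  K <- nAtoms(dict)
  A <- designMatrix(dict, dwi@gradients)
  idx <- which(mask)
  Em <- matrix(E, prod(d[1:3]), d[4])[idx, , drop = FALSE]
  W <- cpp_nnls_batch(A, t(Em), ridge)            # K x Vmask
  ws <- colSums(W)
  nfall <- sum(ws <= 0)
  if (nfall > 0) {
    iso <- which(dict@dpar == dict@dperp)
    fallback_atom <- if (length(iso)) iso[1] else K
    W[, ws <= 0] <- 0
    W[fallback_atom, ws <= 0] <- 1
    ws[ws <= 0] <- 1
    warning(sprintf("%d voxels fell back to the isotropic atom", nfall))
  }
  if (is.finite(max_components) && max_components < K) {
    for (v in seq_len(ncol(W))) {
      wv <- W[, v]
      nz <- which(wv > 0)
      if (length(nz) > max_components) {
        drop_ <- nz[order(wv[nz], decreasing = TRUE)][-seq_len(max_components)]
        W[drop_, v] <- 0
      }
    }
    ws <- colSums(W)
  }
  W <- sweep(W, 2, ws, "/")
  weights <- matrix(0, prod(d[1:3]), K)
  weights[idx, ] <- t(W)
  dim(weights) <- c(d[1:3], K)
  out <- new("GMField", weights = weights, dictionary = dict,
             atomAxes = dict@axes, affine = dwi@affine,
             mask = array(mask, d[1:3]), axes = NULL)
  attr(out, "n_fallback") <- nfall
  out
}

#' Evaluate an EAP density
#'
#' P(r) = sum_k w~_k N(r; 0, C_k), the inverse Fourier transform of the
#' mixture attenuation model evaluated at displacement r (mm).
#'
#' @param gm a [GaussianMixture-class].
#' @param r displacement 3-vector (mm) or 3 x M matrix of displacements.
#' @return density value(s) (mm^-3).
#' @export
eapValue <- function(gm, r) {
  r <- as.matrix(r)
  if (nrow(r) != 3L) r <- t(r)
  w <- gm@weights / sum(gm@weights)
  out <- numeric(ncol(r))
  for (k in seq_along(w)) {
    if (w[k] == 0) next
    C <- gm@covariances[, , k]
    Ci <- solve(C)
    nc <- (2 * pi)^(-1.5) / sqrt(det(C))
    q <- colSums(r * (Ci %*% r))
    out <- out + w[k] * nc * exp(-0.5 * q)
  }
  out
}

# Gaussian product kernel c(A, B) = (2 pi)^{-3/2} det(A + B)^{-1/2}
.gmKernel <- function(A, B) (2 * pi)^(-1.5) / sqrt(det(A + B))

#' Closed-form L2 distance between two Gaussian mixtures
#'
#' dist^2 = sum_ij a_i a_j c(C_i, C_j) - 2 sum_ij a_i b_j c(C_i, C'_j)
#' + sum_ij b_i b_j c(C'_i, C'_j), with c(A, B) = (2 pi)^{-3/2}
#' det(A + B)^{-1/2} and weights normalised to sum one. Symmetric, zero iff
#' the densities are equal.
#'
#' @param gm1,gm2 [GaussianMixture-class] objects (covariances may differ,
#'   e.g. after reorientation).
#' @return nonnegative L2 distance (the examples in the tests report its
#'   square).
#' @export
gmL2Distance <- function(gm1, gm2) {
  for (gm in list(gm1, gm2))
    for (k in seq_along(gm@weights))
      if (min(eigen(gm@covariances[, , k], symmetric = TRUE,
                    only.values = TRUE)$values) <= 0)
        .validationError("component covariance is not SPD")
  a <- gm1@weights / sum(gm1@weights)
  b <- gm2@weights / sum(gm2@weights)
  term <- function(wa, Ca, wb, Cb) {
    s <- 0
    for (i in seq_along(wa)) {
      if (wa[i] == 0) next
      for (j in seq_along(wb)) {
        if (wb[j] == 0) next
        s <- s + wa[i] * wb[j] * .gmKernel(Ca[, , i], Cb[, , j])
      }
    }
    s
  }
  d2 <- term(a, gm1@covariances, a, gm1@covariances) +
        term(b, gm2@covariances, b, gm2@covariances) -
    2 * term(a, gm1@covariances, b, gm2@covariances)
  sqrt(max(d2, 0))
}

#' PPD reorientation of a Gaussian mixture
#'
#' Preservation of principal direction: each component covariance
#' C = V diag(s) V' is mapped to V' diag(s) V'' where the new frame is
#' e1' = F e1 / |F e1|, e2' = the F e2 component orthogonal to e1'
#' (normalised), e3' = e1' x e2', with F the local Jacobian (forward
#' convention) or its inverse transpose. Eigenvalues (component shape) are
#' preserved exactly; only the frame rotates.
#'
#' @param gm a [GaussianMixture-class].
#' @param J 3 x 3 Jacobian with det(J) > 0.
#' @param frame `"forward"` uses F = J; `"inverseTranspose"` uses
#'   F = t(solve(J)).
#' @return the reoriented [GaussianMixture-class] (same weights).
#' @export
reorientPPD <- function(gm, J, frame = c("forward", "inverseTranspose")) {
  frame <- match.arg(frame)
  if (abs(det(J)) < 1e-12) .validationError("singular Jacobian")
  if (det(J) <= 0) .validationError("PPD requires det(J) > 0")
  F <- if (frame == "forward") J else t(solve(J))
  K <- length(gm@weights)
  newcov <- gm@covariances
  for (k in seq_len(K)) {
    C <- gm@covariances[, , k]
    eg <- eigen(C, symmetric = TRUE)        # eigenvalues descending
    s <- eg$values
    if (abs(s[1] - s[3]) < 1e-14 * abs(s[1])) next   # isotropic: unchanged
    e1 <- eg$vectors[, 1]; e2 <- eg$vectors[, 2]
    f1 <- F %*% e1
    e1p <- f1 / sqrt(sum(f1^2))
    f2 <- F %*% e2
    f2 <- f2 - sum(f2 * e1p) * e1p
    n2 <- sqrt(sum(f2^2))
    e2p <- if (n2 > 1e-12) f2 / n2 else {
      # degenerate: any unit vector orthogonal to e1p
      v <- if (abs(e1p[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      v <- v - sum(v * e1p) * e1p
      v / sqrt(sum(v^2))
    }
    e3p <- c(e1p[2] * e2p[3] - e1p[3] * e2p[2],
             e1p[3] * e2p[1] - e1p[1] * e2p[3],
             e1p[1] * e2p[2] - e1p[2] * e2p[1])
    Vp <- cbind(e1p, e2p, e3p)
    newcov[, , k] <- Vp %*% diag(s) %*% t(Vp)
  }
  new("GaussianMixture", weights = gm@weights, covariances = newcov)
}

#' Extract the Gaussian mixture at one voxel of a field
#'
#' Honors per-voxel reoriented axes when present (exact [applyWarp()]
#' output).
#'
#' @param gmf a [GMField-class].
#' @param i,j,k 1-based voxel indices.
#' @return a [GaussianMixture-class].
#' @export
gmAt <- function(gmf, i, j, k) {
  w <- gmf@weights[i, j, k, ]
  if (all(w == 0)) .validationError("all-zero weights: undefined voxel")
  d <- dim(gmf@weights)
  K <- d[4]
  cp <- .covParams(gmf@dictionary)
  axes <- gmf@atomAxes
  if (!is.null(gmf@axes)) {
    vox <- i + d[1] * ((j - 1) + d[2] * (k - 1))
    axes <- matrix(gmf@axes[vox, ], nrow = 3)
  }
  covs <- array(0, c(3, 3, K))
  for (a in seq_len(K))
    covs[, , a] <- cp$p[a] * diag(3) + cp$q[a] * tcrossprod(axes[, a])
  gaussianMixture(w, covariances = covs)
}

# weights as a V x K matrix (internal)
.wmat <- function(gmf) {
  d <- dim(gmf@weights)
  matrix(gmf@weights, prod(d[1:3]), d[4])
}

.gmfDims <- function(gmf) as.integer(dim(gmf@weights)[1:3])
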