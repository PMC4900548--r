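# Construction of the shared diffusion dictionary: an n-frequency geodesic
# tessellation of the sphere, antipodally deduplicated to a hemisphere, with
# axially symmetric tensors on each direction plus one isotropic atom.

# vertices of an n-frequency subdivided icosahedron (10 n^2 + 2 points)
.icosphere <- function(freq) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1,12,6), c(1,6,2), c(1,2,8), c(1,8,11), c(1,11,12),
             c(2,6,10), c(6,12,5), c(12,11,3), c(11,8,7), c(8,2,9),
             c(4,10,5), c(4,5,3), c(4,3,7), c(4,7,9), c(4,9,10),
             c(5,10,6), c(3,5,12), c(7,3,11), c(9,7,8), c(10,9,2))
  pts <- list()
  for (t in seq_len(nrow(f))) {
    a <- v[f[t, 1], ]; b <- v[f[t, 2], ]; c3 <- v[f[t, 3], ]
    for (i in 0:freq) for (j in 0:(freq - i)) {
      k <- freq - i - j
      pts[[length(pts) + 1L]] <- (i * a + j * b + k * c3) / freq
    }
  }
  P <- do.call(rbind, pts)
  P <- P / sqrt(rowSums(P^2))
  P <- round(P, 10)
  unique(P)
}

# hemisphere representative: z > 0, or z = 0 & y > 0, or z = y = 0 & x > 0
.hemisphere <- function(P, tol = 1e-8) {
  keep <- P[, 3] > tol |
    (abs(P[, 3]) <= tol & P[, 2] > tol) |
    (abs(P[, 3]) <= tol & abs(P[, 2]) <= tol & P[, 1] > tol)
  P <- P[keep, , drop = FALSE]
  P[order(-P[, 3], P[, 2], P[, 1]), , drop = FALSE]
}

#' Hemisphere tessellation directions
#'
#' Vertices of an n-frequency geodesic subdivision of the icosahedron,
#' antipodally deduplicated; yields 5 freq^2 + 1 unit directions
#' (21, 46, 81, ... for freq = 2, 3, 4, ...).
#'
#' @param freq subdivision frequency (>= 1).
#' @return 3 x M matrix of unit columns.
#' @export
hemisphereDirections <- function(freq) t(.hemisphere(.icosphere(freq)))

#' Build the shared diffusion dictionary
#'
#' Atoms are D_k = (lambda_par - lambda_perp) u_k u_k' + lambda_perp I on
#' `n_orient` hemisphere directions, plus (optionally) one isotropic atom.
#' When `n_orient` equals 5 f^2 + 1 for integer f the directions are an
#' exact geodesic tessellation; otherwise the first `n_orient` directions
#' of the smallest covering tessellation are used.
#'
#' @param n_orient number of oriented atoms (default 46, the freq-3
#'   icosahedral hemisphere).
#' @param lambda_par,lambda_perp axial / radial diffusivity (mm^2/s);
#'   defaults are typical white-matter values.
#' @param tau effective diffusion time in ms; the default is
#'   Delta - delta/3 for the 42.4/10 ms monopolar timing.
#' @param include_isotropic add an isotropic atom of diffusivity
#'   `iso_diffusivity`.
#' @param iso_diffusivity isotropic atom diffusivity (mm^2/s).
#' @return a [DiffusionDictionary-class].
#' @export
buildDictionary <- function(n_orient = 46, lambda_par = 1.7e-3,
                            lambda_perp = 3e-4, tau = 42.4 - 10 / 3,
                            include_isotropic = TRUE,
                            iso_diffusivity = 2.0e-3) {
  if (n_orient < 1) .validationError("n_orient must be >= 1")
  if (lambda_perp <= 0 || lambda_par < lambda_perp)
    .validationError("need lambda_par >= lambda_perp > 0")
  if (n_orient == 1) {
    axes <- matrix(c(1, 0, 0), 3, 1)
  } else {
    freq <- 1
    while (5 * freq^2 + 1 < n_orient) freq <- freq + 1
    axes <- hemisphereDirections(freq)[, seq_len(n_orient), drop = FALSE]
  }
  dpar <- rep(lambda_par, n_orient)
  dperp <- rep(lambda_perp, n_orient)
  if (include_isotropic) {
    if (iso_diffusivity <= 0) .validationError("iso_diffusivity must be > 0")
    axes <- cbind(axes, c(0, 0, 1))
    dpar <- c(dpar, iso_diffusivity)
    dperp <- c(dperp, iso_diffusivity)
  }
  new("DiffusionDictionary", axes = axes, dpar = dpar, dperp = dperp, tau = tau)
}

#' Atom tensors of a dictionary
#'
#' @param dict a [DiffusionDictionary-class].
#' @return 3 x 3 x K array of diffusion tensors (mm^2/s).
#' @export
atomTensors <- function(dict) {
  K <- nAtoms(dict)
  out <- array(0, c(3, 3, K))
  for (k in seq_len(K)) {
    u <- dict@axes[, k]
    out[, , k] <- (dict@dpar[k] - dict@dperp[k]) * tcrossprod(u) +
      dict@dperp[k] * diag(3)
  }
  out
}

# EAP component covariances C_k = 2 tau D_k, tau converted ms -> s so the
# covariance is in mm^2. Returned as the axial parameterisation (p, q):
# C = p I + q u u'.
.covParams <- function(dict) {
  tau_s <- dict@tau * 1e-3
  list(p = 2 * tau_s * dict@dperp, q = 2 * tau_s * (dict@dpar - dict@dperp))
}

#' Component covariances of a dictionary
#'
#' The EAP of one atom with diffusion tensor D is N(0, 2 tau D); this
#' returns those covariances in mm^2.
#'
#' @param dict a [DiffusionDictionary-class].
#' @return 3 x 3 x K array.
#' @export
atomCovariances <- function(dict) {
  2 * (dict@tau * 1e-3) * atomTensors(dict)
}
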