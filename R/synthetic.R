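# Synthetic HARDI fixtures: phantoms with single-fiber, crossing-fiber and
# isotropic compartments (plus smooth compositional texture so registration
# has signal everywhere), random diffeomorphic warps, and labelled
# two-class populations with a planted localized effect. Every generator
# is a pure function of (spec, seed) and returns its ground truth.

#' Electrostatically spread gradient directions
#'
#' Deterministic: golden-angle hemisphere initialisation followed by
#' Coulomb repulsion descent under antipodal symmetry.
#'
#' @param n number of directions.
#' @param n_iter repulsion iterations.
#' @return 3 x n matrix of unit columns.
#' @export
spreadDirections <- function(n = 64, n_iter = 300) {
  i <- seq_len(n)
  z <- (i - 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(1 - z^2)
  P <- rbind(r * cos(phi), r * sin(phi), z)
  # Coulomb energy over all pairs including antipodes
  energy <- function(P) {
    G <- crossprod(P)
    D1 <- 2 - 2 * G; D2 <- 2 + 2 * G
    diag(D1) <- Inf
    sum(1 / sqrt(D1[upper.tri(D1)])) + sum(1 / sqrt(D2[upper.tri(D2)])) +
      sum(1 / sqrt(diag(D2))) / 2
  }
  force <- function(P) {
    F <- matrix(0, 3, n)
    for (a in seq_len(n)) {
      d1 <- P - P[, a]; d2 <- -P - P[, a]
      n1 <- colSums(d1^2); n2 <- pmax(colSums(d2^2), 1e-12)
      n1[a] <- Inf
      f <- rowSums(sweep(d1, 2, n1^1.5, "/")) +
           rowSums(sweep(d2, 2, n2^1.5, "/"))
      F[, a] <- f - sum(f * P[, a]) * P[, a]   # tangential component
    }
    F
  }
  E <- energy(P)
  step <- 0.1
  for (it in seq_len(n_iter)) {
    F <- force(P)
    fm <- max(sqrt(colSums(F^2)))
    if (fm < 1e-12) break
    repeat {
      Pn <- P - (step / fm) * F
      Pn <- sweep(Pn, 2, sqrt(colSums(Pn^2)), "/")
      En <- energy(Pn)
      if (En < E || step < 1e-6) break
      step <- step / 2
    }
    if (En >= E) break
    P <- Pn; E <- En; step <- step * 1.3
  }
  P
}

#' Phantom specification
#'
#' The phantom emulates the acquisition geometry of the study it stands in
#' for: 64 spread directions at b = 1000 s/mm^2 plus one b = 0 volume, at
#' desk scale (default 32 x 32 x 16 rather than 112 x 112 x 60). Layout:
#' a single-fiber bundle along x, a 90-degree crossing region, and
#' isotropic-dominated background, all modulated by a smooth sinusoidal
#' partial-volume texture.
#'
#' @param shape grid dimensions.
#' @param snr Rician signal-to-noise ratio at b = 0 (`Inf` = noise-free).
#' @param s0 b = 0 signal level.
#' @param seed RNG seed for the noise.
#' @param bval diffusion weighting (s/mm^2).
#' @param n_dirs number of gradient directions.
#' @return a named list.
#' @export
phantomSpec <- function(shape = c(32, 32, 16), snr = 20, s0 = 1000,
                        seed = 1, bval = 1000, n_dirs = 64) {
  if (snr <= 0) .validationError("snr must be positive")
  list(shape = as.integer(shape), snr = snr, s0 = s0, seed = seed,
       bval = bval, n_dirs = n_dirs)
}

.phantomGradients <- function(spec) {
  dirs <- spreadDirections(spec$n_dirs)
  gradientTable(c(0, rep(spec$bval, spec$n_dirs)),
                cbind(c(0, 0, 0), dirs))
}

# nearest anisotropic dictionary atom to a direction
.nearestAtom <- function(dict, u) {
  aniso <- which(dict@dpar > dict@dperp)
  dots <- abs(as.vector(crossprod(dict@axes[, aniso, drop = FALSE], u)))
  aniso[which.max(dots)]
}

# ground-truth weight field of the phantom layout
.phantomTruth <- function(spec, dict) {
  dims <- spec$shape
  V <- prod(dims)
  K <- nAtoms(dict)
  X <- .gridCoords(dims)
  yf <- (X[, 2] + 0.5) / dims[2]
  tex <- sin(2 * pi * X[, 1] / 7.3) * sin(2 * pi * X[, 2] / 8.1) *
    sin(2 * pi * X[, 3] / 6.3)
  iso <- which(dict@dpar == dict@dperp)[1]
  if (is.na(iso)) .validationError("phantom needs an isotropic atom")
  ax <- .nearestAtom(dict, c(1, 0, 0))
  ay <- .nearestAtom(dict, c(0, 1, 0))
  W <- matrix(0, V, K)
  single <- yf >= 0.10 & yf < 0.45
  crossing <- yf >= 0.55 & yf < 0.90
  bg <- !(single | crossing)
  isof <- 0.25 + 0.12 * tex
  W[single, iso] <- isof[single]
  W[single, ax] <- 1 - isof[single]
  W[crossing, iso] <- isof[crossing]
  W[crossing, ax] <- (1 - isof[crossing]) / 2
  W[crossing, ay] <- (1 - isof[crossing]) / 2
  fibf <- 0.15 + 0.10 * tex
  W[bg, ax] <- fibf[bg]
  W[bg, iso] <- 1 - fibf[bg]
  W
}

#' Synthesise a diffusion-weighted volume from a mixture field
#'
#' Per-voxel signal S = s0 * E with E from the forward attenuation model;
#' Rician noise sqrt((S + n1)^2 + n2^2), n ~ N(0, (s0/snr)^2), is added
#' unless `snr = Inf`. Voxels with zero weight mass get zero signal.
#'
#' @param gmf a [GMField-class] (weights normalised per voxel).
#' @param gradients a [GradientTable-class].
#' @param s0 b = 0 signal level.
#' @param snr Rician SNR at b = 0.
#' @param seed RNG seed for the noise.
#' @return a [DWIVolume-class].
#' @export
signalFromGMF <- function(gmf, gradients, s0 = 1000, snr = 20, seed = 1) {
  dims <- .gmfDims(gmf)
  W <- .wmat(gmf)
  A <- designMatrix(gmf@dictionary, gradients)
  s <- rowSums(W)
  Wn <- W
  Wn[s > 0, ] <- W[s > 0, , drop = FALSE] / s[s > 0]
  S <- s0 * (Wn %*% t(A))
  S[s == 0, ] <- 0
  if (is.finite(snr)) {
    set.seed(seed)
    sigma <- s0 / snr
    n1 <- matrix(rnorm(length(S), sd = sigma), nrow(S))
    n2 <- matrix(rnorm(length(S), sd = sigma), nrow(S))
    S <- sqrt((S + n1)^2 + n2^2)
    S[s == 0, ] <- 0
  }
  dwiVolume(array(S, c(dims, ncol(S))), gmf@affine, gradients)
}

#' Generate a HARDI phantom with its ground truth
#'
#' @param spec a [phantomSpec()] list.
#' @param dict the shared [DiffusionDictionary-class].
#' @return list with `dwi` (a [DWIVolume-class]), `truth` (the generating
#'   [GMField-class]), `gradients`, and `spec`.
#' @export
makePhantom <- function(spec = phantomSpec(), dict = buildDictionary()) {
  dims <- spec$shape
  W <- .phantomTruth(spec, dict)
  truth <- new("GMField", weights = array(W, c(dims, ncol(W))),
               dictionary = dict, atomAxes = dict@axes, affine = diag(4),
               mask = array(rowSums(W) > 0, dims), axes = NULL)
  grads <- .phantomGradients(spec)
  dwi <- signalFromGMF(truth, grads, spec$s0, spec$snr, spec$seed)
  list(dwi = dwi, truth = truth, gradients = grads, spec = spec)
}

# smooth boundary taper: 0 at the faces, 1 beyond `band` voxels inside
.boundaryTaper <- function(dims, band = 3) {
  X <- .gridCoords(dims)
  w <- rep(1, nrow(X))
  for (a in 1:3) {
    dist <- pmin(X[, a], dims[a] - 1 - X[, a]) / band
    t <- pmin(pmax(dist, 0), 1)
    w <- w * t * t * (3 - 2 * t)
  }
  w
}

#' Random smooth diffeomorphic deformation
#'
#' Gaussian-smoothed white-noise displacement, tapered to zero in a band
#' at the boundary and rescaled to the requested peak amplitude; the
#' amplitude is reduced geometrically until det(I + grad d) > 0 holds
#' everywhere (an error is raised if that fails).
#'
#' @param shape grid dimensions.
#' @param amplitude peak displacement (voxels); 0 gives the identity.
#' @param smoothness Gaussian smoothing width (voxels).
#' @param seed RNG seed.
#' @param boundary width of the zero-displacement boundary band (voxels).
#' @return a [DeformationField-class] with positive Jacobian determinant.
#' @export
makeRandomDiffeo <- function(shape, amplitude, smoothness = 4, seed = 1,
                             boundary = 3) {
  dims <- as.integer(shape)
  V <- prod(dims)
  if (amplitude == 0)
    return(identityDeformation(dims))
  set.seed(seed)
  d <- matrix(rnorm(V * 3), V, 3)
  d <- cpp_smooth3(d, dims, smoothness)
  d <- d * .boundaryTaper(dims, boundary)
  mx <- sqrt(max(rowSums(d^2)))
  d <- d * (amplitude / mx)
  for (try in 1:25) {
    if (min(cpp_det3(cpp_jacobian(d, dims))) > 0.05)
      return(deformationField(array(d, c(dims, 3))))
    d <- d * 0.8
  }
  .validationError("could not achieve det(J) > 0 at this amplitude")
}

#' Population of warped, noised phantom copies
#'
#' n members, each an independently warped (amplitude `warp_amplitude`)
#' and independently Rician-noised copy of one base phantom; ground truth
#' (warped mixture field and deformation) is returned per member.
#'
#' @param n number of subjects (>= 2).
#' @param spec a [phantomSpec()] list.
#' @param warp_amplitude inter-subject deformation amplitude (voxels).
#' @param seed master seed; member seeds are derived from it.
#' @param dict the shared dictionary.
#' @return list of members, each with `dwi`, `gmf_true`, `deformation`.
#' @export
makePopulation <- function(n, spec = phantomSpec(), warp_amplitude = 1,
                           seed = 1, dict = buildDictionary()) {
  if (n < 2) .validationError("need n >= 2")
  base <- makePhantom(spec, dict)
  lapply(seq_len(n), function(i) {
    Ti <- makeRandomDiffeo(spec$shape, warp_amplitude, smoothness = 4,
                           seed = seed * 1000L + i)
    truth_i <- applyWarp(base$truth, Ti)
    dwi <- signalFromGMF(truth_i, base$gradients, spec$s0, spec$snr,
                         seed = seed * 1000L + 500L + i)
    list(dwi = dwi, gmf_true = truth_i, deformation = Ti)
  })
}

#' Planted-effect specification
#'
#' A sub-box standing in for the substantia-nigra ROI, inside which the
#' patient class receives an extra localized effect: a diffeomorphic warp
#' (`shape = "compress"` pulls tissue toward the block centre;
#' `shape = "twist"` rotates it about z), an in-place rotation of the
#' fiber orientations (pure reorientation: no anisotropy or position
#' change), and/or a transfer of `anisotropy_delta` of the fiber weight
#' to the isotropic atom (anisotropy reduction). The rotation is smoothly
#' tapered by the block's Gaussian envelope and applied antisymmetrically
#' (controls get -`rotation_angle`/2, patients +`rotation_angle`/2), so
#' the between-class orientation difference is the full angle while the
#' orientation-gradient statistics -- and with them every partial-volume
#' effect a scalar FA map could see -- are identical across classes.
#'
#' @param roi_lo,roi_hi 1-based inclusive corners of the block (defaults:
#'   a centred 6 x 6 x 4 block for `shape_grid`).
#' @param shape_grid grid the block defaults are computed for.
#' @param warp_amplitude peak effect displacement (voxels).
#' @param anisotropy_delta fraction of fiber weight moved to isotropic.
#' @param rotation_angle in-place fiber rotation (degrees, about z).
#' @param shape effect warp geometry.
#' @return a named list.
#' @export
effectSpec <- function(roi_lo = NULL, roi_hi = NULL,
                       shape_grid = c(32, 32, 16), warp_amplitude = 1.5,
                       anisotropy_delta = 0, rotation_angle = 0,
                       shape = c("compress", "twist")) {
  shape <- match.arg(shape)
  bs <- c(6, 6, 4)
  if (is.null(roi_lo)) roi_lo <- pmax(1, floor((shape_grid - bs) / 2) + 1)
  if (is.null(roi_hi)) roi_hi <- pmin(shape_grid, roi_lo + bs - 1)
  if (any(roi_lo < 1) || any(roi_hi > shape_grid) || any(roi_lo > roi_hi))
    .validationError("effect block must lie inside the grid")
  if (warp_amplitude < 0) .validationError("warp amplitude must be >= 0")
  list(roi_lo = as.integer(roi_lo), roi_hi = as.integer(roi_hi),
       warp_amplitude = warp_amplitude, anisotropy_delta = anisotropy_delta,
       rotation_angle = rotation_angle, shape = shape)
}

#' ROI mask of the planted effect block
#'
#' @param dims grid dimensions.
#' @param effect an [effectSpec()] list.
#' @param margin dilation in voxels (captures boundary strain).
#' @return an [ROIMask-class].
#' @export
effectROI <- function(dims, effect, margin = 2) {
  lo <- pmax(1, effect$roi_lo - margin)
  hi <- pmin(dims, effect$roi_hi + margin)
  m <- array(FALSE, dims)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  roiMask(m)
}

# localized effect warp centred on the block
.effectWarp <- function(dims, effect) {
  if (effect$warp_amplitude == 0) return(matrix(0, prod(dims), 3))
  ctr <- (effect$roi_lo + effect$roi_hi) / 2 - 1   # 0-based centre
  hw <- pmax((effect$roi_hi - effect$roi_lo) / 2 + 1, 1)
  X <- .gridCoords(dims)
  Z <- sweep(X, 2, ctr)
  rho2 <- rowSums(sweep(Z, 2, hw, "/")^2)
  # Gaussian envelope, tightened relative to the block half-width and
  # with a compact smoothstep cutoff: the strain stays confined to the
  # block plus a small collar instead of trailing off in long tails
  rho <- 1.4 * sqrt(rho2)
  cut <- pmin(pmax((2.2 - rho) / 0.5, 0), 1)
  env <- exp(-rho^2 / 2) * cut * cut * (3 - 2 * cut)
  if (effect$shape == "compress") {
    d <- -Z * env
  } else {                                          # twist about z
    th <- 90 * pi / 180 * env
    d <- cbind(cos(th) * Z[, 1] - sin(th) * Z[, 2] - Z[, 1],
               sin(th) * Z[, 1] + cos(th) * Z[, 2] - Z[, 2],
               0)
  }
  mx <- sqrt(max(rowSums(d^2)))
  d <- d * (effect$warp_amplitude / mx)
  for (try in 1:25) {
    if (min(cpp_det3(cpp_jacobian(d, as.integer(dims)))) > 0.05) return(d)
    d <- d * 0.8
  }
  .validationError("effect warp amplitude too large for det(J) > 0")
}

# in-place rotation of fiber orientations about z, smoothly tapered by the
# block's Gaussian envelope (angle `sign * rotation_angle` at the centre,
# fading to zero outside); weights move to the dictionary atom nearest the
# rotated axis. The smooth taper avoids a sharp orientation discontinuity
# at the block edge, which warping would otherwise turn into a genuine
# (FA-visible) partial-volume crossing.
.rotateOrientations <- function(W, dims, dict, effect, sign = 1) {
  ctr <- (effect$roi_lo + effect$roi_hi) / 2 - 1
  hw <- pmax((effect$roi_hi - effect$roi_lo) / 2 + 1, 1)
  X <- .gridCoords(dims)
  rho2 <- rowSums(sweep(sweep(X, 2, ctr), 2, hw, "/")^2)
  th_all <- sign * effect$rotation_angle * pi / 180 * exp(-rho2 / 2)
  act <- which(abs(th_all) > 0.5 * pi / 180)
  aniso <- which(dict@dpar > dict@dperp)
  A <- dict@axes[, aniso, drop = FALSE]
  for (v in act) {
    wv <- W[v, aniso]
    nz <- which(wv > 0)
    if (!length(nz)) next
    th <- th_all[v]
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    wnew <- numeric(length(aniso))
    for (a in nz) {
      tgt <- which.max(abs(crossprod(A, R %*% A[, a])))
      wnew[tgt] <- wnew[tgt] + wv[a]
    }
    W[v, aniso] <- wnew
  }
  W
}

#' Labelled two-class phantom population
#'
#' Controls are warped/noised copies of the base phantom; patients
#' additionally carry the planted localized effect of `effect` inside its
#' block (applied to the ground truth before the subject-level warp).
#'
#' @param n_ctrl,n_pat class sizes (each >= 2).
#' @param spec a [phantomSpec()] list.
#' @param effect an [effectSpec()] list.
#' @param seed master seed.
#' @param subject_warp inter-subject deformation amplitude (voxels).
#' @param dict the shared dictionary.
#' @return list with `members` (as in [makePopulation()]), `labels`
#'   (0 = control, 1 = patient), and `effect`.
#' @export
makeTwoClassPopulation <- function(n_ctrl, n_pat, spec = phantomSpec(),
                                   effect = effectSpec(shape_grid = spec$shape),
                                   seed = 1, subject_warp = 1,
                                   dict = buildDictionary()) {
  if (n_ctrl < 2 || n_pat < 2) .validationError("need >= 2 per class")
  base <- makePhantom(spec, dict)
  dims <- spec$shape
  Wctrl <- .wmat(base$truth)
  Wpat <- Wctrl
  if (effect$rotation_angle != 0) {
    # antisymmetric construction: controls carry a -angle/2 swirl and
    # patients +angle/2, so the between-class orientation difference is
    # the full angle while the orientation-gradient statistics (and hence
    # all partial-volume effects on FA) are identical across classes
    eff2 <- effect
    eff2$rotation_angle <- effect$rotation_angle / 2
    Wctrl <- .rotateOrientations(Wctrl, dims, dict, eff2, sign = -1)
    Wpat <- .rotateOrientations(Wpat, dims, dict, eff2, sign = 1)
  }
  if (effect$anisotropy_delta != 0) {
    lo <- effect$roi_lo; hi <- effect$roi_hi
    X <- .gridCoords(dims)
    inblk <- X[, 1] >= lo[1] - 1 & X[, 1] <= hi[1] - 1 &
             X[, 2] >= lo[2] - 1 & X[, 2] <= hi[2] - 1 &
             X[, 3] >= lo[3] - 1 & X[, 3] <= hi[3] - 1
    iso <- which(dict@dpar == dict@dperp)[1]
    aniso <- which(dict@dpar > dict@dperp)
    moved <- effect$anisotropy_delta *
      rowSums(Wpat[inblk, aniso, drop = FALSE])
    Wpat[inblk, aniso] <- Wpat[inblk, aniso] * (1 - effect$anisotropy_delta)
    Wpat[inblk, iso] <- Wpat[inblk, iso] + moved
  }
  truth_pat <- new("GMField", weights = array(Wpat, c(dims, ncol(Wpat))),
                   dictionary = dict, atomAxes = dict@axes,
                   affine = diag(4), mask = base$truth@mask, axes = NULL)
  truth_ctrl <- new("GMField", weights = array(Wctrl, c(dims, ncol(Wctrl))),
                    dictionary = dict, atomAxes = dict@axes,
                    affine = diag(4), mask = base$truth@mask, axes = NULL)
  d_eff <- .effectWarp(dims, effect)
  members <- vector("list", n_ctrl + n_pat)
  labels <- c(rep(0L, n_ctrl), rep(1L, n_pat))
  for (i in seq_along(members)) {
    Ti <- makeRandomDiffeo(dims, subject_warp, smoothness = 4,
                           seed = seed * 1000L + i)
    if (labels[i] == 1L) {
      dtot <- cpp_compose_disp(.dispMat(Ti), d_eff, as.integer(dims))
      Ti <- deformationField(array(dtot, c(dims, 3)))
      truth_i <- applyWarp(truth_pat, Ti)
    } else {
      truth_i <- applyWarp(truth_ctrl, Ti)
    }
    dwi <- signalFromGMF(truth_i, base$gradients, spec$s0, spec$snr,
                         seed = seed * 1000L + 500L + i)
    members[[i]] <- list(dwi = dwi, gmf_true = truth_i, deformation = Ti)
  }
  list(members = members, labels = labels, effect = effect,
       gradients = base$gradients, base = base)
}
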