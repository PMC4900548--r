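# shared fixtures: small dictionaries, random SPD matrices, a brute-force
# quadrature oracle for the mixture L2 distance, and small gradient tables

tinyDict <- function(n_orient = 21, ...) buildDictionary(n_orient, ...)

randSPD <- function(scale = 1, lo = 0.5, hi = 2) {
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  ev <- runif(3, lo, hi) * scale
  Q %*% diag(ev) %*% t(Q)
}

randMixture <- function(k = 3, scale = 1) {
  covs <- array(0, c(3, 3, k))
  for (i in seq_len(k)) covs[, , i] <- randSPD(scale)
  gaussianMixture(runif(k, 0.2, 1), covariances = covs)
}

# brute-force 3D quadrature of the L2 distance between two mixture densities
quadL2 <- function(gm1, gm2, n = 61, span = 4) {
  smax <- sqrt(max(apply(gm1@covariances, 3, function(C) max(eigen(C)$values)),
                   apply(gm2@covariances, 3, function(C) max(eigen(C)$values))))
  L <- span * smax
  x <- seq(-L, L, length.out = n)
  h <- x[2] - x[1]
  G <- as.matrix(expand.grid(x, x, x))
  diff <- eapValue(gm1, t(G)) - eapValue(gm2, t(G))
  sqrt(sum(diff^2) * h^3)
}

# gradient table of nb0 zero volumes plus spread directions at b
testGradients <- function(n_dirs = 64, b = 1000, nb0 = 1) {
  dirs <- spreadDirections(n_dirs)
  gradientTable(c(rep(0, nb0), rep(b, n_dirs)),
                cbind(matrix(0, 3, nb0), dirs))
}

# DWI volume synthesised from constant dictionary weights on a small grid
uniformDWI <- function(weights, dict, dims = c(4, 4, 4), gradients = NULL,
                       s0 = 1000) {
  if (is.null(gradients)) gradients <- testGradients()
  E <- predictAttenuation(dict, weights, gradients)
  data <- array(rep(s0 * E, each = prod(dims)), c(dims, length(E)))
  dwiVolume(data, diag(4), gradients)
}

# random CDT-like field: exp of small random symmetric matrices, iid voxels
randCDTField <- function(roi, sd = 0.15, id = "s") {
  V <- nVoxels(roi)
  tens <- matrix(0, V, 6)
  for (v in seq_len(V)) {
    S <- matrix(rnorm(9, sd = sd), 3); S <- (S + t(S)) / 2
    eg <- eigen(S, symmetric = TRUE)
    M <- eg$vectors %*% diag(exp(eg$values)) %*% t(eg$vectors)
    tens[v, ] <- c(M[1,1], M[1,2], M[2,2], M[1,3], M[2,3], M[3,3])
  }
  new("CDTField", tensors = tens, roi = roi, subjectId = id)
}

# spherical ROI with exactly n voxels on a grid
sphereROI <- function(dims, n) {
  X <- expand.grid(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
  ctr <- (dims + 1) / 2
  d2 <- (X[, 1] - ctr[1])^2 + (X[, 2] - ctr[2])^2 + (X[, 3] - ctr[3])^2
  m <- array(FALSE, dims)
  m[order(d2)[seq_len(n)]] <- TRUE
  roiMask(m)
}
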