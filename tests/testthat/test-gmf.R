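test_that("dictionary construction follows the axial tensor formula", {
  d <- buildDictionary(n_orient = 1, lambda_par = 1.7e-3,
                       lambda_perp = 0.3e-3, include_isotropic = FALSE)
  expect_equal(atomTensors(d)[, , 1], diag(c(1.7e-3, 0.3e-3, 0.3e-3)))
  # equal eigenvalues give the isotropic tensor whatever the orientation
  di <- buildDictionary(n_orient = 21, lambda_par = 1e-3, lambda_perp = 1e-3,
                        include_isotropic = FALSE)
  for (k in c(1, 10, 21))
    expect_equal(atomTensors(di)[, , k], 1e-3 * diag(3), tolerance = 1e-18)
  # tessellation counts: 5 f^2 + 1 hemisphere points, +1 isotropic atom
  expect_equal(ncol(hemisphereDirections(2)), 21)
  expect_equal(ncol(hemisphereDirections(3)), 46)
  expect_equal(nAtoms(buildDictionary(n_orient = 321)), 322)
  expect_error(buildDictionary(lambda_perp = 0),
               class = "cdtmorph_validation_error")
  expect_error(buildDictionary(lambda_par = 1e-4, lambda_perp = 3e-4),
               class = "cdtmorph_validation_error")
})

test_that("forward attenuation matches the scalar exponential model", {
  d <- buildDictionary(n_orient = 1, lambda_par = 1.7e-3,
                       lambda_perp = 0.3e-3, include_isotropic = FALSE)
  gt <- gradientTable(c(0, 1000, 1000),
                      cbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  E <- predictAttenuation(d, 1, gt)
  expect_equal(E, c(1, exp(-1.7), exp(-0.3)), tolerance = 1e-12)
  # weights normalised internally: scaling weights changes nothing
  expect_equal(predictAttenuation(d, 5, gt), E)
  expect_error(predictAttenuation(d, 0, gt),
               class = "cdtmorph_validation_error")
})

test_that("mixture estimation recovers planted dictionary weights", {
  dict <- tinyDict()
  K <- nAtoms(dict)
  # single atom
  w <- numeric(K); w[4] <- 1
  g <- estimateGMF(uniformDWI(w, dict), dict, ridge = 0)
  expect_gte(g@weights[2, 2, 2, 4], 0.99)
  # 50/50 mix of two near-orthogonal atoms
  ax <- which.max(abs(crossprod(dict@axes, c(1, 0, 0))[seq_len(K - 1), ]))
  ay <- which.max(abs(crossprod(dict@axes, c(0, 1, 0))[seq_len(K - 1), ]))
  w2 <- numeric(K); w2[c(ax, ay)] <- 0.5
  g2 <- estimateGMF(uniformDWI(w2, dict), dict, ridge = 0)
  expect_gte(g2@weights[2, 2, 2, ax], 0.4)
  expect_lte(g2@weights[2, 2, 2, ax], 0.6)
  expect_gte(g2@weights[2, 2, 2, ay], 0.4)
  # pure isotropic signal: isotropic atom dominates
  wi <- numeric(K); wi[K] <- 1
  g3 <- estimateGMF(uniformDWI(wi, dict), dict, ridge = 0)
  expect_equal(which.max(g3@weights[2, 2, 2, ]), K)
})

test_that("estimation depends only on attenuation (signal-scale equivariance)", {
  dict <- tinyDict()
  w <- numeric(nAtoms(dict)); w[c(3, 9)] <- c(0.7, 0.3)
  dwi1 <- uniformDWI(w, dict, s0 = 800)
  dwi2 <- dwiVolume(2.5 * dwi1@data, dwi1@affine, dwi1@gradients)
  g1 <- estimateGMF(dwi1, dict)
  g2 <- estimateGMF(dwi2, dict)
  expect_equal(g1@weights, g2@weights, tolerance = 1e-9)
})

test_that("hand-written NNLS agrees with the reference active-set solver", {
  skip_if_not_installed("pracma")
  set.seed(42)
  for (t in 1:10) {
    A <- matrix(runif(30 * 8), 30, 8)
    b <- as.vector(A %*% pmax(rnorm(8), 0) + rnorm(30, sd = 0.05))
    mine <- cdtmorph:::cpp_nnls(A, b, 0)
    ref <- pracma::lsqnonneg(A, b)$x
    expect_equal(as.vector(mine), ref, tolerance = 1e-6)
  }
})

test_that("EAP density has the Gaussian closed form and unit mass", {
  set.seed(3)
  C <- randSPD()
  gm <- gaussianMixture(1, covariances = array(C, c(3, 3, 1)))
  expect_equal(eapValue(gm, c(0, 0, 0)),
               (2 * pi)^(-1.5) / sqrt(det(C)), tolerance = 1e-12)
  # mixture value is the weight-average of component values
  gm2 <- randMixture(3)
  r <- c(0.3, -0.2, 0.5)
  vals <- vapply(1:3, function(k)
    eapValue(gaussianMixture(1, covariances = gm2@covariances[, , k,
                                                              drop = FALSE]),
             r), numeric(1))
  w <- gm2@weights / sum(gm2@weights)
  expect_equal(eapValue(gm2, r), sum(w * vals), tolerance = 1e-12)
  # numeric quadrature of the density integrates to 1
  smax <- sqrt(max(apply(gm2@covariances, 3,
                         function(C) max(eigen(C)$values))))
  x <- seq(-5 * smax, 5 * smax, length.out = 61)
  G <- as.matrix(expand.grid(x, x, x))
  mass <- sum(eapValue(gm2, t(G))) * (x[2] - x[1])^3
  expect_equal(mass, 1, tolerance = 1e-3)
})

test_that("closed-form mixture L2 distance matches quadrature and theory", {
  # single-Gaussian pair with a hand-computable value
  gm1 <- gaussianMixture(1, covariances = array(diag(3), c(3, 3, 1)))
  gm2 <- gaussianMixture(1, covariances = array(4 * diag(3), c(3, 3, 1)))
  d2 <- (2 * pi)^(-1.5) * (8^-0.5 + 512^-0.5 - 2 * 125^-0.5)
  expect_equal(gmL2Distance(gm1, gm2)^2, d2, tolerance = 1e-12)
  expect_equal(gmL2Distance(gm1, gm2), quadL2(gm1, gm2), tolerance = 1e-2)
  # identity of indiscernibles and symmetry on random mixtures
  set.seed(4)
  for (t in 1:5) {
    a <- randMixture(3); b <- randMixture(2)
    expect_equal(gmL2Distance(a, a), 0, tolerance = 1e-8)
    expect_equal(gmL2Distance(a, b), gmL2Distance(b, a), tolerance = 1e-12)
    expect_equal(gmL2Distance(a, b), quadL2(a, b), tolerance = 1e-2)
  }
})

test_that("PPD reorientation preserves shape and reduces to conjugation for rotations", {
  set.seed(5)
  gm <- randMixture(3)
  # identity leaves the mixture unchanged
  gi <- reorientPPD(gm, diag(3))
  expect_equal(gi@covariances, gm@covariances, tolerance = 1e-12)
  # a rotation conjugates every component
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  gr <- reorientPPD(gm, R)
  for (k in 1:3)
    expect_equal(gr@covariances[, , k],
                 R %*% gm@covariances[, , k] %*% t(R), tolerance = 1e-10)
  # general Jacobian: eigenvalues exactly preserved
  J <- diag(3) + 0.3 * matrix(rnorm(9), 3)
  if (det(J) > 0) {
    gj <- reorientPPD(gm, J)
    for (k in 1:3)
      expect_equal(eigen(gj@covariances[, , k])$values,
                   eigen(gm@covariances[, , k])$values, tolerance = 1e-12)
  }
  expect_error(reorientPPD(gm, diag(c(1, 1, -1))),
               class = "cdtmorph_validation_error")
})

test_that("rotations form a group under PPD (inverse restores exactly)", {
  set.seed(6)
  gm <- randMixture(2)
  ang <- runif(3, -1, 1)
  Rx <- cdtmorph:::.eulerRotation(ang)
  back <- reorientPPD(reorientPPD(gm, Rx), t(Rx))
  expect_equal(back@covariances, gm@covariances, tolerance = 1e-10)
})
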