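test_that("Jacobian field: identity, linear and affine displacement fields", {
  dims <- c(8, 8, 8)
  expect_equal(jacobianField(identityDeformation(dims))@J[3, 4, 5, ],
               as.vector(diag(3)), tolerance = 1e-14)
  # d = (0.1 x1, 0, 0) -> J = diag(1.1, 1, 1)
  X <- cdtmorph:::.gridCoords(dims)
  d1 <- array(cbind(0.1 * X[, 1], 0, 0), c(dims, 3))
  J1 <- jacobianField(deformationField(d1))
  expect_equal(J1@J[4, 4, 4, ], as.vector(diag(c(1.1, 1, 1))),
               tolerance = 1e-12)
  # affine d = A x -> J = I + A at interior voxels to machine precision
  A <- matrix(c(0.05, 0.02, 0, -0.01, 0.03, 0.01, 0, 0.02, -0.04), 3, 3)
  dA <- array(X %*% t(A), c(dims, 3))
  JA <- jacobianField(deformationField(dA))
  expect_equal(matrix(JA@J[5, 3, 6, ], 3, 3), diag(3) + A,
               tolerance = 1e-12)
})

test_that("smoothness penalty: zero at identity, log-det term, asymmetry", {
  dims <- c(6, 6, 6)
  expect_equal(smoothnessPenalty(identityDeformation(dims)), 0)
  # uniform det = 2 via d = (x1, 0, 0): det term log(2) * (2 - 1) * V
  X <- cdtmorph:::.gridCoords(dims)
  Texp <- deformationField(array(cbind(X[, 1], 0, 0), c(dims, 3)))
  V <- prod(dims)
  p1 <- smoothnessPenalty(Texp, registrationConfig(lam = 1))
  p0 <- smoothnessPenalty(Texp, registrationConfig(lam = 0))
  expect_equal(p1 - p0, log(2) * V, tolerance = 1e-8)
  # the det term is asymmetric in det vs 1/det
  Tshr <- deformationField(array(cbind(-0.5 * X[, 1], 0, 0), c(dims, 3)))
  q1 <- smoothnessPenalty(Tshr, registrationConfig(lam = 1))
  q0 <- smoothnessPenalty(Tshr, registrationConfig(lam = 0))
  expect_false(isTRUE(all.equal(p1 - p0, q1 - q0)))
  expect_equal(q1 - q0, log(0.5) * (0.5 - 1) * V, tolerance = 1e-8)
  # folding is rejected with an infinite penalty
  Tfold <- deformationField(array(cbind(-1.5 * X[, 1], 0, 0), c(dims, 3)))
  expect_equal(smoothnessPenalty(Tfold), Inf)
})

test_that("data energy: zero for identical aligned fields, nonnegative", {
  dict <- tinyDict()
  ph <- makePhantom(phantomSpec(shape = c(10, 10, 6), snr = Inf), dict)
  # the kernel scale is ~1e5 per voxel, so "zero" means zero relative to it
  expect_lt(dataEnergy(ph$truth, ph$truth), 1e-4)
  T1 <- makeRandomDiffeo(c(10, 10, 6), 1, seed = 2)
  expect_gt(dataEnergy(ph$truth, ph$truth, T1), 0)
  other <- makePhantom(phantomSpec(shape = c(8, 8, 8), snr = Inf), dict)
  expect_error(dataEnergy(other$truth, ph$truth),
               class = "cdtmorph_validation_error")
})

test_that("self-registration stays at identity", {
  dict <- tinyDict()
  ph <- makePhantom(phantomSpec(shape = c(12, 12, 8), snr = Inf), dict)
  reg <- nonrigidRegister(ph$truth, ph$truth, registrationConfig())
  expect_lt(max(abs(reg$deformation@disp)), 0.1)
})

test_that("registration recovers a small synthetic warp with det(J) > 0", {
  dict <- tinyDict()
  dims <- c(16, 16, 12)
  ph <- makePhantom(phantomSpec(shape = dims, snr = Inf), dict)
  Tt <- makeRandomDiffeo(dims, amplitude = 1.2, smoothness = 3.5, seed = 9)
  fixed <- applyWarp(ph$truth, Tt)
  reg <- nonrigidRegister(ph$truth, fixed, registrationConfig())
  drec <- cdtmorph:::.dispMat(reg$deformation)
  dtru <- cdtmorph:::.dispMat(Tt)
  expect_lt(mean(sqrt(rowSums((drec - dtru)^2))), 0.5)
  expect_gt(min(jacobianDeterminant(reg$deformation)), 0)
  expect_true(all(diff(reg$trace) <= 1e-9))
})

test_that("noise-only perturbations do not hallucinate large deformations", {
  dict <- tinyDict()
  dims <- c(16, 16, 12)
  spec1 <- phantomSpec(shape = dims, snr = 20, seed = 31)
  spec2 <- phantomSpec(shape = dims, snr = 20, seed = 32)
  g1 <- suppressWarnings(estimateGMF(makePhantom(spec1, dict)$dwi, dict))
  g2 <- suppressWarnings(estimateGMF(makePhantom(spec2, dict)$dwi, dict))
  reg <- nonrigidRegister(g1, g2, registrationConfig())
  expect_lt(mean(sqrt(rowSums(cdtmorph:::.dispMat(reg$deformation)^2))), 1.2)
})

test_that("warping by the identity leaves a field unchanged", {
  dict <- tinyDict()
  ph <- makePhantom(phantomSpec(shape = c(10, 10, 6), snr = Inf), dict)
  w <- applyWarp(ph$truth, identityDeformation(c(10, 10, 6)))
  expect_equal(w@weights, ph$truth@weights, tolerance = 1e-12)
})

test_that("warping by a global rotation conjugates component covariances", {
  dict <- tinyDict()
  dims <- c(14, 14, 14)
  ph <- makePhantom(phantomSpec(shape = dims, snr = Inf), dict)
  th <- 25 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  ctr <- (dims - 1) / 2
  X <- cdtmorph:::.gridCoords(dims)
  # T(x) = R^-1 (x - c) + c pulls the image through rotation R
  disp <- sweep(X, 2, ctr) %*% R - sweep(X, 2, ctr)
  Trot <- deformationField(array(disp, c(dims, 3)))
  w <- applyWarp(ph$truth, Trot, snap = FALSE)
  # a voxel inside the single-fiber band whose pre-image also lies in it
  gm0 <- gmAt(ph$truth, 8, 4, 8)
  gmr <- gmAt(w, 8, 4, 8)
  # the Jacobian of T is R (constant); each anisotropic component of the
  # warped voxel must equal some dictionary component conjugated by t(R)
  kmain <- which.max(gmr@weights)
  Cr <- gmr@covariances[, , kmain]
  C0 <- gm0@covariances[, , which.max(gm0@weights)]
  expect_equal(sort(eigen(Cr)$values), sort(eigen(C0)$values),
               tolerance = 1e-8)
  expect_equal(Cr, t(R) %*% C0 %*% R, tolerance = 1e-6)
})

test_that("warp followed by its inverse approximately restores the field", {
  dict <- tinyDict()
  dims <- c(14, 14, 10)
  ph <- makePhantom(phantomSpec(shape = dims, snr = Inf), dict)
  Tt <- makeRandomDiffeo(dims, amplitude = 1.2, smoothness = 4, seed = 12)
  Tinv <- invertDeformation(Tt)
  back <- applyWarp(applyWarp(ph$truth, Tt), Tinv)
  m <- ph$truth@mask & back@mask
  dw <- abs(cdtmorph:::.wmat(back) - cdtmorph:::.wmat(ph$truth))[which(m), ]
  expect_lt(mean(dw), 5e-2)
})

test_that("deformation inversion: identity, translation, random warp", {
  dims <- c(12, 12, 8)
  expect_equal(max(abs(invertDeformation(identityDeformation(dims))@disp)), 0)
  tr <- identityDeformation(dims)
  tr@disp[, , , 1] <- 1.5
  inv <- invertDeformation(tr)
  expect_equal(max(abs(inv@disp[, , , 1] + 1.5)), 0, tolerance = 1e-6)
  Tt <- makeRandomDiffeo(dims, amplitude = 1.5, smoothness = 4, seed = 13)
  Tinv <- invertDeformation(Tt)
  # composition residual below 0.1 voxel
  d <- cdtmorph:::.dispMat(Tt); di <- cdtmorph:::.dispMat(Tinv)
  X <- cdtmorph:::.gridCoords(dims)
  res <- di + cdtmorph:::cpp_sample_field(d, as.integer(dims), X + di, 1L)
  expect_lt(max(sqrt(rowSums(res^2))), 0.1)
})

test_that("similarity registration recovers shift and scale", {
  dims <- c(24, 24, 16)
  X <- cdtmorph:::.gridCoords(dims)
  ctr <- (dims - 1) / 2
  blob <- function(pts) {
    exp(-rowSums(sweep(pts, 2, ctr + c(2, -1, 1))^2) / 18) +
      0.7 * exp(-rowSums(sweep(pts, 2, ctr - c(4, 3, 2))^2) / 10)
  }
  fixedv <- array(blob(X), dims)
  # identity case
  t0 <- similarityRegister(fixedv, fixedv)
  expect_lt(max(abs(t0$translation)), 0.3)
  expect_lt(abs(t0$scale - 1), 0.03)
  # fixed equals the moving volume shifted +3 in x, i.e. moving(x) =
  # fixed(x + 3): recovered translation about (-3, 0, 0)
  moving <- array(blob(sweep(X, 2, c(3, 0, 0), "+")), dims)
  tr <- similarityRegister(moving, fixedv)
  expect_lt(abs(tr$translation[1] + 3), 0.5)
  expect_lt(max(abs(tr$translation[2:3])), 0.5)
  # moving scaled 1.1x about the centre
  movs <- array(blob(sweep(sweep(X, 2, ctr), 2, 1 / 1.1, "*") +
                       rep(ctr, each = nrow(X))), dims)
  ts <- similarityRegister(movs, fixedv)
  expect_gt(ts$scale, 1.05)
  expect_lt(ts$scale, 1.15)
})
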