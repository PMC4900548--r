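test_that("CDT identities: identity, stretches, rotations", {
  expect_equal(cdtFromJacobian(diag(3)), diag(3), tolerance = 1e-12)
  expect_equal(cdtFromJacobian(diag(c(2, 1, 1))), diag(c(2, 1, 1)),
               tolerance = 1e-12)
  th <- 0.9
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(cdtFromJacobian(R), diag(3), tolerance = 1e-12)
  expect_error(cdtFromJacobian(diag(c(-1, 1, 1))),
               class = "cdtmorph_validation_error")
  # eigenvalues of the CDT are the singular values of J
  set.seed(7)
  J <- diag(3) + 0.4 * matrix(rnorm(9), 3)
  if (det(J) < 0) J <- J[, c(2, 1, 3)]
  expect_equal(sort(eigen(cdtFromJacobian(J))$values),
               sort(svd(J)$d), tolerance = 1e-10)
})

test_that("CDT is invariant to right rotations but not left ones", {
  set.seed(8)
  J <- diag(3) + 0.3 * matrix(rnorm(9), 3)
  stopifnot(det(J) > 0)
  ang <- c(0.4, -0.7, 0.2)
  R <- cdtmorph:::.eulerRotation(ang)
  expect_equal(cdtFromJacobian(J %*% R), cdtFromJacobian(J),
               tolerance = 1e-10)
  expect_gt(max(abs(cdtFromJacobian(R %*% J) - cdtFromJacobian(J))), 1e-4)
})

test_that("affine-invariant log/exp maps satisfy their identities", {
  expect_equal(spdLog(diag(3), exp(2) * diag(3)), 2 * diag(3),
               tolerance = 1e-10)
  expect_equal(spdLog(diag(3), diag(3)), matrix(0, 3, 3), tolerance = 1e-12)
  set.seed(9)
  for (t in 1:5) {
    M <- randSPD(); X <- randSPD()
    V <- spdLog(M, X)
    expect_equal(spdExp(M, V), X, tolerance = 1e-8)
    # log-Euclidean round trip too
    Vle <- spdLog(M, X, metric = "logeuclid")
    expect_equal(spdExp(M, Vle, metric = "logeuclid"), X, tolerance = 1e-8)
  }
})

test_that("geodesic distance is invariant under congruence", {
  set.seed(10)
  for (t in 1:5) {
    M <- randSPD(); X <- randSPD()
    A <- diag(3) + 0.5 * matrix(rnorm(9), 3)
    d1 <- spdDistance(M, X)
    d2 <- spdDistance(A %*% M %*% t(A), A %*% X %*% t(A))
    expect_equal(d1, d2, tolerance = 1e-8)
  }
})

test_that("Frechet mean: fixed points, commuting pairs, permutation invariance", {
  A <- randSPD()
  expect_equal(frechetMean(list(A, A)), A, tolerance = 1e-8)
  expect_equal(frechetMean(list(diag(3), 4 * diag(3))), 2 * diag(3),
               tolerance = 1e-8)
  set.seed(11)
  B <- randSPD(); C <- randSPD()
  expect_equal(frechetMean(list(A, B, C)), frechetMean(list(C, A, B)),
               tolerance = 1e-8)
  # mean of a commuting pair is the closed-form geometric mean
  D1 <- diag(c(1, 2, 3)); D2 <- diag(c(4, 1, 9))
  expect_equal(frechetMean(list(D1, D2)),
               diag(sqrt(diag(D1) * diag(D2))), tolerance = 1e-8)
})

test_that("PGA retains N-1 generic components and conserves variance", {
  set.seed(12)
  roi <- sphereROI(c(8, 8, 8), 40)
  fields <- lapply(1:7, function(i) randCDTField(roi, id = as.character(i)))
  model <- pgaFit(fields)
  expect_equal(nComponents(model), 6)
  # non-increasing variances, orthonormal basis (validity enforces both)
  expect_true(validObject(model))
  # total tangent variance equals the sum of component variances
  X <- cdtmorph:::.cdtCube(fields)
  coords <- cdtmorph:::cpp_tangent_coords(X, model@meanField, 0L)
  Xc <- sweep(coords, 2, colMeans(coords))
  expect_equal(sum(model@variances), sum(Xc^2) / (nrow(coords) - 1),
               tolerance = 1e-8)
})

test_that("a one-parameter geodesic family loads on a single component", {
  roi <- sphereROI(c(6, 6, 6), 20)
  V <- nVoxels(roi)
  set.seed(13)
  dirs <- matrix(rnorm(V * 6, sd = 0.2), V, 6)
  ts <- seq(-1, 1, length.out = 8)
  fields <- lapply(seq_along(ts), function(i) {
    tens <- t(vapply(seq_len(V), function(v) {
      S <- ts[i] * cdtmorph:::.unpack6(dirs[v, ])
      M <- cdtmorph:::cpp_spd_expm(S)
      cdtmorph:::.pack6(M)
    }, numeric(6)))
    new("CDTField", tensors = tens, roi = roi, subjectId = as.character(i))
  })
  model <- pgaFit(fields)
  expect_gte(model@variances[1] / sum(model@variances), 0.99)
})

test_that("PGA projection: mean maps to zero, basis is complete", {
  set.seed(14)
  roi <- sphereROI(c(6, 6, 6), 25)
  fields <- lapply(1:6, function(i) randCDTField(roi, id = as.character(i)))
  model <- pgaFit(fields)
  mean_field <- new("CDTField", tensors = model@meanField, roi = roi,
                    subjectId = "mean")
  expect_lt(max(abs(pgaProject(model, mean_field))),
            1e-6 * sqrt(sum(model@variances)))
  # reconstructing a training subject from all components recovers its
  # tangent vector
  X <- cdtmorph:::.cdtCube(fields[3])
  coords <- cdtmorph:::cpp_tangent_coords(X, model@meanField, 0L)[1, ]
  coef <- pgaProject(model, fields[[3]])
  recon <- model@center + as.vector(coef %*% model@components)
  expect_equal(recon, coords, tolerance = 1e-8)
  expect_error(pgaProject(model, fields[[1]], r_sel = 99),
               class = "cdtmorph_validation_error")
})

test_that("log-Euclidean PGA on commuting data equals PCA of matrix logs", {
  set.seed(15)
  roi <- sphereROI(c(5, 5, 5), 10)
  V <- nVoxels(roi)
  N <- 9
  logs <- array(rnorm(N * V * 3, sd = 0.3), c(N, V, 3))  # diagonal tensors
  fields <- lapply(1:N, function(i) {
    tens <- matrix(0, V, 6)
    tens[, c(1, 3, 6)] <- exp(logs[i, , ])
    new("CDTField", tensors = tens, roi = roi, subjectId = as.character(i))
  })
  model <- pgaFit(fields, metric = "logeuclid")
  # oracle: ordinary PCA of the stacked log-eigenvalue features
  feats <- matrix(logs, N, V * 3)
  pc <- prcomp(feats, center = TRUE)
  ev_oracle <- pc$sdev^2
  ev_oracle <- ev_oracle[ev_oracle > 1e-12 * sum(ev_oracle)]
  expect_equal(model@variances, ev_oracle, tolerance = 1e-8)
})

test_that("manifold test: identical groups give zero statistic, p near 1", {
  set.seed(16)
  roi <- sphereROI(c(5, 5, 5), 12)
  A <- lapply(1:4, function(i) randCDTField(roi, id = as.character(i)))
  res <- manifoldTTest(A, A, n_perm = 99, seed = 1)
  expect_equal(max(res$stat), 0, tolerance = 1e-10)
  expect_true(all(res$p > 0.9))
  expect_false(any(res$mask05))
})

test_that("manifold test is invariant to swapping the group labels", {
  set.seed(17)
  roi <- sphereROI(c(5, 5, 5), 15)
  A <- lapply(1:5, function(i) randCDTField(roi, id = paste0("a", i)))
  B <- lapply(1:6, function(i) randCDTField(roi, id = paste0("b", i)))
  r1 <- manifoldTTest(A, B, n_perm = 400, seed = 3)
  r2 <- manifoldTTest(B, A, n_perm = 400, seed = 3)
  # the statistic is exactly symmetric; the permutation p-values agree up
  # to resampling noise
  expect_equal(r1$stat, r2$stat, tolerance = 1e-10)
  expect_lt(max(abs(sort(r1$p) - sort(r2$p))), 0.1)
  expect_equal(mean(r1$p), mean(r2$p), tolerance = 0.05)
})

test_that("a planted strain effect is detected inside its block", {
  set.seed(18)
  dims <- c(10, 10, 6)
  roi <- roiMask(array(TRUE, dims))
  V <- nVoxels(roi)
  blk <- array(FALSE, dims); blk[4:7, 4:7, 3:4] <- TRUE
  blk_idx <- which(blk)
  mk <- function(effect) {
    tens <- matrix(rep(c(1, 0, 1, 0, 0, 1), each = V), V, 6)
    noise <- matrix(rnorm(V * 6, sd = 0.05), V, 6)
    noise[, c(2, 4, 5)] <- noise[, c(2, 4, 5)] / sqrt(2)
    tens <- tens + noise; tens[, c(1, 3, 6)] <- abs(tens[, c(1, 3, 6)])
    if (effect) tens[blk_idx, 1] <- tens[blk_idx, 1] + 0.6  # extra strain
    new("CDTField", tensors = tens, roi = roi,
        subjectId = paste0(sample(letters, 4), collapse = ""))
  }
  A <- lapply(1:8, function(i) mk(FALSE))
  B <- lapply(1:8, function(i) mk(TRUE))
  res <- manifoldTTest(A, B, n_perm = 300, seed = 5)
  det01 <- which(res$mask01)
  expect_gt(length(det01), 0)
  expect_gte(mean(det01 %in% blk_idx), 0.8)
})
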