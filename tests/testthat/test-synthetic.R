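test_that("phantom generation is a pure function of (spec, seed)", {
  dict <- tinyDict()
  spec <- phantomSpec(shape = c(10, 10, 6), snr = 15, seed = 7)
  p1 <- makePhantom(spec, dict)
  p2 <- makePhantom(spec, dict)
  expect_identical(p1$dwi@data, p2$dwi@data)
  p3 <- makePhantom(phantomSpec(shape = c(10, 10, 6), snr = 15, seed = 8),
                    dict)
  expect_false(identical(p1$dwi@data, p3$dwi@data))
  # noise-free phantom has no noise
  pc <- makePhantom(phantomSpec(shape = c(10, 10, 6), snr = Inf), dict)
  expect_identical(pc$dwi@data,
                   makePhantom(phantomSpec(shape = c(10, 10, 6), snr = Inf),
                               dict)$dwi@data)
})

test_that("noise-free estimation recovers the phantom ground truth", {
  dict <- tinyDict()
  ph <- makePhantom(phantomSpec(shape = c(12, 12, 8), snr = Inf), dict)
  g <- estimateGMF(ph$dwi, dict, ridge = 0)
  Wt <- cdtmorph:::.wmat(ph$truth)
  We <- cdtmorph:::.wmat(g)
  # in single-fiber voxels at least 95% of the mass sits on the true atoms
  single <- which(rowSums(Wt > 0) == 2 & Wt[, nAtoms(dict)] < 0.5)
  sup_mass <- vapply(single, function(v) sum(We[v, Wt[v, ] > 0]), numeric(1))
  expect_gte(min(sup_mass), 0.95)
})

test_that("crossing voxels yield two orientations within 15 degrees of truth", {
  dict <- buildDictionary()           # full dictionary for angular resolution
  ph <- makePhantom(phantomSpec(shape = c(12, 12, 8), snr = Inf), dict)
  g <- estimateGMF(ph$dwi, dict, ridge = 0)
  Wt <- cdtmorph:::.wmat(ph$truth)
  We <- cdtmorph:::.wmat(g)
  aniso <- which(dict@dpar > dict@dperp)
  cross_vox <- which(rowSums(Wt[, aniso, drop = FALSE] > 0.2) == 2)
  v <- cross_vox[length(cross_vox) %/% 2]
  true_atoms <- which(Wt[v, aniso] > 0.2)
  west <- We[v, aniso]
  for (ta in true_atoms) {
    # strongest estimated orientation within 15 degrees of this truth axis
    u <- dict@axes[, aniso[ta]]
    angles <- acos(pmin(1, abs(crossprod(dict@axes[, aniso], u)))) * 180 / pi
    near <- which(angles <= 15)
    expect_gte(sum(west[near]), 0.2)
  }
})

test_that("random diffeos are valid and reproducible", {
  expect_equal(max(abs(makeRandomDiffeo(c(10, 10, 6), 0)@disp)), 0)
  T1 <- makeRandomDiffeo(c(12, 12, 8), amplitude = 2, smoothness = 4, seed = 5)
  expect_gt(min(jacobianDeterminant(T1)), 0)
  T2 <- makeRandomDiffeo(c(12, 12, 8), amplitude = 2, smoothness = 4, seed = 5)
  expect_identical(T1@disp, T2@disp)
  T3 <- makeRandomDiffeo(c(12, 12, 8), amplitude = 2, smoothness = 4, seed = 6)
  expect_false(identical(T1@disp, T3@disp))
  # displacement vanishes at the boundary band
  expect_lt(max(abs(T1@disp[1, , , ])), 1e-12)
})

test_that("populations are reproducible and degenerate limits collapse", {
  dict <- tinyDict()
  spec <- phantomSpec(shape = c(10, 10, 6), snr = Inf)
  pop <- makePopulation(3, spec, warp_amplitude = 0, seed = 2, dict = dict)
  # zero warp and no noise: all members identical
  expect_identical(pop[[1]]$dwi@data, pop[[2]]$dwi@data)
  expect_identical(pop[[2]]$dwi@data, pop[[3]]$dwi@data)
  spec2 <- phantomSpec(shape = c(10, 10, 6), snr = 12)
  popa <- makePopulation(3, spec2, warp_amplitude = 1, seed = 9, dict = dict)
  popb <- makePopulation(3, spec2, warp_amplitude = 1, seed = 9, dict = dict)
  expect_identical(popa[[2]]$dwi@data, popb[[2]]$dwi@data)
  expect_error(makePopulation(1, spec), class = "cdtmorph_validation_error")
})

test_that("two-class populations carry the requested class structure", {
  dict <- tinyDict()
  spec <- phantomSpec(shape = c(12, 12, 8), snr = Inf)
  eff <- effectSpec(shape_grid = spec$shape, warp_amplitude = 1)
  pop <- makeTwoClassPopulation(2, 3, spec, eff, seed = 4, subject_warp = 0,
                                dict = dict)
  expect_equal(sum(pop$labels == 0), 2)
  expect_equal(sum(pop$labels == 1), 3)
  # with no subject warp, patients differ from controls inside the block
  Wc <- cdtmorph:::.wmat(pop$members[[1]]$gmf_true)
  Wp <- cdtmorph:::.wmat(pop$members[[3]]$gmf_true)
  expect_gt(max(abs(Wc - Wp)), 0.05)
  # a null effect with no warp gives identical classes
  eff0 <- effectSpec(shape_grid = spec$shape, warp_amplitude = 0)
  pop0 <- makeTwoClassPopulation(2, 2, spec, eff0, seed = 4,
                                 subject_warp = 0, dict = dict)
  expect_identical(pop0$members[[1]]$dwi@data, pop0$members[[3]]$dwi@data)
})

test_that("pure reorientation effect leaves FA untouched but moves orientations", {
  dict <- buildDictionary()
  spec <- phantomSpec(shape = c(12, 12, 8), snr = Inf)
  # block inside the single-fiber band: single prolate atoms keep their FA
  # under any rotation of the axis
  eff <- effectSpec(roi_lo = c(4, 2, 3), roi_hi = c(9, 5, 6),
                    shape_grid = spec$shape, warp_amplitude = 0,
                    rotation_angle = 60)
  pop <- makeTwoClassPopulation(2, 2, spec, eff, seed = 4, subject_warp = 0,
                                dict = dict)
  roi <- effectROI(spec$shape, eff, margin = 0)
  fa_c <- fa(fitDTI(pop$members[[1]]$dwi, mask = roi@mask))
  fa_p <- fa(fitDTI(pop$members[[3]]$dwi, mask = roi@mask))
  expect_equal(as.vector(fa_c), as.vector(fa_p), tolerance = 2e-2)
  expect_gt(max(abs(pop$members[[1]]$dwi@data - pop$members[[3]]$dwi@data)),
            1)
})

test_that("spread directions are unit, antipodally balanced and well separated", {
  P <- spreadDirections(64)
  expect_equal(colSums(P^2), rep(1, 64), tolerance = 1e-10)
  # minimal pairwise angle (with antipodal symmetry) is reasonable
  G <- abs(crossprod(P)); diag(G) <- 0
  expect_lt(max(G), cos(8 * pi / 180))
})
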