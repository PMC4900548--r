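sepClusters <- function(n = 40, p = 5, gap = 10, seed = 20) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  labels <- rep(0:1, each = n / 2)
  X[labels == 1, 1] <- X[labels == 1, 1] + gap
  list(X = X, labels = labels)
}

test_that("LOO nu-SVM separates well-separated clusters perfectly", {
  d <- sepClusters()
  rep_ <- looEvaluate(d$X, d$labels, g = 0.05, nu = 0.3)
  expect_true(rep_@valid)
  expect_equal(rep_@accuracy, 1.0)
  expect_equal(rep_@sensitivity, 1.0)
  expect_equal(rep_@specificity, 1.0)
})

test_that("LOO accuracy agrees with an independent SVM implementation", {
  skip_if_not_installed("kernlab")
  set.seed(21)
  X <- matrix(rnorm(30 * 4), 30, 4)
  labels <- rep(0:1, 15)
  X[labels == 1, ] <- X[labels == 1, ] + 1.2
  g <- 0.2; nu <- 0.25
  mine <- looEvaluate(X, labels, g, nu, standardize = FALSE)
  pred_ref <- vapply(seq_len(nrow(X)), function(i) {
    fit <- kernlab::ksvm(X[-i, ], factor(labels[-i]), type = "nu-svc",
                         kernel = "rbfdot", kpar = list(sigma = g),
                         nu = nu, scaled = FALSE)
    as.integer(as.character(kernlab::predict(fit, X[i, , drop = FALSE])))
  }, integer(1))
  expect_gte(mean(pred_ref == mine@predictions), 0.9)
  expect_lt(abs(mine@accuracy - mean(pred_ref == labels)), 0.1)
})

test_that("chance-level accuracy on permuted labels", {
  d <- sepClusters(n = 40)
  accs <- vapply(1:5, function(s) {
    set.seed(100 + s)
    looEvaluate(d$X, sample(d$labels), g = 0.05, nu = 0.3)@accuracy
  }, numeric(1))
  expect_true(all(accs >= 0.2 & accs <= 0.8))
  expect_lt(mean(accs), 0.75)
})

test_that("degenerate folds mark the cell invalid instead of erroring", {
  set.seed(22)
  X <- matrix(rnorm(10 * 3), 10, 3)
  labels <- c(1L, rep(0L, 9))   # holding out the only patient
  rep_ <- looEvaluate(X, labels, g = 0.1, nu = 0.3)
  expect_false(rep_@valid)
  # infeasible nu also yields an invalid cell
  d <- sepClusters(n = 12)
  rep2 <- looEvaluate(d$X, d$labels, g = 0.1, nu = 0.95)
  expect_false(rep2@valid)
})

test_that("fast LOO driver reproduces the reference implementation", {
  set.seed(23)
  X <- matrix(rnorm(20 * 6), 20, 6)
  labels <- rep(0:1, each = 10)
  X[labels == 1, 2] <- X[labels == 1, 2] + 1.5
  for (cell in list(c(0.01, 0.1), c(0.2, 0.4), c(0.7, 0.6), c(1, 0.85))) {
    ref <- looEvaluate(X, labels, cell[1], cell[2])
    fast <- cdtmorph:::.fastLoo(X, labels, cell[1], cell[2])
    expect_equal(fast, ref@predictions)
  }
})

test_that("grid search finds a separating cell and breaks ties by smaller r", {
  d <- sepClusters(n = 24)
  spec <- gridSpec(r_values = c(5, 10), stride_factor = 100)
  # identical features for both r values: every accuracy ties, r = 5 wins
  fbr <- list(`5` = d$X, `10` = d$X)
  best <- gridSearch(fbr, spec, d$labels)
  expect_equal(best@accuracy, 1.0)
  expect_equal(best@bestR, 5)
  # a coarser stride still finds a near-optimal cell on separable data
  spec2 <- gridSpec(r_values = 5, stride_factor = 300)
  best2 <- gridSearch(list(`5` = d$X), spec2, d$labels)
  expect_lte(abs(best2@accuracy - best@accuracy), 0.05)
})

test_that("confusion-count identities hold on every report", {
  set.seed(24)
  X <- matrix(rnorm(16 * 3), 16, 3)
  labels <- rep(0:1, 8)
  rep_ <- looEvaluate(X, labels, g = 0.3, nu = 0.4)
  cc <- rep_@confusion
  expect_equal(rep_@accuracy, (cc["TP"] + cc["TN"]) / 16, ignore_attr = TRUE)
  expect_equal(rep_@sensitivity, cc["TP"] / (cc["TP"] + cc["FN"]),
               ignore_attr = TRUE)
  expect_equal(rep_@specificity, cc["TN"] / (cc["TN"] + cc["FP"]),
               ignore_attr = TRUE)
})

test_that("FA formula: isotropic 0, linear limit 1, analytic mid case", {
  expect_equal(fa(diag(c(2e-3, 2e-3, 2e-3))), 0, tolerance = 1e-10)
  expect_gt(fa(diag(c(1, 1e-9, 1e-9))), 0.999)
  expect_equal(fa(diag(c(2, 1, 1))), sqrt(1.5) * sqrt(2/3) / sqrt(6),
               tolerance = 1e-10)
  expect_equal(fa(diag(c(2, 1, 1))), 0.4082, tolerance = 1e-3)
})

test_that("DTI fit recovers a planted tensor and its FA", {
  D <- diag(c(1.7e-3, 4e-4, 2e-4))
  R <- cdtmorph:::.eulerRotation(c(0.3, 0.5, -0.2))
  D <- R %*% D %*% t(R)
  gt <- testGradients(n_dirs = 30)
  E <- exp(-gt@bvals * colSums(gt@bvecs * (D %*% gt@bvecs)))
  data <- array(rep(1000 * E, each = 8), c(2, 2, 2, length(E)))
  dwi <- dwiVolume(data, diag(4), gt)
  tens <- fitDTI(dwi)
  Dfit <- cdtmorph:::.unpack6(tens[1, ])
  expect_equal(Dfit, D, tolerance = 1e-6)
  # FA against the closed form on the planted eigenvalues
  ev <- c(1.7e-3, 4e-4, 2e-4)
  fa_true <- sqrt(1.5) * sqrt(sum((ev - mean(ev))^2)) / sqrt(sum(ev^2))
  expect_equal(as.vector(fa(tens))[1], fa_true, tolerance = 1e-6)
})

test_that("FA features are invariant to rotating the fiber orientations", {
  dict <- tinyDict()
  K <- nAtoms(dict)
  gt <- testGradients()
  wx <- numeric(K); wx[cdtmorph:::.nearestAtom(dict, c(1, 0, 0))] <- 1
  wy <- numeric(K); wy[cdtmorph:::.nearestAtom(dict, c(0, 1, 0))] <- 1
  fa_of <- function(w) {
    dwi <- uniformDWI(w, dict, dims = c(2, 2, 2), gradients = gt)
    as.vector(fa(fitDTI(dwi)))[1]
  }
  expect_equal(fa_of(wx), fa_of(wy), tolerance = 1e-6)
})
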