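# Low-overhead leave-one-out driver for the grid search. The solver is
# still libsvm (via e1071's registered native routine); this bypasses only
# the data-frame bookkeeping of the high-level wrapper, which dominates the
# runtime when hundreds of thousands of 23-point fits are needed. The
# high-level e1071::svm path in looEvaluate() is kept as the reference and
# the two are asserted to agree in the test suite.

.svmtrainSym <- local({
  sym <- NULL
  function() {
    if (is.null(sym))
      sym <<- get("R_svmtrain", envir = asNamespace("e1071"))
    sym
  }
})

.emptyErr <- paste(rep(" ", 255), collapse = "")

# train a binary nu-SVC with RBF kernel on (X, y in {1, 2}); returns NULL
# on infeasible nu, otherwise what prediction needs
.nusvcFit <- function(X, y, gamma, nu) {
  nr <- nrow(X)
  cret <- .C(.svmtrainSym(),
             as.double(t(X)), as.integer(nr), as.integer(ncol(X)),
             as.double(y), as.integer(0), as.integer(0),
             as.integer(1L),          # type: nu-classification
             as.integer(2L),          # kernel: radial
             as.integer(3L), as.double(gamma), as.double(0),
             as.double(1), as.double(nu), integer(0), double(0),
             as.integer(0), as.double(40), as.double(0.001),
             as.double(0.1), as.integer(1L), as.integer(0L),
             as.integer(0L), as.integer(0L),
             nclasses = integer(1), nr = integer(1), index = integer(nr),
             labels = integer(2), nSV = integer(2), rho = double(1),
             coefs = double(nr), sigma = double(1), probA = double(1),
             probB = double(1), cresults = double(0), ctotal1 = double(1),
             ctotal2 = double(1), error = .emptyErr)
  if (cret$error != .emptyErr) return(NULL)
  nsv <- cret$nr
  list(SV = X[cret$index[seq_len(nsv)], , drop = FALSE],
       coefs = cret$coefs[seq_len(nsv)], rho = cret$rho,
       labels = cret$labels[1:2])
}

.nusvcPredict <- function(fit, x) {
  d2 <- colSums((t(fit$SV) - x)^2)
  f <- sum(fit$coefs * exp(-fit$gamma * d2)) - fit$rho
  if (f > 0) fit$labels[1] else fit$labels[2]
}

# per-fold training/test sets, standardised on the training fold only;
# computed once per feature matrix and reused across all grid cells
.makeFolds <- function(X, labels, standardize = TRUE) {
  N <- nrow(X)
  lapply(seq_len(N), function(i) {
    tr <- X[-i, , drop = FALSE]
    te <- X[i, ]
    if (standardize) {
      mu <- colMeans(tr)
      sg <- apply(tr, 2, stats::sd)
      sg[sg < 1e-12] <- 1
      tr <- sweep(sweep(tr, 2, mu), 2, sg, "/")
      te <- (te - mu) / sg
    }
    list(tr = tr, te = te, ytr = labels[-i] + 1L)
  })
}

# LOO evaluation of one (g, nu) cell on precomputed folds; NULL when any
# fold is infeasible for this nu
.fastLooFolds <- function(folds, g, nu) {
  pred <- integer(length(folds))
  for (i in seq_along(folds)) {
    fd <- folds[[i]]
    fit <- .nusvcFit(fd$tr, fd$ytr, g, nu)
    if (is.null(fit)) return(NULL)
    fit$gamma <- g
    pred[i] <- .nusvcPredict(fit, fd$te) - 1L
  }
  pred
}

# LOO evaluation of one (g, nu) cell from scratch
.fastLoo <- function(X, labels, g, nu, standardize = TRUE) {
  .fastLooFolds(.makeFolds(X, labels, standardize), g, nu)
}
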