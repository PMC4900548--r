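# Two-stage unbiased template construction: an intermediate average in the
# space of all images, then projection onto the data-spanned space (the
# orbit of a population member) to obtain the sharp template. Each stage
# uses O(N) registrations.

# arithmetic average of weight fields on the shared dictionary; the
# per-voxel support is truncated to the leading atoms so the quadratic
# mixture-distance cost stays bounded (the averaging blur that truncation
# trims is exactly what the projection stage removes anyway)
.averageField <- function(population, max_components = 8) {
  W <- .wmat(population[[1]])
  for (n in seq_along(population)[-1]) W <- W + .wmat(population[[n]])
  W <- W / length(population)
  if (max_components < ncol(W)) {
    for (v in which(rowSums(W > 0) > max_components)) {
      wv <- W[v, ]
      keep <- order(wv, decreasing = TRUE)[seq_len(max_components)]
      wnew <- numeric(length(wv))
      wnew[keep] <- wv[keep] * (sum(wv) / sum(wv[keep]))
      W[v, ] <- wnew
    }
  }
  dims <- .gmfDims(population[[1]])
  mask <- rowSums(W) > 0.05
  new("GMField", weights = array(W, c(dims, ncol(W))),
      dictionary = population[[1]]@dictionary,
      atomAxes = population[[1]]@dictionary@axes,
      affine = population[[1]]@affine,
      mask = array(mask, dims), axes = NULL)
}

.checkPopulation <- function(population) {
  if (length(population) < 2L)
    .validationError("population must have at least 2 members")
  dims <- .gmfDims(population[[1]])
  K <- nAtoms(population[[1]]@dictionary)
  for (g in population) {
    if (!all(.gmfDims(g) == dims)) .validationError("grid mismatch in population")
    if (nAtoms(g@dictionary) != K) .validationError("dictionary mismatch")
  }
  invisible(dims)
}

#' First-stage intermediate template
#'
#' Alternating scheme: initialise the template as the voxel-wise average of
#' the weight fields; register every subject to it; update the template as
#' the average of the warped, reoriented subjects; unbias by composing all
#' deformations with the inverse of their mean displacement so the average
#' deformation stays near identity; iterate while the population energy
#' decreases. Each outer iteration costs exactly N registrations.
#'
#' @param population list of similarity-aligned [GMField-class] objects on
#'   a common grid with a shared dictionary (N >= 2).
#' @param config a [registrationConfig()] list.
#' @param outer_iter maximum outer iterations.
#' @param tol relative population-energy decrease below which to stop.
#' @param unbias apply the inverse-mean-displacement correction.
#' @return list with `intermediate` (a [GMField-class]), `deformations`
#'   (per subject), and `trace` (population energy per outer iteration).
#' @export
buildIntermediate <- function(population, config = registrationConfig(),
                              outer_iter = 3, tol = 1e-3, unbias = TRUE) {
  dims <- .checkPopulation(population)
  N <- length(population)
  Ibar <- .averageField(population)
  defs <- replicate(N, identityDeformation(dims), simplify = FALSE)
  trace <- numeric(0)
  best <- list(Ibar = Ibar, defs = defs, energy = Inf)
  for (outer in seq_len(outer_iter)) {
    disps <- vector("list", N)
    for (n in seq_len(N)) {
      reg <- nonrigidRegister(population[[n]], Ibar, config)
      disps[[n]] <- .dispMat(reg$deformation)
    }
    if (unbias) {
      dbar <- Reduce(`+`, disps) / N
      dinv <- .dispMat(invertDeformation(
        deformationField(array(dbar, c(dims, 3)))))
      disps <- lapply(disps, function(dn) cpp_compose_disp(dinv, dn, dims))
    }
    defs <- lapply(disps, function(dn)
      deformationField(array(dn, c(dims, 3)), population[[1]]@affine))
    warped <- mapply(applyWarp, population, defs, SIMPLIFY = FALSE)
    Ibar_new <- .averageField(warped)
    energy <- sum(mapply(function(img, T) dataEnergy(img, Ibar_new, T),
                         population, defs))
    if (energy >= best$energy) break   # keep the best state; trace stays
                                       # monotone (accepted passes only)
    gain <- if (length(trace)) (trace[length(trace)] - energy) /
      max(trace[length(trace)], 1e-12) else 1
    trace <- c(trace, energy)
    best <- list(Ibar = Ibar_new, defs = defs, energy = energy)
    if (gain < tol) break
    Ibar <- Ibar_new
  }
  list(intermediate = best$Ibar, deformations = best$defs, trace = trace)
}

#' Project the intermediate template onto the data-spanned space
#'
#' Registers every population member to the intermediate template and
#' selects the member/deformation pair with minimal final data energy
#' (ties broken by smallest index); the final sharp template is that
#' member warped and PPD-reoriented into template space. Costs N
#' registrations.
#'
#' @param intermediate the first-stage [GMField-class].
#' @param population the list of [GMField-class] subjects.
#' @param config a [registrationConfig()] list.
#' @return list with `m_star`, `T_star`, `final` (a [GMField-class]),
#'   `energies`, and `deformations`.
#' @export
projectTemplate <- function(intermediate, population,
                            config = registrationConfig()) {
  if (!length(population)) .validationError("empty population")
  N <- length(population)
  energies <- numeric(N)
  defs <- vector("list", N)
  for (n in seq_len(N)) {
    reg <- nonrigidRegister(population[[n]], intermediate, config)
    defs[[n]] <- reg$deformation
    energies[n] <- dataEnergy(population[[n]], intermediate,
                              reg$deformation)
  }
  m_star <- which.min(energies)          # ties: smallest index
  final <- applyWarp(population[[m_star]], defs[[m_star]])
  attr(final, "provenance") <- list(m_star = m_star,
                                    source = "warped population member")
  list(m_star = m_star, T_star = defs[[m_star]], final = final,
       energies = energies, deformations = defs)
}

#' Two-stage unbiased sharp template
#'
#' Runs [buildIntermediate()] followed by [projectTemplate()]; the final
#' template is a warped, reoriented population member by construction
#' (sharp, not a blur), and the whole procedure uses O(N) registrations
#' per stage.
#'
#' @inheritParams buildIntermediate
#' @return a [TemplateResult-class].
#' @export
buildTemplate <- function(population, config = registrationConfig(),
                          outer_iter = 3, tol = 1e-3, unbias = TRUE) {
  count0 <- registrationCount()
  st1 <- buildIntermediate(population, config, outer_iter, tol, unbias)
  st2 <- projectTemplate(st1$intermediate, population, config)
  new("TemplateResult",
      intermediate = st1$intermediate, final = st2$final,
      mStar = as.integer(st2$m_star), TStar = st2$T_star,
      deformations = st2$deformations, energyTable = st2$energies,
      trace = st1$trace,
      regCount = as.integer(registrationCount() - count0))
}
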