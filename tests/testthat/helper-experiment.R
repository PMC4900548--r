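# Shared full-size two-class experiment, computed once per test session and
# reused by the acceptance and module tests (it is by far the most
# expensive fixture: 36 subjects, one control template, 84 registrations).
#
# Design: controls are warped/noised copies of the base phantom; patient
# set A carries a localized compressive warp (strain signal, the planted
# "SN" effect); patient set B carries a pure reorientation of the fiber
# axes in the same block (no anisotropy or position change), the case FA
# is blind to by construction.

.expCache <- new.env(parent = emptyenv())

twoClassExperiment <- function() {
  if (!is.null(.expCache$res)) return(.expCache$res)
  dict <- buildDictionary()
  spec <- phantomSpec()                       # 32 x 32 x 16, snr 20
  # the planted block sits strictly inside the single-fiber band, where a
  # pure reorientation leaves the FA map exactly unchanged. Both effects
  # carry the same rotation so the two populations share one control set
  # (and hence one template); effect A adds the compressive warp.
  blk_lo <- c(13L, 7L, 6L); blk_hi <- c(18L, 12L, 9L)
  effA <- effectSpec(roi_lo = blk_lo, roi_hi = blk_hi,
                     shape_grid = spec$shape, warp_amplitude = 1.5,
                     rotation_angle = 60)
  effB <- effectSpec(roi_lo = blk_lo, roi_hi = blk_hi,
                     shape_grid = spec$shape, warp_amplitude = 0,
                     rotation_angle = 60)
  popA <- makeTwoClassPopulation(12, 12, spec, effA, seed = 11,
                                 subject_warp = 1, dict = dict)
  popB <- makeTwoClassPopulation(12, 12, spec, effB, seed = 11,
                                 subject_warp = 1, dict = dict)
  # identical seeds make the control halves of both populations identical;
  # estimate each distinct subject once
  est <- function(m) suppressWarnings(estimateGMF(m$dwi, dict))
  gm_ctrl <- lapply(popA$members[1:12], est)
  gm_patA <- lapply(popA$members[13:24], est)
  gm_patB <- lapply(popB$members[13:24], est)

  cfg <- registrationConfig()
  resetRegistrationCount()
  tmpl <- buildTemplate(gm_ctrl, cfg, outer_iter = 3)
  template_regs <- registrationCount()

  roi <- effectROI(spec$shape, effA, margin = 2)
  regto <- function(g) nonrigidRegister(g, tmpl@final, cfg)$deformation
  def_ctrl <- lapply(gm_ctrl, regto)
  def_patA <- lapply(gm_patA, regto)
  def_patB <- lapply(gm_patB, regto)
  mkcdt <- function(defs, tag) lapply(seq_along(defs), function(n)
    cdtField(defs[[n]], roi, paste0(tag, n)))

  .expCache$res <- list(
    dict = dict, spec = spec, effA = effA, effB = effB,
    popA = popA, popB = popB, roi = roi, tmpl = tmpl, cfg = cfg,
    template_regs = template_regs,
    def_ctrl = def_ctrl, def_patA = def_patA, def_patB = def_patB,
    cdt_ctrl = mkcdt(def_ctrl, "c"), cdt_patA = mkcdt(def_patA, "a"),
    cdt_patB = mkcdt(def_patB, "b"),
    labels = c(rep(0L, 12), rep(1L, 12)))
  .expCache$res
}

# CDT-feature grid search for one control/patient split of the experiment
experimentGridSearch <- function(cdt_ctrl, cdt_pat, labels,
                                 grid = gridSpec()) {
  cdts <- c(cdt_ctrl, cdt_pat)
  pga <- pgaFit(cdts)
  rs <- grid$r_values[grid$r_values <= nComponents(pga)]
  if (!length(rs)) rs <- nComponents(pga)
  fbr <- setNames(lapply(rs, function(r) pgaFeatures(pga, cdts, r)),
                  as.character(rs))
  g2 <- grid
  g2$r_values <- rs
  gridSearch(fbr, g2, labels)
}
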