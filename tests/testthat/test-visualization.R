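test_that("flag categories partition the pixels and follow the rule table", {
  truth <- generate_phantom(phantom_spec(32L, "ID", seed = 2L))$mask
  pe <- array(runif(4 * 32 * 32, 0, exp(-1)), c(4, 32, 32))
  fm <- flag_pixels(truth, pe, threshold = 0.2, class_id = 1L)
  codes <- unclass(fm)
  expect_true(all(codes %in% 1:4))
  # rule: positive = predicted ctv; uncertain = per-class PE above threshold
  pos <- truth == 1L; unc <- pe[2, , ] > 0.2
  expect_identical(codes == 1L, pos & !unc)
  expect_identical(codes == 3L, pos & unc)
  expect_identical(codes == 4L, !pos & unc)
})

test_that("zero-uncertainty ensembles yield only certain flags", {
  truth <- generate_phantom(phantom_spec(32L, "ID", seed = 3L))$mask
  ens <- simulate_ensemble(ensemble_sim_spec(truth, T = 2L, sigma_epistemic = 0,
                                             sigma_aleatoric = 0, seed = 1L))
  maps <- uncertainty_maps(ens)
  fm <- flag_pixels(mean_and_binarize(ens)$label_mask, maps,
                    threshold = 0.30, class_id = 2L)
  expect_true(all(unclass(fm) %in% 1:2))
})

test_that("thresholds above the per-class PE maximum flag nothing", {
  truth <- generate_phantom(phantom_spec(32L, "ID", seed = 5L))$mask
  pe <- array(runif(4 * 32 * 32, 0, exp(-1)), c(4, 32, 32))
  fm <- flag_pixels(truth, pe, threshold = exp(-1) + 1e-9, class_id = 1L)
  expect_true(all(unclass(fm) %in% 1:2))
})

test_that("flag counts reconcile with grouped-Dice counts at the same threshold", {
  truth <- generate_phantom(phantom_spec(32L, "ID", seed = 6L))$mask
  ens <- simulate_ensemble(ensemble_sim_spec(truth, T = 10L, sigma_epistemic = 1,
                                             sigma_aleatoric = 1, seed = 2L))
  pred <- mean_and_binarize(ens)$label_mask
  pcpe <- per_class_pe(ens)
  out <- classify_outcomes(pred, truth)
  th <- 0.30
  for (cl in 1:3) {
    fm <- flag_pixels(pred, pcpe, threshold = th, class_id = cl)
    gd <- grouped_dice(out, pcpe, th)
    unc <- gd[gd$class == seg_classes()[cl + 1L] & gd$group == "uncertain", ]
    # uncertain_positive pixels are exactly the uncertain TP+FP pixels
    expect_identical(sum(unclass(fm) == 3L), unc$tp + unc$fp)
  }
})

test_that("panel rendering is byte-identical for identical inputs", {
  ph <- generate_phantom(phantom_spec(32L, "ID", seed = 7L))
  ens <- simulate_ensemble(ensemble_sim_spec(ph$mask, T = 5L, sigma_epistemic = 0.5,
                                             sigma_aleatoric = 1, seed = 3L))
  maps <- uncertainty_maps(ens)
  pred <- mean_and_binarize(ens)$label_mask
  fm <- flag_pixels(pred, maps, threshold = 0.30, class_id = 1L)
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  render_panels(ph$image, ph$mask, pred, maps$pe, fm, f1)
  render_panels(ph$image, ph$mask, pred, maps$pe, fm, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # perfect prediction leaves the error panel empty (all white)
  f3 <- tempfile(fileext = ".png")
  render_panels(ph$image, ph$mask, ph$mask, maps$pe, fm, f3)
  img <- png::readPNG(f3)
  err_panel <- img[34 + seq_len(32), seq_len(32), ]
  expect_true(all(err_panel == 1))
})

test_that("boundary-noise ensembles place PE maxima on structure boundaries", {
  ph <- generate_phantom(phantom_spec(32L, "ID", seed = 8L))
  ens <- simulate_ensemble(ensemble_sim_spec(ph$mask, T = 20L, sigma_epistemic = 0.3,
                                             sigma_aleatoric = 1.5, seed = 4L))
  pe <- predictive_entropy(ens)
  peak <- which(pe == max(pe), arr.ind = TRUE)[1, ]
  bnd <- do.call(rbind, lapply(0:3, function(c) {
    if (any(ph$mask == c) && !all(ph$mask == c)) {
      segqa:::boundary_coords(ph$mask == c)
    }
  }))
  d <- sqrt((bnd[, 1] - peak[1])^2 + (bnd[, 2] - peak[2])^2)
  expect_lte(min(d), 2)
})

test_that("all-classes flag mode thresholds the total PE over any structure", {
  truth <- generate_phantom(phantom_spec(32L, "ID", seed = 9L))$mask
  ens <- simulate_ensemble(ensemble_sim_spec(truth, T = 10L, sigma_epistemic = 1,
                                             sigma_aleatoric = 1, seed = 5L))
  maps <- uncertainty_maps(ens)
  pred <- mean_and_binarize(ens)$label_mask
  fm <- flag_pixels(pred, maps, threshold = 0.30, class_id = NULL)
  codes <- unclass(fm)
  pos <- pred != 0L; unc <- maps$pe > 0.30
  expect_identical(codes == 3L, pos & unc)
  expect_identical(codes == 2L, !pos & !unc)
})
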