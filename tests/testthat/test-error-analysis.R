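test_that("outcome classification follows the per-class TP/FP/FN/TN rule", {
  truth <- matrix(c(1L, 1L, 2L, 0L), 1, 4)
  pred <- matrix(c(1L, 2L, 2L, 2L), 1, 4)
  out <- classify_outcomes(pred, truth)
  # class 1 (ctv): TP, FN, TN, TN
  expect_identical(as.vector(out$codes[2, 1, ]), c(1L, 3L, 4L, 4L))
  # class 2 (bladder): TN, FP, TP, FP
  expect_identical(as.vector(out$codes[3, 1, ]), c(4L, 2L, 1L, 2L))
  # brute-force rule application over every pixel and class
  for (c in 0:3) {
    for (k in 1:4) {
      expected <- if (truth[1, k] == c && pred[1, k] == c) 1L
      else if (pred[1, k] == c) 2L
      else if (truth[1, k] == c) 3L else 4L
      expect_identical(out$codes[c + 1L, 1, k], expected)
    }
  }
})

test_that("outcomes partition the pixels for every class", {
  set.seed(8)
  for (r in 1:20) {
    truth <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
    pred <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
    out <- classify_outcomes(pred, truth)
    cnt <- outcome_counts(out)
    expect_identical(unname(rowSums(cnt[, c("tp", "fp", "fn", "tn")])),
                     rep(64, 4))
  }
  # identity prediction: no FP or FN anywhere
  cnt <- outcome_counts(classify_outcomes(truth, truth))
  expect_identical(sum(cnt$fp) + sum(cnt$fn), 0L)
})

test_that("shape and label violations are rejected", {
  expect_error(classify_outcomes(matrix(0L, 2, 2), matrix(0L, 2, 3)), "shape")
  expect_error(classify_outcomes(matrix(7L, 2, 2), matrix(0L, 2, 2)), "labels")
})

test_that("grouped Dice follows the count-based formula with NA when undefined", {
  # build a 1-class scenario with known counts: TP=3, FP=1, FN=2 certain
  truth <- matrix(0L, 2, 4)
  truth[1, 1:3] <- 1L; truth[2, 1:2] <- 1L
  pred <- truth
  pred[2, 1:2] <- 0L      # 2 FN
  pred[2, 4] <- 1L        # 1 FP
  out <- classify_outcomes(pred, truth)
  pcpe <- array(0, c(4, 2, 4))   # everything certain at threshold 0
  gd <- grouped_dice(out, pcpe, threshold = 0.1)
  ctv_cert <- gd[gd$class == "ctv" & gd$group == "certain", ]
  expect_identical(c(ctv_cert$tp, ctv_cert$fp, ctv_cert$fn), c(3L, 1L, 2L))
  expect_equal(ctv_cert$dice, 6 / 9)
  # the empty uncertain group is undefined, not 0 or 1
  expect_true(is.na(gd[gd$class == "ctv" & gd$group == "uncertain", "dice"]))
})

test_that("above the per-class PE maximum grouped Dice equals set-based Dice", {
  set.seed(31)
  for (r in 1:100) {
    truth <- matrix(sample(0:3, 256, replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1)), 16, 16)
    pred <- truth
    flip <- runif(256) < 0.15
    pred[flip] <- sample(0:3, sum(flip), replace = TRUE)
    out <- classify_outcomes(pred, truth)
    pcpe <- array(runif(4 * 256, 0, exp(-1)), c(4, 16, 16))
    gd <- grouped_dice(out, pcpe, threshold = exp(-1))
    for (c in 0:3) {
      row <- gd[gd$class == seg_classes()[c + 1L] & gd$group == "certain", ]
      expect_equal(row$dice, dice_coefficient(pred == c, truth == c))
      unc <- gd[gd$class == seg_classes()[c + 1L] & gd$group == "uncertain", ]
      expect_true(is.na(unc$dice))
      # group counts conserve the class totals
      cnt <- outcome_counts(out)[c + 1L, ]
      expect_identical(row$tp + unc$tp, cnt$tp)
      expect_identical(row$fp + unc$fp, cnt$fp)
      expect_identical(row$fn + unc$fn, cnt$fn)
    }
  }
})

test_that("threshold zero sends every positive-PE pixel to the uncertain group", {
  truth <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
  out <- classify_outcomes(truth, truth)
  pcpe <- array(0.2, c(4, 8, 8))
  gd <- grouped_dice(out, pcpe, threshold = 0)
  expect_true(all(is.na(gd[gd$group == "certain", "dice"])))
})

test_that("perfect predictions give certain-group Dice 1 and a clean uncertain group", {
  truth <- generate_phantom(phantom_spec(32L, "ID", seed = 2L))$mask
  out <- classify_outcomes(truth, truth)
  pcpe <- array(runif(4 * 32 * 32, 0, exp(-1)), c(4, 32, 32))
  gd <- grouped_dice(out, pcpe, threshold = 0.2)
  defined <- !is.na(gd$dice)
  expect_true(all(gd$dice[defined & gd$group == "certain"] == 1))
  expect_identical(sum(gd$fp) + sum(gd$fn), 0L)
})

test_that("threshold sweep uses the conventional default grid and validates input", {
  truth <- generate_phantom(phantom_spec(32L, "ID", seed = 2L))$mask
  out <- classify_outcomes(truth, truth)
  pcpe <- array(0.1, c(4, 32, 32))
  sw <- threshold_sweep(out, pcpe)
  expect_equal(sw$thresholds, c(0.30, 0.31, 0.32, 0.33, 0.34, 0.35, 0.36))
  expect_error(threshold_sweep(out, pcpe, thresholds = c(0.3, 0.3)),
               "strictly increasing")
})

test_that("PE histograms conserve counts and flag empty outcome categories", {
  truth <- generate_phantom(phantom_spec(32L, "ID", seed = 4L))$mask
  out <- classify_outcomes(truth, truth)          # no FP/FN anywhere
  pcpe <- array(runif(4 * 32 * 32, 0, exp(-1)), c(4, 32, 32))
  d <- pe_distribution_by_outcome(out, pcpe, bins = c(0, 0.05, 0.10, exp(-1)))
  h <- d$histogram
  for (cl in seg_classes()) {
    for (oc in c("TP", "TN", "FP", "FN")) {
      sub <- h[h$class == cl & h$outcome == oc, ]
      n_pix <- sum(out$codes[match(cl, seg_classes()), , ] ==
                     match(oc, c("TP", "FP", "FN", "TN")))
      expect_identical(sum(sub$count), n_pix)
      if (n_pix == 0) expect_true(all(sub$empty))
    }
  }
  expect_true(all(is.na(d$summary$frac_wrong_gt_0.10)))
})

test_that("correct one-hot predictions all fall in the lowest PE bin", {
  truth <- generate_phantom(phantom_spec(32L, "ID", seed = 5L))$mask
  ens <- simulate_ensemble(ensemble_sim_spec(truth, T = 3L, sigma_epistemic = 0,
                                             sigma_aleatoric = 0, seed = 1L))
  pred <- mean_and_binarize(ens)$label_mask
  out <- classify_outcomes(pred, truth)
  d <- pe_distribution_by_outcome(out, per_class_pe(ens))
  interiorish <- d$summary$frac_correct_le_0.05
  expect_true(all(interiorish > 0.99))
})

test_that("boundary-error ensembles place higher per-class PE on wrong pixels", {
  truth <- generate_phantom(phantom_spec(32L, "ID", seed = 6L))$mask
  # few samples and strong noise so the averaged prediction actually commits
  # boundary errors
  ens <- simulate_ensemble(ensemble_sim_spec(truth, T = 5L, sigma_epistemic = 2,
                                             sigma_aleatoric = 2, seed = 3L))
  pred <- mean_and_binarize(ens)$label_mask
  out <- classify_outcomes(pred, truth)
  pcpe <- per_class_pe(ens)
  n_wrong <- 0L
  for (ci in 1:4) {
    codes <- as.vector(out$codes[ci, , ])
    pes <- as.vector(pcpe[ci, , ])
    wrong <- pes[codes %in% c(2L, 3L)]
    right <- pes[codes %in% c(1L, 4L)]
    if (length(wrong) > 10) {
      n_wrong <- n_wrong + length(wrong)
      expect_gt(median(wrong), median(right))
    }
  }
  expect_gt(n_wrong, 0L)   # the noisy ensemble must actually commit errors
})
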