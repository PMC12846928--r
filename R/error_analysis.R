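OUTCOME_LEVELS <- c("TP", "FP", "FN", "TN")

#' Per-class pixel outcome classification
#'
#' For each class `c`, every pixel is exactly one of: TP (truth and
#' prediction both `c`), FP (predicted `c`, truth another class), FN (truth
#' `c`, predicted another class), TN (neither). The four outcomes partition
#' the pixels for every class.
#'
#' @param pred Predicted integer label mask (H x W, labels 0..3).
#' @param truth Ground-truth label mask of the same shape.
#' @return An `outcome_map`: integer array `(C, H, W)` with codes
#'   1=TP, 2=FP, 3=FN, 4=TN, plus class names.
#' @export
classify_outcomes <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("pred and truth shapes differ")
  check_label_mask(pred, what = "pred")
  check_label_mask(truth, what = "truth")
  H <- nrow(pred); W <- ncol(pred); C <- SEG_N_CLASSES
  out <- array(0L, c(C, H, W))
  for (c in seq_len(C) - 1L) {
    p <- pred == c; t <- truth == c
    code <- ifelse(p & t, 1L, ifelse(p & !t, 2L, ifelse(!p & t, 3L, 4L)))
    out[c + 1L, , ] <- code
  }
  structure(list(codes = out, class_names = seg_classes(),
                 levels = OUTCOME_LEVELS),
            class = "outcome_map")
}

#' Outcome counts per class
#'
#' @param outcomes An [classify_outcomes()] result.
#' @return Data frame with one row per class and TP/FP/FN/TN counts.
#' @export
outcome_counts <- function(outcomes) {
  stopifnot(inherits(outcomes, "outcome_map"))
  C <- dim(outcomes$codes)[1]
  do.call(rbind, lapply(seq_len(C), function(ci) {
    tab <- tabulate(outcomes$codes[ci, , ], nbins = 4L)
    data.frame(class = outcomes$class_names[ci], tp = tab[1], fp = tab[2],
               fn = tab[3], tn = tab[4])
  }))
}

#' Per-class PE distributions stratified by pixel outcome
#'
#' Histograms the per-class predictive entropy separately for TP, TN, FP and
#' FN pixels, and reports per class the fraction of correct pixels (TP and
#' TN pooled) with PE at or below 0.05 and the fraction of wrong pixels
#' (FP and FN pooled) with PE above 0.10.
#'
#' @param outcomes An [classify_outcomes()] result (or a list of them).
#' @param pcpe `C x H x W` per-class PE array (or a list, matching
#'   `outcomes`); see [per_class_pe()].
#' @param bins Strictly increasing histogram bin edges covering \[0, 1/e\].
#' @return List with `histogram` (per class/outcome/bin counts; empty
#'   outcome categories are zero-filled and flagged) and `summary` (per
#'   class: `frac_correct_le_0.05`, `frac_wrong_gt_0.10`, pixel counts).
#' @export
pe_distribution_by_outcome <- function(outcomes, pcpe,
                                       bins = c(0, 0.05, 0.10, 0.20, 0.30, exp(-1))) {
  if (inherits(outcomes, "outcome_map")) {
    outcomes <- list(outcomes); pcpe <- list(pcpe)
  }
  stopifnot(length(outcomes) == length(pcpe), length(bins) >= 2L,
            all(diff(bins) > 0))
  C <- dim(outcomes[[1]]$codes)[1]
  cls <- outcomes[[1]]$class_names
  hist_rows <- list(); sum_rows <- list()
  for (ci in seq_len(C)) {
    codes <- unlist(lapply(outcomes, function(o) as.vector(o$codes[ci, , ])))
    pes <- unlist(lapply(pcpe, function(p) as.vector(p[ci, , ])))
    for (oi in seq_along(OUTCOME_LEVELS)) {
      x <- pes[codes == oi]
      cnt <- if (length(x)) {
        tabulate(findInterval(x, bins, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = length(bins) - 1L)
      } else rep(0L, length(bins) - 1L)
      hist_rows[[length(hist_rows) + 1L]] <- data.frame(
        class = cls[ci], outcome = OUTCOME_LEVELS[oi],
        bin_lo = head(bins, -1L), bin_hi = tail(bins, -1L), count = cnt,
        empty = length(x) == 0L)
    }
    correct <- pes[codes %in% c(1L, 4L)]
    wrong <- pes[codes %in% c(2L, 3L)]
    sum_rows[[length(sum_rows) + 1L]] <- data.frame(
      class = cls[ci],
      n_correct = length(correct), n_wrong = length(wrong),
      frac_correct_le_0.05 = if (length(correct)) mean(correct <= 0.05) else NA_real_,
      frac_wrong_gt_0.10 = if (length(wrong)) mean(wrong > 0.10) else NA_real_)
  }
  list(histogram = do.call(rbind, hist_rows), summary = do.call(rbind, sum_rows))
}

# Count-based Dice with the undefined case flagged as NA (not 0 or 1).
dice_from_counts <- function(tp, fp, fn) {
  den <- 2 * tp + fp + fn
  if (den == 0) NA_real_ else 2 * tp / den
}

#' Certain/uncertain grouped Dice at a PE threshold
#'
#' Splits each class's pixels into an "uncertain" group (per-class PE
#' strictly above the threshold) and a "certain" group (at or below), then
#' computes the count-based Dice `2TP / (2TP + FP + FN)` within each group.
#' TN pixels enter neither numerator nor denominator. A group with
#' `2TP + FP + FN = 0` has undefined Dice, reported as `NA`.
#'
#' @param outcomes An [classify_outcomes()] result.
#' @param pcpe `C x H x W` per-class PE array.
#' @param threshold PE threshold (>= 0), in nats.
#' @return Data frame: class, group, tp/fp/fn counts, dice.
#' @export
grouped_dice <- function(outcomes, pcpe, threshold) {
  stopifnot(inherits(outcomes, "outcome_map"), threshold >= 0,
            identical(dim(outcomes$codes), dim(pcpe)))
  C <- dim(outcomes$codes)[1]
  rows <- list()
  for (ci in seq_len(C)) {
    codes <- as.vector(outcomes$codes[ci, , ])
    unc <- as.vector(pcpe[ci, , ]) > threshold
    for (g in c("certain", "uncertain")) {
      sel <- if (g == "certain") !unc else unc
      tp <- sum(codes == 1L & sel); fp <- sum(codes == 2L & sel)
      fn <- sum(codes == 3L & sel)
      rows[[length(rows) + 1L]] <- data.frame(
        class = outcomes$class_names[ci], group = g, threshold = threshold,
        tp = tp, fp = fp, fn = fn, dice = dice_from_counts(tp, fp, fn))
    }
  }
  do.call(rbind, rows)
}

#' Sweep PE thresholds and report grouped Dice per group and class
#'
#' Runs [grouped_dice()] at each threshold for each image, then reports the
#' per-image mean and standard deviation of the group Dice per class and
#' threshold (undefined group Dice excluded), together with a pooled-count
#' variant in which TP/FP/FN are summed over all images before the Dice is
#' formed. The default sweep is 0.30 to 0.36 in steps of 0.01.
#'
#' @param outcomes An [classify_outcomes()] result or a list of them (one
#'   per image).
#' @param pcpe A `C x H x W` array or a list matching `outcomes`.
#' @param thresholds Strictly increasing PE thresholds.
#' @return A `threshold_sweep` object with `per_image` and `summary` data
#'   frames; `summary` carries both the per-image mean +/- sd and the
#'   pooled-count Dice.
#' @export
threshold_sweep <- function(outcomes, pcpe,
                            thresholds = seq(0.30, 0.36, by = 0.01)) {
  if (inherits(outcomes, "outcome_map")) {
    outcomes <- list(outcomes); pcpe <- list(pcpe)
  }
  if (length(thresholds) < 1L || any(diff(thresholds) <= 0)) {
    stop("thresholds must be a strictly increasing sequence")
  }
  stopifnot(length(outcomes) == length(pcpe))
  per_image <- do.call(rbind, lapply(seq_along(outcomes), function(i) {
    do.call(rbind, lapply(thresholds, function(th) {
      cbind(image = i, grouped_dice(outcomes[[i]], pcpe[[i]], th))
    }))
  }))
  agg <- function(df) {
    sp <- split(df, list(df$threshold, df$class, df$group), drop = FALSE)
    do.call(rbind, lapply(sp, function(d) {
      data.frame(threshold = d$threshold[1], class = d$class[1],
                 group = d$group[1],
                 mean_dice = mean(d$dice, na.rm = TRUE),
                 sd_dice = if (sum(!is.na(d$dice)) > 1) sd(d$dice, na.rm = TRUE) else NA_real_,
                 n_images = sum(!is.na(d$dice)),
                 pooled_dice = dice_from_counts(sum(d$tp), sum(d$fp), sum(d$fn)))
    }))
  }
  summary <- agg(per_image)
  rownames(summary) <- NULL
  structure(list(per_image = per_image, summary = summary,
                 thresholds = thresholds),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("<threshold_sweep> thresholds %s over %d image(s)\n",
              paste(format(x$thresholds), collapse = ", "),
              max(x$per_image$image)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
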