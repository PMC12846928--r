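#' Scan-level uncertainty summary
#'
#' Global (unmasked) arithmetic means of the mutual-information and
#' predictive-entropy maps over all voxels of a scan. The mean MI is the
#' scan-level out-of-distribution score: epistemic uncertainty is expected
#' to rise when the model is applied outside its training distribution.
#'
#' @param mi_volume Array (any shape) of per-voxel MI values.
#' @param pe_volume Array of the same shape of per-voxel PE values.
#' @param scan_id Identifier for the scan.
#' @param cohort_label `"ID"`, `"OOD"` or `"unknown"`.
#' @return A `scan_uncertainty_summary` list with `scan_id`, `mean_mi`,
#'   `mean_pe` and `cohort_label`.
#' @export
summarize_scan <- function(mi_volume, pe_volume, scan_id,
                           cohort_label = c("unknown", "ID", "OOD")) {
  cohort_label <- match.arg(cohort_label)
  if (length(mi_volume) == 0) stop("empty volume")
  if (!identical(dim(mi_volume), dim(pe_volume))) stop("volume shapes differ")
  structure(list(scan_id = scan_id, mean_mi = mean(mi_volume),
                 mean_pe = mean(pe_volume), cohort_label = cohort_label),
            class = "scan_uncertainty_summary")
}

extract_mean_mi <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  vapply(x, function(s) {
    if (inherits(s, "scan_uncertainty_summary")) s$mean_mi else as.numeric(s)
  }, 0)
}

#' Separation analysis between ID and OOD scan-level scores
#'
#' Exhaustively scans decision thresholds over the pooled scan scores
#' (a scan is called OOD when its score is at or above the threshold) and
#' reports the best achievable accuracy, the threshold interval achieving
#' it, and the margin `min(OOD) - max(ID)`. The margin is positive exactly
#' when a strict threshold separates the cohorts completely.
#'
#' @param id_summaries,ood_summaries Numeric vectors of scan scores (e.g.
#'   mean MI), or lists of [summarize_scan()] results.
#' @return A `separation_report` with `best_accuracy`,
#'   `threshold_interval` (lo, hi\]: thresholds in this half-open interval
#'   achieve the best accuracy), `margin`, and the raw score vectors.
#' @export
separation_analysis <- function(id_summaries, ood_summaries) {
  id <- extract_mean_mi(id_summaries)
  ood <- extract_mean_mi(ood_summaries)
  stopifnot(length(id) > 0, length(ood) > 0)
  vals <- sort(unique(c(id, ood)))
  cand <- c(vals, Inf)
  acc <- vapply(cand, function(t) (sum(ood >= t) + sum(id < t)) /
                  (length(id) + length(ood)), 0)
  best <- max(acc)
  ib <- which(acc == best)
  # contiguous run of best candidates starting at the first; thresholds in
  # (previous candidate, last of run] all achieve the best accuracy
  run_end <- ib[1]
  while (run_end + 1L <= length(cand) && acc[run_end + 1L] == best) {
    run_end <- run_end + 1L
  }
  lo <- if (ib[1] == 1L) -Inf else cand[ib[1] - 1L]
  hi <- cand[run_end]
  structure(list(best_accuracy = best, threshold_interval = c(lo, hi),
                 margin = min(ood) - max(id), id_values = id,
                 ood_values = ood),
            class = "separation_report")
}

#' @export
print.separation_report <- function(x, ...) {
  cat(sprintf(paste0("<separation_report> accuracy %.1f%% for thresholds in ",
                     "(%.4g, %.4g]; margin %.4g\n"),
              100 * x$best_accuracy, x$threshold_interval[1],
              x$threshold_interval[2], x$margin))
  invisible(x)
}
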