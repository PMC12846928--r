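FLAG_LEVELS <- c("certain_positive", "certain_negative",
                 "uncertain_positive", "uncertain_negative")

#' Four-way certainty flagging of a predicted segmentation
#'
#' Partitions pixels by predicted label and a PE threshold (default 0.30
#' nats): a pixel predicted as the structure of interest with PE above the
#' threshold is `uncertain_positive` (a potential false positive); a pixel
#' predicted as something else with PE above the threshold is
#' `uncertain_negative` (a potential false negative); below-threshold pixels
#' are `certain_positive` / `certain_negative` by predicted label.
#'
#' @param label_mask Predicted integer label mask (H x W).
#' @param maps An [uncertainty_maps()] object, or a numeric PE matrix/array.
#' @param threshold PE threshold in nats (>= 0; default 0.30).
#' @param class_id Structure class (1..3) whose per-class PE drives the
#'   flags, or `NULL` for all-classes mode ("positive" means any structure,
#'   thresholding the total PE map).
#' @return A `flag_map`: integer H x W matrix with levels
#'   `certain_positive` (1), `certain_negative` (2), `uncertain_positive`
#'   (3), `uncertain_negative` (4), plus `threshold`/`class_id` attributes.
#' @export
flag_pixels <- function(label_mask, maps, threshold = 0.30, class_id = 1L) {
  stopifnot(threshold >= 0)
  check_label_mask(label_mask, what = "label_mask")
  if (is.null(class_id)) {
    pe <- if (inherits(maps, "uncertainty_maps")) maps$pe else maps
    stopifnot(is.matrix(pe))
    positive <- label_mask != 0L
  } else {
    stopifnot(class_id %in% 1:3)
    pe <- if (inherits(maps, "uncertainty_maps")) {
      maps$per_class_pe[class_id + 1L, , ]
    } else if (is.matrix(maps)) maps else maps[class_id + 1L, , ]
    positive <- label_mask == class_id
  }
  if (!identical(dim(pe), dim(label_mask))) stop("map and mask shapes differ")
  unc <- pe > threshold
  codes <- matrix(2L, nrow(label_mask), ncol(label_mask))
  codes[positive & !unc] <- 1L
  codes[positive & unc] <- 3L
  codes[!positive & unc] <- 4L
  structure(codes, class = "flag_map", levels = FLAG_LEVELS,
            threshold = threshold, class_id = class_id)
}

#' @export
print.flag_map <- function(x, ...) {
  tab <- tabulate(unclass(x), nbins = 4L)
  cat("<flag_map> threshold", attr(x, "threshold"), "\n")
  print(setNames(tab, FLAG_LEVELS))
  invisible(x)
}

# fixed palettes ------------------------------------------------------------

label_palette <- function() {
  # background, ctv, bladder, rectum
  rbind(c(0, 0, 0), c(0.85, 0.33, 0.10), c(0.00, 0.45, 0.74), c(0.47, 0.67, 0.19))
}

flag_palette <- function() {
  # lightest -> darkest: certain_negative, certain_positive,
  # uncertain_negative, uncertain_positive (darkest = potential FP)
  rbind(certain_positive = c(0.74, 0.74, 0.74),
        certain_negative = c(0.94, 0.94, 0.94),
        uncertain_positive = c(0.15, 0.15, 0.15),
        uncertain_negative = c(0.45, 0.45, 0.45))
}

heat_colors <- function(x, max_val) {
  # black-red-yellow sequential map on [0, max_val]
  v <- pmin(pmax(x / max_val, 0), 1)
  r <- pmin(2 * v, 1); g <- pmax(2 * v - 1, 0)
  array(c(r, g, 0 * v), c(dim(x), 3L))
}

gray_rgb <- function(x) {
  v <- pmin(pmax(x, 0), 1)
  array(rep(v, 3L), c(dim(x), 3L))
}

index_rgb <- function(idx, palette) {
  array(c(matrix(palette[idx, 1], nrow(idx)), matrix(palette[idx, 2], nrow(idx)),
          matrix(palette[idx, 3], nrow(idx))), c(dim(idx), 3L))
}

#' Render a QA panel figure for one slice
#'
#' Writes a deterministic PNG with six panels: input image, ground truth,
#' prediction, prediction error (the mismatch between the binarized average
#' prediction and the reference), the PE uncertainty map, and the four-shade
#' flag map (uncertain pixels in the two darkest shades).
#'
#' @param image H x W grayscale input in \[0, 1\].
#' @param truth,pred Integer label masks.
#' @param pe_map H x W predictive entropy map.
#' @param flag_map A [flag_pixels()] result.
#' @param file Output PNG path.
#' @param error_map Optional logical mismatch map; defaults to
#'   `pred != truth`.
#' @return The output path, invisibly.
#' @export
render_panels <- function(image, truth, pred, pe_map, flag_map, file,
                          error_map = NULL) {
  stopifnot(identical(dim(image), dim(truth)), identical(dim(image), dim(pred)))
  if (is.null(error_map)) error_map <- pred != truth
  pal <- label_palette()
  panels <- list(gray_rgb(image),
                 index_rgb(truth + 1L, pal),
                 index_rgb(pred + 1L, pal),
                 gray_rgb(1 - 1 * error_map),
                 heat_colors(pe_map, log(4)),
                 index_rgb(matrix(unclass(flag_map), nrow(flag_map)), flag_palette()))
  H <- nrow(image); W <- ncol(image); gap <- 2L
  canvas <- array(1, c(2L * H + gap, 3L * W + 2L * gap, 3L))
  for (i in seq_along(panels)) {
    r0 <- if (i <= 3L) 0L else H + gap
    c0 <- ((i - 1L) %% 3L) * (W + gap)
    canvas[r0 + seq_len(H), c0 + seq_len(W), ] <- panels[[i]]
  }
  png::writePNG(canvas, target = file)
  invisible(file)
}
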