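default_shape_params <- function(cohort) {
  # All geometry in fractions of the image side: center (row, col), ellipse
  # semi-axes (row, col). The OOD cohort has smaller bladders and a wider
  # spread of rectum sizes, mimicking a healthy-volunteer cohort scanned
  # without a drinking protocol.
  sp <- list(
    ctv     = list(center_mu = c(0.50, 0.50), center_sd = 0.020,
                   axes_mu = c(0.110, 0.100), axes_sd = 0.010),
    bladder = list(center_mu = c(0.20, 0.50), center_sd = 0.020,
                   axes_mu = c(0.135, 0.155), axes_sd = 0.015),
    rectum  = list(center_mu = c(0.79, 0.50), center_sd = 0.020,
                   axes_mu = c(0.070, 0.080), axes_sd = 0.007)
  )
  if (cohort == "OOD") {
    sp$bladder$axes_mu <- c(0.095, 0.105)
    sp$bladder$axes_sd <- 0.012
    sp$rectum$axes_mu <- c(0.080, 0.090)
    sp$rectum$axes_sd <- 0.022
  }
  sp
}

default_intensity_means <- function(cohort) {
  # ID mimics T2-weighted contrast (bright urine-filled bladder); OOD inverts
  # the bladder/background ordering and shifts the overall contrast, the two
  # axes along which the out-of-distribution cohort differs.
  if (cohort == "ID") {
    c(background = 0.20, ctv = 0.50, bladder = 0.90, rectum = 0.35)
  } else {
    c(background = 0.45, ctv = 0.65, bladder = 0.15, rectum = 0.30)
  }
}

#' Specification of a synthetic pelvic phantom
#'
#' Describes a square grayscale image containing three elliptical structures
#' (a central target, an anterior bladder and a posterior rectum) on a
#' uniform background, with per-class mean intensities and additive Gaussian
#' noise. Two cohorts are built in: `"ID"` (in-distribution, the training
#' domain) and `"OOD"`, which differs in both intensity contrast (the
#' bladder/background intensity ordering is inverted) and shape statistics
#' (smaller bladders, more variable rectums).
#'
#' @param image_size Pixels per side (must be divisible by 8 for the default
#'   network depth; default 64).
#' @param cohort `"ID"` or `"OOD"`.
#' @param intensity_means Length-4 vector of per-class mean gray values in
#'   \[0, 1\] (background, ctv, bladder, rectum). Defaults depend on cohort.
#' @param noise_sigma Standard deviation of additive Gaussian noise (>= 0).
#' @param shape_params Per-structure center/axis distributions (fractions of
#'   the image side); see `default_shape_params`. Defaults depend on cohort.
#' @param seed Integer seed; identical spec + seed reproduces identical
#'   output bit for bit.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(image_size = 64L, cohort = c("ID", "OOD"),
                         intensity_means = NULL, noise_sigma = 0.05,
                         shape_params = NULL, seed = 1L) {
  cohort <- match.arg(cohort)
  if (is.null(intensity_means)) intensity_means <- default_intensity_means(cohort)
  if (is.null(shape_params)) shape_params <- default_shape_params(cohort)
  stopifnot(is_count(image_size), image_size >= 16,
            length(intensity_means) == SEG_N_CLASSES,
            all(intensity_means >= 0), all(intensity_means <= 1),
            noise_sigma >= 0,
            setequal(names(shape_params), c("ctv", "bladder", "rectum")))
  structure(list(image_size = as.integer(image_size), class_count = SEG_N_CLASSES,
                 cohort = cohort, intensity_means = intensity_means,
                 noise_sigma = noise_sigma, shape_params = shape_params,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Draw one set of structure parameters (in pixels) from the spec.
draw_structure_params <- function(spec) {
  n <- spec$image_size
  lapply(spec$shape_params, function(sp) {
    list(center = (sp$center_mu + rnorm(2) * sp$center_sd) * n,
         axes = pmax((sp$axes_mu + rnorm(2) * sp$axes_sd), 0.02) * n)
  })
}

# Rasterize the three ellipses into a label mask; NULL if the configuration
# is invalid (overlap, out of bounds, or a structure below 1% area).
rasterize_structures <- function(params, n) {
  mask <- matrix(0L, n, n)
  ii <- matrix(seq_len(n), n, n)        # row coordinate
  jj <- matrix(seq_len(n), n, n, byrow = TRUE)
  min_area <- 0.01 * n * n
  for (k in seq_along(params)) {
    p <- params[[k]]
    if (any(p$center - p$axes < 1) || any(p$center + p$axes > n)) return(NULL)
    inside <- ((ii - p$center[1]) / p$axes[1])^2 +
      ((jj - p$center[2]) / p$axes[2])^2 <= 1
    if (sum(inside) < min_area) return(NULL)
    if (any(mask[inside] != 0L)) return(NULL)  # structures must not overlap
    mask[inside] <- k
  }
  mask
}

render_phantom_image <- function(mask, spec) {
  img <- matrix(spec$intensity_means[mask + 1L], nrow(mask), ncol(mask))
  if (spec$noise_sigma > 0) {
    img <- img + rnorm(length(img), sd = spec$noise_sigma)
    img <- pmin(pmax(img, 0), 1)
  }
  img
}

#' Generate a single phantom slice
#'
#' @param spec A [phantom_spec()].
#' @param max_tries Rejection-sampling retries for non-overlapping placement.
#' @return A list with `image` (H x W matrix in \[0, 1\]), `mask` (H x W
#'   integer label matrix, 0..3) and the `spec`.
#' @export
generate_phantom <- function(spec, max_tries = 100L) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_rng(spec$seed, {
    mask <- NULL
    for (i in seq_len(max_tries)) {
      params <- draw_structure_params(spec)
      mask <- rasterize_structures(params, spec$image_size)
      if (!is.null(mask)) break
    }
    if (is.null(mask)) {
      stop("could not place non-overlapping structures; loosen shape_params")
    }
    list(image = render_phantom_image(mask, spec), mask = mask, spec = spec)
  })
}

#' Generate a cohort of multi-slice phantom scans
#'
#' Each scan draws one set of structure parameters and perturbs it slightly
#' per slice (small center jitter and axis scaling), emulating through-plane
#' anatomical variation. Each scan uses its own random substream derived from
#' the spec seed, so the cohort is reproducible independent of generation
#' order.
#'
#' @param spec A [phantom_spec()].
#' @param n_scans Number of scans (>= 1).
#' @param slices_per_scan Slices per scan (>= 1).
#' @param slice_jitter Per-slice center jitter (fraction of image side).
#' @param slice_axis_cv Per-slice coefficient of variation of the axes.
#' @return A list of scans; each scan is a list with `image` and `mask`
#'   arrays of shape `(slices, H, W)`, a `scan_id` and the `cohort` label.
#' @export
generate_cohort <- function(spec, n_scans = 10L, slices_per_scan = 8L,
                            slice_jitter = 0.004, slice_axis_cv = 0.03) {
  stopifnot(inherits(spec, "phantom_spec"), is_count(n_scans),
            is_count(slices_per_scan))
  n <- spec$image_size
  lapply(seq_len(n_scans), function(s) {
    with_rng(derive_seed(spec$seed, s), {
      base <- NULL
      for (i in seq_len(100L)) {
        params <- draw_structure_params(spec)
        if (!is.null(rasterize_structures(params, n))) { base <- params; break }
      }
      if (is.null(base)) stop("could not place non-overlapping structures")
      img <- array(0, c(slices_per_scan, n, n))
      msk <- array(0L, c(slices_per_scan, n, n))
      for (sl in seq_len(slices_per_scan)) {
        mask <- NULL
        for (i in seq_len(20L)) {
          pert <- lapply(base, function(p) {
            list(center = p$center + rnorm(2) * slice_jitter * n,
                 axes = p$axes * (1 + rnorm(2) * slice_axis_cv))
          })
          mask <- rasterize_structures(pert, n)
          if (!is.null(mask)) break
        }
        if (is.null(mask)) mask <- rasterize_structures(base, n)
        msk[sl, , ] <- mask
        img[sl, , ] <- render_phantom_image(mask, spec)
      }
      list(image = img, mask = msk,
           scan_id = sprintf("%s_scan%02d", spec$cohort, s),
           cohort = spec$cohort)
    })
  })
}
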