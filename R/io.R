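#' Read a NIfTI volume
#'
#' @param path Path to a NIfTI file.
#' @param mask If `TRUE`, validate that the volume contains integer labels
#'   in 0..3 and return an integer array.
#' @return List with `data` (array) and `spacing` (per-axis physical size;
#'   unit spacing with a warning when the file carries none).
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  data <- array(as.vector(img), dim(img))
  spacing <- RNifti::pixdim(img)
  if (length(spacing) != length(dim(data)) || any(!is.finite(spacing)) ||
      any(spacing <= 0)) {
    warning("no usable voxel spacing in ", path, "; assuming unit spacing")
    spacing <- rep(1, length(dim(data)))
  }
  if (mask) {
    check_label_mask(data, what = paste0("mask file ", path))
    data <- array(as.integer(data), dim(data))
  }
  list(data = data, spacing = as.numeric(spacing))
}

#' Write a NIfTI volume
#'
#' @param volume Numeric or integer array (image or label mask).
#' @param spacing Per-axis physical size.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param mask If `TRUE`, store as unsigned 8-bit integer labels; images are
#'   stored as double precision so that a write/read round trip is bitwise
#'   exact.
#' @return The path, invisibly.
#' @export
write_volume <- function(volume, spacing, path, mask = FALSE) {
  stopifnot(length(spacing) == length(dim(volume)), all(spacing > 0))
  if (mask) check_label_mask(volume, what = "mask volume")
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = if (mask) "uint8" else "double")
  invisible(path)
}

#' Write a phantom cohort to a directory as NIfTI pairs
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param spacing Per-axis spacing of the `(slice, row, col)` volumes.
#' @return Data frame of written image/mask paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, spacing = c(3, 1, 1)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- do.call(rbind, lapply(cohort, function(sc) {
    ip <- file.path(dir, paste0(sc$scan_id, "_image.nii.gz"))
    mp <- file.path(dir, paste0(sc$scan_id, "_mask.nii.gz"))
    write_volume(sc$image, spacing, ip)
    write_volume(sc$mask, spacing, mp, mask = TRUE)
    data.frame(scan_id = sc$scan_id, image = ip, mask = mp)
  }))
  invisible(paths)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is self-describing: it stores the model configuration,
#' all weights, the learned per-layer dropout probabilities and the loss
#' trace.
#'
#' @param model A `seg_unet`.
#' @param path Checkpoint path.
#' @return `save_model` returns the path invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "seg_unet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "seg_unet")) stop("not a seg_unet checkpoint: ", path)
  model
}

#' Configuration for a full phantom study
#'
#' Bundles every tunable of the end-to-end pipeline: cohort sizes, model and
#' training configuration, the number of Monte Carlo passes, the PE
#' threshold sweep and the master seed. All invariants of the component
#' configurations are checked here, before any stage runs.
#'
#' @param out_dir Output directory.
#' @param image_size Phantom side length in pixels.
#' @param n_train_scans,n_test_scans,n_ood_scans Cohort sizes.
#' @param slices_per_scan Slices per scan.
#' @param model A [model_config()].
#' @param train A [train_config()].
#' @param T Monte Carlo passes per slice (>= 1).
#' @param thresholds Strictly increasing PE thresholds for the sweep.
#' @param flag_threshold PE threshold for the rendered flag map.
#' @param render Whether to write example panel figures.
#' @param seed Master seed; every stage derives its own substream from it.
#' @return A `run_config` object.
#' @export
run_config <- function(out_dir = tempfile("segqa_run_"), image_size = 64L,
                       n_train_scans = 10L, n_test_scans = 10L,
                       n_ood_scans = 10L, slices_per_scan = 8L,
                       model = model_config(), train = train_config(),
                       T = 50L, thresholds = seq(0.30, 0.36, by = 0.01),
                       flag_threshold = 0.30, render = TRUE, seed = 1L) {
  stopifnot(inherits(model, "model_config"), inherits(train, "train_config"),
            is_count(T), is_count(image_size), is_count(n_train_scans),
            is_count(n_test_scans), is_count(n_ood_scans),
            is_count(slices_per_scan), flag_threshold >= 0)
  if (length(thresholds) == 0) stop("thresholds must be a non-empty increasing list")
  if (any(diff(thresholds) <= 0)) stop("thresholds must be strictly increasing")
  if (image_size %% 2^(model$levels - 1L) != 0) {
    stop("image_size must be divisible by 2^(levels-1)")
  }
  if (n_train_scans <= train$val_scans) {
    stop("n_train_scans must exceed the validation split")
  }
  structure(list(out_dir = out_dir, image_size = as.integer(image_size),
                 n_train_scans = as.integer(n_train_scans),
                 n_test_scans = as.integer(n_test_scans),
                 n_ood_scans = as.integer(n_ood_scans),
                 slices_per_scan = as.integer(slices_per_scan),
                 model = model, train = train, T = as.integer(T),
                 thresholds = thresholds, flag_threshold = flag_threshold,
                 render = isTRUE(render), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; `model` and `train`
#' sub-maps are passed to [model_config()] and [train_config()].
#'
#' @param path YAML file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$model)) y$model <- do.call(model_config, y$model)
  if (!is.null(y$train)) y$train <- do.call(train_config, y$train)
  do.call(run_config, y)
}

stage_msg <- function(stage, seed, ...) {
  message(sprintf("[segqa:%s] seed=%s %s", stage, seed, sprintf(...)))
}

#' Run the full phantom study end to end
#'
#' Executes generate -> train -> Monte Carlo inference -> uncertainty ->
#' error analysis -> geometry evaluation -> OOD scoring -> rendering, with
#' every stage's outputs written under `config$out_dir` and a manifest
#' recording seeds, versions and the configuration hash. The whole run is
#' reproducible from the master seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the trained model, per-scan uncertainty
#'   summaries, the threshold sweep, the PE-by-outcome distribution report,
#'   the geometry metrics and the ID/OOD separation report.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(config$out_dir, "config.yaml")
  # the written configuration omits out_dir so that identical studies in
  # different directories produce identical config files and manifests
  cfg_plain <- rapply(unclass(config)[names(unclass(config)) != "out_dir"],
                      unclass, how = "replace")
  yaml::write_yaml(cfg_plain, cfg_path)
  seed <- config$seed

  # --- generate ------------------------------------------------------------
  stage_msg("generate", seed, "phantom cohorts (%d train / %d test / %d OOD)",
            config$n_train_scans, config$n_test_scans, config$n_ood_scans)
  id_spec <- function(salt) phantom_spec(config$image_size, "ID",
                                         seed = derive_seed(seed, salt))
  train_cohort <- generate_cohort(id_spec(1L), config$n_train_scans,
                                  config$slices_per_scan)
  test_cohort <- generate_cohort(id_spec(2L), config$n_test_scans,
                                 config$slices_per_scan)
  ood_cohort <- generate_cohort(phantom_spec(config$image_size, "OOD",
                                             seed = derive_seed(seed, 3L)),
                                config$n_ood_scans, config$slices_per_scan)
  write_cohort(train_cohort, file.path(config$out_dir, "cohort_train"))
  write_cohort(test_cohort, file.path(config$out_dir, "cohort_test"))
  write_cohort(ood_cohort, file.path(config$out_dir, "cohort_ood"))

  # --- train ---------------------------------------------------------------
  stage_msg("train", derive_seed(seed, 5L), "%d epochs, batch %d, lr %g",
            config$train$epochs, config$train$batch_size, config$train$lr)
  model <- build_model(config$model, seed = derive_seed(seed, 4L))
  tc <- config$train
  tc$seed <- derive_seed(seed, 5L)
  model <- train_model(model, train_cohort, tc)
  save_model(model, file.path(config$out_dir, "checkpoint.rds"))

  # --- inference + uncertainty + analysis ---------------------------------
  analyze_scan <- function(sc, idx) {
    ens <- sample_ensemble_volume(model, sc$image, T = config$T,
                                  seed = derive_seed(seed, 100L + idx))
    maps <- lapply(ens, uncertainty_maps)
    preds <- lapply(ens, mean_and_binarize)
    S <- dim(sc$image)[1]
    list(maps = maps, preds = preds,
         mi = array(unlist(lapply(maps, `[[`, "mi")),
                    c(dim(sc$image)[2:3], S)),
         pe = array(unlist(lapply(maps, `[[`, "pe")),
                    c(dim(sc$image)[2:3], S)))
  }
  stage_msg("infer", seed, "T=%d passes over %d ID test + %d OOD scans",
            config$T, length(test_cohort), length(ood_cohort))
  test_res <- lapply(seq_along(test_cohort),
                     function(i) analyze_scan(test_cohort[[i]], i))
  ood_res <- lapply(seq_along(ood_cohort),
                    function(i) analyze_scan(ood_cohort[[i]], 1000L + i))
  for (i in seq_along(test_cohort)) {
    write_volume(test_res[[i]]$mi, c(1, 1, 3),
                 file.path(config$out_dir,
                           paste0(test_cohort[[i]]$scan_id, "_mi.nii.gz")))
  }

  stage_msg("analyze", seed, "outcome stratification and threshold sweep")
  outcomes <- list(); pcpes <- list(); metr <- list()
  for (i in seq_along(test_cohort)) {
    sc <- test_cohort[[i]]; res <- test_res[[i]]
    for (s in seq_len(dim(sc$image)[1])) {
      pred <- res$preds[[s]]$label_mask
      truth <- sc$mask[s, , ]
      outcomes[[length(outcomes) + 1L]] <- classify_outcomes(pred, truth)
      pcpes[[length(pcpes) + 1L]] <- res$maps[[s]]$per_class_pe
      m <- seg_metrics(pred, truth)
      m$scan <- sc$scan_id; m$slice <- s
      metr[[length(metr) + 1L]] <- m
    }
  }
  sweep <- threshold_sweep(outcomes, pcpes, config$thresholds)
  dist <- pe_distribution_by_outcome(outcomes, pcpes)
  metrics <- do.call(rbind, metr)
  utils::write.csv(sweep$summary, file.path(config$out_dir, "threshold_sweep.csv"),
                   row.names = FALSE)
  utils::write.csv(dist$summary, file.path(config$out_dir, "pe_by_outcome.csv"),
                   row.names = FALSE)
  utils::write.csv(metrics, file.path(config$out_dir, "seg_metrics.csv"),
                   row.names = FALSE)

  # --- OOD -----------------------------------------------------------------
  stage_msg("ood", seed, "scan-level mean MI separation")
  summ <- function(res, cohort, label) {
    lapply(seq_along(cohort), function(i) {
      summarize_scan(res[[i]]$mi, res[[i]]$pe, cohort[[i]]$scan_id, label)
    })
  }
  id_sum <- summ(test_res, test_cohort, "ID")
  ood_sum <- summ(ood_res, ood_cohort, "OOD")
  sep <- separation_analysis(id_sum, ood_sum)
  jsonlite::write_json(
    list(id = lapply(id_sum, unclass), ood = lapply(ood_sum, unclass),
         best_accuracy = sep$best_accuracy,
         threshold_interval = sep$threshold_interval, margin = sep$margin),
    file.path(config$out_dir, "ood_separation.json"), auto_unbox = TRUE,
    digits = NA)

  # --- render --------------------------------------------------------------
  if (config$render) {
    stage_msg("render", seed, "example QA panels")
    sc <- test_cohort[[1]]; res <- test_res[[1]]
    fm <- flag_pixels(res$preds[[1]]$label_mask, res$maps[[1]],
                      threshold = config$flag_threshold, class_id = 1L)
    render_panels(sc$image[1, , ], sc$mask[1, , ], res$preds[[1]]$label_mask,
                  res$maps[[1]]$pe, fm,
                  file.path(config$out_dir, "example_panels.png"))
  }

  manifest <- list(package = "segqa",
                   version = as.character(utils::packageVersion("segqa")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = seed,
                   stage_seeds = list(generate = sapply(1:3, derive_seed,
                                                        master = seed),
                                      init = derive_seed(seed, 4L),
                                      train = derive_seed(seed, 5L)),
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   mean_dropout_probability = mean(model$dropout_probs))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(model = model, sweep = sweep, dist = dist, metrics = metrics,
                 separation = sep, id_summaries = id_sum,
                 ood_summaries = ood_sum, config = config))
}
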