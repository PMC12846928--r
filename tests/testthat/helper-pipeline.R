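# The full desk-scale study (default cohorts, trained dropout U-Net, T = 50
# Monte Carlo ensembles over the held-out ID test set and the OOD cohort),
# trained once per test run and shared by the acceptance tests.
acceptance_pipeline <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    seed <- 1L
    ds <- function(salt) segqa:::derive_seed(seed, salt)
    size <- formals(phantom_spec)$image_size
    train_cohort <- generate_cohort(phantom_spec(size, "ID", seed = ds(1L)))
    test_cohort <- generate_cohort(phantom_spec(size, "ID", seed = ds(2L)))
    ood_cohort <- generate_cohort(phantom_spec(size, "OOD", seed = ds(3L)))
    model <- build_model(model_config(), seed = ds(4L))
    model <- train_model(model, train_cohort, train_config(seed = ds(5L)))

    outcomes <- list(); pcpes <- list(); dsc <- NULL
    id_mi <- ood_mi <- c()
    for (i in seq_along(test_cohort)) {
      sc <- test_cohort[[i]]
      ens <- sample_ensemble_volume(model, sc$image, T = 50L, seed = ds(100L + i))
      mis <- c()
      for (s in seq_along(ens)) {
        pred <- mean_and_binarize(ens[[s]])$label_mask
        maps <- uncertainty_maps(ens[[s]])
        outcomes[[length(outcomes) + 1L]] <- classify_outcomes(pred, sc$mask[s, , ])
        pcpes[[length(pcpes) + 1L]] <- maps$per_class_pe
        mis <- c(mis, mean(maps$mi))
        dsc <- rbind(dsc, seg_metrics(pred, sc$mask[s, , ])$dsc)
      }
      id_mi <- c(id_mi, mean(mis))
    }
    for (i in seq_along(ood_cohort)) {
      ens <- sample_ensemble_volume(model, ood_cohort[[i]]$image, T = 50L,
                                    seed = ds(1000L + i))
      ood_mi <- c(ood_mi, mean(vapply(ens, function(e)
        mean(mutual_information(e)), 0)))
    }
    cache <<- list(model = model, outcomes = outcomes, pcpes = pcpes,
                   dsc = dsc, id_mi = id_mi, ood_mi = ood_mi,
                   sweep = threshold_sweep(outcomes, pcpes),
                   dist = pe_distribution_by_outcome(outcomes, pcpes))
    cache
  }
})
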