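# Shared study-scale experiment runner for the acceptance-style tests.
# Trained models are cached per (seed, variant) within the test session so
# the signal, collaboration and interpretability checks reuse the same runs.

study_sim_config <- function(seed) {
  sim_config(n_proteins = 300L, len_range = c(30L, 60L), d_h = 16L,
             catalogue = default_motif_catalogue(k = 10L, mu = 4),
             noise_rate = 0.05, seed = seed)
}

study_model_config <- function(seed, variant = "full") {
  cfg <- model_config(d_h = 16L, d_p = 32L, h_d = 4L, n_layers = 2L,
                      d_fe = 32L, d_F = 64L, h_ki = 4L, ratio = 0.5,
                      M_bp = 8L, M_cc = 5L, M_mf = 5L, C = 4L,
                      alpha = 2, beta = 0.2, omega = 2,
                      lr = 3e-3, weight_decay = 5e-4, batch_size = 4L,
                      epochs = 30L, seed = seed)
  if (variant != "full") {
    cfg[[variant]] <- TRUE
    class(cfg) <- "model_config"
  }
  cfg
}

.study_cache <- new.env(parent = emptyenv())

# train on the 80% split, select on the 10% validation split, and evaluate
# on the 10% test split; returns model, per-task metric reports and the
# test records (for the interpretability check)
study_run <- function(seed, variant = "full") {
  key <- paste(variant, seed, sep = "_")
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  cfg <- study_model_config(seed, variant)
  dkey <- paste0("data_", seed)
  if (is.null(.study_cache[[dkey]])) {
    recs <- generate_records(study_sim_config(seed))
    .study_cache[[dkey]] <- list(recs = recs,
                                 ds = prepare_dataset(recs, config = cfg),
                                 sp = split_dataset(seq_along(recs),
                                                    seed = seed))
  }
  recs <- .study_cache[[dkey]]$recs
  ds <- .study_cache[[dkey]]$ds
  sp <- .study_cache[[dkey]]$sp
  model <- train_model(init_model(cfg), subset_dataset(ds, sp$train),
                       valid_data = subset_dataset(ds, sp$valid))
  test <- subset_dataset(ds, sp$test)
  ev <- evaluate_model(model, test)
  out <- list(model = model, ev = ev, test = test,
              test_records = recs[sp$test],
              go_auroc = mean(c(ev$bp$auroc, ev$cc$auroc, ev$mf$auroc)),
              sl_auroc = ev$sl$auroc)
  .study_cache[[key]] <- out
  out
}
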