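# Pipeline fixtures at the study's default scale (1000 frames, 10/80/10
# imbalance, 8 planted H1 residues), shared by the end-to-end checks.

default_study <- function() get_fixture("default_study", function() {
  sim <- generate_ensemble(synth_config(seed = 2024))
  lf <- label_ensemble(sim$ensemble)
  sp <- split_data(lf$X, lf$y, 0.2, seed = 2025)
  list(sim = sim, lf = lf, sp = sp)
})

# the default 1D-CNN trained on the unresampled training split
default_cnn <- function() get_fixture("default_cnn", function() {
  d <- default_study()
  train_cnn(d$sp$train,
            model_config(epochs = 25, early_stop_patience = 4,
                         seed = 2026),
            validation = d$sp$validation)
})

# one arm of the recovery experiment: resample the training split with
# `method`, train the CNN, explain the validation samples with LRP
# toward their true class, filter with the IQR rule, and score recall
# of the planted residues
recovery_recall <- function(seed, method) {
  sim <- generate_ensemble(synth_config(seed = seed))
  lf <- label_ensemble(sim$ensemble)
  sp <- split_data(lf$X, lf$y, 0.2, seed = derive_seed(seed, "split"))
  # on well-separated synthetic classes ADASYN's pure-neighborhood
  # fallback fires by design; the warning is expected here
  rs <- suppressWarnings(
    resample_dataset(sp$train$X, sp$train$y,
                     resampler_config(method,
                                      seed = derive_seed(seed, method))))
  m <- train_cnn(rs,
                 model_config(epochs = 15, early_stop_patience = 4,
                              seed = derive_seed(seed, "train")),
                 validation = sp$validation)
  E <- lrp(m, sp$validation$X, as.character(sp$validation$y))
  cmap <- aggregate_class_map(E, sp$validation$y, method = "lrp")
  recovery_score(iqr_relevant(cmap), sim$truth)$recall
}
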