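# End-to-end experiment driver: simulate -> featurize -> split -> for
# each imbalance method: resample (training split only) -> train ->
# metrics -> for each explainer: contribution maps, robustness,
# stability, IQR relevance -> consensus across explainers and across
# imbalance methods. Every stage's seed is derived from the master seed.

#' Experiment configuration
#'
#' @param synth a [synth_config()].
#' @param labeling a [labeling_config()]; its marker pair should match
#'   the generator's.
#' @param resamplers list of [resampler_config()]s to sweep.
#' @param model a [model_config()].
#' @param explainers attribution methods to sweep, a subset of
#'   `c("lrp", "saliency", "lime", "shap", "perm")`.
#' @param assessment a [robustness_config()].
#' @param output_dir directory for reports (created); `NULL` keeps
#'   everything in memory.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param val_fraction validation fraction of the stratified split.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(synth = synth_config(),
                              labeling = labeling_config(
                                marker_pair = synth$marker_pair),
                              resamplers = list(
                                resampler_config("none"),
                                resampler_config("smoteenn")),
                              model = model_config(),
                              explainers = c("lrp", "saliency"),
                              assessment = robustness_config(),
                              output_dir = NULL,
                              seed = 1L,
                              val_fraction = 0.2) {
  allowed <- c("lrp", "saliency", "lime", "shap", "perm")
  if (!all(explainers %in% allowed))
    stopf("unknown explainer(s): %s",
          paste(setdiff(explainers, allowed), collapse = ", "))
  structure(list(synth = synth, labeling = labeling,
                 resamplers = resamplers, model = model,
                 explainers = explainers, assessment = assessment,
                 output_dir = output_dir,
                 seed = assert_count(seed, "seed", min = 0L),
                 val_fraction = assert_number(val_fraction,
                                              "val_fraction",
                                              lower = 0, upper = 1)),
            class = "experiment_config")
}

log_stage <- function(log_path, stage, seed, t0, files = character(0)) {
  entry <- list(stage = stage, seed = seed,
                duration_s = round(as.numeric(Sys.time()) - t0, 3),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  files <- files[file.exists(files)]
  if (length(files))
    entry$outputs <- lapply(stats::setNames(files, basename(files)),
                            function(f) unname(tools::md5sum(f)))
  if (!is.null(log_path))
    cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE, sep = "")
  invisible(entry)
}

#' Run the full imbalance x explainer experiment
#'
#' Executes the pipeline described in [experiment_config()]. Resampling
#' is applied to the training split only; validation rows never enter a
#' resampler. Deterministic under the master seed.
#'
#' @param cfg an [experiment_config()].
#' @param verbose print stage progress.
#' @return an `assessment_report`: per-resampler metrics and
#'   per-explainer assessment (robustness, stability, relevant residues,
#'   recovery against the planted truth), plus Venn consensus counts
#'   across explainers and across resamplers. Written to
#'   `output_dir/report.json` (with contribution-map CSVs alongside)
#'   when an output directory is configured.
#' @export
run_experiment <- function(cfg = experiment_config(), verbose = FALSE) {
  out_dir <- cfg$output_dir
  log_path <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log_path <- file.path(out_dir, "stages.jsonl")
    if (file.exists(log_path)) unlink(log_path)
    write_experiment_config(cfg, file.path(out_dir, "config.yaml"))
  }
  say <- function(...) if (verbose) message(sprintf(...))

  t0 <- as.numeric(Sys.time())
  synth_cfg <- cfg$synth
  synth_cfg$seed <- derive_seed(cfg$seed, "simulate")
  sim <- generate_ensemble(synth_cfg)
  log_stage(log_path, "simulate", synth_cfg$seed, t0)
  say("simulate: %d frames", cfg$synth$n_frames)

  t0 <- as.numeric(Sys.time())
  lf <- label_ensemble(sim$ensemble, cfg$labeling)
  log_stage(log_path, "featurize", NA, t0)

  t0 <- as.numeric(Sys.time())
  split_seed <- derive_seed(cfg$seed, "split")
  sp <- split_data(lf$X, lf$y, cfg$val_fraction, seed = split_seed)
  log_stage(log_path, "split", split_seed, t0)
  say("split: %d train / %d validation", length(sp$train$y),
      length(sp$validation$y))

  n_val <- nrow(sp$validation$X)
  heavy_n <- min(cfg$assessment$subset_size, n_val)
  assess_seed <- derive_seed(cfg$seed, "assess")
  subset_idx <- {
    set.seed(assess_seed)
    sort(sample.int(n_val, heavy_n))
  }

  results <- list()
  maps_by <- list()
  for (rc in cfg$resamplers) {
    method <- rc$method
    say("resampler: %s", method)
    t0 <- as.numeric(Sys.time())
    rc$seed <- derive_seed(cfg$seed, paste0("resample_", method))
    rs <- resample_dataset(sp$train$X, sp$train$y, rc)
    log_stage(log_path, paste0("resample_", method), rc$seed, t0)

    t0 <- as.numeric(Sys.time())
    mcfg <- cfg$model
    mcfg$seed <- derive_seed(cfg$seed, paste0("train_", method))
    model <- train_cnn(rs, mcfg, validation = sp$validation)
    log_stage(log_path, paste0("train_", method), mcfg$seed, t0)

    pred <- predict(model, sp$validation$X, type = "class")
    prob <- predict(model, sp$validation$X, type = "prob")
    rates <- confusion_and_rates(sp$validation$y, pred)
    metrics <- list(
      accuracy = rates$accuracy,
      precision = as.list(rates$precision),
      recall = as.list(rates$recall),
      f1 = as.list(rates$f1),
      weighted = as.list(rates$weighted),
      mcc = mcc(sp$validation$y, pred),
      auc = as.list(roc_auc_ova(sp$validation$y, prob)))

    expl_results <- list()
    for (ex in cfg$explainers) {
      say("  explainer: %s", ex)
      t0 <- as.numeric(Sys.time())
      ex_seed <- derive_seed(cfg$seed, paste0("explain_", method, "_", ex))
      use_idx <- if (ex %in% c("lime", "shap")) subset_idx else
        seq_len(n_val)
      cmap <- class_contribution_map(
        model, sp$validation$X[use_idx, , drop = FALSE],
        sp$validation$y[use_idx], method = ex, seed = ex_seed,
        imbalance_method = method)
      rel <- iqr_relevant(cmap)
      rec <- recovery_score(rel, sim$truth)

      acfg <- cfg$assessment
      acfg$seed <- derive_seed(cfg$seed,
                               paste0("stab_", method, "_", ex))
      Xsub <- sp$validation$X[subset_idx, , drop = FALSE]
      tsub <- as.character(sp$validation$y[subset_idx])
      explainer <- if (ex == "perm") NULL else
        make_explainer(ex, background = sp$train$X[
          seq_len(min(20L, nrow(sp$train$X))), , drop = FALSE])
      rob <- if (is.null(explainer)) NA_real_ else
        as.numeric(robustness_score(explainer, model, Xsub, acfg,
                                    targets = tsub))
      stab <- if (is.null(explainer)) NA_real_ else
        stability_score(explainer, model, Xsub, acfg, targets = tsub)

      map_file <- NULL
      if (!is.null(out_dir)) {
        map_file <- file.path(out_dir,
                              sprintf("map_%s_%s.csv", method, ex))
        write_contribution_map_csv(cmap, map_file)
      }
      log_stage(log_path, paste0("explain_", method, "_", ex), ex_seed,
                t0, files = map_file %||% character(0))
      expl_results[[ex]] <- list(
        robustness = rob, stability = stab,
        relevant = lapply(rel$per_state, function(d)
          as.list(d[c("residue", "contribution")])),
        relevant_union = relevant_union(rel),
        recovery = rec[c("precision", "recall")])
      maps_by[[ex]][[method]] <- rel
    }
    results[[method]] <- list(metrics = metrics,
                              explainers = expl_results,
                              n_train_resampled = nrow(rs$X))
  }

  consensus_across_explainers <- list()
  if (length(cfg$explainers) >= 2) {
    for (method in names(results)) {
      sets <- lapply(maps_by, function(m) m[[method]])
      sets <- sets[!vapply(sets, is.null, TRUE)]
      if (length(sets) >= 2 && length(sets) <= 4)
        consensus_across_explainers[[method]] <-
          as.list(consensus(sets)$counts)
    }
  }
  consensus_across_resamplers <- list()
  if (length(cfg$resamplers) >= 2) {
    for (ex in names(maps_by)) {
      sets <- maps_by[[ex]]
      if (length(sets) >= 2 && length(sets) <= 4)
        consensus_across_resamplers[[ex]] <-
          as.list(consensus(sets)$counts)
    }
  }

  report <- structure(list(
    seed = cfg$seed,
    n_frames = cfg$synth$n_frames,
    resamplers = results,
    consensus = list(across_explainers = consensus_across_explainers,
                     across_resamplers = consensus_across_resamplers),
    truth = list(informative_residues = sim$truth$informative_residues,
                 marker_pair = sim$truth$marker_pair)),
    class = "assessment_report")

  if (!is.null(out_dir)) {
    t0 <- as.numeric(Sys.time())
    rp <- file.path(out_dir, "report.json")
    jsonlite::write_json(unclass(report), rp, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    log_stage(log_path, "report", NA, t0, files = rp)
  }
  report
}

#' @export
print.assessment_report <- function(x, ...) {
  cat(sprintf("assessment_report (seed %d, %d frames)\n", x$seed,
              x$n_frames))
  for (m in names(x$resamplers)) {
    r <- x$resamplers[[m]]
    cat(sprintf("  %-13s acc %.3f  mcc %.3f  wF1 %.3f\n", m,
                r$metrics$accuracy, r$metrics$mcc,
                r$metrics$weighted$f1))
    for (ex in names(r$explainers)) {
      e <- r$explainers[[ex]]
      cat(sprintf("    %-9s robustness %.3f  stability %.3f  recall of planted %.2f\n",
                  ex, e$robustness, e$stability, e$recovery$recall))
    }
  }
  invisible(x)
}
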