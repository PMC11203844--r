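# Plain-text readers and writers: trajectory/residue-table/feature CSVs
# (comma-separated, header row, "." decimal, Angstrom units, 0-based
# residue indices), contribution-map CSV, report JSON and config YAML.
# All numeric payloads round-trip at double precision.

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stopf("%s: missing column(s) %s", what,
          paste(sprintf("'%s'", missing), collapse = ", "))
}

#' Write / read a trajectory ensemble as long-format CSV
#'
#' Columns: `frame` (1-based), `residue` (0-based), `x`, `y`, `z`.
#'
#' @param ensemble a `trajectory_ensemble`.
#' @param path output CSV path.
#' @export
write_trajectory_csv <- function(ensemble, path) {
  d <- dim(ensemble$coords)
  df <- data.frame(
    frame = rep(seq_len(d[1]), times = d[2]),
    residue = rep(seq_len(d[2]) - 1L, each = d[1]),
    x = as.vector(ensemble$coords[, , 1]),
    y = as.vector(ensemble$coords[, , 2]),
    z = as.vector(ensemble$coords[, , 3]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param residue_table optional residue metadata (as from
#'   [default_region_table()]); reconstructed as a default table when
#'   absent.
#' @return `read_trajectory_csv()` returns a `trajectory_ensemble`.
#' @export
read_trajectory_csv <- function(path, residue_table = NULL) {
  df <- utils::read.csv(path)
  check_columns(df, c("frame", "residue", "x", "y", "z"),
                "trajectory CSV")
  frames <- sort(unique(df$frame))
  residues <- sort(unique(df$residue))
  if (!identical(residues, seq_along(residues) - 1L) &&
      !identical(as.integer(residues), seq_along(residues) - 1L))
    stopf("trajectory CSV: residue indices must be 0-based and contiguous")
  n <- length(frames); R <- length(residues)
  if (nrow(df) != n * R)
    stopf("trajectory CSV: expected %d rows (frames x residues), found %d",
          n * R, nrow(df))
  df <- df[order(df$residue, df$frame), ]
  coords <- array(0, c(n, R, 3))
  coords[, , 1] <- df$x; coords[, , 2] <- df$y; coords[, , 3] <- df$z
  if (is.null(residue_table)) residue_table <- default_region_table(R)
  structure(list(coords = coords, residue_table = residue_table),
            class = "trajectory_ensemble")
}

#' Write / read the residue metadata table
#'
#' Columns: `residue` (0-based), `name`, `region`.
#' @param residue_table the metadata data.frame. @param path CSV path.
#' @export
write_residue_table_csv <- function(residue_table, path) {
  utils::write.csv(residue_table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_residue_table_csv
#' @export
read_residue_table_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("residue", "name", "region"), "residue table CSV")
  df
}

#' Write / read labeled features as CSV
#'
#' One row per sample: the 3R feature columns (`r000_x`, ...), a `label`
#' column, and optionally a `provenance` column for resampled data.
#'
#' @param lf a `labeled_features` or `resampled_dataset`.
#' @param path CSV path.
#' @export
write_features_csv <- function(lf, path) {
  df <- as.data.frame(lf$X)
  df$label <- as.character(lf$y)
  if (!is.null(lf$provenance)) df$provenance <- lf$provenance
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, "label", "features CSV")
  feat <- grep("^r[0-9]+_[xyz]$", names(df), value = TRUE)
  if (length(feat) == 0L || length(feat) %% 3L != 0L)
    stopf("features CSV: expected r###_x/y/z feature columns")
  X <- as.matrix(df[, feat])
  if (!all(is.finite(X))) stopf("features CSV: non-finite values")
  out <- list(X = X, y = state_factor(df$label))
  if ("provenance" %in% names(df)) out$provenance <- df$provenance
  class(out) <- if (is.null(out$provenance)) "labeled_features" else
    "resampled_dataset"
  out
}

#' Write / read a contribution map as CSV
#'
#' Rows are states, columns residues (`r000`, `r001`, ...).
#' @param map a `contribution_map`. @param path CSV path.
#' @export
write_contribution_map_csv <- function(map, path) {
  M <- map$map
  df <- data.frame(state = rownames(M))
  cols <- as.data.frame(M)
  names(cols) <- sprintf("r%03d", seq_len(ncol(M)) - 1L)
  utils::write.csv(cbind(df, cols), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contribution_map_csv
#' @export
read_contribution_map_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, "state", "contribution map CSV")
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df$state
  structure(list(map = M,
                 n_samples_per_state = NULL,
                 method = NA_character_,
                 imbalance_method = NA_character_),
            class = "contribution_map")
}

#' Write ground truth to JSON
#' @param truth a `ground_truth`. @param path JSON path.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(list(
    informative_residues = truth$informative_residues,
    marker_pair = truth$marker_pair,
    per_state_shift_magnitude = truth$per_state_shift_magnitude,
    true_labels = as.character(truth$true_labels)),
    path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an experiment configuration from YAML
#'
#' Any field absent from the file keeps its constructor default; unknown
#' top-level fields are rejected.
#'
#' @param path YAML file path.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("synth", "labeling", "resamplers", "model", "explainers",
             "assessment", "output_dir", "seed", "val_fraction")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stopf("config YAML: unknown field(s) %s",
          paste(sprintf("'%s'", unknown), collapse = ", "))
  args <- list()
  if (!is.null(raw$synth)) {
    s <- raw$synth
    if (!is.null(s$class_proportions))
      s$class_proportions <- unlist(s$class_proportions)
    args$synth <- do.call(synth_config, s)
  }
  if (!is.null(raw$labeling))
    args$labeling <- do.call(labeling_config, raw$labeling)
  if (!is.null(raw$resamplers))
    args$resamplers <- lapply(raw$resamplers, function(rc)
      do.call(resampler_config, rc))
  if (!is.null(raw$model)) {
    m <- raw$model
    if (!is.null(m$conv_blocks))
      m$conv_blocks <- lapply(m$conv_blocks, unlist)
    args$model <- do.call(model_config, m)
  }
  for (f in c("explainers", "output_dir", "seed", "val_fraction"))
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  if (!is.null(raw$assessment))
    args$assessment <- do.call(robustness_config, raw$assessment)
  do.call(experiment_config, args)
}

#' @rdname read_experiment_config
#' @param cfg an `experiment_config` to serialize.
#' @export
write_experiment_config <- function(cfg, path) {
  strip <- function(x) {
    x <- unclass(x)
    lapply(x, function(v) if (is.list(v)) strip(v) else v)
  }
  yaml::write_yaml(list(
    synth = strip(cfg$synth),
    labeling = strip(cfg$labeling),
    resamplers = lapply(cfg$resamplers, strip),
    model = strip(cfg$model),
    explainers = cfg$explainers,
    assessment = strip(cfg$assessment),
    output_dir = cfg$output_dir,
    seed = cfg$seed,
    val_fraction = cfg$val_fraction), path)
  invisible(path)
}
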