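# Featurization: residue centers of mass, flat 3R feature vectors, and
# marker-distance state labeling.

#' Marker-distance labeling configuration
#'
#' The state-defining coordinate is the Euclidean distance between two
#' marker residues (helix 3 / helix 6 in the receptor). Distances at or
#' above `active_min` are labeled active, at or below `inactive_max`
#' inactive, anything strictly between intermediate; both boundaries are
#' inclusive toward the extreme states.
#'
#' @param active_min lower bound of the active band in Angstrom
#'   (default 14).
#' @param inactive_max upper bound of the inactive band in Angstrom
#'   (default 8.5).
#' @param marker_pair 0-based residue index pair.
#' @return an object of class `labeling_config`.
#' @export
labeling_config <- function(active_min = 14.0, inactive_max = 8.5,
                            marker_pair = c(95L, 225L)) {
  active_min <- assert_number(active_min, "active_min", lower = 0,
                              strict_lower = TRUE)
  inactive_max <- assert_number(inactive_max, "inactive_max", lower = 0,
                                strict_lower = TRUE)
  if (inactive_max >= active_min)
    stopf("'inactive_max' (%g) must be below 'active_min' (%g)",
          inactive_max, active_min)
  marker_pair <- as.integer(marker_pair)
  if (length(marker_pair) != 2L || anyNA(marker_pair) ||
      marker_pair[1] == marker_pair[2] || any(marker_pair < 0L))
    stopf("'marker_pair' must be two distinct non-negative indices")
  structure(list(active_min = active_min, inactive_max = inactive_max,
                 marker_pair = marker_pair),
            class = "labeling_config")
}

#' Center of mass of a residue's atoms
#'
#' @param atom_coords numeric matrix of atom positions, one row per atom,
#'   columns x, y, z.
#' @param masses optional positive atomic masses (amu), one per atom;
#'   when absent the unweighted mean (geometric center) is returned.
#' @return a length-3 numeric point.
#' @export
residue_center_of_mass <- function(atom_coords, masses = NULL) {
  atom_coords <- as.matrix(atom_coords)
  if (nrow(atom_coords) < 1L) stopf("at least one atom is required")
  if (ncol(atom_coords) != 3L) stopf("'atom_coords' must have 3 columns")
  if (!all(is.finite(atom_coords))) stopf("non-finite atom coordinates")
  if (is.null(masses)) {
    return(colMeans(atom_coords))
  }
  if (length(masses) != nrow(atom_coords))
    stopf("'masses' must have one entry per atom")
  if (any(!is.finite(masses)) || any(masses <= 0))
    stopf("'masses' must be positive and finite")
  colSums(atom_coords * masses) / sum(masses)
}

feature_colnames <- function(n_residues) {
  as.vector(t(outer(seq_len(n_residues) - 1L, c("x", "y", "z"),
                    function(r, a) sprintf("r%03d_%s", r, a))))
}

#' Flatten an ensemble into the n x 3R feature matrix
#'
#' Columns are residue-major then coordinate: r000_x, r000_y, r000_z,
#' r001_x, ... A 282-residue ensemble therefore yields 846 columns.
#'
#' @param ensemble a `trajectory_ensemble`.
#' @return numeric matrix, frames x (3 * residues).
#' @seealso [unflatten_features()] for the inverse.
#' @export
flatten_features <- function(ensemble) {
  coords <- ensemble$coords
  if (is.null(dim(coords)) || length(dim(coords)) != 3L)
    stopf("'ensemble$coords' must be a frames x residues x 3 array")
  bad <- which(!is.finite(coords), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("non-finite coordinate at frame %d, residue %d",
          bad[1, 1], bad[1, 2] - 1L)
  n <- dim(coords)[1]; R <- dim(coords)[2]
  X <- matrix(0, n, 3 * R)
  for (a in 1:3) X[, seq(a, 3 * R, by = 3)] <- coords[, , a]
  colnames(X) <- feature_colnames(R)
  X
}

#' Invert [flatten_features()]
#'
#' @param X feature matrix (or single row) with 3R columns.
#' @return frames x residues x 3 array (a residues x 3 matrix for a
#'   single row).
#' @export
unflatten_features <- function(X) {
  if (is.null(dim(X))) X <- matrix(X, 1)
  if (ncol(X) %% 3L != 0L)
    stopf("column count %d is not a multiple of 3", ncol(X))
  R <- ncol(X) %/% 3L
  out <- array(0, c(nrow(X), R, 3))
  for (a in 1:3) out[, , a] <- X[, seq(a, 3 * R, by = 3), drop = FALSE]
  if (nrow(X) == 1L) out[1, , ] else out
}

#' Marker-pair Euclidean distance for one frame
#'
#' @param frame_coords residues x 3 coordinate matrix.
#' @param pair 0-based residue index pair.
#' @return distance in Angstrom.
#' @export
marker_distance <- function(frame_coords, pair) {
  frame_coords <- as.matrix(frame_coords)
  pair <- as.integer(pair)
  if (any(pair < 0L) || any(pair >= nrow(frame_coords)))
    stopf("marker index out of range [0, %d)", nrow(frame_coords))
  sqrt(sum((frame_coords[pair[1] + 1L, ] - frame_coords[pair[2] + 1L, ])^2))
}

# vectorized marker distance across all frames of an ensemble
marker_distances <- function(ensemble, pair) {
  pair <- as.integer(pair)
  R <- dim(ensemble$coords)[2]
  if (any(pair < 0L) || any(pair >= R))
    stopf("marker index out of range [0, %d)", R)
  d <- ensemble$coords[, pair[1] + 1L, ] - ensemble$coords[, pair[2] + 1L, ]
  if (is.null(dim(d))) d <- matrix(d, 1)
  sqrt(rowSums(d^2))
}

#' Assign conformational states from marker distances
#'
#' @param distance non-negative distances in Angstrom (vectorized).
#' @param cfg a [labeling_config()].
#' @return factor with levels active, intermediate, inactive.
#' @export
assign_state <- function(distance, cfg = labeling_config()) {
  if (any(!is.finite(distance)) || any(distance < 0))
    stopf("'distance' must be non-negative and finite")
  out <- rep("intermediate", length(distance))
  out[distance >= cfg$active_min] <- "active"
  out[distance <= cfg$inactive_max] <- "inactive"
  state_factor(out)
}

#' Featurize and label an ensemble
#'
#' Composes [flatten_features()], [marker_distance()] and
#' [assign_state()]: every frame becomes one 3R-dimensional sample with a
#' state label derived from its marker distance.
#'
#' @param ensemble a `trajectory_ensemble`.
#' @param cfg a [labeling_config()].
#' @return an object of class `labeled_features` with components `X`
#'   (n x 3R matrix), `y` (state factor) and `residue_table`.
#' @export
label_ensemble <- function(ensemble, cfg = labeling_config()) {
  X <- flatten_features(ensemble)
  d <- marker_distances(ensemble, cfg$marker_pair)
  y <- assign_state(d, cfg)
  structure(list(X = X, y = y, residue_table = ensemble$residue_table,
                 marker_distance = d),
            class = "labeled_features")
}

#' @export
print.labeled_features <- function(x, ...) {
  cat(sprintf("labeled_features: %d samples x %d features (%d residues)\n",
              nrow(x$X), ncol(x$X), ncol(x$X) / 3))
  print(table(x$y))
  invisible(x)
}
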