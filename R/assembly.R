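#' Column value of one relationship at a concentration state
#'
#' Linear relationships contribute the source concentration; bi-linear
#' relationships contribute the product of modulator and source
#' concentrations. The `ext` unit modulator (non-biomarker modulation)
#' contributes the source concentration.
#'
#' @param rel One row of a Knowledge-Model relationship table (list or
#'   single-row data frame with `modulator`, `source`).
#' @param x Named numeric vector of concentrations, one per panel biomarker.
#' @return Scalar column value.
#' @export
column_value <- function(rel, x) {
  src <- rel$source
  if (!src %in% names(x)) stop("biomarker absent from x: ", src)
  m <- rel$modulator
  if (is.na(m)) return(unname(x[src]))
  if (identical(m, "ext")) return(unname(x[src]))
  if (!m %in% names(x)) stop("biomarker absent from x: ", m)
  unname(x[m] * x[src])
}

# Vectorized column values for all relationships of a model.
snapshot_colvals <- function(km, x) {
  v <- x[km$relationships$src_idx]
  mi <- km$relationships$mod_idx
  bil <- mi > 0L
  v[bil] <- v[bil] * x[mi[bil]]
  v
}

#' Build the system snapshot at one grid point
#'
#' The characterization matrix `K` has one row per panel biomarker (the
#' target of each rate equation) and one column per Knowledge-Model
#' relationship; column `j` has a single potentially nonzero entry, at the
#' row of its target biomarker, equal to the column value of relationship
#' `j` at this instant. The snapshot stores `K` as the pair (target row per
#' column, column value) -- a lossless sparse column map; use
#' [snapshot_matrix()] to materialize the dense matrix.
#'
#' @param grid A `participant_grid`.
#' @param km A `knowledge_model` over the same panel.
#' @param point Grid point index (1-based).
#' @return A `system_snapshot`.
#' @export
build_snapshot <- function(grid, km, point = 1L) {
  stopifnot(inherits(grid, "participant_grid"), inherits(km, "knowledge_model"))
  if (!identical(rownames(grid$x), km$panel$name)) {
    stop("grid and knowledge model use different panels")
  }
  point <- as.integer(point)
  if (point < 1L || point > length(grid$times)) stop("grid point out of range")
  x <- grid$x[, point]
  if (any(!is.finite(x)) || any(x < 0)) stop("concentrations must be finite and >= 0")
  structure(list(
    participant_id = grid$participant_id,
    time = grid$times[point],
    targets = km$relationships$tgt_idx,
    colvals = snapshot_colvals(km, x),
    dxdt = grid$dxdt[, point],
    n_biomarkers = nrow(km$panel),
    biomarker_names = km$panel$name
  ), class = "system_snapshot")
}

#' Materialize the dense characterization matrix of a snapshot
#'
#' @param snapshot A `system_snapshot`.
#' @return Dense numeric matrix, biomarkers x relationships.
#' @export
snapshot_matrix <- function(snapshot) {
  stopifnot(inherits(snapshot, "system_snapshot"))
  K <- matrix(0, nrow = snapshot$n_biomarkers, ncol = length(snapshot$colvals))
  K[cbind(snapshot$targets, seq_along(snapshot$colvals))] <- snapshot$colvals
  rownames(K) <- snapshot$biomarker_names
  K
}

#' @export
print.system_snapshot <- function(x, ...) {
  cat(sprintf("<system_snapshot> '%s' t=%g: %d x %d, %d nonzero entries\n",
              x$participant_id, x$time, x$n_biomarkers, length(x$colvals),
              sum(x$colvals != 0)))
  invisible(x)
}

#' Assemble one snapshot per grid point
#'
#' @param grid A `participant_grid`.
#' @param km A `knowledge_model`.
#' @return List of `system_snapshot`, in time order.
#' @export
assemble_participant <- function(grid, km) {
  lapply(seq_along(grid$times), function(i) build_snapshot(grid, km, i))
}
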