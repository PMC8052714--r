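#' Activity thresholds
#'
#' Three rules declare a 5-dimensional relationship (time, LSV, target,
#' source, modulator) active: its unknown must be nonzero
#' (`|a_j| > zero_rel_tol * max|a|`), the LSV must carry its target's
#' component above `lsv_threshold` (absolute, LSVs being unit vectors), and
#' its RSV component must reach `rsv_threshold` of the largest RSV component
#' of that LSV. Each conjunct can be disabled for sensitivity analysis by
#' setting its threshold to 0.
#'
#' @param lsv_threshold Minimum absolute LSV component magnitude.
#' @param rsv_threshold Minimum RSV component magnitude, relative to the row
#'   maximum.
#' @param zero_rel_tol Relative tolerance under which an unknown counts as
#'   zero.
#' @return An `activity_thresholds` list.
#' @export
activity_thresholds <- function(lsv_threshold = 0.10, rsv_threshold = 0.05,
                                zero_rel_tol = 1e-12) {
  stopifnot(lsv_threshold >= 0, rsv_threshold >= 0, zero_rel_tol >= 0)
  structure(list(lsv_threshold = lsv_threshold, rsv_threshold = rsv_threshold,
                 zero_rel_tol = zero_rel_tol),
            class = "activity_thresholds")
}

#' Name-tag every left singular vector with a unique biomarker
#'
#' Greedy unique assignment: all (biomarker, LSV) pairs are ranked by |U|
#' descending and assigned whenever both the biomarker and the LSV are still
#' free, until the assignment is a bijection. Ties break by panel order, then
#' LSV index. LSVs whose top two components are within 5 percent of each
#' other are logged as ambiguous.
#'
#' @param U Square LSV matrix (rows in panel order).
#' @param panel The `cicd_panel` giving row names.
#' @return An `lsv_tagging`: `assignment` (biomarker name per LSV column),
#'   `tag_row` (panel row per LSV) and `ambiguous` (data frame of logged
#'   near-ties: lsv, top row, runner-up row, ratio).
#' @export
tag_lsvs <- function(U, panel) {
  U <- as.matrix(U)
  if (nrow(U) != ncol(U)) stop("U must be square for tagging")
  if (nrow(U) != nrow(panel)) stop("U does not match panel size")
  res <- .cpp_tag(U)
  tag_row <- as.integer(res$tag)
  amb <- res$ambiguous
  amb_df <- if (length(amb)) {
    data.frame(lsv = amb[, 1], top_row = amb[, 2], second_row = amb[, 3],
               ratio = vapply(seq_len(nrow(amb)), function(i) {
                 abs(U[amb[i, 3], amb[i, 1]]) / abs(U[amb[i, 2], amb[i, 1]])
               }, 0))
  } else {
    data.frame(lsv = integer(), top_row = integer(), second_row = integer(),
               ratio = numeric())
  }
  structure(list(assignment = panel$name[tag_row], tag_row = tag_row,
                 ambiguous = amb_df),
            class = "lsv_tagging")
}

#' Score relationship activity at one analysis instant
#'
#' Applies the composite threshold rule to every (LSV, relationship) pair of
#' a factorization and returns the active quints. The recorded value is the
#' RSV component magnitude.
#'
#' @param factors An `svd_factors` for the snapshot.
#' @param solution The `solution_vector` for the same snapshot.
#' @param tagging The `lsv_tagging` for the same factors.
#' @param km The `knowledge_model`.
#' @param thresholds An [activity_thresholds()].
#' @param time Time of the snapshot (carried into the records).
#' @return Data frame of active quints: `time`, `lsv` (column index),
#'   `lsv_tag`, `modulator`, `source`, `target`, `value`.
#' @export
score_activity <- function(factors, solution, tagging, km,
                           thresholds = activity_thresholds(), time = NA_real_) {
  stopifnot(inherits(factors, "svd_factors"),
            inherits(solution, "solution_vector"),
            inherits(tagging, "lsv_tagging"),
            inherits(km, "knowledge_model"))
  if (length(tagging$tag_row) != ncol(factors$U)) stop("tagging does not match factors")
  if (length(solution$a) != nrow(km$relationships)) stop("solution does not match model")
  zero_tol <- thresholds$zero_rel_tol * max(abs(solution$a), 0)
  res <- .cpp_score(factors$U, factors$Vt, solution$a,
                    km$relationships$tgt_idx,
                    thresholds$lsv_threshold, thresholds$rsv_threshold,
                    zero_tol)
  if (!length(res$rel)) {
    return(data.frame(time = numeric(), lsv = integer(),
                      lsv_tag = character(), modulator = character(),
                      source = character(), target = character(),
                      value = numeric(), stringsAsFactors = FALSE))
  }
  rel <- km$relationships[res$rel]
  data.frame(
    time = time,
    lsv = res$lsv,
    lsv_tag = tagging$assignment[res$lsv],
    modulator = rel$modulator,
    source = rel$source,
    target = rel$target,
    value = res$value,
    stringsAsFactors = FALSE
  )
}

#' Accumulate raw occurrence counts over a test period
#'
#' A quad (modulator, source, target, LSV tag) scores one occurrence for
#' every analysis instant at which it is active. Only quads with a positive
#' count are stored. Keys use the LSV tag name, not the column index, so
#' counts accumulate across instants even as column order changes.
#'
#' @param quints Data frame of active quints (rows from [score_activity()]
#'   over all time points of one participant).
#' @param participant,cohort Identifiers carried into the table.
#' @return A `quad_table` (data.table) with `raw_count` per quad.
#' @export
count_occurrences <- function(quints, participant = NA_character_,
                              cohort = NA_character_) {
  dt <- data.table::as.data.table(quints)
  if (!nrow(dt)) {
    out <- data.table::data.table(modulator = character(), source = character(),
                                  target = character(), lsv = character(),
                                  raw_count = integer())
  } else {
    out <- dt[, .(raw_count = data.table::uniqueN(time)),
              by = .(modulator, source, target, lsv = lsv_tag)]
  }
  out[, `:=`(participant = participant, cohort = cohort)]
  data.table::setorder(out, modulator, source, target, lsv, na.last = FALSE)
  structure(out[], class = c("quad_table", class(out)))
}

#' Normalize occurrence counts to the 0-100 scale
#'
#' Each raw count is divided by the maximum attainable count (the
#' participant's grid size) and multiplied by 100, giving the percentage of
#' analysis instants at which the quad was active. Presentation rounding to
#' two decimals happens only at export.
#'
#' @param qt A `quad_table` with `raw_count`.
#' @param max_count Grid size (48 on the standard schedule).
#' @return The table with `normalized` and `max_count` columns added.
#' @export
normalize_counts <- function(qt, max_count) {
  stopifnot(max_count >= 1)
  qt <- data.table::as.data.table(qt)
  if (any(qt$raw_count > max_count)) stop("raw count exceeds max_count")
  qt[, `:=`(normalized = 100 * raw_count / max_count, max_count = max_count)]
  structure(qt[], class = c("quad_table", class(qt)))
}

#' Flag departures from the expected quad activity pattern
#'
#' For cytokine-target quads, supporter activity (LSV tag different from the
#' target) is empirically expected only when the dominator quad (LSV tag
#' equal to the target) and the same-cell quad (source, target and LSV all
#' the source cell) are active for the same modulator/source pair. This
#' checker reports violations; it is a monitored report, not an assertion.
#'
#' @param qt A normalized `quad_table` for one participant.
#' @param panel The `cicd_panel`.
#' @return Data frame of flagged supporter quads (possibly empty).
#' @export
check_activity_pattern <- function(qt, panel) {
  dt <- data.table::as.data.table(qt)
  if (!nrow(dt)) return(dt[0])
  is_cyt <- function(x) x %in% panel$name[panel$klass == "cytokine"]
  sup <- dt[is_cyt(target) & lsv != target]
  if (!nrow(sup)) return(sup[0])
  dom_keys <- dt[is_cyt(target) & lsv == target,
                 paste(modulator, source, target, sep = "\r")]
  cell_keys <- dt[source == target & lsv == target,
                  paste(modulator, source, sep = "\r")]
  flag <- !(paste(sup$modulator, sup$source, sup$target, sep = "\r") %in% dom_keys) |
    !(paste(sup$modulator, sup$source, sep = "\r") %in% cell_keys)
  sup[flag]
}
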