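#' Collapse quads into the triplet view
#'
#' Sums normalized occurrence counts over the LSV dimension, grouping by
#' (modulator, source, target). When the table carries raw counts and a
#' single `max_count`, the sum goes through the raw integers and is
#' normalized once, which avoids the rounding drift of summing 2-decimal
#' presentation values.
#'
#' @param qt A `quad_table`.
#' @return data.table keyed by (modulator, source, target) with `value`.
#' @export
sum_triplets <- function(qt) {
  dt <- data.table::as.data.table(qt)
  if (!nrow(dt)) {
    return(data.table::data.table(modulator = character(), source = character(),
                                  target = character(), value = numeric()))
  }
  if ("raw_count" %in% names(dt) && "max_count" %in% names(dt) &&
      data.table::uniqueN(dt$max_count) == 1L) {
    mx <- dt$max_count[1L]
    out <- dt[, .(value = 100 * sum(raw_count) / mx),
              by = .(modulator, source, target)]
  } else {
    out <- dt[, .(value = sum(quad_value(.SD))), by = .(modulator, source, target)]
  }
  data.table::setorder(out, modulator, source, target, na.last = FALSE)
  out[]
}

quad_value <- function(dt) {
  if ("normalized" %in% names(dt)) dt$normalized else dt$value
}

#' Collapse quads into one of the three doublet views
#'
#' @param qt A `quad_table` (or triplet table).
#' @param view `"modulator_source"`, `"source_target"` or
#'   `"target_modulator"`.
#' @return data.table keyed by the retained pair with summed `value`.
#' @export
sum_doublets <- function(qt, view = c("modulator_source", "source_target",
                                      "target_modulator")) {
  view <- match.arg(view)
  dt <- data.table::as.data.table(qt)
  keys <- switch(view,
    modulator_source = c("modulator", "source"),
    source_target = c("source", "target"),
    target_modulator = c("target", "modulator"))
  if (!nrow(dt)) {
    out <- data.table::data.table(k1 = character(), k2 = character(), value = numeric())
    data.table::setnames(out, c("k1", "k2"), keys)
    return(out)
  }
  v <- quad_value(dt)
  out <- dt[, .(value = sum(v[.I])), by = keys]
  data.table::setorderv(out, keys, na.last = FALSE)
  out[]
}

#' Collapse quads into a singlet view
#'
#' @param qt A `quad_table`.
#' @param role `"modulator"`, `"source"`, `"target"` or `"lsv"`. The absent
#'   modulator of linear relationships forms its own `NA` key (exported as
#'   `"n.a."`).
#' @return data.table of per-biomarker summed `value`.
#' @export
sum_singlets <- function(qt, role = c("modulator", "source", "target", "lsv")) {
  role <- match.arg(role)
  dt <- data.table::as.data.table(qt)
  if (!nrow(dt)) {
    out <- data.table::data.table(k = character(), value = numeric())
    data.table::setnames(out, "k", role)
    return(out)
  }
  v <- quad_value(dt)
  out <- dt[, .(value = sum(v[.I])), by = role]
  data.table::setorderv(out, role, na.last = FALSE)
  out[]
}

#' Average quad tables across the participants of a cohort
#'
#' Quads absent from a participant contribute zero, so the mean for each quad
#' is the sum of its normalized counts divided by the number of participants.
#' An active-only mean (dividing by the number of participants in which the
#' quad is active) is available behind `active_only`.
#'
#' @param tables List of normalized `quad_table`s, one per participant.
#' @param active_only If `TRUE`, divide by the number of participants with
#'   the quad active instead of the cohort size.
#' @return data.table keyed by (modulator, source, target, lsv) with the mean
#'   `value` and `n_active`; attribute `n_participants` records the cohort
#'   size.
#' @export
average_cohort <- function(tables, active_only = FALSE) {
  if (!length(tables)) stop("empty list of quad tables")
  all <- data.table::rbindlist(lapply(tables, function(x) {
    dt <- data.table::as.data.table(x)
    dt[, .(modulator, source, target, lsv, v = quad_value(dt))]
  }))
  n <- length(tables)
  out <- all[, .(value = if (active_only) sum(v) / .N else sum(v) / n,
                 n_active = .N),
             by = .(modulator, source, target, lsv)]
  data.table::setorder(out, modulator, source, target, lsv, na.last = FALSE)
  data.table::setattr(out, "n_participants", n)
  out[]
}

#' Signed difference between two averaged cohorts
#'
#' @param a,b Averaged quad tables (as from [average_cohort()]); the
#'   difference is `a - b` elementwise over the union of quad keys.
#' @return A `cohort_comparison`: `mean_a`, `mean_b`, `diff` (signed),
#'   `positive` (quads greater in `a`) and `negative` (greater in `b`).
#' @export
diff_cohorts <- function(a, b) {
  a <- data.table::as.data.table(a)[, .(modulator, source, target, lsv, va = value)]
  b <- data.table::as.data.table(b)[, .(modulator, source, target, lsv, vb = value)]
  m <- merge(a, b, by = c("modulator", "source", "target", "lsv"), all = TRUE)
  m[is.na(va), va := 0]
  m[is.na(vb), vb := 0]
  d <- m[, .(modulator, source, target, lsv, value = va - vb)]
  data.table::setorder(d, modulator, source, target, lsv, na.last = FALSE)
  structure(list(mean_a = a, mean_b = b, diff = d[],
                 positive = d[value > 0][], negative = d[value < 0][]),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("<cohort_comparison> %d differing quads (%d positive, %d negative)\n",
              sum(x$diff$value != 0), nrow(x$positive), nrow(x$negative)))
  invisible(x)
}

#' Rank the doublets with the greatest cohort difference
#'
#' @param cmp A `cohort_comparison` (or a plain quad/diff table).
#' @param view Doublet view to rank (default modulator-source).
#' @param n Number of rows to return.
#' @return data.table of the top `n` doublet differences, descending, ties
#'   broken by key order.
#' @export
top_doublets <- function(cmp, view = "modulator_source", n = 10L) {
  tbl <- if (inherits(cmp, "cohort_comparison")) cmp$diff else cmp
  d <- sum_doublets(tbl, view)
  keys <- setdiff(names(d), "value")
  data.table::setorderv(d, c("value", keys), order = c(-1L, 1L, 1L),
                        na.last = FALSE)
  head(d, n)
}
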