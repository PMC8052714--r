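#' Load a cohort of participant time series
#'
#' Reads a long-format delimited table with header columns
#' `participant, cohort, biomarker, day, value` and returns one
#' `participant_series` per participant. Every participant must supply a
#' finite, non-negative value for every panel biomarker at every draw day,
#' and no biomarkers outside the panel are allowed.
#'
#' @param file Path to the cohort table, or a data frame in the same layout.
#' @param panel A `cicd_panel`; defaults to [default_panel()].
#' @return A named list of `participant_series` objects, one per participant,
#'   in first-appearance order.
#' @export
load_cohort <- function(file, panel = default_panel()) {
  df <- if (is.data.frame(file)) as.data.frame(file) else read_delim_auto(file)
  need <- c("participant", "cohort", "biomarker", "day", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort table missing columns: ", paste(miss, collapse = ", "))
  df$participant <- as.character(df$participant)
  df$cohort <- as.character(df$cohort)
  df$biomarker <- as.character(df$biomarker)
  df$day <- as.numeric(df$day)
  df$value <- as.numeric(df$value)

  unknown <- setdiff(unique(df$biomarker), panel$name)
  if (length(unknown)) stop("unknown biomarker name: ", paste(unknown, collapse = ", "))
  bad <- which(!is.finite(df$value) | df$value < 0)
  if (length(bad)) {
    b <- bad[1L]
    stop(sprintf("invalid value %s for participant '%s', biomarker '%s', day %g",
                 format(df$value[b]), df$participant[b], df$biomarker[b], df$day[b]))
  }

  ids <- unique(df$participant)
  out <- lapply(ids, function(id) {
    sub <- df[df$participant == id, , drop = FALSE]
    days <- sort(unique(sub$day))
    if (length(days) < 2L) stop("participant '", id, "' has fewer than 2 draws")
    m <- matrix(NA_real_, nrow = nrow(panel), ncol = length(days),
                dimnames = list(panel$name, format_day(days)))
    ri <- match(sub$biomarker, panel$name)
    ci <- match(sub$day, days)
    if (anyDuplicated(cbind(ri, ci))) stop("participant '", id, "' has duplicate (biomarker, day) rows")
    m[cbind(ri, ci)] <- sub$value
    if (anyNA(m)) {
      hole <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop(sprintf("participant '%s' missing biomarker '%s' for day %g",
                   id, panel$name[hole[1L]], days[hole[2L]]))
    }
    new_participant_series(id, sub$cohort[1L], days, m, panel)
  })
  names(out) <- ids
  out
}

new_participant_series <- function(participant_id, cohort, draw_times, values, panel) {
  stopifnot(is.matrix(values), nrow(values) == nrow(panel),
            ncol(values) == length(draw_times))
  if (is.unsorted(draw_times, strictly = TRUE)) stop("draw times must be strictly increasing")
  structure(list(
    participant_id = participant_id,
    cohort = cohort,
    draw_times = as.numeric(draw_times),
    values = values,
    panel = panel
  ), class = "participant_series")
}

#' @export
print.participant_series <- function(x, ...) {
  cat(sprintf("<participant_series> '%s' (%s): %d biomarkers x %d draws (days %s)\n",
              x$participant_id, x$cohort, nrow(x$values), length(x$draw_times),
              paste(format_day(x$draw_times), collapse = ", ")))
  invisible(x)
}

#' Write a cohort table in the canonical long-format dialect
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip is bit-identical.
#'
#' @param series_list A list of `participant_series` (as from [load_cohort()]),
#'   or a single `participant_series`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_cohort <- function(series_list, file) {
  if (inherits(series_list, "participant_series")) series_list <- list(series_list)
  rows <- lapply(series_list, function(s) {
    data.table::data.table(
      participant = s$participant_id,
      cohort = s$cohort,
      biomarker = rep(rownames(s$values), times = ncol(s$values)),
      day = rep(s$draw_times, each = nrow(s$values)),
      value = sprintf("%.17g", as.vector(s$values))
    )
  })
  dt <- data.table::rbindlist(rows)
  data.table::fwrite(dt, file)
  invisible(file)
}

#' Rescale selected biomarkers of a participant series
#'
#' Optional per-biomarker scaling hook. Concentrations are analyzed on their
#' native scales by default; this helper applies multiplicative factors when a
#' study chooses to harmonize ranges.
#'
#' @param series A `participant_series`.
#' @param factors Named numeric vector of multiplicative factors; names are
#'   biomarker names, unnamed biomarkers keep factor 1.
#' @return A rescaled `participant_series`.
#' @export
rescale_series <- function(series, factors) {
  stopifnot(inherits(series, "participant_series"), is.numeric(factors))
  unknown <- setdiff(names(factors), rownames(series$values))
  if (length(unknown)) stop("unknown biomarker name: ", paste(unknown, collapse = ", "))
  f <- rep(1, nrow(series$values))
  f[match(names(factors), rownames(series$values))] <- factors
  series$values <- series$values * f
  series
}

format_day <- function(d) {
  ifelse(d == round(d), sprintf("%d", as.integer(round(d))), sprintf("%g", d))
}
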