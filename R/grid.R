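#' Build the interpolated analysis grid for one participant
#'
#' Between each retained pair of consecutive draws, `points_per_interval`
#' analysis points are placed strictly inside the interval at fractions
#' `j / (points_per_interval + 1)`, `j = 1..points_per_interval`. Biomarker
#' values at grid times come from the two-point linear interpolant of the
#' bounding draws, and the rate of change is the interval slope
#' `(x[i+1] - x[i]) / (t[i+1] - t[i])`, constant within an interval. Grid
#' points never coincide with draw instants, where the piecewise-linear slope
#' is undefined.
#'
#' With the standard two-week weekday schedule (draw days 0-4 and 7-11) the
#' `"exclude"` weekend policy drops the Friday-to-Monday interval, leaving
#' 8 intervals and `8 * points_per_interval` grid points (48 for the default
#' 6). An interval is dropped when it spans more than 2 days, which keeps
#' 1-day and 2-day (holiday-bridging) within-week intervals and removes any
#' weekend-spanning gap.
#'
#' @param series A `participant_series`.
#' @param points_per_interval Analysis points per retained interval (>= 1).
#' @param weekend_policy `"exclude"` (default) drops intervals spanning more
#'   than 2 days; `"include"` keeps every interval.
#' @return A `participant_grid`: list with `times`, `interval` (index of the
#'   source interval per grid point), `x` (biomarkers x points concentration
#'   matrix) and `dxdt` (same shape, concentration per day).
#' @export
#' @examples
#' p <- default_panel()
#' cohort <- simulate_sinusoid_cohort(simulation_spec(
#'   panel = p, n_per_cohort = c(healthy = 1), seed = 1))
#' g <- build_grid(load_cohort(cohort, p)[[1]])
#' length(g$times)  # 48
build_grid <- function(series, points_per_interval = 6L,
                       weekend_policy = c("exclude", "include")) {
  stopifnot(inherits(series, "participant_series"))
  weekend_policy <- match.arg(weekend_policy)
  p <- as.integer(points_per_interval)
  if (p < 1L) stop("points_per_interval must be >= 1")
  tt <- series$draw_times
  if (length(tt) < 2L) stop("fewer than 2 draws")
  if (is.unsorted(tt, strictly = TRUE)) stop("non-increasing draw times")

  spans <- diff(tt)
  keep <- if (weekend_policy == "exclude") which(spans <= 2) else seq_along(spans)
  if (!length(keep)) stop("no intervals retained by weekend policy")

  nb <- nrow(series$values)
  frac <- seq_len(p) / (p + 1)
  times <- numeric(0); interval <- integer(0)
  x <- matrix(numeric(0), nrow = nb, ncol = 0)
  dxdt <- matrix(numeric(0), nrow = nb, ncol = 0)
  for (i in keep) {
    t0 <- tt[i]; t1 <- tt[i + 1L]
    x0 <- series$values[, i]; x1 <- series$values[, i + 1L]
    slope <- (x1 - x0) / (t1 - t0)
    xi <- outer(x0, rep(1, p)) + outer(slope, frac * (t1 - t0))
    times <- c(times, t0 + frac * (t1 - t0))
    interval <- c(interval, rep(i, p))
    x <- cbind(x, xi)
    dxdt <- cbind(dxdt, matrix(slope, nrow = nb, ncol = p))
  }
  rownames(x) <- rownames(dxdt) <- rownames(series$values)
  structure(list(
    participant_id = series$participant_id,
    cohort = series$cohort,
    times = times,
    interval = interval,
    x = x,
    dxdt = dxdt,
    panel = series$panel
  ), class = "participant_grid")
}

#' @export
print.participant_grid <- function(x, ...) {
  cat(sprintf("<participant_grid> '%s': %d grid points over %d intervals\n",
              x$participant_id, length(x$times), length(unique(x$interval))))
  invisible(x)
}
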