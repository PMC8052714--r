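#' Specification for a synthetic cohort
#'
#' Describes the panel, cohort sizes, draw schedule and generator mode for a
#' seeded synthetic cohort. The default schedule is the two-week weekday
#' schedule (days 0-4 and 7-11); the default cohort sizes are 14 cancer and
#' 27 healthy participants. Two modes are available: `"sinusoid"` draws
#' independent positive oscillations per biomarker (emulating the dynamic,
#' fluctuating concentrations seen in real panels), and `"glv"` integrates a
#' generalized Lotka-Volterra system from a known sparse coefficient vector,
#' providing a ground truth for rate-consistency tests.
#'
#' Cytokine baselines are drawn on a log scale spanning roughly two orders of
#' magnitude (pg/mL), cell baselines on the percent scale, so the two classes
#' live on very different numeric ranges, as in real panels.
#'
#' @param panel A `cicd_panel`.
#' @param n_per_cohort Named integer vector of participants per cohort label.
#' @param days Draw schedule in days.
#' @param seed Integer seed; fully determines the output.
#' @param mode `"sinusoid"` or `"glv"`.
#' @param amplitude Oscillation amplitude as a fraction of baseline.
#' @param noise_sd Gaussian noise standard deviation as a fraction of
#'   baseline.
#' @param period_range Oscillation period range in days.
#' @param coefficients For `"glv"`: data frame with `index` (relationship
#'   index into a knowledge model) and `coefficient`.
#' @param km For `"glv"`: the `knowledge_model` the coefficients refer to.
#' @param init For `"glv"`: named initial concentrations (defaults to the
#'   sinusoid baselines).
#' @param step For `"glv"`: explicit Euler integration step in days.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(panel = default_panel(),
                            n_per_cohort = c(cancer = 14L, healthy = 27L),
                            days = c(0:4, 7:11), seed = 1L,
                            mode = c("sinusoid", "glv"),
                            amplitude = 0.3, noise_sd = 0.05,
                            period_range = c(2, 7),
                            coefficients = NULL, km = NULL, init = NULL,
                            step = 0.01) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "cicd_panel"), length(days) >= 2,
            amplitude >= 0, noise_sd >= 0, step > 0,
            length(n_per_cohort) >= 1, !is.null(names(n_per_cohort)))
  if (amplitude >= 1) warning("amplitude >= 1 can drive concentrations to zero")
  structure(list(panel = panel, n_per_cohort = n_per_cohort, days = days,
                 seed = as.integer(seed), mode = mode, amplitude = amplitude,
                 noise_sd = noise_sd, period_range = period_range,
                 coefficients = coefficients, km = km, init = init,
                 step = step),
            class = "simulation_spec")
}

# Deterministic per-biomarker baselines on the two class scales.
sim_baselines <- function(panel) {
  nb <- nrow(panel)
  # spread baselines deterministically across each class range (log-spaced)
  out <- numeric(nb)
  for (kl in c("cytokine", "cell")) {
    idx <- which(panel$klass == kl)
    rng <- if (kl == "cytokine") c(5, 500) else c(0.5, 40)
    out[idx] <- exp(seq(log(rng[1]), log(rng[2]), length.out = max(length(idx), 2L)))[seq_along(idx)]
  }
  names(out) <- panel$name
  out
}

#' Generate a sinusoidal synthetic cohort
#'
#' Per participant and biomarker:
#' `baseline * (1 + amplitude * sin(2 pi t / period + phase)) + noise`,
#' with phase and period drawn per participant and biomarker from the seeded
#' generator (R's Mersenne-Twister) and Gaussian noise scaled to the
#' baseline. Negative values (possible only with large amplitude or noise)
#' are clipped to zero with a warning.
#'
#' @param spec A `simulation_spec`.
#' @return A cohort data frame in the long-format dialect of
#'   [load_cohort()], with a `seed` attribute.
#' @export
simulate_sinusoid_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  panel <- spec$panel
  base <- sim_baselines(panel)
  nb <- nrow(panel)
  nd <- length(spec$days)
  set.seed(spec$seed)
  rows <- list()
  for (ci in seq_along(spec$n_per_cohort)) {
    cohort <- names(spec$n_per_cohort)[ci]
    for (p in seq_len(spec$n_per_cohort[ci])) {
      id <- sprintf("%s_%02d", cohort, p)
      mult <- exp(rnorm(nb, 0, 0.3))
      phase <- runif(nb, 0, 2 * pi)
      period <- runif(nb, spec$period_range[1], spec$period_range[2])
      vals <- matrix(0, nb, nd)
      for (j in seq_len(nd)) {
        t <- spec$days[j]
        mu <- base * mult * (1 + spec$amplitude * sin(2 * pi * t / period + phase))
        vals[, j] <- mu + rnorm(nb, 0, spec$noise_sd * base * mult)
      }
      if (any(vals < 0)) {
        warning("negative synthetic values clipped to zero")
        vals[vals < 0] <- 0
      }
      rows[[length(rows) + 1L]] <- data.frame(
        participant = id, cohort = cohort,
        biomarker = rep(panel$name, times = nd),
        day = rep(spec$days, each = nb),
        value = as.vector(vals), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- spec$seed
  out
}

#' Generate a cohort from a generalized Lotka-Volterra ground truth
#'
#' Integrates `dx_T/dt = sum_j a_j x_M(j) x_S(j)` (linear terms contribute
#' `a_j x_S(j)`) by explicit Euler from the initial state and samples the
#' trajectory at the draw days. The sparse coefficient vector used is
#' returned as ground truth. Recovery of the coefficients by the pipeline is
#' not promised -- the inverse problem is massively underdetermined and its
#' solution is minimum-norm, not sparse -- but the sampled states and rates
#' are exactly consistent with the characterization matrix, which end-to-end
#' tests exploit.
#'
#' @param spec A `simulation_spec` with `mode = "glv"`, `km` and
#'   `coefficients` set.
#' @return List with `cohort` (long-format data frame) and `truth`
#'   (data frame `index`, `coefficient`).
#' @export
simulate_glv_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"), spec$mode == "glv",
            inherits(spec$km, "knowledge_model"),
            is.data.frame(spec$coefficients))
  km <- spec$km
  rel <- km$relationships
  coef <- spec$coefficients
  if (any(coef$index < 1 | coef$index > nrow(rel))) {
    stop("coefficient references a relationship outside the knowledge model")
  }
  panel <- km$panel
  nb <- nrow(panel)
  x0 <- if (is.null(spec$init)) sim_baselines(panel) else spec$init[panel$name]
  if (anyNA(x0)) stop("init must name every panel biomarker")
  cap <- 1e6 * max(x0, 1)

  a_idx <- coef$index
  a_val <- coef$coefficient
  src <- rel$src_idx[a_idx]
  mod <- rel$mod_idx[a_idx]
  tgt <- rel$tgt_idx[a_idx]

  rate_of <- function(x) {
    contrib <- a_val * x[src]
    bil <- mod > 0L
    contrib[bil] <- contrib[bil] * x[mod[bil]]
    r <- numeric(nb)
    for (k in seq_along(contrib)) r[tgt[k]] <- r[tgt[k]] + contrib[k]
    r
  }

  t_end <- max(spec$days)
  nstep <- ceiling(t_end / spec$step)
  times <- c(0, seq_len(nstep) * spec$step)
  rows <- list()
  for (ci in seq_along(spec$n_per_cohort)) {
    cohort <- names(spec$n_per_cohort)[ci]
    for (p in seq_len(spec$n_per_cohort[ci])) {
      id <- sprintf("%s_%02d", cohort, p)
      x <- x0
      traj <- matrix(NA_real_, nb, length(spec$days))
      done <- vapply(spec$days, function(d) FALSE, TRUE)
      for (si in seq_along(times)) {
        t <- times[si]
        hit <- which(!done & abs(spec$days - t) <= spec$step / 2)
        if (length(hit)) {
          traj[, hit] <- x
          done[hit] <- TRUE
        }
        if (any(abs(x) > cap)) {
          stop(sprintf("gLV integration diverged at step %d (t=%.3f)", si, t))
        }
        x <- x + spec$step * rate_of(x)
        x[x < 0] <- 0
      }
      traj[, !done] <- x
      rows[[length(rows) + 1L]] <- data.frame(
        participant = id, cohort = cohort,
        biomarker = rep(panel$name, times = length(spec$days)),
        day = rep(spec$days, each = nb),
        value = as.vector(traj), stringsAsFactors = FALSE)
    }
  }
  cohort_df <- do.call(rbind, rows)
  attr(cohort_df, "seed") <- spec$seed
  list(cohort = cohort_df,
       truth = data.frame(index = a_idx, coefficient = a_val))
}
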