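#' Analyze one participant end to end
#'
#' Builds the analysis grid, assembles the per-instant characterization
#' systems and runs the fused factorize/solve/tag/score loop, returning the
#' normalized quad table plus per-instant diagnostics. This is the fast path
#' used by [run_pipeline()]; it produces results identical to chaining the
#' granular operations ([build_snapshot()], [svd_factorize()],
#' [pseudo_solve()], [tag_lsvs()], [score_activity()],
#' [count_occurrences()], [normalize_counts()]).
#'
#' @param series A `participant_series`.
#' @param km A `knowledge_model`.
#' @param policy A [stop_policy()].
#' @param thresholds An [activity_thresholds()].
#' @param points_per_interval,weekend_policy Grid options, see
#'   [build_grid()].
#' @param rank_tol Relative rank threshold for the minimum-norm solve.
#' @return List with `quads` (normalized `quad_table`), `diagnostics`
#'   (per-instant data frame) and `n_grid_points`.
#' @export
analyze_participant <- function(series, km, policy = stop_policy(),
                                thresholds = activity_thresholds(),
                                points_per_interval = 6L,
                                weekend_policy = "exclude",
                                rank_tol = 1e-12) {
  grid <- build_grid(series, points_per_interval, weekend_policy)
  np <- length(grid$times)
  colvals <- vapply(seq_len(np), function(i) snapshot_colvals(km, grid$x[, i]),
                    numeric(nrow(km$relationships)))
  res <- .cpp_analyze(km$relationships$tgt_idx, colvals, grid$dxdt,
                      policy_mode_code(policy), policy$off_diagonal_tol,
                      policy$max_sweeps, policy$near_equal_ratio,
                      rank_tol, thresholds$lsv_threshold,
                      thresholds$rsv_threshold, thresholds$zero_rel_tol)
  quints <- data.frame(
    time = grid$times[res$time_idx],
    lsv_tag = km$panel$name[res$tag_row],
    modulator = km$relationships$modulator[res$rel],
    source = km$relationships$source[res$rel],
    target = km$relationships$target[res$rel],
    value = res$value, stringsAsFactors = FALSE)
  qt <- count_occurrences(quints, series$participant_id, series$cohort)
  qt <- normalize_counts(qt, np)
  diagnostics <- data.frame(
    time = grid$times, sweeps = res$sweeps,
    stopped_early = res$stopped_early, converged = res$converged,
    recon_error = res$recon_error, residual = res$residual,
    rank_used = res$rank_used, n_ambiguous = res$n_ambiguous)
  list(quads = qt, diagnostics = diagnostics, n_grid_points = np)
}

#' Assemble a run configuration
#'
#' @param cohort Path to a cohort table (or a cohort data frame).
#' @param panel Path to a panel table, or `NULL` for the built-in panel.
#' @param ruleset Path to a rule table, or `NULL` for the built-in rules.
#' @param out_dir Output directory (created if needed).
#' @param compare Character vector of two cohort labels to difference
#'   (`compare[1] - compare[2]`), or `NULL` to difference the first two
#'   labels present.
#' @param points_per_interval,weekend_policy Grid options.
#' @param policy,thresholds Engine options.
#' @param rank_tol Relative rank threshold.
#' @param top_n Number of top doublets to report.
#' @param export_flow_diagrams Write DOT/JSON flow diagrams.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort, out_dir, panel = NULL, ruleset = NULL,
                       compare = NULL, points_per_interval = 6L,
                       weekend_policy = "exclude",
                       policy = stop_policy(),
                       thresholds = activity_thresholds(),
                       rank_tol = 1e-12, top_n = 10L,
                       export_flow_diagrams = TRUE) {
  structure(list(cohort = cohort, panel = panel, ruleset = ruleset,
                 out_dir = out_dir, compare = compare,
                 points_per_interval = as.integer(points_per_interval),
                 weekend_policy = weekend_policy, policy = policy,
                 thresholds = thresholds, rank_tol = rank_tol,
                 top_n = as.integer(top_n),
                 export_flow_diagrams = isTRUE(export_flow_diagrams)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Scalar keys mirror the arguments of [run_config()]; `policy` and
#' `thresholds` are nested maps passed to [stop_policy()] and
#' [activity_thresholds()].
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  pol <- if (is.null(y$policy)) stop_policy() else do.call(stop_policy, y$policy)
  thr <- if (is.null(y$thresholds)) activity_thresholds() else do.call(activity_thresholds, y$thresholds)
  y$policy <- NULL; y$thresholds <- NULL
  do.call(run_config, c(y, list(policy = pol, thresholds = thr)))
}

#' Run the full pipeline over a cohort
#'
#' For every participant: analysis grid, per-instant system assembly, SVD
#' with quality check, LSV tagging, activity scoring and occurrence-count
#' accumulation; then cohort averages, the signed cohort difference, the
#' top doublet ranking and flow-diagram exports. A machine-readable manifest
#' records the configuration, quality summary and output files. Reruns with
#' an identical configuration produce byte-identical outputs.
#'
#' @param config A `run_config`.
#' @return The manifest, invisibly; outputs are written under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$cohort, config$panel, config$ruleset)) {
    if (is.character(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  panel <- if (is.null(config$panel)) default_panel() else load_panel(config$panel)
  ruleset <- if (is.null(config$ruleset)) default_ruleset() else load_ruleset(config$ruleset)
  km <- enumerate_relationships(panel, ruleset)
  cohort <- load_cohort(config$cohort, panel)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  per_part <- list()
  quality <- list()
  for (id in names(cohort)) {
    res <- tryCatch(
      analyze_participant(cohort[[id]], km, config$policy, config$thresholds,
                          config$points_per_interval, config$weekend_policy,
                          config$rank_tol),
      error = function(e) stop("participant '", id, "': ", conditionMessage(e)))
    per_part[[id]] <- res$quads
    f <- file.path(config$out_dir, sprintf("quads_%s.csv", id))
    write_quads(res$quads, f, config$thresholds)
    d <- res$diagnostics
    quality[[id]] <- list(
      n_grid_points = res$n_grid_points,
      n_active_quads = nrow(res$quads),
      max_recon_error = max(d$recon_error),
      max_residual = max(d$residual[!d$stopped_early], 0),
      any_stopped_early = any(d$stopped_early),
      checks_passed = all(d$recon_error <= 1e-8) &&
        all(d$residual[!d$stopped_early] <= 1e-6))
  }

  labels <- unique(vapply(cohort, function(s) s$cohort, ""))
  means <- list()
  for (lb in labels) {
    ids <- names(cohort)[vapply(cohort, function(s) s$cohort, "") == lb]
    means[[lb]] <- average_cohort(per_part[ids])
    data.table::fwrite(
      format_value_table(means[[lb]]),
      file.path(config$out_dir, sprintf("mean_quads_%s.csv", lb)))
  }

  cmp_labels <- config$compare
  if (is.null(cmp_labels) && length(labels) >= 2) cmp_labels <- labels[1:2]
  cmp <- NULL
  if (!is.null(cmp_labels)) {
    cmp <- diff_cohorts(means[[cmp_labels[1]]], means[[cmp_labels[2]]])
    data.table::fwrite(format_value_table(cmp$diff),
                       file.path(config$out_dir, "diff_quads.csv"))
    top <- top_doublets(cmp, n = config$top_n)
    data.table::fwrite(format_value_table(top),
                       file.path(config$out_dir, "top_doublets.csv"))
    if (config$export_flow_diagrams) {
      export_flow(cmp, file.path(config$out_dir, "flow_diff"))
    }
  }
  if (config$export_flow_diagrams) {
    for (lb in labels) {
      export_flow(means[[lb]], file.path(config$out_dir, sprintf("flow_%s", lb)))
    }
  }

  manifest <- list(
    package = "cicdr",
    version = as.character(packageVersion("cicdr")),
    config = list(
      cohort = if (is.character(config$cohort)) config$cohort else "<in-memory>",
      panel = if (is.null(config$panel)) "<built-in>" else config$panel,
      ruleset = if (is.null(config$ruleset)) "<built-in>" else config$ruleset,
      points_per_interval = config$points_per_interval,
      weekend_policy = config$weekend_policy,
      policy = unclass(config$policy),
      thresholds = unclass(config$thresholds),
      rank_tol = config$rank_tol,
      compare = cmp_labels),
    knowledge_model = list(
      n_relationships = nrow(km$relationships),
      per_type = as.list(validate_model(km)$per_type)),
    participants = quality,
    all_checks_passed = all(vapply(quality, function(q) q$checks_passed, TRUE))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

format_value_table <- function(dt) {
  dt <- data.table::as.data.table(dt)
  out <- data.table::copy(dt)
  if ("modulator" %in% names(out)) {
    out[, modulator := ifelse(is.na(modulator), "n.a.", modulator)]
  }
  if ("value" %in% names(out)) {
    out[, value := formatC(value, format = "f", digits = 4)]
  }
  out
}
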