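#' Export a modulator-source flow diagram
#'
#' Reduces a quad dataset (or a cohort comparison) to modulator-source
#' doublets (edges) and modulator/source singlets (nodes) and writes a
#' Graphviz DOT file plus a JSON twin with identical attributes. Modulator
#' nodes are octagons (cytokines and the `"n.a."` node for linear
#' relationships), source nodes are circles (cells). Node size is
#' proportional to the singlet value and edge width to the doublet value;
#' for signed difference tables, positive edges are green and negative edges
#' red. Only the `top_sources` largest cellular sources and `top_modulators`
#' largest modulators (plus `"n.a."`) are drawn. The size scale is a linear
#' configuration constant so the same scale can be reused across diagrams.
#'
#' @param x A `quad_table`, an averaged quad table, or a `cohort_comparison`
#'   (whose signed `diff` is drawn).
#' @param out Output path without extension; writes `<out>.dot` and
#'   `<out>.json`.
#' @param view Doublet view; only `"modulator_source"` is supported.
#' @param top_sources,top_modulators How many of the highest-valued source
#'   and modulator nodes to keep.
#' @param node_scale,edge_scale Linear size scale constants (node inches and
#'   edge points per unit of summed occurrence count).
#' @return Invisibly, a list with the node and edge tables written.
#' @export
export_flow <- function(x, out, view = "modulator_source",
                        top_sources = 10L, top_modulators = 15L,
                        node_scale = 0.002, edge_scale = 0.005) {
  if (view != "modulator_source") stop("unsupported view: ", view)
  signed <- inherits(x, "cohort_comparison")
  tbl <- if (signed) x$diff else x

  edges <- sum_doublets(tbl, "modulator_source")
  mods <- sum_singlets(tbl, "modulator")
  srcs <- sum_singlets(tbl, "source")

  rank_keep <- function(s, k) {
    o <- order(-abs(s$value), s[[1L]], na.last = FALSE)
    s <- s[o]
    keep <- head(s[[1L]][!is.na(s[[1L]])], k)
    s[s[[1L]] %in% keep | is.na(s[[1L]])]
  }
  mods <- rank_keep(mods, top_modulators)
  srcs <- rank_keep(srcs, top_sources)
  edges <- edges[(modulator %in% mods$modulator | is.na(modulator)) &
                   source %in% srcs$source]

  label_of <- function(v) ifelse(is.na(v), "n.a.", v)
  fmt <- function(v) formatC(v, format = "f", digits = 2)

  lines <- c("digraph flow {", "  rankdir=LR;",
             "  node [fontsize=10];")
  for (i in seq_len(nrow(mods))) {
    lines <- c(lines, sprintf(
      '  "%s" [shape=octagon, width=%.4f, xlabel="%s"];',
      label_of(mods$modulator[i]), 0.5 + node_scale * abs(mods$value[i]),
      fmt(mods$value[i])))
  }
  for (i in seq_len(nrow(srcs))) {
    lines <- c(lines, sprintf(
      '  "%s" [shape=circle, width=%.4f, xlabel="%s"];',
      srcs$source[i], 0.5 + node_scale * abs(srcs$value[i]),
      fmt(srcs$value[i])))
  }
  for (i in seq_len(nrow(edges))) {
    col <- if (!signed || edges$value[i] == 0) "black" else if (edges$value[i] > 0) "forestgreen" else "red3"
    lines <- c(lines, sprintf(
      '  "%s" -> "%s" [penwidth=%.4f, color=%s, label="%s"];',
      label_of(edges$modulator[i]), edges$source[i],
      0.5 + edge_scale * abs(edges$value[i]), col, fmt(edges$value[i])))
  }
  lines <- c(lines, "}")

  dot_path <- paste0(out, ".dot")
  json_path <- paste0(out, ".json")
  writeLines(lines, dot_path)
  payload <- list(
    view = view, signed = signed,
    nodes = list(
      modulators = data.frame(name = label_of(mods$modulator),
                              shape = rep("octagon", nrow(mods)),
                              value = mods$value),
      sources = data.frame(name = srcs$source,
                           shape = rep("circle", nrow(srcs)),
                           value = srcs$value)
    ),
    edges = data.frame(modulator = label_of(edges$modulator),
                       source = edges$source, value = edges$value)
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(nodes_modulator = mods, nodes_source = srcs, edges = edges,
                 dot = dot_path, json = json_path))
}

#' Write a quad table in the canonical export dialect
#'
#' Normalized counts are rounded to two decimals at export only; the
#' thresholds used are recorded in a header comment.
#'
#' @param qt A normalized `quad_table`.
#' @param file Output path.
#' @param thresholds The `activity_thresholds` used (recorded in the
#'   header), or `NULL`.
#' @return `file`, invisibly.
#' @export
write_quads <- function(qt, file, thresholds = NULL) {
  dt <- data.table::as.data.table(qt)
  hdr <- if (!is.null(thresholds)) {
    sprintf("# lsv_threshold=%g rsv_threshold=%g zero_rel_tol=%g",
            thresholds$lsv_threshold, thresholds$rsv_threshold,
            thresholds$zero_rel_tol)
  }
  out <- dt[, .(participant, cohort,
                modulator = ifelse(is.na(modulator), "n.a.", modulator),
                source, target, lsv, raw_count,
                normalized = formatC(normalized, format = "f", digits = 2))]
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(hdr)) writeLines(hdr, con)
  writeLines(paste(names(out), collapse = ","), con)
  if (nrow(out)) {
    writeLines(do.call(paste, c(as.list(out), sep = ",")), con)
  }
  invisible(file)
}
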