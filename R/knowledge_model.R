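#' The default relationship-type rule table
#'
#' Seven declarative relationship types define which biomarker classes may
#' occupy the modulator, source and target roles of a relationship. Every
#' relationship must carry a cell in its source or target role. Bi-linear
#' relationships with more than one cellular component are restricted to a
#' single cell (autocrine signaling; paracrine excluded), except when a cell
#' acts as modulator for a cytokine target. Linear relationships have no
#' modulator. The `ext` modulator is a unit-valued sentinel representing
#' non-biomarker modulation (hormones, drugs, unmeasured factors) of a cell's
#' self-relationship; it is distinct from the absent modulator of a linear
#' relationship, although both contribute a column equal to the source
#' concentration.
#'
#' Expanded over the default 50-biomarker panel the seven types contribute
#' 18,375 + 7,875 + 525 + 525 + 525 + 750 + 30 = 28,605 unique relationships.
#'
#' @return Data frame with columns `type_id`, `modulator_domain`,
#'   `source_domain`, `target_domain`, `same_cell`, `notes`.
#' @export
default_ruleset <- function() {
  validate_ruleset(data.frame(
    type_id = c(
      "cyt_mod_cell_src_cyt_tgt",
      "cell_mod_cell_src_cyt_tgt",
      "cyt_mod_cell_autocrine",
      "cell_mod_cyt_src_same_cell",
      "linear_cyt_to_cell",
      "linear_cell_to_any",
      "cell_self_unit_mod"
    ),
    modulator_domain = c("cytokine", "cell", "cytokine", "cell",
                         "none", "none", "cell_or_ext"),
    source_domain = c("cell", "cell", "cell", "cytokine",
                      "cytokine", "cell", "cell"),
    target_domain = c("cytokine", "cytokine", "cell", "cell",
                      "cell", "any", "cell"),
    same_cell = c("none", "none", "source_target_same", "all_cell_roles_same",
                  "none", "none", "all_cell_roles_same"),
    notes = c(
      "cytokine modulates a cell that stimulates/suppresses a cytokine",
      "cell modulates a cell acting on a cytokine target; the two cells may differ",
      "cytokine modulates a cell acting on itself (autocrine)",
      "cell modulates a cytokine that acts back on the same cell",
      "non-modulated cytokine acting on a cell",
      "non-modulated cell acting on any biomarker",
      "cell self-relationship modulated by the same cell or by non-biomarker factors (ext)"
    ),
    stringsAsFactors = FALSE
  ))
}

MOD_DOMAINS <- c("cytokine", "cell", "any", "none", "ext",
                 "cytokine_or_none", "cell_or_ext", "any_or_ext")
ROLE_DOMAINS <- c("cytokine", "cell", "any")
SAME_CELL <- c("none", "all_cell_roles_same", "source_target_same")

validate_ruleset <- function(df) {
  need <- c("type_id", "modulator_domain", "source_domain", "target_domain", "same_cell")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("ruleset missing columns: ", paste(miss, collapse = ", "))
  if (is.null(df$notes)) df$notes <- ""
  if (anyDuplicated(df$type_id)) stop("duplicate type_id in ruleset")
  for (col in c("modulator_domain", "source_domain", "target_domain", "same_cell")) {
    ok <- switch(col,
      modulator_domain = MOD_DOMAINS,
      same_cell = SAME_CELL,
      ROLE_DOMAINS)
    bad <- setdiff(unique(df[[col]]), ok)
    if (length(bad)) stop("unknown ", col, " token: ", paste(bad, collapse = ", "))
  }
  no_cell <- df$source_domain != "cell" & df$target_domain != "cell"
  if (any(no_cell)) {
    stop("relationship type(s) without a cell in source or target: ",
         paste(df$type_id[no_cell], collapse = ", "))
  }
  rownames(df) <- NULL
  df[, c(need, "notes")]
}

#' Load a relationship-type rule table
#'
#' @param source Path to a delimited rule table (columns `type_id`,
#'   `modulator_domain`, `source_domain`, `target_domain`, `same_cell`,
#'   optional `notes`), or a data frame.
#' @return Validated ruleset data frame.
#' @export
load_ruleset <- function(source) {
  df <- if (is.data.frame(source)) source else read_delim_auto(source)
  validate_ruleset(df)
}

#' Write a ruleset to a CSV file
#' @param ruleset A ruleset data frame.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_ruleset <- function(ruleset, file) {
  write.csv(validate_ruleset(ruleset), file, row.names = FALSE)
  invisible(file)
}

# role domain token -> panel row indices; modulator also admits the sentinels
# 0 (no modulator, linear) and -1 (ext, unit-valued non-biomarker modulator).
domain_indices <- function(token, panel, role) {
  cy <- which(panel$klass == "cytokine")
  ce <- which(panel$klass == "cell")
  switch(token,
    cytokine = cy, cell = ce, any = c(cy, ce),
    none = 0L, ext = -1L,
    cytokine_or_none = c(0L, cy),
    cell_or_ext = c(-1L, ce),
    any_or_ext = c(-1L, cy, ce),
    stop("unknown ", role, " domain token: ", token))
}

#' Enumerate the Knowledge Model over a panel
#'
#' Expands every relationship type over the panel subject to its domain and
#' same-cell constraints, deduplicates globally on the
#' (modulator, source, target) key keeping the first generating type, and
#' fixes the canonical relationship order: by type, then modulator, source
#' and target in panel order. The canonical order defines the column order of
#' every characterization matrix, so right singular vectors are comparable
#' across time points and participants.
#'
#' @param panel A `cicd_panel`.
#' @param ruleset A ruleset data frame; defaults to [default_ruleset()].
#' @return A `knowledge_model` with the relationship table and index maps.
#' @export
#' @examples
#' km <- enumerate_relationships(default_panel())
#' nrow(km$relationships)  # 28605
enumerate_relationships <- function(panel, ruleset = default_ruleset()) {
  stopifnot(inherits(panel, "cicd_panel"))
  ruleset <- validate_ruleset(ruleset)
  is_cell <- panel$klass == "cell"

  pieces <- vector("list", nrow(ruleset))
  for (i in seq_len(nrow(ruleset))) {
    r <- ruleset[i, ]
    mi <- domain_indices(r$modulator_domain, panel, "modulator")
    si <- domain_indices(r$source_domain, panel, "source")
    ti <- domain_indices(r$target_domain, panel, "target")
    dt <- data.table::CJ(tgt = ti, src = si, mod = mi)  # CJ sorts keys
    # same-cell constraints over the cell-class roles of each row
    if (r$same_cell == "source_target_same") {
      both_cell <- is_cell[dt$src] & is_cell[dt$tgt]
      dt <- dt[!both_cell | dt$src == dt$tgt]
    } else if (r$same_cell == "all_cell_roles_same") {
      mc <- dt$mod > 0L & is_cell[pmax(dt$mod, 1L)]
      sc <- is_cell[dt$src]
      tc <- is_cell[dt$tgt]
      ok <- rep(TRUE, nrow(dt))
      ok <- ok & (!(sc & tc) | dt$src == dt$tgt)
      ok <- ok & (!(mc & sc) | dt$mod == dt$src)
      ok <- ok & (!(mc & tc) | dt$mod == dt$tgt)
      dt <- dt[ok]
    }
    if (nrow(dt)) dt[, type_id := r$type_id]
    pieces[[i]] <- dt
  }
  rel <- data.table::rbindlist(pieces[vapply(pieces, nrow, 0L) > 0L])
  if (is.null(rel) || !nrow(rel)) {
    rel <- data.table::data.table(tgt = integer(), src = integer(),
                                  mod = integer(), type_id = character())
  }
  # canonical order: type (ruleset order), then modulator, source, target
  rel[, type_ord := match(type_id, ruleset$type_id)]
  # modulator order: none (0) first, then panel order, ext last
  rel[, mod_ord := ifelse(mod == -1L, nrow(panel) + 1L, mod)]
  data.table::setorder(rel, type_ord, mod_ord, src, tgt)
  rel <- unique(rel, by = c("mod", "src", "tgt"))
  n_dup <- sum(vapply(pieces, nrow, 0L)) - nrow(rel)

  rel[, `:=`(
    index = seq_len(.N),
    modulator = ifelse(mod == 0L, NA_character_,
                       ifelse(mod == -1L, "ext", panel$name[pmax(mod, 1L)])),
    source = panel$name[src],
    target = panel$name[tgt],
    kind = ifelse(mod == 0L, "linear", "bilinear")
  )]
  data.table::setnames(rel, c("mod", "src", "tgt"), c("mod_idx", "src_idx", "tgt_idx"))
  rel[, c("type_ord", "mod_ord") := NULL]
  data.table::setcolorder(rel, c("index", "type_id", "modulator", "source",
                                 "target", "kind", "mod_idx", "src_idx", "tgt_idx"))
  structure(list(
    panel = panel,
    ruleset = ruleset,
    relationships = rel[],
    duplicates_removed = n_dup
  ), class = "knowledge_model")
}

#' @export
print.knowledge_model <- function(x, ...) {
  cat(sprintf("<knowledge_model> %d relationships (%d types, panel of %d)\n",
              nrow(x$relationships), nrow(x$ruleset), nrow(x$panel)))
  invisible(x)
}

#' Validate a Knowledge Model against an expected total
#'
#' @param km A `knowledge_model`.
#' @param expected_total Expected number of unique relationships, or `NULL`.
#' @return A list with per-type counts, duplicate collisions removed, the
#'   total, and `pass`/`delta` versus `expected_total` when given.
#' @export
validate_model <- function(km, expected_total = NULL) {
  stopifnot(inherits(km, "knowledge_model"))
  per_type <- km$relationships[, .N, by = type_id]
  counts <- setNames(per_type$N, per_type$type_id)
  total <- nrow(km$relationships)
  out <- list(per_type = counts, duplicates_removed = km$duplicates_removed,
              total = total, expected_total = expected_total)
  if (!is.null(expected_total)) {
    out$delta <- total - expected_total
    out$pass <- out$delta == 0L
  }
  out
}

#' Export the enumerated relationship table
#' @param km A `knowledge_model`.
#' @param file Output path (CSV with columns index, type_id, modulator,
#'   source, target, kind; linear modulator written as `n.a.`).
#' @return `file`, invisibly.
#' @export
write_knowledge_model <- function(km, file) {
  dt <- km$relationships[, .(index, type_id,
                             modulator = ifelse(is.na(modulator), "n.a.", modulator),
                             source, target, kind)]
  data.table::fwrite(dt, file)
  invisible(file)
}
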