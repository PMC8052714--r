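#' The default biomarker panel
#'
#' The standard panel measured in peripheral blood: 35 cytokines quantified as
#' plasma concentrations (pg/mL scale) and 15 cell phenotypes quantified as
#' relative concentrations among peripheral blood mononuclear cells (percent
#' scale). Panel order is canonical: it fixes the row order of every
#' characterization matrix and the biomarker order used for deterministic
#' tie-breaking, so it must not be permuted between steps of an analysis.
#'
#' @return A `cicd_panel` object (a data frame with columns `name`, `klass`,
#'   `units`), cytokines first, in canonical order.
#' @export
#' @examples
#' p <- default_panel()
#' table(p$klass)
default_panel <- function() {
  cytokines <- c(
    "EGF", "EOTAXIN", "FGF-2", "FLT-3L", "FRACTALKINE", "G-CSF", "GM-CSF",
    "IFNa2", "IFNg", "IL-10", "IL-12p40", "IL-12p70", "IL-13", "IL-15",
    "IL-17A", "IL-1a", "IL-1b", "IL-1ra", "IL-2", "IL-3", "IL-4", "IL-5",
    "IL-6", "IL-7", "IL-8", "IL-9", "IP-10", "MCP-1", "MCP-3", "MIP-1a",
    "MIP-1b", "TGFa", "TNFa", "TNFb", "VEGF"
  )
  cells <- c(
    "CD11c+", "CD11c/CD14+", "CD11c/CD86+", "CD11c/HLA-DR+", "CD123/HLA-DR+",
    "CD14/CD197+", "CD16/CD56+", "CD3+", "CD3/CD4+", "CD3/CD62L+",
    "CD3/CD69+", "CD3/CD8+", "CD4/CD294+", "CD4/TIM3+", "CD56+"
  )
  new_panel(data.frame(
    name  = c(cytokines, cells),
    klass = rep(c("cytokine", "cell"), c(length(cytokines), length(cells))),
    stringsAsFactors = FALSE
  ))
}

new_panel <- function(df) {
  stopifnot(is.data.frame(df), all(c("name", "klass") %in% names(df)))
  if (nrow(df) == 0L) stop("empty panel")
  df$name <- as.character(df$name)
  df$klass <- as.character(df$klass)
  if (any(!nzchar(df$name)) || anyNA(df$name)) stop("panel biomarker names must be non-empty")
  bad <- setdiff(unique(df$klass), c("cytokine", "cell"))
  if (length(bad)) stop("unknown klass: ", paste(bad, collapse = ", "))
  dup <- df$name[duplicated(df$name)]
  if (length(dup)) stop("duplicate biomarker name: ", paste(unique(dup), collapse = ", "))
  if (is.null(df$units)) {
    df$units <- ifelse(df$klass == "cytokine", "pg/mL", "percent")
  }
  rownames(df) <- NULL
  structure(df, class = c("cicd_panel", "data.frame"))
}

#' Load a biomarker panel from a delimited table
#'
#' The file must have a header row with columns `name` and `klass`
#' (`cytokine` or `cell`); an optional `units` column is carried through.
#' File order defines the canonical panel order.
#'
#' @param source Path to a delimited file (comma- or tab-separated), or a
#'   data frame with the same columns.
#' @return A `cicd_panel`.
#' @export
load_panel <- function(source) {
  df <- if (is.data.frame(source)) source else read_delim_auto(source)
  if (nrow(df) == 0L) stop("empty panel")
  new_panel(df)
}

#' @export
print.cicd_panel <- function(x, ...) {
  cat(sprintf("<cicd_panel> %d biomarkers: %d cytokines, %d cells\n",
              nrow(x), sum(x$klass == "cytokine"), sum(x$klass == "cell")))
  invisible(x)
}

#' Count biomarkers of one class in a panel
#'
#' @param panel A `cicd_panel`.
#' @param klass `"cytokine"` or `"cell"`.
#' @return Integer count.
#' @export
panel_count <- function(panel, klass) {
  stopifnot(inherits(panel, "cicd_panel"))
  sum(panel$klass == match.arg(klass, c("cytokine", "cell")))
}

# Read a small delimited table, sniffing comma vs tab from the header line.
read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
  read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE,
           comment.char = "#")
}
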