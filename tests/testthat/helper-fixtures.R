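# Shared fixtures: small panels, toy knowledge models and hand-sized series
# built in code so every expected value can be derived by inspection.

toy_panel <- function() {
  load_panel(data.frame(
    name = c("A", "B", "C"),
    klass = c("cytokine", "cytokine", "cell")))
}

# single type: cytokine modulator, cell source, cytokine target
toy_ruleset <- function() {
  load_ruleset(data.frame(
    type_id = "cyt_cell_cyt",
    modulator_domain = "cytokine",
    source_domain = "cell",
    target_domain = "cytokine",
    same_cell = "none",
    notes = ""))
}

toy_km <- function() enumerate_relationships(toy_panel(), toy_ruleset())

# one participant with hand-pickable values on the toy panel
toy_series <- function(values = NULL, days = c(0, 1)) {
  if (is.null(values)) {
    values <- matrix(c(2, 3, 5, 4, 6, 10), nrow = 3,
                     dimnames = list(c("A", "B", "C"), NULL))
  }
  cicdr:::new_participant_series("toy", "other", days, values, toy_panel())
}

standard_days <- c(0:4, 7:11)

# a small strictly positive series on the default panel
default_panel_series <- function(seed = 7L) {
  panel <- default_panel()
  df <- simulate_sinusoid_cohort(simulation_spec(
    panel = panel, n_per_cohort = c(healthy = 1L), seed = seed))
  load_cohort(df, panel)[[1]]
}

# a quad table built by hand (already normalized)
hand_quads <- function() {
  normalize_counts(structure(data.table::data.table(
    modulator = c("M1", "M1", NA),
    source = c("S1", "S1", "S2"),
    target = c("T1", "T2", "T1"),
    lsv = c("L1", "L2", "L1"),
    raw_count = c(24L, 12L, 6L),
    participant = "p1", cohort = "x"),
    class = c("quad_table", "data.table", "data.frame")), 48)
}

# the shipped example occurrence-count table (printed 2-dp values)
example_quads_path <- function() {
  system.file("extdata", "example_quads.csv", package = "cicdr")
}

load_example_quads <- function(who = c("cancer_12A", "healthy_10")) {
  who <- match.arg(who)
  df <- read.csv(example_quads_path(), comment.char = "#",
                 stringsAsFactors = FALSE, check.names = FALSE)
  val <- df[[paste0("occ_", who)]]
  dt <- data.table::data.table(
    modulator = ifelse(df$modulator == "n.a.", NA_character_, df$modulator),
    source = df$source, target = df$target, lsv = df$lsv,
    raw_count = as.integer(round(val * 48 / 100)),
    normalized = val, max_count = 48L,
    participant = who, cohort = sub("_.*", "", who))
  structure(dt, class = c("quad_table", class(dt)))
}

# dense matrix with CICD structure (single nonzero per column) from a seed
structured_K <- function(r = 5L, n = 40L, seed = 1L) {
  set.seed(seed)
  targets <- sample(r, n, replace = TRUE)
  targets[seq_len(r)] <- seq_len(r)  # every row hit
  vals <- runif(n, 0.5, 2)
  K <- matrix(0, r, n)
  K[cbind(targets, seq_len(n))] <- vals
  K
}

expect_relative <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(abs(y), 1e-300), tol)
}
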