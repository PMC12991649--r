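# Shared fixtures, built once per test run and memoized: a 12-participant
# synthetic study with a moderate weight effect, and cheap fits of both
# model variants to it.
.fixture_cache <- new.env(parent = emptyenv())

fixture_study <- function() {
  if (is.null(.fixture_cache$study)) {
    spec <- population_spec(effects = list(salience = list(dw = 0.06)))
    .fixture_cache$study <- simulate_study(spec, 12, seed = 42)
  }
  .fixture_cache$study
}

fixture_fit <- function(variant = "shared_C") {
  key <- paste0("fit_", variant)
  if (is.null(.fixture_cache[[key]])) {
    mod <- build_toj_model(fixture_study()$toj, variant = variant)
    .fixture_cache[[key]] <- suppressWarnings(
      fit_toj_model(mod, draws = 1200, tune = 500, chains = 2, seed = 7))
  }
  .fixture_cache[[key]]
}

# tiny table for structural/error tests (no fitting)
tiny_toj_table <- function() {
  expand_cells <- expand.grid(
    participant_id = 1:2, condition = c("baseline", "salience"),
    soa_ms = c(-40, 0, 40), KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE)
  expand_cells$n_trials <- 10L
  expand_cells$n_probe_first <- 5L
  expand_cells
}
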