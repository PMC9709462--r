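# Shared fixtures, built in code. The full synthetic assessment is expensive
# enough to be worth memoizing across test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture_registry <- function() {
  if (is.null(.fixture_cache$registry))
    .fixture_cache$registry <- suppressMessages(default_registry())
  .fixture_cache$registry
}

fixture_records <- function() {
  if (is.null(.fixture_cache$records))
    .fixture_cache$records <-
      suppressMessages(generate_exposure(default_exposure_spec(), seed = 1))
  .fixture_cache$records
}

fixture_results <- function() {
  if (is.null(.fixture_cache$results))
    .fixture_cache$results <-
      suppressMessages(assess_all(fixture_records(), fixture_registry()))
  .fixture_cache$results
}

# Minimal two-chemical registry written to a temp CSV.
write_tiny_registry <- function(path = tempfile(fileext = ".csv"),
                                rfc = c(30, NA)) {
  df <- data.frame(
    name = c("ChemA", "DustB"),
    cas = c("1-1-1", ""),
    rfc = rfc, iur = NA,
    oel_china_twa = c(6, 8), oel_acgih_twa = c(1.6, NA),
    carcinogenicity = c("IARC-1", "none"),
    ld50_oral = c(930, 12000), lc50_inhal = NA,
    risk_phrases = c("R45;R11", "R36/37"),
    physical_form = c("liquid", "solid"),
    dustiness_band = c("", "low"), volatility_band = c("medium", ""),
    hr_override = NA, notes = "")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

tiny_records <- function(ca = c(0.06, 0.5), hazard = c("ChemA", "DustB")) {
  suppressMessages(validate_exposure(data.frame(
    industry = "Test industry", location = "Test job", hazard = hazard,
    ca_mg_m3 = ca)))
}
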