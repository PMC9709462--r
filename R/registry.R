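#' Hazard-property registry
#'
#' The registry holds per-chemical toxicology and limit data consumed by all
#' six scoring engines: the inhalation reference concentration (RfC, in
#' \eqn{\mu g/m^3}), occupational exposure limits (China PC-TWA and ACGIH
#' TLV-TWA, both in \eqn{mg/m^3}), carcinogenicity class, acute-toxicity data
#' (oral LD50, inhalation LC50), risk phrases, physical form and its
#' dustiness/volatility band, and an optional hazard-rating override for the
#' Singaporean method.
#'
#' Unit convention: RfC is stored in \eqn{\mu g/m^3}; OELs and all airborne
#' concentrations in \eqn{mg/m^3}. Conversions are explicit in the code paths
#' that need them, never implicit in storage.
#'
#' @name hazard_registry
NULL

.registry_cols <- c(
  "name", "cas", "rfc", "iur", "oel_china_twa", "oel_acgih_twa",
  "carcinogenicity", "ld50_oral", "lc50_inhal", "risk_phrases",
  "physical_form", "dustiness_band", "volatility_band", "hr_override", "notes"
)
.carc_levels <- c("IARC-1", "IARC-2A", "IARC-2B", "IARC-3", "none")
.band_levels <- c("low", "medium", "high")

.num_or_na <- function(x) suppressWarnings(as.numeric(x))

validate_profile <- function(row, line = NA_integer_) {
  where <- if (is.na(line)) row$name else sprintf("%s (line %d)", row$name, line)
  for (f in c("rfc", "iur", "oel_china_twa", "oel_acgih_twa", "ld50_oral", "lc50_inhal")) {
    v <- row[[f]]
    if (!is.na(v) && v <= 0)
      ohra_stop("registry field '%s' must be strictly positive for %s (got %g)",
                f, where, v, class = "ohra_validation_error")
  }
  if (!is.na(row$hr_override) && !(row$hr_override %in% 1:5))
    ohra_stop("hr_override must be in 1..5 for %s", where,
              class = "ohra_validation_error")
  if (!(row$carcinogenicity %in% .carc_levels))
    ohra_stop("unknown carcinogenicity class '%s' for %s", row$carcinogenicity,
              where, class = "ohra_validation_error")
  scoreable <- !is.na(row$rfc) || !is.na(row$oel_china_twa) ||
    !is.na(row$oel_acgih_twa) || nzchar(row$risk_phrases %||% "") ||
    row$carcinogenicity != "none" || !is.na(row$ld50_oral) || !is.na(row$lc50_inhal)
  if (!scoreable)
    ohra_stop("no engine can score '%s': all of RfC, OELs, risk phrases, carcinogenicity and acute toxicity are absent",
              where, class = "ohra_validation_error")
  if (!(row$physical_form %in% c("solid", "liquid", "gas")))
    ohra_stop("unknown physical_form '%s' for %s", row$physical_form, where,
              class = "ohra_validation_error")
  invisible(TRUE)
}

#' Load a hazard registry from a delimited file
#'
#' Reads a comma-separated registry (one chemical per row, header matching the
#' registry schema; `risk_phrases` semicolon-joined) or an equivalent JSON
#' array, validates every row, and rejects duplicate chemical names.
#'
#' @param path Path to a `.csv` or `.json` registry file.
#' @return An object of class `ohra_registry` (a data frame keyed by `name`).
#' @examples
#' reg <- load_registry(system.file("extdata", "hazard_registry.csv", package = "ohra"))
#' get_rfc(get_profile(reg, "Benzene"))
#' @export
load_registry <- function(path) {
  if (!file.exists(path)) ohra_stop("registry file not found: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  }
  if (nrow(df) == 0) {
    warning("registry file is empty: ", path)
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(.registry_cols)),
                                        .registry_cols))
  }
  missing <- setdiff(c("name"), names(df))
  if (length(missing))
    ohra_stop("registry is missing required column(s): %s", paste(missing, collapse = ", "))
  for (col in setdiff(.registry_cols, names(df))) df[[col]] <- NA_character_
  df <- df[, .registry_cols]
  for (f in c("rfc", "iur", "oel_china_twa", "oel_acgih_twa", "ld50_oral",
              "lc50_inhal", "hr_override")) {
    raw <- df[[f]]
    df[[f]] <- .num_or_na(raw)
    bad <- which(!is.na(raw) & nzchar(trimws(raw)) & is.na(df[[f]]))
    if (length(bad))
      ohra_stop("registry field '%s' is not numeric at line %d ('%s')",
                f, bad[1] + 1L, raw[bad[1]], class = "ohra_validation_error")
  }
  df$risk_phrases[is.na(df$risk_phrases)] <- ""
  df$carcinogenicity[is.na(df$carcinogenicity) | df$carcinogenicity == ""] <- "none"
  if (anyDuplicated(df$name))
    ohra_stop("duplicate chemical name(s) in registry: %s",
              paste(unique(df$name[duplicated(df$name)]), collapse = ", "),
              class = "ohra_duplicate_error")
  if (nrow(df)) {
    for (i in seq_len(nrow(df))) validate_profile(as.list(df[i, ]), line = i + 1L)
    n_placeholder <- sum(grepl("placeholder", df$notes, ignore.case = TRUE))
    if (n_placeholder > 0)
      message(sprintf(
        "registry '%s': %d chemical(s) carry placeholder limit values not taken from a primary source; confirm before regulatory use",
        basename(path), n_placeholder))
  }
  rownames(df) <- NULL
  class(df) <- c("ohra_registry", "data.frame")
  df
}

#' Write a hazard registry to a CSV file
#'
#' Inverse of [load_registry()]: `load_registry(write_registry(reg, f))`
#' returns a registry equal to `reg`.
#'
#' @param registry An `ohra_registry`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  utils::write.csv(as.data.frame(registry), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Look up one chemical's profile
#'
#' @param registry An `ohra_registry`.
#' @param name Chemical name (registry key).
#' @return A one-row profile as a named list.
#' @export
get_profile <- function(registry, name) {
  i <- match(name, registry$name)
  if (is.na(i)) ohra_stop("hazard '%s' not found in registry", name,
                          class = "ohra_lookup_error")
  as.list(registry[i, ])
}

#' Reference concentration of a chemical
#'
#' Returns the stored inhalation RfC in \eqn{\mu g/m^3}. A chemical without an
#' RfC cannot be scored by the EPA hazard-quotient engine; requesting its RfC
#' is an error rather than an `NA` so the caller must handle the skip.
#'
#' @param profile A profile from [get_profile()].
#' @return RfC in \eqn{\mu g/m^3}.
#' @export
get_rfc <- function(profile) {
  if (is.null(profile$rfc) || is.na(profile$rfc))
    ohra_stop("'%s' has no reference concentration (RfC); it cannot be scored by the EPA engine",
              profile$name, class = "ohra_missing_parameter")
  profile$rfc
}

#' Occupational exposure limit of a chemical
#'
#' @param profile A profile from [get_profile()].
#' @param source `"china"` (PC-TWA) or `"acgih"` (TLV-TWA).
#' @return OEL in \eqn{mg/m^3}.
#' @export
get_oel <- function(profile, source = c("china", "acgih")) {
  source <- match.arg(source)
  oel <- switch(source, china = profile$oel_china_twa, acgih = profile$oel_acgih_twa)
  if (is.null(oel) || is.na(oel))
    ohra_stop("'%s' has no %s occupational exposure limit", profile$name,
              toupper(source), class = "ohra_missing_parameter")
  oel
}

#' @export
print.ohra_registry <- function(x, ...) {
  cat(sprintf("<ohra_registry> %d chemical(s)\n", nrow(x)))
  if (nrow(x)) {
    shown <- data.frame(name = x$name, rfc_ug_m3 = x$rfc,
                        oel_china = x$oel_china_twa, carc = x$carcinogenicity,
                        form = x$physical_form)
    print(shown, row.names = FALSE)
  }
  invisible(x)
}

#' Path to the registry shipped with the package
#'
#' Covers the hazards of the bundled five-industry synthetic study. Limit
#' values not traceable to a primary source are flagged as placeholders in the
#' `notes` column and logged at load.
#'
#' @return File path.
#' @export
default_registry_path <- function() {
  system.file("extdata", "hazard_registry.csv", package = "ohra", mustWork = TRUE)
}

#' Load the registry shipped with the package
#' @return An `ohra_registry`.
#' @export
default_registry <- function() load_registry(default_registry_path())
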