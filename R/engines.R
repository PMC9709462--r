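#' Scoring engines
#'
#' Six occupational health risk assessment models, each mapping an exposure
#' record (plus the chemical's hazard profile) to a raw score and an ordinal
#' risk level:
#'
#' * **EPA** — quantitative: hazard quotient HQ = EC/RfC, banded to levels 1-5.
#' * **Singaporean** — semi-quantitative: risk = sqrt(HR x ER), HR from
#'   carcinogenicity/acute toxicity, ER from the concentration ratio.
#' * **COSHH** — control banding: risk phrases give a hazard band A-E,
#'   dustiness/volatility and quantity give an exposure-potential band, a
#'   matrix gives control strategies CS1-CS4 (levels 2-5). Airborne
#'   concentration is ignored by design.
#' * **ICMM** — consequence x likelihood matrix, likelihood shifted by an
#'   exposure-time weight.
#' * **Australian** — calculator on likelihood x frequency x severity,
#'   rescaled to 1-5; fractional levels attainable.
#' * **Romanian** — 7x6 severity x probability matrix, levels 1-7.
#'
#' All band lookups are left-closed, right-open, with the top band closed
#' above.
#'
#' @name risk_models
NULL

#' EPA hazard quotient
#'
#' \deqn{HQ = EC / RfC} with EC and RfC both in \eqn{\mu g/m^3}. (When the
#' RfC is quoted in \eqn{mg/m^3} the required factor of 1,000 \eqn{\mu g/mg}
#' is exactly the unit conversion applied here; HQ is dimensionless.)
#'
#' @param ec Exposure concentration, \eqn{\mu g/m^3} (vectorized).
#' @param rfc Reference concentration, \eqn{\mu g/m^3}.
#' @return Dimensionless hazard quotient.
#' @export
epa_hq <- function(ec, rfc) {
  if (any(is.na(rfc)) || any(rfc <= 0))
    ohra_stop("RfC must be a positive concentration", class = "ohra_parameter_error")
  stopifnot(all(ec >= 0))
  ec / rfc
}

#' EPA risk level from the hazard quotient
#'
#' Bands `<0.1, [0.1,0.5), [0.5,1), [1,2), >=2` map HQ to levels 1-5.
#'
#' @param hq Hazard quotient (vectorized).
#' @param bands Band breakpoints (length 4, increasing).
#' @return Integer level 1-5.
#' @export
epa_level <- function(hq, bands = default_method_config()$hq_bands) {
  if (any(is.na(hq)) || any(hq < 0))
    ohra_stop("hazard quotient must be >= 0", class = "ohra_parameter_error")
  band_lookup(hq, bands)
}

#' Singaporean hazard rating (HR)
#'
#' An explicit `hr_override` on the profile wins. Otherwise the shipped rule
#' table applies: IARC group 1 or 2A gives HR 5 and group 2B gives HR 4;
#' failing that, acute-toxicity bands on the oral LD50 (mg/kg) or inhalation
#' LC50 (\eqn{mg/m^3}) give HR 5 (most toxic band) down to 1, taking the
#' more severe of the two when both are present.
#'
#' @param profile Profile from [get_profile()].
#' @param hr_table Rule table (see [default_method_config()]).
#' @return Integer rating 1-5.
#' @export
singapore_hr <- function(profile, hr_table = default_method_config()$hr_table) {
  if (!is.null(profile$hr_override) && !is.na(profile$hr_override))
    return(as.integer(profile$hr_override))
  carc <- hr_table$carcinogenicity
  if (!is.null(profile$carcinogenicity) && profile$carcinogenicity %in% names(carc))
    return(as.integer(carc[[profile$carcinogenicity]]))
  hr <- integer(0)
  if (!is.null(profile$ld50_oral) && !is.na(profile$ld50_oral))
    hr <- c(hr, 6L - band_lookup(profile$ld50_oral, hr_table$ld50_breaks))
  if (!is.null(profile$lc50_inhal) && !is.na(profile$lc50_inhal))
    hr <- c(hr, 6L - band_lookup(profile$lc50_inhal, hr_table$lc50_breaks))
  if (!length(hr))
    ohra_stop("cannot derive a hazard rating for '%s': no override, informative carcinogenicity class, or acute-toxicity data",
              profile$name %||% "<unnamed>", class = "ohra_missing_parameter")
  max(hr)
}

#' Singaporean exposure rating (ER)
#'
#' Concentration-ratio bands `<0.1, [0.1,0.5), [0.5,1), [1,2), >=2` map CR to
#' ratings 1-5.
#'
#' @param cr Concentration ratio (vectorized).
#' @param bands Band breakpoints (length 4, increasing).
#' @return Integer rating 1-5.
#' @export
singapore_er <- function(cr, bands = default_method_config()$er_bands) {
  if (any(is.na(cr)) || any(cr < 0))
    ohra_stop("concentration ratio must be >= 0", class = "ohra_parameter_error")
  band_lookup(cr, bands)
}

#' Singaporean risk level
#'
#' \deqn{Risk = \sqrt{HR \times ER}} rounded up to the next integer
#' (conservative convention), capped at 5.
#'
#' @param hr Hazard rating 1-5.
#' @param er Exposure rating 1-5.
#' @return Integer level 1-5.
#' @export
singapore_risk <- function(hr, er) {
  if (any(!(hr %in% 1:5)) || any(!(er %in% 1:5)))
    ohra_stop("hazard and exposure ratings must be integers in 1..5",
              class = "ohra_parameter_error")
  pmin(5L, as.integer(ceiling(sqrt(hr * er) - 1e-9)))
}

#' COSHH hazard band from risk phrases
#'
#' Each phrase maps to a band A-E via the shipped table; the chemical's band
#' is the most severe among its phrases.
#'
#' @param phrases Character vector of risk-phrase codes (or a single
#'   semicolon-joined string).
#' @param phrase_bands Named list of phrase vectors per band.
#' @return One of `"A".."E"`.
#' @export
coshh_hazard_band <- function(phrases,
                              phrase_bands = default_method_config()$coshh$phrase_bands) {
  if (length(phrases) == 1 && grepl(";", phrases))
    phrases <- strsplit(phrases, ";", fixed = TRUE)[[1]]
  phrases <- trimws(phrases[nzchar(trimws(phrases))])
  if (!length(phrases))
    ohra_stop("no risk phrases available to derive a COSHH hazard band",
              class = "ohra_missing_parameter")
  bands <- vapply(phrases, function(p) {
    hit <- names(phrase_bands)[vapply(phrase_bands, function(v) p %in% v, logical(1))]
    if (!length(hit))
      ohra_stop("risk phrase '%s' is not in the COSHH band table", p,
                class = "ohra_unknown_phrase")
    hit[1]
  }, character(1))
  c("A", "B", "C", "D", "E")[max(match(bands, c("A", "B", "C", "D", "E")))]
}

#' COSHH assessment
#'
#' Hazard band (A-E) from risk phrases; exposure potential (EP1-EP4) from the
#' quantity band crossed with the dustiness band (solids) or volatility band
#' (liquids; gases are treated as highly volatile); the control-approach
#' matrix then yields a control strategy CS1-CS4 and, via the conversion
#' table, a level 2-5.
#'
#' @param profile Profile from [get_profile()].
#' @param quantity_band `"small"`, `"medium"` (default) or `"large"`.
#' @param config An `ohra_config`.
#' @return List with `band`, `ep`, `cs` (e.g. `"CS1"`), `level`.
#' @export
coshh_assess <- function(profile, quantity_band = NULL,
                         config = default_method_config()) {
  quantity_band <- quantity_band %||% config$defaults$quantity_band
  if (!(quantity_band %in% rownames(config$coshh$ep_table)))
    ohra_stop("unknown quantity band '%s'", quantity_band,
              class = "ohra_parameter_error")
  band <- coshh_hazard_band(profile$risk_phrases, config$coshh$phrase_bands)
  dv <- switch(profile$physical_form,
               solid  = profile$dustiness_band,
               liquid = profile$volatility_band,
               gas    = "high",
               ohra_stop("unknown physical form '%s' for '%s'",
                         profile$physical_form, profile$name))
  if (is.null(dv) || is.na(dv) || !nzchar(dv))
    ohra_stop("'%s' lacks a dustiness/volatility band", profile$name,
              class = "ohra_missing_parameter")
  ep <- config$coshh$ep_table[quantity_band, dv]
  cs <- config$coshh$ca_matrix[band, ep]
  list(band = band, ep = as.integer(ep), cs = paste0("CS", cs),
       level = coshh_cs_to_level(paste0("CS", cs)))
}

#' ICMM matrix assessment
#'
#' Looks up the 5x5 likelihood x consequence grid. The exposure-time weight
#' (1 = short, 2 = typical, 3 = long) shifts the likelihood one step down or
#' up before the lookup, clamped to 1-5.
#'
#' @param consequence Rating 1-5.
#' @param exposure_probability Likelihood rating 1-5 (derivable from CR bands
#'   upstream).
#' @param exposure_time_weight Rating 1-3; default 2 (no shift).
#' @param grid 5x5 matrix, rows = likelihood, cols = consequence.
#' @return Integer level 1-5.
#' @export
icmm_assess <- function(consequence, exposure_probability,
                        exposure_time_weight = 2L,
                        grid = default_method_config()$icmm_matrix) {
  if (!(consequence %in% 1:5) || !(exposure_probability %in% 1:5))
    ohra_stop("ICMM ratings must be integers in 1..5", class = "ohra_parameter_error")
  if (!(exposure_time_weight %in% 1:3))
    ohra_stop("ICMM exposure-time weight must be 1, 2 or 3",
              class = "ohra_parameter_error")
  likelihood <- min(5L, max(1L, exposure_probability + (exposure_time_weight - 2L)))
  as.integer(grid[likelihood, consequence])
}

#' Australian calculator assessment
#'
#' Table lookup on the shipped 125-cell calculator table
#' (see [australian_table()]); fractional levels are attainable.
#'
#' @param likelihood,exposure_frequency,severity Ratings 1-5.
#' @param table Calculator table.
#' @return Level in `[1, 5]`, possibly fractional.
#' @export
australian_assess <- function(likelihood, exposure_frequency, severity,
                              table = default_method_config()$australian) {
  ok <- function(x) length(x) == 1 && x %in% 1:5
  if (!ok(likelihood) || !ok(exposure_frequency) || !ok(severity))
    ohra_stop("Australian ratings must be integers in 1..5",
              class = "ohra_parameter_error")
  i <- which(table$likelihood == likelihood &
               table$frequency == exposure_frequency &
               table$severity == severity)
  table$level[i]
}

#' Romanian matrix assessment
#'
#' 7x6 severity x probability grid giving levels 1-7.
#'
#' @param severity Rating 1-7.
#' @param probability Rating 1-6.
#' @param grid 7x6 matrix.
#' @return Integer level 1-7.
#' @export
romanian_assess <- function(severity, probability,
                            grid = default_method_config()$romanian_matrix) {
  if (!(severity %in% 1:7) || !(probability %in% 1:6))
    ohra_stop("Romanian ratings must be severity 1..7, probability 1..6",
              class = "ohra_parameter_error")
  as.integer(grid[severity, probability])
}
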