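#' Exposure records
#'
#' An exposure record is one job/location measurement: industry, location
#' (job or operation), hazard (a registry key), the time-weighted airborne
#' concentration `ca` in \eqn{mg/m^3}, the exposure pattern (`et` hours/day,
#' `ef` days/year, `ed` years) and the number of exposed workers. The
#' averaging time used by the exposure-concentration formula is derived
#' (`ed` x 365 d/y x 24 h/d), never stored.
#'
#' @name exposure_records
NULL

.exposure_cols <- c("industry", "location", "hazard", "ca_mg_m3",
                    "et_h_d", "ef_d_y", "ed_y", "n_workers")

#' Validate a table of exposure records
#'
#' Checks `ca >= 0`, `0 < et <= 24`, `0 < ef <= 365`, `ed > 0`, and fills
#' missing exposure-pattern cells with the full-shift defaults (8 h/d,
#' 250 d/y, 25 y), with a message naming how many cells were defaulted.
#'
#' @param records Data frame in the exposure schema.
#' @param defaults Named list with `et`, `ef`, `ed`.
#' @return The validated data frame, class `ohra_exposure`.
#' @export
validate_exposure <- function(records,
                              defaults = default_method_config()$defaults) {
  missing <- setdiff(c("industry", "location", "hazard", "ca_mg_m3"),
                     names(records))
  if (length(missing))
    ohra_stop("exposure table is missing column(s): %s",
              paste(missing, collapse = ", "))
  for (col in setdiff(.exposure_cols, names(records))) records[[col]] <- NA
  n_def <- 0L
  for (p in c("et", "ef", "ed")) {
    col <- paste0(p, switch(p, et = "_h_d", ef = "_d_y", ed = "_y"))
    records[[col]] <- suppressWarnings(as.numeric(records[[col]]))
    idx <- is.na(records[[col]])
    n_def <- n_def + sum(idx)
    records[[col]][idx] <- defaults[[p]]
  }
  if (n_def > 0)
    message(sprintf("exposure records: %d missing exposure-pattern cell(s) filled with full-shift defaults (et=%g h/d, ef=%g d/y, ed=%g y)",
                    n_def, defaults$et, defaults$ef, defaults$ed))
  records$ca_mg_m3 <- as.numeric(records$ca_mg_m3)
  records$n_workers[is.na(records$n_workers)] <- 1L
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i))
      ohra_stop("invalid exposure record at row %d: %s", i[1], what,
                class = "ohra_validation_error")
  }
  bad(is.na(records$ca_mg_m3) | records$ca_mg_m3 < 0, "ca must be >= 0")
  bad(records$et_h_d <= 0 | records$et_h_d > 24, "et must be in (0, 24]")
  bad(records$ef_d_y <= 0 | records$ef_d_y > 365, "ef must be in (0, 365]")
  bad(records$ed_y <= 0, "ed must be > 0")
  bad(records$n_workers < 0, "n_workers must be >= 0")
  records <- records[, .exposure_cols]
  class(records) <- c("ohra_exposure", "data.frame")
  records
}

#' Read exposure records from a delimited file
#'
#' Comma-separated with header columns `industry, location, hazard, ca_mg_m3,
#' et_h_d, ef_d_y, ed_y, n_workers`; missing exposure-pattern cells are filled
#' with full-shift defaults (logged).
#'
#' @param path File path.
#' @inheritParams validate_exposure
#' @return An `ohra_exposure` data frame.
#' @export
read_exposure <- function(path, defaults = default_method_config()$defaults) {
  if (!file.exists(path)) ohra_stop("exposure file not found: %s", path)
  validate_exposure(utils::read.csv(path, stringsAsFactors = FALSE), defaults)
}

#' Write exposure records
#' @param records An `ohra_exposure` data frame.
#' @param path Output path.
#' @export
write_exposure <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' Exposure concentration (EC)
#'
#' Time-averaged exposure concentration in \eqn{\mu g/m^3}:
#' \deqn{EC = \frac{CA \times ET \times EF \times ED}{AT}, \qquad
#'       AT = ED \times 365 \times 24}
#' with CA converted from \eqn{mg/m^3} to \eqn{\mu g/m^3}. The exposure
#' duration ED cancels against the averaging time, so EC depends only on CA,
#' ET and EF; with continuous exposure (ET = 24, EF = 365) EC equals CA.
#'
#' @param ca_mg_m3 Airborne concentration, \eqn{mg/m^3} (vectorized).
#' @param et Exposure time, hours/day.
#' @param ef Exposure frequency, days/year.
#' @param ed Exposure duration, years (kept for the record interface; cancels).
#' @return EC in \eqn{\mu g/m^3}.
#' @examples
#' compute_ec(1, et = 8, ef = 250)  # 228.31
#' @export
compute_ec <- function(ca_mg_m3, et = 8, ef = 250, ed = 25) {
  stopifnot(all(ca_mg_m3 >= 0), all(et > 0 & et <= 24),
            all(ef > 0 & ef <= 365), all(ed > 0))
  (ca_mg_m3 * 1000) * et * ef * ed / (ed * 365 * 24)
}

#' Concentration ratio (CR)
#'
#' Ratio of the measured airborne concentration to the occupational exposure
#' limit (both \eqn{mg/m^3}). CR > 1 means the exposure exceeds the limit.
#'
#' @param ca_mg_m3 Airborne concentration, \eqn{mg/m^3}.
#' @param oel_mg_m3 Occupational exposure limit, \eqn{mg/m^3}.
#' @return Dimensionless ratio.
#' @export
compute_cr <- function(ca_mg_m3, oel_mg_m3) {
  stopifnot(all(ca_mg_m3 >= 0))
  if (any(is.na(oel_mg_m3)) || any(oel_mg_m3 <= 0))
    ohra_stop("occupational exposure limit must be a positive number",
              class = "ohra_missing_parameter")
  ca_mg_m3 / oel_mg_m3
}

#' CR for a record against a registry profile
#'
#' @param record One exposure record (list or one-row data frame).
#' @param profile Profile from [get_profile()].
#' @param limit OEL source, `"china"` (default) or `"acgih"`.
#' @return Dimensionless ratio.
#' @export
record_cr <- function(record, profile, limit = c("china", "acgih")) {
  compute_cr(record$ca_mg_m3, get_oel(profile, match.arg(limit)))
}
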