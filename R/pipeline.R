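#' Run all requested scoring engines over a set of exposure records
#'
#' The central constructor of the package: for every (record, method) pair it
#' derives the method's inputs, scores the record, and harmonizes the level
#' to a risk ratio. Records a method cannot score (a chemical without an RfC
#' for the EPA engine, a missing OEL for the concentration-ratio bands, a
#' missing dustiness band for COSHH) are skipped, with the reason kept in the
#' skip log (`attr(x, "skipped")`) rather than scored with a default.
#'
#' Unattended defaults: the Singaporean hazard rating doubles as the
#' consequence/severity rating for the ICMM, Australian and Romanian engines;
#' the exposure probability/likelihood rating is banded from the
#' concentration ratio; the Australian frequency rating is banded from the
#' exposure frequency (days/year). All of these can be overridden per
#' (industry, location, hazard) through `config$ratings`, a data frame with
#' those three key columns plus any of `icmm_consequence`,
#' `icmm_probability`, `icmm_time_weight`, `australian_likelihood`,
#' `australian_frequency`, `australian_severity`, `romanian_severity`,
#' `romanian_probability`, `coshh_quantity`.
#'
#' @param records An `ohra_exposure` table (see [validate_exposure()]).
#' @param registry An `ohra_registry`.
#' @param methods Subset of the six method names; default all.
#' @param config An `ohra_config`; default [default_method_config()].
#' @param oel_source `"china"` (default) or `"acgih"`; which OEL the
#'   concentration ratio uses.
#' @return An `ohra_results` data frame: one row per scored (record, method)
#'   with `record_id, industry, location, hazard, ca_mg_m3, cr, method,
#'   raw_score, level, rr, rr_display, config_checksum`; attributes `skipped`
#'   (skip log) and `checksum`.
#' @export
assess_all <- function(records, registry, methods = .methods_all,
                       config = default_method_config(),
                       oel_source = NULL) {
  methods <- match.arg(methods, .methods_all, several.ok = TRUE)
  oel_source <- oel_source %||% config$defaults$oel_source
  checksum <- config_checksum(config)
  romanian_scale <- method_scale("Romanian", config$romanian_denominator)
  if (!nrow(records)) {
    warning("no exposure records to assess")
    out <- data.frame()
    attr(out, "skipped") <- data.frame()
    attr(out, "checksum") <- checksum
    class(out) <- c("ohra_results", "data.frame")
    return(out)
  }

  # Per-hazard derivations are shared by every record of that hazard.
  hazard_info <- new.env(parent = emptyenv())
  get_info <- function(hz) {
    if (!is.null(hazard_info[[hz]])) return(hazard_info[[hz]])
    info <- list(profile = get_profile(registry, hz))
    info$rfc <- tryCatch(get_rfc(info$profile), error = function(e) e)
    info$oel <- tryCatch(get_oel(info$profile, oel_source), error = function(e) e)
    info$hr <- tryCatch(singapore_hr(info$profile, config$hr_table),
                        error = function(e) e)
    hazard_info[[hz]] <- info
    info
  }

  ratings_for <- function(rec) {
    rt <- config$ratings
    if (is.null(rt)) return(NULL)
    i <- which(rt$industry == rec$industry & rt$location == rec$location &
                 rt$hazard == rec$hazard)
    if (!length(i)) NULL else as.list(rt[i[1], ])
  }
  pick <- function(ov, field, fallback) {
    v <- ov[[field]]
    if (is.null(v) || is.na(v)) fallback() else v
  }

  rows <- vector("list", nrow(records) * length(methods))
  skips <- list()
  k <- 0L
  for (i in seq_len(nrow(records))) {
    rec <- as.list(records[i, ])
    info <- get_info(rec$hazard)
    ov <- ratings_for(rec)
    cr <- if (inherits(info$oel, "error")) NA_real_ else
      compute_cr(rec$ca_mg_m3, info$oel)
    for (m in methods) {
      res <- tryCatch({
        switch(m,
          EPA = {
            if (inherits(info$rfc, "error")) stop(info$rfc)
            ec <- compute_ec(rec$ca_mg_m3, rec$et_h_d, rec$ef_d_y, rec$ed_y)
            hq <- epa_hq(ec, info$rfc)
            list(raw = hq, level = epa_level(hq, config$hq_bands))
          },
          Singaporean = {
            if (inherits(info$hr, "error")) stop(info$hr)
            if (is.na(cr)) stop(info$oel)
            er <- singapore_er(cr, config$er_bands)
            list(raw = sqrt(info$hr * er),
                 level = singapore_risk(info$hr, er))
          },
          COSHH = {
            co <- coshh_assess(info$profile,
                               quantity_band = if (!is.null(ov)) pick(ov, "coshh_quantity", function() NULL),
                               config = config)
            list(raw = as.numeric(sub("CS", "", co$cs)), level = co$level)
          },
          ICMM = {
            cons <- pick(ov, "icmm_consequence", function() {
              if (inherits(info$hr, "error")) stop(info$hr); info$hr })
            prob <- pick(ov, "icmm_probability", function() {
              if (is.na(cr)) stop(info$oel)
              band_lookup(cr, config$cr_probability_bands) })
            wt <- pick(ov, "icmm_time_weight", function() 2L)
            lv <- icmm_assess(cons, prob, wt, config$icmm_matrix)
            list(raw = lv, level = lv)
          },
          Australian = {
            lik <- pick(ov, "australian_likelihood", function() {
              if (is.na(cr)) stop(info$oel)
              band_lookup(cr, config$cr_probability_bands) })
            freq <- pick(ov, "australian_frequency", function()
              band_lookup(rec$ef_d_y, config$defaults$ef_frequency_breaks))
            sev <- pick(ov, "australian_severity", function() {
              if (inherits(info$hr, "error")) stop(info$hr); info$hr })
            lv <- australian_assess(lik, freq, sev, config$australian)
            list(raw = lv, level = lv)
          },
          Romanian = {
            sev <- pick(ov, "romanian_severity", function() {
              if (inherits(info$hr, "error")) stop(info$hr); info$hr })
            prob <- pick(ov, "romanian_probability", function() {
              if (is.na(cr)) stop(info$oel)
              min(6L, band_lookup(cr, config$cr_probability_bands)) })
            lv <- romanian_assess(sev, prob, config$romanian_matrix)
            list(raw = lv, level = lv)
          })
      }, error = function(e) e)
      if (inherits(res, "error")) {
        skips[[length(skips) + 1L]] <- data.frame(
          record_id = i, industry = rec$industry, location = rec$location,
          hazard = rec$hazard, method = m, reason = conditionMessage(res),
          stringsAsFactors = FALSE)
        next
      }
      scale <- if (m == "Romanian") romanian_scale else method_scale(m)
      rrv <- level_to_rr(m, res$level, scale)
      k <- k + 1L
      rows[[k]] <- data.frame(
        record_id = i, industry = rec$industry, location = rec$location,
        hazard = rec$hazard, ca_mg_m3 = rec$ca_mg_m3, cr = cr, method = m,
        raw_score = res$raw, level = res$level, rr = rrv$rr,
        rr_display = rrv$rr_display, stringsAsFactors = FALSE)
    }
  }
  out <- if (k) do.call(rbind, rows[seq_len(k)]) else data.frame()
  if (k) out$config_checksum <- checksum
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skips)) do.call(rbind, skips) else
    data.frame(record_id = integer(0), industry = character(0),
               location = character(0), hazard = character(0),
               method = character(0), reason = character(0))
  attr(out, "checksum") <- checksum
  class(out) <- c("ohra_results", "data.frame")
  out
}

#' @export
print.ohra_results <- function(x, ...) {
  sk <- attr(x, "skipped")
  cat(sprintf("<ohra_results> %d assessment(s), %d skipped; config %s\n",
              nrow(x), if (is.null(sk)) 0L else nrow(sk),
              substr(attr(x, "checksum") %||% "", 1, 8)))
  if (nrow(x)) {
    utils::head(as.data.frame(x)[, c("industry", "location", "hazard",
                                     "method", "level", "rr_display")], 10) |>
      print(row.names = FALSE)
    if (nrow(x) > 10) cat(sprintf("... %d more row(s)\n", nrow(x) - 10))
  }
  invisible(x)
}

#' @export
summary.ohra_results <- function(object, group_by = "method", ...) {
  summarize_rr(object, group_by = group_by)
}

#' @export
plot.ohra_results <- function(x, ...) {
  if (!nrow(x)) return(invisible(x))
  graphics::boxplot(rr ~ method, data = x, ylab = "risk ratio",
                    xlab = "method", ylim = c(0, 1), ...)
  invisible(x)
}

#' Write an assessment results table
#'
#' Delimited text with one header line, the layout used by the command-line
#' pipeline; the skip log goes to a sibling `*_skipped.csv` when non-empty.
#'
#' @param results An `ohra_results`.
#' @param path Output path.
#' @export
write_results <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  sk <- attr(results, "skipped")
  if (!is.null(sk) && nrow(sk))
    utils::write.csv(sk, sub("\\.csv$", "_skipped.csv", path), row.names = FALSE)
  invisible(path)
}
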