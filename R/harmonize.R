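#' Method scales and risk ratios
#'
#' Each method emits levels on its own ordinal scale: the EPA, Singaporean,
#' ICMM and Australian methods use five levels; COSHH attains levels 2-5
#' (control strategies CS1-CS4); the Romanian method has seven. To compare
#' methods, each level is converted to a risk ratio
#' \deqn{RR = level / max\_level \in (0, 1],}
#' the level relative to the top of the method's scale. For the Romanian
#' scale the default denominator is 10 rather than the seven-level maximum:
#' with denominator 10 the Romanian ratios land on the same one-decimal grid
#' as the five-level methods (level 4 -> 0.4, 6 -> 0.6), which is the
#' convention this package reproduces; the literal seven-level definition is
#' available via `romanian_denominator = 7`.
#'
#' @name harmonization
NULL

.methods_all <- c("EPA", "COSHH", "Singaporean", "ICMM", "Australian", "Romanian")

#' Scale bookkeeping for one method
#'
#' @param method One of `"EPA", "COSHH", "Singaporean", "ICMM", "Australian",
#'   "Romanian"`.
#' @param romanian_denominator 10 (default) or 7.
#' @return List with `method`, `levels` (attainable levels), `max_level`
#'   (risk-ratio denominator) and `allows_fractional`.
#' @export
method_scale <- function(method, romanian_denominator = 10) {
  method <- match.arg(method, .methods_all)
  switch(method,
    EPA         = list(method = method, levels = 1:5, max_level = 5,
                       allows_fractional = FALSE),
    Singaporean = list(method = method, levels = 1:5, max_level = 5,
                       allows_fractional = FALSE),
    ICMM        = list(method = method, levels = 1:5, max_level = 5,
                       allows_fractional = FALSE),
    Australian  = list(method = method, levels = 1:5, max_level = 5,
                       allows_fractional = TRUE),
    COSHH       = list(method = method, levels = 2:5, max_level = 5,
                       allows_fractional = FALSE),
    Romanian    = {
      if (!(romanian_denominator %in% c(7, 10)))
        ohra_stop("Romanian risk-ratio denominator must be 7 or 10",
                  class = "ohra_parameter_error")
      list(method = method, levels = 1:7, max_level = romanian_denominator,
           allows_fractional = FALSE)
    })
}

#' Convert a risk level to a risk ratio
#'
#' @param method Method name.
#' @param level Level on the method's scale (fractional allowed where the
#'   scale allows it).
#' @param scale Scale from [method_scale()]; defaults to the method's scale.
#' @return List with `method`, `level`, `rr` (full precision) and
#'   `rr_display` (rounded half-up to one decimal).
#' @examples
#' level_to_rr("EPA", 5)$rr          # 1.0
#' level_to_rr("Romanian", 4)$rr     # 0.4 (denominator 10)
#' @export
level_to_rr <- function(method, level, scale = method_scale(method)) {
  if (scale$allows_fractional) {
    ok <- level >= min(scale$levels) & level <= max(scale$levels)
  } else {
    ok <- level %in% scale$levels
  }
  if (any(is.na(level)) || !all(ok))
    ohra_stop("level %s is outside the %s scale (attainable: %s)",
              paste(level[!ok], collapse = ","), scale$method,
              paste(range(scale$levels), collapse = "-"),
              class = "ohra_scale_error")
  rr <- level / scale$max_level
  list(method = scale$method, level = level, rr = rr,
       rr_display = round_half_up(rr, 1L))
}

#' COSHH control strategy to risk level
#'
#' CS1 -> 2, CS2 -> 3, CS3 -> 4, CS4 -> 5 (the COSHH output aligned with the
#' Singaporean level scale).
#'
#' @param cs `"CS1".."CS4"` (or integer 1-4).
#' @return Integer level 2-5.
#' @export
coshh_cs_to_level <- function(cs) {
  if (is.numeric(cs)) cs <- paste0("CS", cs)
  map <- c(CS1 = 2L, CS2 = 3L, CS3 = 4L, CS4 = 5L)
  if (any(!(cs %in% names(map))))
    ohra_stop("unknown control strategy '%s'", paste(setdiff(cs, names(map)),
              collapse = ","), class = "ohra_parameter_error")
  unname(map[cs])
}

#' Median and range of risk ratios per group
#'
#' Summarizes display-rounded risk ratios as `median (min-max)` per group,
#' the layout used for cross-method comparison tables. Groups with no rows
#' are omitted with a warning.
#'
#' @param results An `ohra_results` table (from [assess_all()]) or any data
#'   frame with an `rr_display` column.
#' @param group_by Character vector of grouping columns, default `"method"`.
#' @return Data frame with the group keys, `n`, `median`, `min`, `max` and a
#'   formatted `summary` column.
#' @export
summarize_rr <- function(results, group_by = "method") {
  if (!nrow(results)) {
    warning("no assessment results to summarize")
    return(data.frame())
  }
  missing <- setdiff(c(group_by, "rr_display"), names(results))
  if (length(missing))
    ohra_stop("results table lacks column(s): %s", paste(missing, collapse = ", "))
  key <- interaction(results[group_by], drop = TRUE, sep = "\r")
  parts <- lapply(split(results$rr_display, key), function(v) {
    c(n = length(v), median = stats::median(v), min = min(v), max = max(v))
  })
  keys <- do.call(rbind, strsplit(names(parts), "\r", fixed = TRUE))
  out <- as.data.frame(keys, stringsAsFactors = FALSE)
  names(out) <- group_by
  stat <- do.call(rbind, parts)
  out$n <- as.integer(stat[, "n"])
  out$median <- round_half_up(stat[, "median"], 1L)
  out$min <- stat[, "min"]
  out$max <- stat[, "max"]
  out$summary <- sprintf("%.1f (%.1f-%.1f)", out$median, out$min, out$max)
  rownames(out) <- NULL
  out <- out[do.call(order, unname(as.list(out[group_by]))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
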