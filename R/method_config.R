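#' Method configuration
#'
#' The ICMM, Australian and Romanian methods are matrix/calculator methods
#' whose rating tables are ordinarily filled in by an evaluator; COSHH and the
#' Singaporean method rely on published band tables. To make an inherently
#' judgment-driven assessment reproducible, every table the engines consult is
#' frozen in one configuration object, and each result row carries the MD5
#' checksum of that configuration. All tables are editable; the shipped
#' defaults are monotone reconstructions in the spirit of the source methods.
#'
#' Components:
#' \describe{
#'   \item{hq_bands}{Breakpoints mapping the EPA hazard quotient to levels
#'     1-5: `<0.1, [0.1,0.5), [0.5,1), [1,2), >=2`.}
#'   \item{er_bands}{Breakpoints mapping the concentration ratio (CR) to the
#'     Singaporean exposure rating 1-5 (same cut points as `hq_bands`).}
#'   \item{hr_table}{Default hazard-rating rules: carcinogenicity class to HR,
#'     plus acute-toxicity bands (oral LD50 mg/kg, inhalation LC50 mg/m3) used
#'     when the class is uninformative.}
#'   \item{coshh}{Risk-phrase to hazard-band map (A-E), the exposure-potential
#'     table (quantity x dustiness/volatility), and the control-approach
#'     matrix (band x EP -> CS1-CS4).}
#'   \item{icmm_matrix}{5x5 likelihood x consequence grid; the exposure-time
#'     weight (1-3) shifts likelihood down/up one step.}
#'   \item{australian}{Nomogram in table form: level = 1 + 4 log(LxFxS)/log(125),
#'     rounded to one decimal, enumerated over all 125 rating triples.}
#'   \item{romanian_matrix}{7x6 severity x probability grid giving levels 1-7.}
#'   \item{romanian_denominator}{Risk-ratio denominator for the Romanian
#'     scale, 10 by default (see [method_scale()]).}
#'   \item{defaults}{Full-shift exposure pattern (`et` 8 h/d, `ef` 250 d/y,
#'     `ed` 25 y), COSHH quantity band (`medium`), OEL source (`china`),
#'     frequency-rating breakpoints on days/year, and `alpha` 0.05.}
#' }
#'
#' @return A list of class `ohra_config`.
#' @export
default_method_config <- function() {
  cfg <- list(
    hq_bands = c(0.1, 0.5, 1, 2),
    er_bands = c(0.1, 0.5, 1, 2),
    cr_probability_bands = c(0.1, 0.5, 1, 2),
    hr_table = list(
      carcinogenicity = c("IARC-1" = 5, "IARC-2A" = 5, "IARC-2B" = 4),
      ld50_breaks = c(25, 200, 2000, 5000),     # mg/kg;  bands map to HR 5..1
      lc50_breaks = c(500, 2000, 10000, 20000)  # mg/m^3; bands map to HR 5..1
    ),
    coshh = list(
      phrase_bands = list(
        A = c("R10", "R11", "R36", "R36/37", "R36/38", "R36/37/38", "R38",
              "R65", "R66", "R67"),
        B = c("R20", "R21", "R22", "R20/21", "R20/22", "R21/22",
              "R20/21/22", "R40"),
        C = c("R23", "R24", "R25", "R23/24", "R23/25", "R24/25",
              "R23/24/25", "R34", "R35", "R37", "R41", "R43", "R48/20",
              "R48/20/22"),
        D = c("R26", "R27", "R28", "R26/27", "R26/28", "R26/27/28",
              "R48/23", "R48/23/24/25", "R60", "R61", "R62", "R63"),
        E = c("R42", "R45", "R46", "R49", "R68")
      ),
      # exposure potential: rows = quantity band, cols = dustiness/volatility
      ep_table = matrix(c(1, 1, 2,
                          1, 2, 3,
                          2, 3, 4), nrow = 3, byrow = TRUE,
                        dimnames = list(c("small", "medium", "large"),
                                        c("low", "medium", "high"))),
      # control approach: rows = hazard band A-E, cols = EP1-EP4
      ca_matrix = matrix(c(1, 1, 1, 2,
                           1, 1, 2, 3,
                           1, 2, 3, 4,
                           2, 3, 4, 4,
                           4, 4, 4, 4), nrow = 5, byrow = TRUE,
                         dimnames = list(c("A", "B", "C", "D", "E"), NULL))
    ),
    # rows = likelihood 1-5, cols = consequence 1-5
    icmm_matrix = matrix(c(1, 1, 1, 2, 3,
                           1, 2, 2, 3, 4,
                           1, 2, 3, 4, 5,
                           2, 3, 4, 4, 5,
                           3, 4, 5, 5, 5), nrow = 5, byrow = TRUE),
    # rows = severity 1-7, cols = probability 1-6
    romanian_matrix = matrix(c(1, 1, 1, 1, 1, 1,
                               1, 1, 2, 2, 2, 3,
                               2, 2, 2, 3, 3, 3,
                               2, 3, 3, 3, 4, 4,
                               3, 3, 4, 4, 4, 5,
                               4, 4, 5, 5, 6, 6,
                               5, 6, 6, 7, 7, 7), nrow = 7, byrow = TRUE),
    romanian_denominator = 10,
    defaults = list(et = 8, ef = 250, ed = 25,
                    quantity_band = "medium", oel_source = "china",
                    ef_frequency_breaks = c(13, 53, 105, 201),
                    alpha = 0.05)
  )
  cfg$australian <- australian_table()
  class(cfg) <- c("ohra_config", "list")
  cfg
}

#' Australian calculator table
#'
#' Enumerates the shipped nomogram over all 125 rating triples
#' (likelihood, frequency, severity, each 1-5). The combined score is the
#' product of the three ratings; the level rescales it logarithmically onto
#' 1-5 and is rounded to one decimal, so fractional levels are attainable.
#'
#' @return A data frame with columns `likelihood`, `frequency`, `severity`,
#'   `score`, `level`.
#' @export
australian_table <- function() {
  g <- expand.grid(likelihood = 1:5, frequency = 1:5, severity = 1:5)
  g$score <- g$likelihood * g$frequency * g$severity
  g$level <- round_half_up(1 + 4 * log(g$score) / log(125), 1L)
  g
}

#' Load / write a method configuration (JSON)
#'
#' @param path Path to a JSON configuration written by [write_method_config()].
#' @return An `ohra_config` list.
#' @export
load_method_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  cfg <- default_method_config()
  for (nm in intersect(names(raw), setdiff(names(cfg), "australian"))) {
    cfg[[nm]] <- .restore_component(raw[[nm]], cfg[[nm]])
  }
  if (!is.null(raw$australian)) cfg$australian <- as.data.frame(raw$australian)
  class(cfg) <- c("ohra_config", "list")
  cfg
}

.restore_component <- function(new, template) {
  if (is.matrix(template)) {
    m <- as.matrix(new)
    dimnames(m) <- dimnames(template)
    return(m)
  }
  if (is.list(template)) {
    for (nm in intersect(names(new), names(template)))
      template[[nm]] <- .restore_component(new[[nm]], template[[nm]])
    return(template)
  }
  out <- unlist(new)
  if (!is.null(names(template)) && length(out) == length(template))
    names(out) <- names(template)
  out
}

#' @rdname load_method_config
#' @param config An `ohra_config`.
#' @export
write_method_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", matrix = "rowmajor")
  invisible(path)
}
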