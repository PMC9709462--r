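#' Inherent-risk consistency verification
#'
#' A method is judged by whether its risk-ratio ordering across industries
#' (or hazards) reproduces the inherent risk (IR): the catalog-assigned
#' baseline tier of an industry, or the toxicity/exposure-derived rank of a
#' chemical. Two properties are reported per method:
#'
#' * `consistent`: group medians are weakly decreasing along increasing IR
#'   rank (ties allowed within a tier) AND every cross-pair between adjacent
#'   IR tiers separates significantly (Mann-Whitney p < alpha). Both
#'   components are also reported separately, so stricter readings can be
#'   applied.
#' * `distinguishes_all`: every off-diagonal pairwise p-value is below alpha,
#'   i.e. the method statistically separates all groups from one another.
#'
#' @name verification
NULL

.default_ir_catalog <- function() {
  data.frame(
    industry = c("Mining of soil and sand", "Ferrous casting", "Ship repair",
                 "Equipment repair", "Petrol station"),
    tier = c("severe", "severe", "medium", "medium", "low"),
    stringsAsFactors = FALSE)
}

.tier_rank <- c(severe = 1L, medium = 2L, low = 3L)

#' Inherent-risk tier of industries
#'
#' Looks industries up in a catalog of occupational-hazard risk
#' classifications (severe / medium / low, ranks 1-3). The shipped catalog
#' covers the five bundled industries; supply `catalog` for others.
#'
#' @param industries Character vector of industry names.
#' @param catalog Data frame with columns `industry`, `tier`.
#' @return Data frame with `industry`, `tier`, `rank` (1 = highest IR).
#' @export
ir_rank_industries <- function(industries, catalog = .default_ir_catalog()) {
  i <- match(industries, catalog$industry)
  if (anyNA(i))
    ohra_stop("industry not in the inherent-risk catalog: %s",
              paste(industries[is.na(i)], collapse = ", "),
              class = "ohra_lookup_error")
  data.frame(industry = industries, tier = catalog$tier[i],
             rank = unname(.tier_rank[catalog$tier[i]]),
             stringsAsFactors = FALSE)
}

#' Inherent-risk ranking of hazards
#'
#' Ranks chemicals by inherent hazard consequence (RfC ascending: the smaller
#' the reference concentration, the more severe the consequence) with the
#' exposure side used to arbitrate near-ties: two hazards whose RfC values
#' lie within one order of magnitude of each other AND whose concentration-
#' ratio ranges overlap are tied. Hazards without an RfC are excluded with a
#' warning.
#'
#' @param profiles List of profiles (from [get_profile()]).
#' @param cr_summary Data frame with columns `hazard`, `min`, `max` of the
#'   concentration ratio per hazard; optional (without it, ties require equal
#'   RfC).
#' @return Data frame with `hazard`, `rfc`, `rank` (1 = highest IR; tied
#'   hazards share a rank), ordered by rank.
#' @export
ir_rank_hazards <- function(profiles, cr_summary = NULL) {
  rfc <- vapply(profiles, function(p) if (is.null(p$rfc)) NA_real_ else p$rfc,
                numeric(1))
  name <- vapply(profiles, function(p) p$name, character(1))
  if (anyNA(rfc)) {
    warning("excluded from IR ranking (no RfC): ",
            paste(name[is.na(rfc)], collapse = ", "))
    name <- name[!is.na(rfc)]; rfc <- rfc[!is.na(rfc)]
  }
  o <- order(rfc)
  name <- name[o]; rfc <- rfc[o]
  k <- length(name)
  if (!k) return(data.frame(hazard = character(0), rfc = numeric(0),
                            rank = integer(0)))
  tied_with_prev <- logical(k)
  for (i in seq_len(k)[-1]) {
    near <- rfc[i] / rfc[i - 1] <= 10 + 1e-9
    overlap <- TRUE
    if (!is.null(cr_summary)) {
      a <- cr_summary[cr_summary$hazard == name[i - 1], ]
      b <- cr_summary[cr_summary$hazard == name[i], ]
      if (nrow(a) && nrow(b))
        overlap <- a$min[1] <= b$max[1] && b$min[1] <= a$max[1]
    }
    tied_with_prev[i] <- if (rfc[i] == rfc[i - 1]) overlap else near && overlap
  }
  rank <- integer(k)
  rank[1] <- 1L
  for (i in seq_len(k)[-1])
    rank[i] <- if (tied_with_prev[i]) rank[i - 1] else rank[i - 1] + 1L
  data.frame(hazard = name, rfc = rfc, rank = rank, stringsAsFactors = FALSE)
}

#' Consistency check of group medians against inherent risk
#'
#' @param rr_summary Data frame with one row per group: a group key column
#'   (first column) and a `median` column (e.g. from [summarize_rr()]).
#' @param ir_ranks Data frame mapping the same groups to IR `rank` (1 =
#'   highest); first column is the group key.
#' @param pairwise_p Symmetric matrix of pairwise Mann-Whitney p-values with
#'   the group names as dimnames.
#' @param alpha Significance threshold.
#' @return An `ohra_consistency` list: ordered medians, IR rank sequence,
#'   `ordering_ok`, `adjacent_tiers_separated`, `consistent`
#'   (= both), and `distinguishes_all`.
#' @export
check_consistency <- function(rr_summary, ir_ranks, pairwise_p, alpha = 0.05) {
  groups <- as.character(rr_summary[[1]])
  if (!setequal(groups, as.character(ir_ranks[[1]])) ||
      !setequal(groups, rownames(pairwise_p)))
    ohra_stop("group sets of the summary, IR ranks and p-matrix differ",
              class = "ohra_parameter_error")
  rank <- ir_ranks$rank[match(groups, as.character(ir_ranks[[1]]))]
  med <- rr_summary$median[match(groups, as.character(rr_summary[[1]]))]
  o <- order(rank, -med, groups)  # within a tier, order is immaterial
  groups <- groups[o]
  rank <- rank[o]
  med <- med[o]

  # weakly decreasing across tiers: no group in a lower-IR tier may exceed
  # any group in a higher-IR tier; within-tier differences are allowed
  tiers <- sort(unique(rank))
  ordering_ok <- TRUE
  for (t in seq_along(tiers)[-1]) {
    if (max(med[rank == tiers[t]]) > min(med[rank == tiers[t - 1]]) + 1e-12) {
      ordering_ok <- FALSE
      break
    }
  }
  sep <- TRUE
  for (t in seq_along(tiers)[-1]) {
    gi <- groups[rank == tiers[t - 1]]
    gj <- groups[rank == tiers[t]]
    ps <- pairwise_p[gi, gj, drop = FALSE]
    if (anyNA(ps) || any(ps >= alpha)) { sep <- FALSE; break }
  }
  offdiag <- pairwise_p[upper.tri(pairwise_p)]
  structure(list(groups = groups, medians = med, ir_rank = rank,
                 ordering_ok = ordering_ok, adjacent_tiers_separated = sep,
                 consistent = ordering_ok && sep,
                 distinguishes_all = length(offdiag) > 0 && !anyNA(offdiag) &&
                   all(offdiag < alpha),
                 pairwise_p = pairwise_p, alpha = alpha),
            class = "ohra_consistency")
}

#' @export
print.ohra_consistency <- function(x, ...) {
  cat("<ohra_consistency>\n")
  cat("  groups (by IR rank):",
      paste(sprintf("%s[%d]=%.1f", x$groups, x$ir_rank, x$medians),
            collapse = ", "), "\n")
  cat(sprintf("  ordering_ok=%s adjacent_tiers_separated=%s consistent=%s distinguishes_all=%s (alpha=%g)\n",
              x$ordering_ok, x$adjacent_tiers_separated, x$consistent,
              x$distinguishes_all, x$alpha))
  invisible(x)
}

#' Per-method verification against inherent risk
#'
#' Runs [check_consistency()] for every method in an assessment, across
#' industries (IR from the catalog) and across the focal hazards (IR from
#' [ir_rank_hazards()]).
#'
#' @param results An `ohra_results` table.
#' @param registry The `ohra_registry` used for the assessment.
#' @param hazards Hazards to rank by IR; defaults to all RfC-bearing hazards
#'   present in `results`.
#' @param alpha Significance threshold.
#' @param catalog Industry IR catalog (see [ir_rank_industries()]).
#' @return List with `industries` and `hazards`, each a per-method list of
#'   `ohra_consistency` reports, plus the hazard IR table.
#' @export
verify_methods <- function(results, registry, hazards = NULL, alpha = 0.05,
                           catalog = .default_ir_catalog()) {
  if (!nrow(results)) ohra_stop("no assessment results to verify")
  methods <- sort(unique(results$method))

  ind_reports <- list()
  for (m in methods) {
    sub <- results[results$method == m, ]
    groups <- sort(unique(sub$industry))
    if (length(groups) < 2) next
    smry <- summarize_rr(sub, group_by = "industry")
    ir <- ir_rank_industries(smry$industry, catalog)
    mw <- .pairwise_mw(split(sub$rr, sub$industry)[groups])
    ind_reports[[m]] <- check_consistency(smry, ir, mw$p, alpha)
  }

  if (is.null(hazards)) {
    present <- unique(results$hazard)
    has_rfc <- vapply(present, function(h) !is.na(get_profile(registry, h)$rfc),
                      logical(1))
    hazards <- present[has_rfc]
  }
  haz_reports <- list()
  hazard_ir <- NULL
  if (length(hazards) >= 2) {
    sub_all <- results[results$hazard %in% hazards & !is.na(results$cr), ]
    sub_all <- sub_all[!duplicated(sub_all$record_id), ]
    crs <- stats::aggregate(cr ~ hazard, data = sub_all,
                            FUN = function(v) c(min = min(v), max = max(v)))
    cr_summary <- data.frame(hazard = crs$hazard, min = crs$cr[, "min"],
                             max = crs$cr[, "max"])
    hazard_ir <- ir_rank_hazards(lapply(hazards,
                                        function(h) get_profile(registry, h)),
                                 cr_summary)
    for (m in methods) {
      sub <- results[results$method == m & results$hazard %in% hazards, ]
      groups <- sort(unique(sub$hazard))
      if (length(groups) < 2) next
      smry <- summarize_rr(sub, group_by = "hazard")
      ir <- hazard_ir[match(smry$hazard, hazard_ir$hazard),
                      c("hazard", "rank")]
      mw <- .pairwise_mw(split(sub$rr, sub$hazard)[groups])
      haz_reports[[m]] <- check_consistency(smry, ir, mw$p, alpha)
    }
  }
  list(industries = ind_reports, hazards = haz_reports,
       hazard_ir = hazard_ir, alpha = alpha)
}
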