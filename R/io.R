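#' Command layer
#'
#' File-to-file orchestration of the pipeline: `cmd_simulate` writes a seeded
#' synthetic exposure file, `cmd_assess` scores it, `cmd_compare` runs the
#' nonparametric comparisons, `cmd_verify` runs the inherent-risk
#' verification. Every tabular output is plain delimited text with one header
#' line, with a JSON twin for machine use, and every output embeds the method
#' configuration checksum, so a run is reproducible from its artifacts. These
#' functions back the `exec/ohra` command-line script but are ordinary
#' exported functions.
#'
#' @name cli_io
NULL

.cfg_or_default <- function(path) {
  if (is.null(path)) default_method_config() else load_method_config(path)
}

#' Simulate a synthetic exposure file
#'
#' @param out Output CSV path.
#' @param spec Path to a spec CSV ([default_exposure_spec()] layout); `NULL`
#'   uses the bundled design.
#' @param seed Global seed.
#' @return Path of the written file, invisibly; prints a per-industry summary.
#' @export
cmd_simulate <- function(out, spec = NULL, seed = 1L) {
  sp <- if (is.null(spec)) default_exposure_spec() else {
    if (!file.exists(spec)) ohra_stop("spec file not found: %s", spec,
                                      class = "ohra_usage_error")
    utils::read.csv(spec, stringsAsFactors = FALSE)
  }
  records <- generate_exposure(sp, seed = seed)
  write_exposure(records, out)
  tab <- table(records$industry)
  cat(sprintf("wrote %d exposure record(s) to %s\n", nrow(records), out))
  print(tab)
  invisible(out)
}

#' Assess an exposure file with the requested methods
#'
#' @param exposure Path to an exposure CSV.
#' @param out Output CSV path (skip log goes to `*_skipped.csv`).
#' @param registry Path to a registry CSV; `NULL` uses the bundled registry.
#' @param config Path to a method-config JSON; `NULL` uses the defaults.
#' @param methods Subset of the six method names.
#' @param oel_source `"china"` or `"acgih"`.
#' @return The `ohra_results` object, invisibly.
#' @export
cmd_assess <- function(exposure, out, registry = NULL, config = NULL,
                       methods = .methods_all, oel_source = NULL) {
  if (!file.exists(exposure))
    ohra_stop("exposure file not found: %s", exposure, class = "ohra_usage_error")
  reg <- if (is.null(registry)) default_registry() else load_registry(registry)
  cfg <- .cfg_or_default(config)
  records <- read_exposure(exposure, cfg$defaults)
  if (!nrow(records)) ohra_stop("exposure file is empty: %s", exposure,
                                class = "ohra_usage_error")
  res <- assess_all(records, reg, methods = methods, config = cfg,
                    oel_source = oel_source)
  sk <- attr(res, "skipped")
  if (nrow(sk)) {
    for (r in unique(sk$reason))
      message(sprintf("skipped %d (record, method) pair(s): %s",
                      sum(sk$reason == r), r))
  }
  write_results(res, out)
  cat(sprintf("wrote %d assessment(s) to %s (config %s)\n", nrow(res), out,
              substr(attr(res, "checksum"), 1, 8)))
  invisible(res)
}

#' Compare methods on a results file
#'
#' Writes the per-group `median (min-max)` table, the Spearman matrix (CSV)
#' and a JSON twin of the full report.
#'
#' @param results Path to a results CSV from [cmd_assess()].
#' @param out_dir Output directory.
#' @param group_by Grouping column for within-method comparisons.
#' @param alpha Significance threshold.
#' @return The `ohra_comparison` object, invisibly.
#' @export
cmd_compare <- function(results, out_dir, group_by = "industry", alpha = 0.05) {
  if (!file.exists(results))
    ohra_stop("results file not found: %s", results, class = "ohra_usage_error")
  res <- utils::read.csv(results, stringsAsFactors = FALSE)
  if (!nrow(res)) ohra_stop("results file is empty", class = "ohra_usage_error")
  attr(res, "checksum") <- res$config_checksum[1]
  cmp <- compare_methods(res, group_by = group_by, alpha = alpha)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  smry <- summarize_rr(res, group_by = c("method", group_by))
  smry$config_checksum <- res$config_checksum[1]
  utils::write.csv(smry, file.path(out_dir, "rr_summary.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(round(cmp$spearman$rho, 3)),
                   file.path(out_dir, "spearman_rho.csv"))
  jsonlite::write_json(.comparison_json(cmp),
                       file.path(out_dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(cmp)
}

.comparison_json <- function(cmp) {
  list(alpha = cmp$alpha, config_checksum = cmp$checksum,
       omnibus = cmp$omnibus,
       pairwise_methods = list(U = cmp$pairwise_methods$U,
                               p = cmp$pairwise_methods$p),
       spearman = list(rho = cmp$spearman$rho, p = cmp$spearman$p,
                       n = cmp$spearman$n),
       by_group = lapply(cmp$by_group, function(g)
         list(groups = g$groups, medians = g$medians, omnibus = g$omnibus,
              pairwise_p = g$pairwise$p)))
}

#' Verify methods against inherent risk on a results file
#'
#' @param results Path to a results CSV from [cmd_assess()].
#' @param out_dir Output directory (`consistency.json` plus a text table).
#' @param registry Path to a registry CSV; `NULL` uses the bundled registry.
#' @param alpha Significance threshold.
#' @return The verification report list, invisibly.
#' @export
cmd_verify <- function(results, out_dir, registry = NULL, alpha = 0.05) {
  if (!file.exists(results))
    ohra_stop("results file not found: %s", results, class = "ohra_usage_error")
  res <- utils::read.csv(results, stringsAsFactors = FALSE)
  if (!nrow(res)) ohra_stop("results file is empty", class = "ohra_usage_error")
  reg <- if (is.null(registry)) default_registry() else load_registry(registry)
  ver <- verify_methods(res, reg, alpha = alpha)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  flat <- function(reports) lapply(reports, function(r)
    list(groups = r$groups, medians = r$medians, ir_rank = r$ir_rank,
         ordering_ok = r$ordering_ok,
         adjacent_tiers_separated = r$adjacent_tiers_separated,
         consistent = r$consistent, distinguishes_all = r$distinguishes_all))
  jsonlite::write_json(list(alpha = alpha,
                            industries = flat(ver$industries),
                            hazards = flat(ver$hazards),
                            hazard_ir = ver$hazard_ir),
                       file.path(out_dir, "consistency.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  txt <- file.path(out_dir, "consistency.txt")
  con <- file(txt, "w")
  on.exit(close(con))
  for (scope in c("industries", "hazards")) {
    writeLines(sprintf("== %s ==", scope), con)
    for (m in names(ver[[scope]])) {
      r <- ver[[scope]][[m]]
      writeLines(sprintf("%-12s consistent=%-5s distinguishes_all=%-5s  %s",
                         m, r$consistent, r$distinguishes_all,
                         paste(sprintf("%s=%.1f", r$groups, r$medians),
                               collapse = " ")), con)
    }
  }
  invisible(ver)
}
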