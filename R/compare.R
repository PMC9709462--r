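#' Nonparametric comparison of risk-ratio distributions
#'
#' Risk ratios are ordinal-scale quantities taking few distinct values, so
#' all comparisons are rank-based: Kruskal-Wallis across more than two
#' groups, Mann-Whitney between two, Spearman correlation between methods
#' (and against the concentration ratio). Ties are handled with midranks and
#' tie correction throughout; the Mann-Whitney test switches to exact
#' enumeration of group assignments for small samples, where the normal
#' approximation is poorest. Tests are two-sided and p-values are reported
#' raw (an optional Holm adjustment is available but off by default).
#'
#' @name comparison_stats
NULL

#' Kruskal-Wallis test across groups of risk ratios
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return List with `H` (tie-corrected statistic), `df` and `p`
#'   (chi-square approximation).
#' @export
kruskal_wallis_rr <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    ohra_stop("need at least two groups", class = "ohra_parameter_error")
  if (any(vapply(groups, length, integer(1)) == 0))
    ohra_stop("every group must be non-empty", class = "ohra_parameter_error")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (length(unique(x)) == 1)  # kruskal.test is NaN on all-constant data
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}

#' Mann-Whitney U test between two groups of risk ratios
#'
#' U is the midrank statistic for the first sample. When both samples have at
#' most `exact_max` observations the two-sided p-value is computed by exact
#' enumeration of all group assignments of the pooled values (valid under
#' ties, where the usual exact formulae are not); otherwise the tie-corrected
#' normal approximation is used.
#'
#' @param a,b Non-empty numeric vectors.
#' @param exact_max Enumeration threshold per group; default 8.
#' @return List with `U` (for `a`), `p` (two-sided) and `method`.
#' @export
mann_whitney_rr <- function(a, b, exact_max = 8L) {
  if (!length(a) || !length(b))
    ohra_stop("both samples must be non-empty", class = "ohra_parameter_error")
  m <- length(a); n <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (m <= exact_max && n <= exact_max) {
    # Exact permutation null: U over all assignments is symmetric about mn/2.
    pooled <- c(a, b)
    idx <- utils::combn(m + n, m)
    rk <- rank(pooled)
    us <- apply(idx, 2, function(s) sum(rk[s])) - m * (m + 1) / 2
    p <- mean(abs(us - m * n / 2) >= abs(u - m * n / 2) - 1e-9)
    return(list(U = u, p = p, method = "exact enumeration"))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = FALSE))
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # all pooled values tied: no evidence of a shift
  list(U = u, p = p, method = "normal approximation (tie-corrected)")
}

#' Spearman correlation matrix of per-record risk ratios
#'
#' Builds the method-by-method (plus optional concentration-ratio column)
#' Spearman matrix with pairwise-complete observations: a method that cannot
#' score some records (e.g. the EPA engine where the RfC is absent)
#' contributes only its scored records to each pair. Cells with fewer than
#' three complete pairs are reported as `NA`, not zero.
#'
#' @param rr_table Data frame or matrix, one row per record, one column per
#'   method, `NA` where unscored.
#' @param cr Optional per-record concentration-ratio vector appended as a
#'   final `CR` column.
#' @return List of matrices `rho`, `p` and pair counts `n`.
#' @export
spearman_matrix <- function(rr_table, cr = NULL) {
  m <- as.matrix(as.data.frame(rr_table))
  if (!is.null(cr)) m <- cbind(m, CR = cr)
  k <- ncol(m)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
  n <- matrix(0L, k, k, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(k)) for (j in seq_len(i)) {
    ok <- stats::complete.cases(m[, i], m[, j])
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) < 3) next
    if (i == j) {
      rho[i, i] <- 1
      p[i, i] <- 0
      next
    }
    x <- m[ok, i]; y <- m[ok, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next  # rank-degenerate
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(rho = rho, p = p, n = n)
}

#' Full comparison report for an assessment
#'
#' Omnibus Kruskal-Wallis across methods, the pairwise Mann-Whitney matrix
#' between methods, per-method Kruskal-Wallis across a grouping variable
#' (industry by default), pairwise Mann-Whitney matrices between groups
#' within each method, and the Spearman matrix of per-record risk ratios with
#' the concentration ratio appended.
#'
#' @param results An `ohra_results` table.
#' @param group_by Grouping column for the within-method comparisons,
#'   default `"industry"`.
#' @param alpha Significance threshold, default 0.05.
#' @param p_adjust `"none"` (default, raw p-values) or `"holm"`.
#' @return An `ohra_comparison` list.
#' @export
compare_methods <- function(results, group_by = "industry", alpha = 0.05,
                            p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  if (!nrow(results)) ohra_stop("no assessment results to compare")
  if (!(alpha > 0 && alpha < 1))
    ohra_stop("alpha must be in (0, 1)", class = "ohra_parameter_error")
  methods <- sort(unique(results$method))
  by_method <- split(results$rr, results$method)[methods]

  omnibus <- if (length(methods) >= 2) kruskal_wallis_rr(by_method) else NULL
  pairwise <- .pairwise_mw(by_method, p_adjust)

  group_reports <- list()
  for (m in methods) {
    sub <- results[results$method == m, ]
    gs <- split(sub$rr, sub[[group_by]])
    gs <- gs[vapply(gs, length, integer(1)) > 0]
    group_reports[[m]] <- list(
      groups = names(gs),
      medians = vapply(gs, function(v) round_half_up(stats::median(v), 1L),
                       numeric(1)),
      omnibus = if (length(gs) >= 2) kruskal_wallis_rr(gs) else NULL,
      pairwise = .pairwise_mw(gs, p_adjust))
  }

  wide <- .rr_wide(results)
  sp <- spearman_matrix(wide$rr, cr = wide$cr)

  structure(list(methods = methods, omnibus = omnibus,
                 pairwise_methods = pairwise, by_group = group_reports,
                 group_by = group_by, spearman = sp, alpha = alpha,
                 checksum = attr(results, "checksum")),
            class = "ohra_comparison")
}

.pairwise_mw <- function(groups, p_adjust = "none") {
  k <- length(groups)
  nm <- names(groups)
  U <- p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  if (k < 2) return(list(U = U, p = p))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    mw <- mann_whitney_rr(groups[[i]], groups[[j]])
    U[i, j] <- U[j, i] <- mw$U
    p[i, j] <- p[j, i] <- mw$p
  }
  if (p_adjust == "holm") {
    up <- upper.tri(p)
    p[up] <- stats::p.adjust(p[up], method = "holm")
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  list(U = U, p = p)
}

# One row per record, one column per method (NA where unscored), plus the
# per-record concentration ratio.
.rr_wide <- function(results) {
  ids <- sort(unique(results$record_id))
  methods <- sort(unique(results$method))
  rr <- matrix(NA_real_, length(ids), length(methods),
               dimnames = list(NULL, methods))
  ri <- match(results$record_id, ids)
  ci <- match(results$method, methods)
  rr[cbind(ri, ci)] <- results$rr
  cr <- rep(NA_real_, length(ids))
  cr[ri] <- results$cr
  list(rr = as.data.frame(rr), cr = cr, record_id = ids)
}

#' @export
print.ohra_comparison <- function(x, ...) {
  cat("<ohra_comparison>\n")
  if (!is.null(x$omnibus))
    cat(sprintf("Across methods: Kruskal-Wallis H = %.3f, df = %d, p = %.3g\n",
                x$omnibus$H, x$omnibus$df, x$omnibus$p))
  cat("Spearman rho (", paste(colnames(x$spearman$rho), collapse = ", "),
      ")\n", sep = "")
  print(round(x$spearman$rho, 3))
  invisible(x)
}
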