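# Hand-rank oracles, independent of the implementation path.

oracle_kw <- function(groups) {
  x <- unlist(groups)
  r <- rank(x)  # midranks
  n <- length(x)
  h <- 12 / (n * (n + 1)) *
    sum(vapply(split(r, rep(seq_along(groups), lengths(groups))),
               function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2,
               numeric(1)))
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

test_that("Kruskal-Wallis matches a hand-ranked oracle and handles degenerate input", {
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  kw <- kruskal_wallis_rr(g)
  expect_equal(kw$H, oracle_kw(g))
  expect_equal(kw$df, 2L)
  # identical constant groups: no between-group variation
  expect_equal(kruskal_wallis_rr(list(rep(0.4, 5), rep(0.4, 7)))$H, 0)
  # tied data still matches the tie-corrected oracle
  gt <- list(c(0.2, 0.2, 0.4), c(0.4, 0.4, 1), c(0.2, 1, 1))
  expect_equal(kruskal_wallis_rr(gt)$H, oracle_kw(gt))
  expect_error(kruskal_wallis_rr(list(1:3)), class = "ohra_parameter_error")
  expect_error(kruskal_wallis_rr(list(1:3, numeric(0))),
               class = "ohra_parameter_error")
})

test_that("Mann-Whitney exact enumeration reproduces small-sample distributions", {
  # complete separation: U = 0 for the lower sample; two-sided p = 2/6
  mw <- mann_whitney_rr(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3)
  expect_match(mw$method, "exact")
  # exchangeable samples: p = 1
  expect_equal(mann_whitney_rr(c(0.2, 0.4), c(0.2, 0.4))$p, 1)
  # singleton vs singleton, distinct values
  expect_true(mann_whitney_rr(1, 2)$U %in% c(0, 1))
  expect_error(mann_whitney_rr(numeric(0), 1), class = "ohra_parameter_error")
})

test_that("Mann-Whitney U uses midranks under ties", {
  # a = {1, 2, 2}, b = {2, 3}: pairs won 1.5 (one win + two half-ties) -> U
  mw <- mann_whitney_rr(c(1, 2, 2), c(2, 3))
  r <- rank(c(1, 2, 2, 2, 3))
  expect_equal(mw$U, sum(r[1:3]) - 3 * 4 / 2)
})

test_that("two-group Kruskal-Wallis equals the squared Mann-Whitney z on tie-free data", {
  set.seed(7)
  a <- rnorm(12)
  b <- rnorm(15, mean = 0.8)
  m <- length(a); n <- length(b)
  u <- mann_whitney_rr(a, b, exact_max = 0)$U
  z <- (u - m * n / 2) / sqrt(m * n * (m + n + 1) / 12)
  expect_equal(kruskal_wallis_rr(list(a, b))$H, z^2)
})

test_that("Spearman matrix has unit diagonal, symmetry, and matches the rank oracle", {
  set.seed(11)
  tab <- data.frame(m1 = c(5, 2, 4, 1, 3), m2 = c(4, 1, 5, 2, 3),
                    m3 = c(1, 4, 2, 5, 3))
  sp <- spearman_matrix(tab)
  expect_equal(diag(sp$rho), c(m1 = 1, m2 = 1, m3 = 1))
  expect_equal(sp$rho, t(sp$rho))
  expect_equal(sp$rho["m1", "m2"], oracle_spearman(tab$m1, tab$m2))
  expect_equal(sp$rho["m1", "m3"], oracle_spearman(tab$m1, tab$m3))
  # perfectly reversed ranks
  expect_equal(spearman_matrix(data.frame(a = 1:5, b = 5:1))$rho["a", "b"], -1)
  expect_true(all(sp$p >= 0 & sp$p <= 1, na.rm = TRUE))
})

test_that("Spearman cells with under three complete pairs are NA, not zero", {
  tab <- data.frame(a = c(1, 2, 5, NA, NA), b = c(2, 1, NA, NA, NA),
                    c = 1:5)
  sp <- spearman_matrix(tab)
  expect_true(is.na(sp$rho["a", "b"]))
  expect_equal(sp$n["a", "b"], 2L)
  expect_false(is.na(sp$rho["a", "c"]))
})

test_that("all comparison statistics are invariant under monotone transformation", {
  set.seed(3)
  g <- list(runif(9), runif(11), runif(7))
  tr <- function(v) exp(3 * v) + 1
  kw1 <- kruskal_wallis_rr(g); kw2 <- kruskal_wallis_rr(lapply(g, tr))
  expect_equal(kw1$H, kw2$H)
  expect_equal(kw1$p, kw2$p)
  mw1 <- mann_whitney_rr(g[[1]], g[[2]]); mw2 <- mann_whitney_rr(tr(g[[1]]), tr(g[[2]]))
  expect_equal(mw1$U, mw2$U)
  expect_equal(mw1$p, mw2$p)
  tab <- data.frame(x = runif(8), y = runif(8))
  expect_equal(spearman_matrix(tab)$rho,
               spearman_matrix(as.data.frame(lapply(tab, tr)))$rho)
})

test_that("comparison outputs are invariant to record order", {
  set.seed(5)
  tab <- data.frame(x = runif(10), y = runif(10))
  perm <- sample(10)
  expect_equal(spearman_matrix(tab)$rho, spearman_matrix(tab[perm, ])$rho)
})

test_that("the full comparison report assembles omnibus, pairwise and correlation parts", {
  res <- fixture_results()
  cmp <- compare_methods(res)
  expect_s3_class(cmp, "ohra_comparison")
  expect_lt(cmp$omnibus$p, 0.05)  # six methods genuinely differ on this design
  rho <- cmp$spearman$rho
  expect_equal(rho, t(rho))
  expect_true(all(abs(diag(rho)[!is.na(diag(rho))] - 1) < 1e-12))
  expect_true("CR" %in% colnames(rho))
  # EPA column restricted to RfC-scorable records: pairwise-complete n is smaller
  expect_lt(cmp$spearman$n["EPA", "COSHH"], cmp$spearman$n["ICMM", "COSHH"])
})
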