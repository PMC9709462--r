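test_that("industry inherent-risk catalog lookups", {
  ir <- ir_rank_industries(c("Mining of soil and sand", "Petrol station",
                             "Ship repair"))
  expect_equal(ir$tier, c("severe", "low", "medium"))
  expect_equal(ir$rank, c(1L, 3L, 2L))
  expect_error(ir_rank_industries("Unknown works"), class = "ohra_lookup_error")
})

test_that("hazard inherent risk ranks by RfC with CR-based near-tie arbitration", {
  reg <- fixture_registry()
  focal <- c("Manganese and inorganic compounds", "Benzene", "Xylene",
             "Ethyl acetate")
  profiles <- lapply(focal, function(h) get_profile(reg, h))
  cr_summary <- data.frame(
    hazard = focal,
    min = c(0.06, 0.01, 0.019, 0), max = c(0.62, 0.05, 0.66, 0.0004))
  ir <- ir_rank_hazards(profiles, cr_summary)
  expect_equal(ir$hazard[1], "Manganese and inorganic compounds")
  expect_equal(ir$hazard[4], "Ethyl acetate")
  # benzene and xylene: RfC within one order of magnitude, overlapping CR -> tied
  expect_equal(ir$rank[ir$hazard == "Benzene"], ir$rank[ir$hazard == "Xylene"])
  expect_lt(ir$rank[ir$hazard == "Manganese and inorganic compounds"],
            ir$rank[ir$hazard == "Benzene"])
  expect_lt(ir$rank[ir$hazard == "Benzene"],
            ir$rank[ir$hazard == "Ethyl acetate"])

  # single hazard is trivially rank 1
  expect_equal(ir_rank_hazards(profiles[1])$rank, 1L)

  # equal RfC with overlapping CR ranges ties; hazards without RfC are dropped
  p1 <- list(name = "A", rfc = 10); p2 <- list(name = "B", rfc = 10)
  cs <- data.frame(hazard = c("A", "B"), min = c(0.1, 0.2), max = c(0.5, 0.6))
  expect_equal(ir_rank_hazards(list(p1, p2), cs)$rank, c(1L, 1L))
  expect_warning(ir <- ir_rank_hazards(list(p1, list(name = "C", rfc = NA))),
                 "no RfC")
  expect_equal(ir$hazard, "A")
})

test_that("consistency flags combine median ordering with adjacent-tier separation", {
  groups <- c("g1", "g2", "g3", "g4", "g5")
  smry <- data.frame(group = groups, median = c(0.8, 0.8, 0.4, 0.4, 0.4))
  ir <- data.frame(group = groups, rank = c(1L, 1L, 2L, 2L, 3L))
  pmat <- matrix(0.001, 5, 5, dimnames = list(groups, groups))
  diag(pmat) <- NA
  rep <- check_consistency(smry, ir, pmat, alpha = 0.05)
  expect_true(rep$ordering_ok)
  expect_true(rep$adjacent_tiers_separated)
  expect_true(rep$consistent)
  expect_true(rep$distinguishes_all)

  # all groups identical: nothing separates, nothing distinguishes
  pmat1 <- matrix(1, 5, 5, dimnames = list(groups, groups)); diag(pmat1) <- NA
  smry1 <- data.frame(group = groups, median = rep(0.4, 5))
  rep1 <- check_consistency(smry1, ir, pmat1, alpha = 0.05)
  expect_true(rep1$ordering_ok)         # weak ordering tolerates ties
  expect_false(rep1$adjacent_tiers_separated)
  expect_false(rep1$consistent)
  expect_false(rep1$distinguishes_all)

  # median ordering violated
  smry2 <- data.frame(group = groups, median = c(0.2, 0.8, 0.4, 0.4, 0.6))
  expect_false(check_consistency(smry2, ir, pmat, 0.05)$consistent)

  expect_error(check_consistency(smry[1:3, ], ir, pmat, 0.05),
               class = "ohra_parameter_error")
})

test_that("consistency is invariant to input group order and monotone in alpha", {
  groups <- c("a", "b", "c")
  smry <- data.frame(group = groups, median = c(0.9, 0.5, 0.1))
  ir <- data.frame(group = groups, rank = 1:3)
  pmat <- matrix(c(NA, 0.03, 0.01, 0.03, NA, 0.04, 0.01, 0.04, NA), 3, 3,
                 dimnames = list(groups, groups))
  r1 <- check_consistency(smry, ir, pmat, 0.05)
  perm <- c(3, 1, 2)
  r2 <- check_consistency(smry[perm, ], ir[perm, ], pmat[perm, perm], 0.05)
  expect_equal(r1$consistent, r2$consistent)
  expect_equal(r1$groups, r2$groups)
  expect_equal(r1$medians, r2$medians)
  # distinguishes_all at alpha implies it at any larger alpha
  expect_true(r1$distinguishes_all)
  expect_false(check_consistency(smry, ir, pmat, 0.02)$distinguishes_all)
  expect_true(check_consistency(smry, ir, pmat, 0.2)$distinguishes_all)
})

test_that("constructed groups with disjoint supports pass both flags end to end", {
  # three industries whose rr distributions do not overlap
  df <- data.frame(
    industry = rep(c("hi", "mid", "lo"), each = 12),
    rr = c(runif(12, 0.8, 1.0), runif(12, 0.4, 0.6), runif(12, 0.05, 0.2)))
  df$rr_display <- round(df$rr, 1)
  smry <- summarize_rr(df, "industry")
  ir <- data.frame(industry = c("hi", "mid", "lo"), rank = 1:3)
  groups <- sort(unique(df$industry))
  p <- matrix(NA_real_, 3, 3, dimnames = list(groups, groups))
  for (i in 1:2) for (j in (i + 1):3) {
    pv <- mann_whitney_rr(df$rr[df$industry == groups[i]],
                          df$rr[df$industry == groups[j]])$p
    p[i, j] <- p[j, i] <- pv
  }
  rep <- check_consistency(smry, ir, p, alpha = 0.05)
  expect_true(rep$consistent)
  expect_true(rep$distinguishes_all)
})

test_that("full verification report covers every method and ranks manganese first", {
  res <- fixture_results()
  reg <- fixture_registry()
  ver <- verify_methods(res, reg)
  expect_setequal(names(ver$industries),
                  c("COSHH", "Singaporean", "ICMM", "Australian", "Romanian", "EPA"))
  expect_equal(ver$hazard_ir$hazard[1], "Manganese and inorganic compounds")
  for (m in names(ver$industries)) {
    r <- ver$industries[[m]]
    expect_type(r$consistent, "logical")
    expect_type(r$distinguishes_all, "logical")
    if (isTRUE(r$distinguishes_all)) {
      off <- r$pairwise_p[upper.tri(r$pairwise_p)]
      expect_true(all(off < ver$alpha))
    }
  }
})
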