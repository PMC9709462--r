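# Independent brute-force oracles for band and matrix lookups.

oracle_band <- function(x, breaks) {
  # scan the (left-closed, right-open) bands one by one
  for (k in seq_along(breaks)) if (x < breaks[k]) return(k)
  length(breaks) + 1L
}

test_that("EPA hazard quotient is the EC/RfC ratio", {
  expect_equal(epa_hq(228.31, 100), 2.2831)
  expect_equal(epa_hq(50, 50), 1)
  expect_error(epa_hq(1, 0), class = "ohra_parameter_error")
  expect_error(epa_hq(1, -3), class = "ohra_parameter_error")
})

test_that("EPA level banding matches the interval oracle over a dense sweep", {
  bands <- default_method_config()$hq_bands
  hq <- c(0, 0.05, 0.0999, 0.1, 0.3, 0.4999, 0.5, 0.75, 0.9999, 1, 1.5,
          1.9999, 2, 2.5, 100, seq(0.01, 5, by = 0.07))
  expect_equal(epa_level(hq),
               vapply(hq, oracle_band, integer(1), breaks = bands))
  expect_equal(epa_level(0.05), 1L)
  expect_equal(epa_level(2.5), 5L)
  expect_equal(epa_level(0.5), 3L)  # boundary is left-closed
  expect_error(epa_level(-0.1), class = "ohra_parameter_error")
})

test_that("EPA level is monotone nondecreasing in airborne concentration", {
  ca <- sort(runif(50, 0, 40))
  lv <- epa_level(epa_hq(compute_ec(ca), rfc = 100))
  expect_true(all(diff(lv) >= 0))
})

test_that("hazard rating honours the override, carcinogenicity and acute-toxicity rules", {
  reg <- fixture_registry()
  expect_equal(singapore_hr(get_profile(reg, "Manganese and inorganic compounds")), 4L)
  expect_equal(singapore_hr(get_profile(reg, "Benzene")), 5L)       # IARC-1
  expect_equal(singapore_hr(get_profile(reg, "Ethyl acetate")), 1L) # LD50 >= 5000
  expect_equal(singapore_hr(get_profile(reg, "Xylene")), 2L)        # LD50 band
  expect_error(singapore_hr(list(name = "void", carcinogenicity = "none")),
               class = "ohra_missing_parameter")
})

test_that("exposure rating bands match the interval oracle", {
  bands <- default_method_config()$er_bands
  cr <- c(0, 0.05, 0.1, 0.21, 0.5, 0.75, 1, 1.5, 2, 2.5, 10)
  expect_equal(singapore_er(cr),
               vapply(cr, oracle_band, integer(1), breaks = bands))
  expect_equal(singapore_er(0.05), 1L)
  expect_equal(singapore_er(0.21), 2L)
  expect_equal(singapore_er(2.5), 5L)
  expect_error(singapore_er(-1), class = "ohra_parameter_error")
})

test_that("Singaporean risk is the rounded-up geometric mean, symmetric and monotone", {
  expect_equal(singapore_risk(4, 2), 3L)  # sqrt(8) = 2.83, rounds up
  expect_equal(singapore_risk(5, 5), 5L)
  expect_equal(singapore_risk(1, 1), 1L)
  for (hr in 1:5) for (er in 1:5) {
    expect_equal(singapore_risk(hr, er), as.integer(ceiling(sqrt(hr * er))))
    expect_equal(singapore_risk(hr, er), singapore_risk(er, hr))
    if (er < 5) expect_lte(singapore_risk(hr, er), singapore_risk(hr, er + 1))
  }
  expect_error(singapore_risk(0, 3), class = "ohra_parameter_error")
  expect_error(singapore_risk(3, 6), class = "ohra_parameter_error")
})

test_that("COSHH banding reproduces the configured cases and rejects unknown phrases", {
  reg <- fixture_registry()
  b <- coshh_assess(get_profile(reg, "Benzene"))
  expect_equal(b$band, "E")
  expect_equal(b$cs, "CS4")
  expect_equal(b$level, 5L)
  expect_equal(coshh_assess(get_profile(reg, "Manganese and inorganic compounds"))$level, 2L)
  expect_equal(coshh_assess(get_profile(reg, "Xylene"))$level, 2L)
  expect_error(coshh_hazard_band("R999"), "R999", class = "ohra_unknown_phrase")
  expect_error(coshh_hazard_band(character(0)), class = "ohra_missing_parameter")
})

test_that("COSHH levels are confined to 2-5 over the whole configuration grid", {
  cfg <- default_method_config()
  for (band in c("A", "B", "C", "D", "E")) for (ep in 1:4) {
    lv <- coshh_cs_to_level(paste0("CS", cfg$coshh$ca_matrix[band, ep]))
    expect_true(lv %in% 2:5)
  }
})

test_that("ICMM engine equals a brute-force lookup over all 75 rating cells", {
  grid <- default_method_config()$icmm_matrix
  for (cons in 1:5) for (prob in 1:5) for (wt in 1:3) {
    shifted <- min(5, max(1, prob + wt - 2))
    expect_equal(icmm_assess(cons, prob, wt), as.integer(grid[shifted, cons]))
  }
  expect_equal(icmm_assess(5, 5), 5L)
  expect_equal(icmm_assess(1, 1), 1L)
  expect_error(icmm_assess(6, 1), class = "ohra_parameter_error")
  expect_error(icmm_assess(1, 1, 4), class = "ohra_parameter_error")
})

test_that("Australian calculator equals the closed-form rescaling over all 125 cells", {
  for (l in 1:5) for (f in 1:5) for (s in 1:5) {
    want <- floor((1 + 4 * log(l * f * s) / log(125)) * 10 + 0.5 + 1e-9) / 10
    expect_equal(australian_assess(l, f, s), want)
  }
  expect_equal(australian_assess(5, 5, 5), 5)
  expect_equal(australian_assess(1, 1, 1), 1)
  expect_error(australian_assess(0, 1, 1), class = "ohra_parameter_error")
})

test_that("Romanian matrix is a valid monotone 7x6 grid with the expected corners", {
  grid <- default_method_config()$romanian_matrix
  expect_equal(romanian_assess(7, 6), 7L)
  expect_equal(romanian_assess(1, 1), 1L)
  for (s in 1:7) for (p in 1:6) {
    expect_equal(romanian_assess(s, p), as.integer(grid[s, p]))
    expect_true(romanian_assess(s, p) %in% 1:7)
    if (s < 7) expect_lte(romanian_assess(s, p), romanian_assess(s + 1, p))
    if (p < 6) expect_lte(romanian_assess(s, p), romanian_assess(s, p + 1))
  }
  expect_error(romanian_assess(8, 1), class = "ohra_parameter_error")
})

test_that("assess_all skips unscoreable pairs with a reason and is deterministic", {
  reg <- load_registry(write_tiny_registry())
  rec <- tiny_records()

  # dust without RfC under the EPA engine alone: no results, a logged reason
  res <- suppressWarnings(assess_all(rec[2, ], reg, methods = "EPA"))
  expect_equal(nrow(res), 0L)
  expect_match(attr(res, "skipped")$reason, "RfC")

  # one fully-parameterized chemical under all six methods: six results
  reg2 <- fixture_registry()
  rec2 <- suppressMessages(validate_exposure(data.frame(
    industry = "Ship repair", location = "Electrowelding",
    hazard = "Manganese and inorganic compounds", ca_mg_m3 = 0.2)))
  res2 <- assess_all(rec2, reg2)
  expect_equal(nrow(res2), 6L)
  expect_setequal(res2$method, c("EPA", "COSHH", "Singaporean", "ICMM",
                                 "Australian", "Romanian"))
  res3 <- assess_all(rec2, reg2)
  expect_identical(as.data.frame(res2), as.data.frame(res3))

  # every level lies on its method's scale
  for (i in seq_len(nrow(res2))) {
    sc <- method_scale(res2$method[i])
    if (sc$allows_fractional) {
      expect_gte(res2$level[i], min(sc$levels))
      expect_lte(res2$level[i], max(sc$levels))
    } else {
      expect_true(res2$level[i] %in% sc$levels)
    }
  }

  # empty input warns and returns an empty result
  expect_warning(res0 <- assess_all(rec[0, ], reg), "no exposure records")
  expect_equal(nrow(res0), 0L)
})

test_that("closed-form range sweeps: manganese always top level, ethyl acetate always bottom", {
  # endpoints and interior of the bundled concentration ranges, full-shift pattern
  mn <- c(0.003, 0.01, 0.1, 1, 10, 28.98)
  expect_true(all(epa_level(epa_hq(compute_ec(mn), rfc = 0.05)) == 5L))
  ea <- c(0.0003, 0.001, 0.01, 0.031)
  hq <- epa_hq(compute_ec(ea), rfc = 3500)
  expect_true(all(hq <= 0.003))
  expect_true(all(epa_level(hq) == 1L))
})
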