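test_that("isotope ratio follows the 13C/12C weighting of the three peaks", {
  expect_equal(isotope_ratio(c(100, 0, 0), 2), 0)
  # acetate reduces to (AI1 + 2 AI2) / (2 AI0 + AI1)
  ai <- c(80, 15, 5)
  expect_equal(isotope_ratio(ai, 2), (ai[2] + 2 * ai[3]) / (2 * ai[1] + ai[2]))
  # butyrate hand example: numerator 2*50, denominator 4*100 + 2*50
  expect_equal(isotope_ratio(c(100, 0, 50), 4), 100 / 500)
  expect_error(isotope_ratio(c(0, 0, 0), 2), class = "sr_undefined_ratio")
  expect_error(isotope_ratio(c(0, 0, 100), 2), class = "sr_undefined_ratio")
})

test_that("isotope ratio is invariant to uniform intensity scaling", {
  set.seed(3)
  for (i in 1:20) {
    ai <- runif(3, 0, 1000)
    n <- sample(2:4, 1)
    for (k in c(1e-6, 0.5, 7, 1e6))
      expect_equal(isotope_ratio(k * ai, n), isotope_ratio(ai, n))
  }
})

test_that("complete binomial spectra give IR = p/(1-p) exactly; truncation bias matches the oracle", {
  # oracle: full-binomial intensities, atom-counting identity
  for (n in 2:4) {
    for (p in c(0.0107, 0.02, 0.05, 0.1)) {
      full <- binomial_isotopologs(p, n, truncate = FALSE)
      expect_equal(isotope_ratio(full, n), p / (1 - p), tolerance = 1e-12)
    }
  }
  # truncated spectra: exact for 2 carbons, biased low for 3-4 carbons by an
  # amount the full-binomial oracle quantifies; negligible in the measured
  # regime (natural abundance and the ~5% label, p <= 0.012)
  for (p in c(0.0107, 0.0107 * 1.05, 0.012)) {
    for (n in 2:4) {
      tr <- binomial_isotopologs(p, n, truncate = TRUE)
      rel <- abs(isotope_ratio(tr, n) / (p / (1 - p)) - 1)
      expect_lt(rel, 1e-3)
    }
  }
  expect_equal(isotope_ratio(binomial_isotopologs(0.1, 2), 2), 0.1 / 0.9)
  # the bias grows with p and n and is always toward depletion
  bias <- function(p, n) isotope_ratio(binomial_isotopologs(p, n), n) - p / (1 - p)
  expect_lt(bias(0.1, 4), bias(0.02, 4))
  expect_lt(bias(0.1, 4), 0)
})

test_that("delta notation scales the ratio difference per mil", {
  expect_equal(delta_enrichment(0.0110, 0.0100), 100)
  expect_equal(delta_enrichment(0.0100, 0.0110), -1000 / 11)
  expect_equal(delta_enrichment(0.0107, 0.0107), 0)
  expect_error(delta_enrichment(0.01, 0), class = "sr_invalid_input")
})

test_that("standards pair by treatment cell and analyte", {
  sim <- zero_noise_sim()
  paired <- pair_with_standard(sim$isotopologs)
  # 2 labeled bottles x 6 substrate-dilution cells x 3 analytes
  expect_identical(nrow(paired), 36L)
  expect_false(any(paired$is_standard))
  # label strength recovered exactly without noise
  p_lab <- sim$params$label$p_labeled
  p_nat <- sim$params$label$p_natural
  ions <- vfa_ions()
  for (an in ions$analyte) {
    n <- ions$n_carbons[ions$analyte == an]
    want <- delta_enrichment(
      isotope_ratio(binomial_isotopologs(p_lab, n), n),
      isotope_ratio(binomial_isotopologs(p_nat, n), n))
    expect_equal(paired$delta_permil[paired$analyte == an], rep(want, 12))
  }
})

test_that("samples identical to their standard have delta zero", {
  sp <- data.frame(substrate = "high_forage", dilution_level = "low",
                   analyte = "acetate",
                   ai_m0 = c(100, 200), ai_m1 = c(2, 4), ai_m2 = c(0.1, 0.2),
                   is_standard = c(FALSE, TRUE))
  out <- pair_with_standard(sp)
  expect_equal(out$delta_permil, 0)
})

test_that("missing or duplicated standards are pairing errors naming the cell", {
  sp <- data.frame(substrate = "high_forage", dilution_level = "low",
                   analyte = "acetate",
                   ai_m0 = c(100, 100), ai_m1 = c(2, 2), ai_m2 = c(0, 0),
                   is_standard = c(FALSE, FALSE))
  err <- tryCatch(pair_with_standard(sp), error = function(e) e)
  expect_s3_class(err, "sr_pairing_error")
  expect_match(conditionMessage(err), "high_forage/low/acetate")
  sp$is_standard <- c(TRUE, TRUE)
  expect_error(pair_with_standard(sp), class = "sr_pairing_error")
})

test_that("ion assignments carry the study's m/z windows", {
  ions <- vfa_ions()
  expect_identical(ions$base_mz, c(117L, 131L, 145L))
  expect_identical(ions$n_carbons, c(2L, 3L, 4L))
})
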