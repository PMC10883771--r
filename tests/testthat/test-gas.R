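test_that("total pressure adds one atmosphere to the gauge reading", {
  expect_equal(total_pressure(0), 101325)
  expect_equal(total_pressure(50000), 151325)
  expect_equal(total_pressure(-101325), 0)
  expect_error(total_pressure(-101326), class = "sr_invalid_input")
})

test_that("headspace moles follow the ideal gas law", {
  # independent closed-form recomputation at 1 atm, 60 mL, 39 degC
  n_ref <- 101325 * 60e-6 / (8.314 * (39 + 273.15))
  expect_equal(headspace_moles(0), n_ref)
  expect_equal(n_ref, 2.342e-3, tolerance = 1e-3)
  # linear in absolute pressure, zero at zero volume
  expect_equal(headspace_moles(101325), 2 * headspace_moles(0))
  expect_equal(headspace_moles(0, volume_ml = 0), 0)
  expect_error(headspace_moles(0, temperature_c = -300), class = "sr_invalid_input")
})

test_that("residual air fraction is the O2 fraction over atmospheric O2", {
  expect_equal(residual_air_fraction(0), 0)
  expect_equal(residual_air_fraction(0.02095), 0.10)
  expect_equal(residual_air_fraction(0.2095), 1.0)
  expect_error(residual_air_fraction(0.21), class = "sr_invalid_input")
  expect_warning(f <- residual_air_fraction(NA), "assuming no residual air")
  expect_equal(f, 0)
})

test_that("air correction renormalises over the non-air portion", {
  expect_equal(correct_species_fraction(0.09, 0.10), 0.10)
  expect_equal(correct_species_fraction(0.37, 0), 0.37)
  expect_error(correct_species_fraction(0.5, 1.0),
               class = "sr_correction_impossible")
  expect_warning(capped <- correct_species_fraction(0.95, 0.5), "capped")
  expect_equal(capped, 1)
})

test_that("air correction exactly inverts a simulated air dilution", {
  set.seed(42)
  for (i in 1:50) {
    true_frac <- runif(3, 0, 0.3)
    f_air <- runif(1, 0, 0.9)
    measured <- true_frac * (1 - f_air)
    o2 <- 0.2095 * f_air
    est_air <- residual_air_fraction(o2)
    expect_equal(correct_species_fraction(measured, est_air), true_frac,
                 tolerance = 1e-14)
  }
})

test_that("species amounts and H2 partial pressure follow the corrected fractions", {
  r <- data.frame(gauge_pressure_pa = 0, frac_ch4 = 0.10, frac_h2 = 0.05,
                  frac_o2 = 0)
  res <- gas_amounts(r)
  expect_equal(res$umol_ch4, 0.10 * headspace_moles(0) * 1e6)
  expect_equal(res$umol_ch4, 234.2, tolerance = 1e-3)
  expect_equal(res$ph2_atm, 0.05)
  expect_equal(res$air_fraction, 0)
  zero <- gas_amounts(data.frame(gauge_pressure_pa = 0, frac_ch4 = 0,
                                 frac_h2 = 0, frac_o2 = 0))
  expect_equal(zero$umol_ch4, 0)
  expect_equal(zero$umol_h2, 0)
  expect_equal(zero$ph2_atm, 0)
  # sum of species amounts cannot exceed total moles
  expect_lte(res$umol_ch4 + res$umol_h2, res$total_mol * 1e6)
})

test_that("H2 partial pressure is monotone in H2 fraction and total pressure", {
  base <- function(frac, gauge) gas_amounts(
    data.frame(gauge_pressure_pa = gauge, frac_ch4 = 0, frac_h2 = frac,
               frac_o2 = 0))$ph2_atm
  fr <- seq(0.01, 0.3, length.out = 8)
  expect_true(all(diff(vapply(fr, base, numeric(1), gauge = 5e4)) > 0))
  gs <- seq(0, 2e5, length.out = 8)
  expect_true(all(diff(vapply(gs, function(g) base(0.1, g), numeric(1))) > 0))
})

test_that("a missing O2 column falls back to no residual air with a warning", {
  r <- data.frame(gauge_pressure_pa = 0, frac_ch4 = 0.1, frac_h2 = 0.02)
  expect_warning(res <- gas_amounts(r), "assuming no residual air")
  expect_equal(res$air_fraction, 0)
})
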