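test_that("the generator is deterministic in the seed and covers the full grid", {
  a <- simulate_experiment(seed = 4)
  b <- simulate_experiment(seed = 4)
  expect_identical(a$gas, b$gas)
  expect_identical(a$metabolites, b$metabolites)
  expect_identical(a$qpcr, b$qpcr)
  expect_identical(a$isotopologs, b$isotopologs)
  expect_identical(nrow(a$design), 288L)
  expect_true(validate_design(a$design)$complete)
  # two seeds: same structure, different noise, identical deterministic cols
  c <- simulate_experiment(seed = 5)
  expect_identical(dim(a$gas), dim(c$gas))
  expect_false(identical(a$gas$gauge_pressure_pa, c$gas$gauge_pressure_pa))
  expect_identical(a$ground_truth$bacteria, c$ground_truth$bacteria)
})

test_that("archaea wash out monotonically under high concentrate but grow with high forage", {
  gt <- zero_noise_sim()$ground_truth
  for (lev in c("low", "mid", "high")) {
    for (sq in 1:3) {
      hc <- gt[gt$substrate == "high_concentrate" & gt$incubation == 1 &
                 gt$dilution_level == lev & gt$sequence == sq, ]
      hc <- hc[order(hc$transfer), ]
      expect_true(all(diff(hc$archaea) < 0))
      hf <- gt[gt$substrate == "high_forage" & gt$incubation == 1 &
                 gt$dilution_level == lev & gt$sequence == sq, ]
      expect_gt(hf$archaea[hf$transfer == 8], hc$archaea[hc$transfer == 8])
    }
  }
})

test_that("the default scenario shows the concentrate H2/formate signature", {
  gt <- zero_noise_sim()$ground_truth
  h2 <- tapply(gt$umol_h2, gt$substrate, sum)
  expect_gte(h2[["high_concentrate"]], 10 * h2[["high_forage"]])
  fo <- tapply(gt$formate, gt$substrate, sum)
  expect_gt(fo[["high_concentrate"]], fo[["high_forage"]])
  # hydrogenotrophic stoichiometry: CH4 never exceeds a quarter of gross H2
  expect_true(all(gt$umol_ch4 <= gt$h2_produced / 4 + 1e-9))
})

test_that("zero yields produce nothing and leave pH at its intercept", {
  p <- noise_free_params()
  for (s in names(p$substrates)) p$substrates[[s]]$yields[] <- 0
  sim <- simulate_experiment(p, seed = 2, n_sequences = 1, n_incubations = 1,
                             n_transfers = 8)
  gt <- sim$ground_truth
  expect_true(all(gt$umol_ch4 == 0 & gt$umol_h2 == 0 & gt$umol_co2 == 0))
  expect_true(all(abs(gt$gauge_pa) < 1e-6))
  int <- vapply(gt$substrate, function(s) p$substrates[[s]]$ph_intercept,
                numeric(1))
  # carryover of inoculum VFA still depresses pH slightly; production adds none
  expect_true(all(abs(gt$acetate) == 0))
  expect_true(all(gt$ph <= unname(int)))
})

test_that("parameter validation rejects impossible settings", {
  expect_error(simulation_params(noise = list(sigma_conc = -1, sigma_copies = 0,
                                              sigma_pressure = 0, air_max = 0)),
               class = "sr_invalid_input")
  expect_error(simulation_params(noise = list(sigma_conc = 0, sigma_copies = 0,
                                              sigma_pressure = 0, air_max = 1)),
               class = "sr_invalid_input")
})
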