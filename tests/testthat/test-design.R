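test_that("average dilution rate matches the volume/interval arithmetic", {
  expect_equal(average_dilution_rate(1, 39), 40 / 72)
  expect_equal(average_dilution_rate(2, 38), 40 / 144)
  expect_equal(average_dilution_rate(4, 36), 40 / 288)
  # whole-volume transfer degenerates to 1/interval
  expect_equal(average_dilution_rate(40, 0), 1 / 72)
  # the study's presentation values after half-to-even 2-decimal rounding
  expect_identical(round(average_dilution_rate(c(1, 2, 4), c(39, 38, 36)), 2),
                   c(0.56, 0.28, 0.14))
})

test_that("dilution rate is homogeneous of degree -1 in the interval and decreasing in inoculum volume", {
  for (v in c(1, 2, 4)) {
    d1 <- average_dilution_rate(v, 40 - v, interval = 72)
    d2 <- average_dilution_rate(v, 40 - v, interval = 144)
    expect_equal(d2, d1 / 2)
  }
  vols <- seq(1, 39, by = 2)
  d <- average_dilution_rate(vols, 40 - vols)
  expect_true(all(diff(d) < 0))
})

test_that("invalid bottle geometry is rejected", {
  expect_error(average_dilution_rate(0, 40), class = "sr_invalid_input")
  expect_error(average_dilution_rate(-1, 41), class = "sr_invalid_input")
  expect_error(average_dilution_rate(1, 39, interval = 0), class = "sr_invalid_input")
  expect_error(bottle_spec(0, 40), class = "sr_invalid_input")
  expect_error(bottle_spec(1, -1), class = "sr_invalid_input")
  s <- bottle_spec(2, 38)
  expect_equal(s$total_volume, 40)
  expect_equal(average_dilution_rate(s), 40 / 144)
})

test_that("dilution_levels recomputes rates from volumes", {
  lv <- dilution_levels()
  expect_identical(lv$dilution_level, c("low", "mid", "high"))
  expect_equal(round(lv$dilution_rate_h, 2), c(0.14, 0.28, 0.56))
  expect_equal(lv$dilution_rate_d, lv$dilution_rate_h * 24)
})

test_that("the full factorial grid has 288 rows and validates as complete", {
  g <- design_grid()
  expect_identical(nrow(g), 2L * 3L * 3L * 2L * 8L)
  rep <- validate_design(g)
  expect_true(rep$complete)
  expect_identical(nrow(rep$missing), 0L)
})

test_that("validate_design reports gaps and rejects duplicate keys", {
  g <- design_grid()
  gap <- g[!(g$incubation == 1 & g$sequence == 2 &
               g$substrate == "high_forage" &
               g$dilution_level == "mid" & g$transfer == 5), ]
  rep <- validate_design(gap)
  expect_false(rep$complete)
  expect_identical(nrow(rep$missing), 1L)
  expect_identical(rep$missing$transfer, 5L)
  dup <- rbind(g, g[17, ])
  expect_error(validate_design(dup), class = "sr_integrity_error")
})

test_that("reads per sample divides totals over the 56 sequenced samples", {
  expect_identical(round(reads_per_sample(16317083)), 291376)
  expect_identical(round(reads_per_sample(7700832)), 137515)
  expect_error(reads_per_sample(100, 0), class = "sr_invalid_input")
})
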