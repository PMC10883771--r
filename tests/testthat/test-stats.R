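test_that("linear contrast coefficients reproduce the unequal-spacing vectors", {
  # inoculum volumes (low, mid, high dilution) -> the study's coefficients
  expect_identical(linear_contrast_coefficients(c(4, 2, 1)), c(5L, -1L, -4L))
  expect_identical(linear_contrast_coefficients(c(1, 2, 3)), c(-1L, 0L, 1L))
  # the same treatments on the h^-1 rate scale reverse the pattern
  expect_identical(linear_contrast_coefficients(c(5 / 36, 10 / 36, 20 / 36)),
                   c(-4L, -1L, 5L))
  expect_error(linear_contrast_coefficients(c(2, 2, 2)),
               class = "sr_degenerate_contrast")
})

test_that("contrast coefficients sum to zero and are affine-invariant up to scale", {
  set.seed(5)
  for (i in 1:20) {
    lv <- sort(sample(1:40, 3))
    v <- linear_contrast_coefficients(lv)
    expect_identical(sum(v), 0L)
    a <- sample(c(-3, -1, 2, 5), 1)
    b <- sample(-10:10, 1)
    v2 <- linear_contrast_coefficients(a * lv + b)
    expect_true(identical(v2, v * sign(a)) || identical(v2, as.integer(v * sign(a))))
  }
})

test_that("the outlier rule flags beyond the 99.9% central normal region", {
  expect_identical(sum(flag_outliers(rep(0, 50))$report$flagged), 0L)
  r <- c(rnorm(20, 0, 0.5), 3.5, 3.0)
  rep <- flag_outliers(r)
  expect_equal(rep$threshold, qnorm(0.9995))
  expect_identical(which(rep$report$flagged), 21L)
  # t reference is wider than the normal one
  rep_t <- flag_outliers(r, distribution = "t", df = 10)
  expect_gt(rep_t$threshold, rep$threshold)
  expect_error(flag_outliers(c(1, Inf)), class = "sr_invalid_input")
})

test_that("clustered flagged observations are annotated as biological, retained", {
  r <- c(4, 4.2, 0.1, 0.2, 5)
  g <- c("A", "A", "A", "B", "B")
  rep <- flag_outliers(r, groups = g)$report
  expect_identical(rep$retain_reason[1:2],
                   rep("clustered in treatment: biological, retained", 2))
  expect_identical(rep$retain_reason[5], "isolated: re-examine")
})

test_that("Pearson correlations recover exact and near-exact linear relations", {
  d <- data.frame(x = 1:20)
  d$y <- d$x
  set.seed(9)
  d$z <- -2 * d$x + rnorm(20, 0, 1e-6)
  d$c <- 5
  out <- pearson_correlations(d, list(c("x", "y"), c("x", "z")))
  expect_equal(out$r, c(1, -1), tolerance = 1e-6)
  expect_lt(out$p[1], 1e-10)
  expect_warning(cc <- pearson_correlations(d, list(c("x", "c"))),
                 "zero variance")
  expect_true(is.na(cc$r))
  # independent noise: correlation near zero
  set.seed(10)
  ind <- data.frame(a = rnorm(1000), b = rnorm(1000))
  expect_lt(abs(pearson_correlations(ind, list(c("a", "b")))$r), 0.1)
})

test_that("the factorial mixed model detects an injected substrate effect", {
  hits <- 0L
  for (seed in 1:20) {
    d <- factorial_data(seed, substrate_effect = 3, sd = 1)
    fit <- suppressWarnings(fit_factorial_mixed_model(d, "y"))
    s_row <- fit$terms[fit$terms$term == "S", ]
    hits <- hits + as.integer(s_row$significant)
  }
  expect_gte(hits, 18L)
})

test_that("a null response yields no significant terms and fits carry the term structure", {
  d <- factorial_data(101, substrate_effect = 0, sd = 1)
  fit <- fit_factorial_mixed_model(d, "y")
  expect_identical(sort(fit$terms$term),
                   sort(c("S", "D", "T", "S:D", "S:T", "D:T", "S:D:T")))
  # a pure-noise response should rarely show effects; re-check flags are consistent
  expect_identical(fit$terms$significant, fit$terms$p < 0.05)
  dc <- d
  dc$y <- 1
  fitc <- NULL
  w <- capture_warnings(fitc <- fit_factorial_mixed_model(dc, "y"))
  expect_true(any(grepl("constant", w)))
  expect_false(any(fitc$terms$significant, na.rm = TRUE))
})

test_that("a single incubation drops the incubation random terms with a warning", {
  d <- factorial_data(3, substrate_effect = 2, sd = 1)
  d1 <- d[d$incubation == 1, ]
  expect_warning(fit <- fit_factorial_mixed_model(d1, "y"),
                 "single incubation")
  expect_s3_class(fit, "factorial_fit")
})

test_that("leave-one-out refits report whether an outlier changes conclusions", {
  d <- factorial_data(4, substrate_effect = 3, sd = 1)
  d$y[5] <- d$y[5] + 12
  inf <- outlier_influence(d, "y", rows = 5)
  expect_identical(nrow(inf), 1L)
  expect_type(inf$influential, "logical")
})
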