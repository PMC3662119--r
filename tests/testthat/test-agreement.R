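test_that("reference standard is the per-subject median", {
  panel <- rater_panel(rbind(c(10, 20, 20, 30, 100)))
  expect_equal(reference_standard(panel), c(S001 = 20))

  same <- rater_panel(matrix(35, 4, 5))
  expect_true(all(reference_standard(same) == 35))

  even <- rater_panel(rbind(c(10, 20, 30, 40)))
  expect_equal(unname(reference_standard(even)), 25) # mean of central pair

  expect_error(reference_standard(matrix(numeric(0), 0, 0)),
               class = "mammodensity_error_spec")
})

test_that("rater panel constructor validates its input", {
  expect_error(rater_panel(matrix(c(10, NA), 1, 2)),
               class = "mammodensity_error_spec")
  expect_error(rater_panel(matrix(c(10, 120), 1, 2)),
               class = "mammodensity_error_spec")
})

test_that("ICC(2,1): perfect duplicate rater gives 1", {
  x <- cbind(c(1, 5, 9, 14), c(1, 5, 9, 14))
  r <- icc_two_way(x)
  expect_equal(r$icc, 1)
  expect_equal(r$ci_low, 1)
})

test_that("ICC(2,1) matches an independently computed reference value", {
  # fixture checked against a separate statistical implementation
  x <- matrix(c(10, 14.9, 6.2,
                22.3, 27.6, 19,
                40.2, 48, 35.5,
                53.1, 60.5, 53.1,
                70.3, 71.2, 66.9,
                87.1, 85, 80.6), nrow = 6, byrow = TRUE)
  r <- icc_two_way(x)
  expect_equal(r$icc, 0.976656015319, tolerance = 1e-10)
  expect_equal(r$ci_low, 0.7569, tolerance = 1e-3)
  expect_equal(r$ci_high, 0.9969, tolerance = 1e-3)
  rc <- icc_two_way(x, type = "consistency")
  expect_equal(rc$icc, 0.993836775624, tolerance = 1e-10)
})

test_that("ICC is undefined for a constant matrix", {
  expect_error(icc_two_way(matrix(5, 4, 3)),
               class = "mammodensity_error_undefined")
})

test_that("ICC interpretation labels follow the published scale", {
  expect_identical(icc_interpretation(0.884), "excellent")
  expect_identical(icc_interpretation(0.862), "excellent")
  expect_identical(icc_interpretation(0.20), "poor")
  expect_identical(icc_interpretation(0.21), "fair")
  expect_identical(icc_interpretation(c(0.40, 0.41, 0.60, 0.61, 0.80, 0.81)),
                   c("fair", "moderate", "moderate", "substantial",
                     "substantial", "excellent"))
  expect_identical(icc_interpretation(-0.3), "poor")
  expect_error(icc_interpretation(1.2), class = "mammodensity_error_spec")
})

test_that("weighted kappa: identity, chance level, undefined cases", {
  a <- seq(0, 100, by = 5)
  expect_equal(quadratic_weighted_kappa(a, a), 1)

  set.seed(42)
  x <- sample(seq(0, 100, 5), 4000, replace = TRUE)
  y <- sample(seq(0, 100, 5), 4000, replace = TRUE)
  expect_lt(abs(quadratic_weighted_kappa(x, y)), 0.05)

  expect_error(quadratic_weighted_kappa(rep(50, 5), rep(50, 5)),
               class = "mammodensity_error_undefined")
  expect_error(quadratic_weighted_kappa(c(0, 3), c(0, 5)),
               class = "mammodensity_error_spec") # off-grid value
})

test_that("pearson rho: linear relation vs agreement, longhand oracle", {
  x <- c(10, 20, 30, 40, 50)
  y <- 2 * x + 5
  expect_equal(pearson_rho(x, y), 1)
  expect_lt(icc_two_way(cbind(x, y))$icc, 1)

  a <- c(3, 7, 1, 9, 4)
  b <- c(2, 8, 3, 10, 2)
  longhand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_rho(a, b), longhand, tolerance = 1e-12)

  expect_error(pearson_rho(c(1, 1, 1), c(1, 2, 3)),
               class = "mammodensity_error_undefined")
})

test_that("Bland-Altman hand case, identity and sign convention", {
  ref <- c(11, 22, 33)
  alg <- ref - c(1, 2, 3)
  ba <- bland_altman(ref, alg)
  expect_equal(ba$bias, 2)
  expect_equal(ba$loa_low, 2 - 1.96, tolerance = 1e-12)
  expect_equal(ba$loa_high, 2 + 1.96, tolerance = 1e-12)

  same <- bland_altman(ref, ref)
  expect_equal(same$bias, 0)
  expect_equal(same$loa_low, 0)
  expect_equal(same$loa_high, 0)

  swapped <- bland_altman(alg, ref)
  expect_equal(swapped$bias, -ba$bias)
  expect_equal(swapped$loa_low, -ba$loa_high)

  # bias always inside the limits; limits symmetric about the bias
  set.seed(10)
  r <- runif(30, 0, 100); a <- pmin(pmax(r + rnorm(30, 0, 6), 0), 100)
  b2 <- bland_altman(r, a)
  expect_gte(b2$bias, b2$loa_low)
  expect_lte(b2$bias, b2$loa_high)
  expect_equal(b2$loa_high - b2$bias, b2$bias - b2$loa_low)

  expect_error(bland_altman(1:3, 1:4), class = "mammodensity_error_spec")
})

test_that("within-one-BI-RADS proportion", {
  v <- c(10, 30, 55, 80, 95)
  expect_equal(within_one_birads(v, v), 1)
  expect_equal(within_one_birads(rep(10, 4), rep(90, 4)), 0)

  # 10 pairs, exactly 2 discordant by two or more categories
  ref <- c(10, 10, 30, 30, 55, 55, 80, 80, 10, 90)
  alg <- c(12, 30, 10, 55, 30, 80, 55, 90, 60, 20)
  expect_equal(within_one_birads(ref, alg), 0.8)
})

test_that("per-category summaries: conventions, absents, percentile oracle", {
  ref <- c(0, 10, 20, 30, 40)
  s <- category_distribution_summary(ref, rep(1L, 5))
  expect_equal(s$present, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(s$q1[1], 10)
  expect_equal(s$median[1], 20)
  expect_equal(s$q3[1], 30)

  set.seed(20)
  ref2 <- runif(80, 0, 100)
  cats <- sample(1:4, 80, replace = TRUE)
  s2 <- category_distribution_summary(ref2, cats)
  for (k in 1:4) {
    v <- ref2[cats == k]
    expect_equal(s2$q1[k], oracle_quantile7(v, 0.25), tolerance = 1e-12)
    expect_equal(s2$median[k], oracle_quantile7(v, 0.5), tolerance = 1e-12)
    expect_equal(s2$q3[k], oracle_quantile7(v, 0.75), tolerance = 1e-12)
    expect_gte(s2$whisker_low[k], s2$min[k])
    expect_lte(s2$whisker_high[k], s2$max[k])
  }
})

test_that("evaluate_agreement: self-evaluation and field invariants", {
  panel <- simulate_rater_panel(withr::with_seed(6L, runif(60)),
                                rater_model(seed = 6L))
  ref <- reference_standard(panel)
  rep_self <- evaluate_agreement(panel, ref)
  expect_equal(rep_self$icc, 1)
  expect_equal(rep_self$bias, 0)
  expect_equal(rep_self$within_one_birads, 1)
  expect_true(rep_self$promising)

  alg <- pmin(pmax(ref + withr::with_seed(7L, rnorm(60, 0, 6)), 0), 100)
  rep2 <- evaluate_agreement(panel, alg)
  expect_lte(rep2$icc_ci_low, rep2$icc)
  expect_gte(rep2$icc_ci_high, rep2$icc)
  expect_equal(rep2$loa_high - rep2$bias, rep2$bias - rep2$loa_low)
  expect_true(rep2$icc_label %in%
                c("poor", "fair", "moderate", "substantial", "excellent"))
  expect_s3_class(rep2$category_summary, "data.frame")
  expect_equal(nrow(rep2$category_summary), 4L)
  expect_output(print(rep2), "agreement_report")
})

test_that("a constant offset hurts absolute agreement but not correlation", {
  x <- seq(5, 95, length.out = 40)
  y <- x + 15
  expect_equal(pearson_rho(x, y), 1)
  icc_offset <- icc_two_way(cbind(x, y))$icc
  icc_same <- icc_two_way(cbind(x, x))$icc
  expect_lt(icc_offset, icc_same)
})
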