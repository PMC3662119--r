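test_that("maxentropy threshold separates a two-spike histogram at the low level", {
  counts <- integer(64)
  counts[21] <- 40L # gray level 20
  counts[51] <- 60L # gray level 50
  t <- maxentropy_threshold(hist_from_counts(counts))
  expect_gte(t, 20)
  expect_lt(t, 50)
  expect_equal(t, 20) # lower-threshold tie break
})

test_that("maxentropy threshold equals the exhaustive-search oracle", {
  set.seed(101)
  for (i in 1:200) {
    counts <- rpois(64, lambda = runif(1, 0.5, 30))
    if (sum(counts > 0) < 2) counts[c(3, 40)] <- counts[c(3, 40)] + 1L
    h <- hist_from_counts(counts)
    expect_identical(as.integer(maxentropy_threshold(h)),
                     as.integer(oracle_maxentropy(counts)))
  }
})

test_that("maxentropy threshold is invariant to count scaling", {
  set.seed(7)
  counts <- rpois(64, 5)
  counts[c(10, 50)] <- counts[c(10, 50)] + 3L
  t1 <- maxentropy_threshold(hist_from_counts(counts))
  t2 <- maxentropy_threshold(hist_from_counts(counts * 7L))
  expect_identical(t1, t2)
})

test_that("moments threshold exactly recovers two-level mixtures", {
  set.seed(55)
  for (i in 1:100) {
    a <- sample(0:100, 1)
    b <- a + sample(20:150, 1)
    n <- 1000L
    p <- runif(1, 0.05, 0.95)
    na <- round(p * n)
    counts <- integer(b + 1L)
    counts[a + 1L] <- na
    counts[b + 1L] <- n - na
    t <- moments_threshold(hist_from_counts(counts))
    expect_equal(attr(t, "p0"), na / n, tolerance = 1e-9)
    expect_false(attr(t, "fallback"))
    expect_gte(as.numeric(t), a)
    expect_lt(as.numeric(t), b)
  }
})

test_that("moments solution satisfies the moment-preservation equations", {
  set.seed(77)
  for (i in 1:200) {
    counts <- rpois(64, lambda = runif(1, 1, 20))
    if (sum(counts > 0) < 2) counts[c(5, 30)] <- 2L
    h <- hist_from_counts(counts)
    t <- moments_threshold(h)
    if (isTRUE(attr(t, "fallback"))) next
    p0 <- attr(t, "p0")
    z0 <- attr(t, "z0")
    z1 <- attr(t, "z1")
    p <- h$counts / h$total
    z <- h$mids
    for (j in 1:3) {
      mj <- sum(p * z^j)
      expect_equal(p0 * z0^j + (1 - p0) * z1^j, mj, tolerance = 1e-7)
    }
  }
})

test_that("moments threshold ignores appended empty bins", {
  counts <- c(integer(10), 50L, integer(20), 30L, integer(5))
  t1 <- moments_threshold(hist_from_counts(counts))
  t2 <- moments_threshold(hist_from_counts(c(counts, integer(40))))
  expect_equal(as.numeric(t1), as.numeric(t2))
})

test_that("degenerate histograms are rejected", {
  counts <- integer(64)
  counts[10] <- 100L
  expect_error(maxentropy_threshold(hist_from_counts(counts)),
               class = "mammodensity_error_degenerate_histogram")
  expect_error(moments_threshold(hist_from_counts(counts)),
               class = "mammodensity_error_degenerate_histogram")
})

test_that("threshold combination rules", {
  expect_equal(combine_thresholds(110, 110), 110)
  expect_equal(combine_thresholds(100, 120), 110)
  expect_equal(combine_thresholds(100, 121), 110) # halves round down
  expect_equal(combine_thresholds(100, 120, rule = "min"), 100)
  expect_equal(combine_thresholds(100, 120, rule = "max"), 120)
  set.seed(3)
  for (i in 1:20) {
    a <- sample(0:255, 1); b <- sample(0:255, 1)
    t <- combine_thresholds(a, b)
    expect_gte(t, min(a, b))
    expect_lte(t, max(a, b))
  }
})

test_that("BI-RADS category boundaries", {
  expect_identical(birads_category(c(0, 24.9, 25, 49.9, 50, 74.9, 75, 100)),
                   c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_error(birads_category(101), class = "mammodensity_error_spec")
  expect_error(birads_category(-0.1), class = "mammodensity_error_spec")
})

test_that("percent density is monotone in the painted dense fraction", {
  est <- sapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(td) {
    ph <- generate_phantom(phantom_spec(seed = 77, true_density = td))
    compute_density(ph$image, build_envelope(ph$image))$percent_density
  })
  expect_true(all(diff(est) > 0))
})

test_that("an all-fat phantom reads near zero percent density", {
  ph <- generate_phantom(phantom_spec(seed = 13, true_density = 0))
  d <- compute_density(ph$image, build_envelope(ph$image))
  expect_lt(d$percent_density, 2)
})

test_that("percent density is invariant to mirroring", {
  ph <- generate_phantom(phantom_spec(seed = 17, true_density = 0.45))
  d1 <- compute_density(ph$image, build_envelope(ph$image))
  m <- mirror_mammogram(ph$image)
  d2 <- compute_density(m, build_envelope(m))
  expect_equal(d2$percent_density, d1$percent_density)
  expect_equal(d2$threshold_final, d1$threshold_final)
})

test_that("strict vs non-strict dense comparison differs by the threshold bin only", {
  ph <- generate_phantom(phantom_spec(seed = 23, true_density = 0.35))
  masks <- build_envelope(ph$image)
  d <- compute_density(ph$image, masks)
  vals <- ph$image$pixels[masks$envelope]
  n_gt <- sum(vals > d$threshold_final)
  n_ge <- sum(vals >= d$threshold_final)
  expect_identical(d$dense_pixels, n_gt)
  expect_identical(n_ge - n_gt, sum(vals == d$threshold_final))
})

test_that("density result invariants hold and empty envelopes error", {
  b <- phantom_battery(50L)[[1]]
  d <- b$density
  expect_equal(d$percent_density, 100 * d$dense_pixels / d$roi_pixels)
  expect_lte(d$dense_pixels, d$roi_pixels)
  expect_gt(d$roi_pixels, 0L)
  expect_identical(d$birads_category, birads_category(d$percent_density))

  empty <- list(envelope = matrix(FALSE, 10, 10))
  expect_error(compute_density(b$phantom$image, empty),
               class = "mammodensity_error_degenerate_mask")
})
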