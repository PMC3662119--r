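test_that("background segmentation matches phantom truth within 1% of pixels", {
  ph <- generate_phantom(phantom_spec(seed = 11, background_intensity = 0L,
                                      fat_intensity = 100L))
  bg <- segment_background(ph$image)
  truth_bg <- !(ph$truth$envelope_mask | ph$truth$pectoral_mask)
  disagree <- mean(bg$background != truth_bg)
  expect_lt(disagree, 0.01)
  # candidate is breast + pectoral
  expect_gt(jaccard(bg$candidate,
                    ph$truth$envelope_mask | ph$truth$pectoral_mask), 0.98)
})

test_that("uniform images raise an empty-image error", {
  img <- mammogram_image(matrix(0L, 128, 128), laterality = "L")
  expect_error(segment_background(img),
               class = "mammodensity_error_empty_image")
  expect_error(build_envelope(img),
               class = "mammodensity_error_empty_image")
})

test_that("Otsu background mask is invariant to a constant intensity shift", {
  ph <- generate_phantom(phantom_spec(seed = 12))
  shifted <- ph$image
  shifted$pixels <- shifted$pixels + 20L
  bg1 <- segment_background(ph$image)
  bg2 <- segment_background(shifted)
  expect_identical(bg1$background, bg2$background)
  expect_identical(bg2$threshold, bg1$threshold + 20L)
})

test_that("pectoral removal recovers the wedge (Jaccard >= 0.8 over seeds)", {
  for (seed in 1:12) {
    ph <- generate_phantom(phantom_spec(seed = seed, pectoral_fraction = 0.1,
                                        true_density = 0.3))
    bg <- segment_background(ph$image)
    pect <- remove_pectoral(ph$image, bg$candidate)
    expect_gte(jaccard(pect, ph$truth$pectoral_mask), 0.8)
    expect_true(attr(pect, "pectoral_found"))
  }
})

test_that("a near-absent pectoral yields an empty mask, not an error", {
  ph <- generate_phantom(phantom_spec(seed = 4, pectoral_fraction = 1e-4))
  bg <- segment_background(ph$image)
  pect <- remove_pectoral(ph$image, bg$candidate)
  expect_equal(sum(pect), 0L)
  expect_false(attr(pect, "pectoral_found"))
})

test_that("pectoral removal is laterality-equivariant", {
  ph <- generate_phantom(phantom_spec(seed = 9, true_density = 0.4))
  bg <- segment_background(ph$image)
  pect <- remove_pectoral(ph$image, bg$candidate)

  mirrored <- mirror_mammogram(ph$image)
  bg_m <- segment_background(mirrored)
  pect_m <- remove_pectoral(mirrored, bg_m$candidate)
  expect_identical(strip_mask(pect_m), strip_mask(mirror_cols(pect)))
})

test_that("overlay text is detected inside the background only", {
  ph <- generate_phantom(phantom_spec(seed = 21, with_text_overlay = TRUE))
  bg <- segment_background(ph$image)
  text <- remove_text_overlay(ph$image, bg$background)
  covered <- sum(text & ph$truth$text_mask) / sum(ph$truth$text_mask)
  expect_gte(covered, 0.95)

  masks <- build_envelope(ph$image)
  expect_equal(sum(masks$text & masks$envelope), 0L)

  ph2 <- generate_phantom(phantom_spec(seed = 21, with_text_overlay = FALSE))
  bg2 <- segment_background(ph2$image)
  expect_equal(sum(remove_text_overlay(ph2$image, bg2$background)), 0L)
})

test_that("fat peel: identity at margin 0, closed-form band on a rectangle", {
  m <- matrix(FALSE, 100, 100)
  m[20:59, 1:30] <- TRUE # chest wall on the left image edge
  expect_identical(peel_subcutaneous_fat(m, 0L), m)

  peeled <- peel_subcutaneous_fat(m, 3L)
  # three exposed sides (top, bottom, right); chest-wall side protected:
  # remaining area = (h - 2m) * (w - m)
  expect_equal(sum(peeled), (40L - 6L) * (30L - 3L))
  expect_true(all(peeled[23:56, 1:27]))

  # anti-extensivity on random masks
  set.seed(5)
  for (i in 1:5) {
    rm <- matrix(runif(64 * 64) < 0.6, 64, 64)
    out <- mammodensity:::.binary_erode(rm, 2L)
    expect_true(all(!out | rm))
  }

  expect_error(peel_subcutaneous_fat(m, 50L),
               class = "mammodensity_error_degenerate_mask")
})

test_that("build_envelope: partition, disjointness, determinism, fidelity", {
  battery <- phantom_battery(50L)[1:12]
  cfg <- segmentation_config()
  for (b in battery) {
    masks <- b$masks
    total <- masks$envelope | masks$pectoral | masks$text | masks$background
    expect_true(all(total))
    expect_equal(sum(masks$envelope & masks$pectoral), 0L)
    expect_equal(sum(masks$envelope & masks$text), 0L)
    expect_equal(sum(masks$envelope & masks$background), 0L)
    expect_equal(sum(masks$pectoral & masks$text), 0L)

    # envelope is one connected component
    labels <- mammodensity:::.cc_label(masks$envelope, 4L)
    expect_equal(max(labels), 1L)

    # fidelity vs truth envelope peeled by the same margin
    tr <- b$phantom$truth
    cand_truth <- tr$envelope_mask | tr$pectoral_mask
    truth_env <- mammodensity:::.binary_erode(cand_truth,
                                              cfg$fat_peel_margin) &
      !tr$pectoral_mask
    expect_gte(jaccard(masks$envelope, truth_env), 0.9)
    roi_err <- abs(sum(masks$envelope) - sum(truth_env)) / sum(truth_env)
    expect_lte(roi_err, 0.1)
  }

  one <- battery[[1]]
  again <- build_envelope(one$phantom$image)
  expect_identical(unname(again$envelope), unname(one$masks$envelope))
})

test_that("build_envelope is laterality-equivariant end to end", {
  ph <- generate_phantom(phantom_spec(seed = 33, true_density = 0.5,
                                      with_text_overlay = TRUE))
  masks <- build_envelope(ph$image)
  masks_m <- build_envelope(mirror_mammogram(ph$image))
  expect_identical(unname(masks_m$envelope),
                   unname(mirror_cols(masks$envelope)))
  expect_identical(strip_mask(masks_m$pectoral),
                   strip_mask(mirror_cols(masks$pectoral)))
})

test_that("non-MLO images are rejected by the segmentation pipeline", {
  ph <- generate_phantom(phantom_spec(seed = 2))
  img <- ph$image
  img$view_position <- "CC"
  expect_error(build_envelope(img),
               class = "mammodensity_error_unsupported_view")
})

test_that("segmentation config validates its arguments", {
  expect_error(segmentation_config(fat_peel_margin = -1),
               class = "mammodensity_error_spec")
  expect_error(segmentation_config(pectoral_method = "line_fit"),
               class = "mammodensity_error_spec")
})
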