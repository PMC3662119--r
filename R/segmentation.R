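#' Segmentation configuration
#'
#' Tunable parameters of the breast-envelope masking stage. The published
#' pipeline names what is removed (background, pectoral muscle, subcutaneous
#' fat margin, overlay text) but not how; the concrete methods here are
#' package design choices, each swappable through this config.
#'
#' @param fat_peel_margin pixels of skin-line (subcutaneous fat) margin to
#'   erode off the breast candidate; 0 disables the peel. Default 3 px: at
#'   typical phantom/preview resolutions a few pixels of bright skin-line
#'   band is what inflates density, and the ROI loss stays below a few
#'   percent.
#' @param min_text_component_area smallest connected component (pixels)
#'   counted as overlay text.
#' @param pectoral_method only `"corner_region_growing"` is implemented: a
#'   noise-adaptive region grown from the chest-wall top corner.
#' @param background_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_background_level gray level used when
#'   `background_method = "fixed"`.
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(fat_peel_margin = 3L,
                                min_text_component_area = 20L,
                                pectoral_method = "corner_region_growing",
                                background_method = c("otsu", "fixed"),
                                fixed_background_level = 0L) {
  background_method <- match.arg(background_method)
  if (fat_peel_margin < 0L || min_text_component_area < 0L) {
    md_stop("margins and areas must be nonnegative", "mammodensity_error_spec")
  }
  if (!identical(pectoral_method, "corner_region_growing")) {
    md_stop("only pectoral_method = 'corner_region_growing' is implemented",
            "mammodensity_error_spec")
  }
  structure(
    list(
      fat_peel_margin = as.integer(fat_peel_margin),
      min_text_component_area = as.integer(min_text_component_area),
      pectoral_method = pectoral_method,
      background_method = background_method,
      fixed_background_level = as.integer(fixed_background_level)
    ),
    class = "segmentation_config"
  )
}

# Otsu threshold from a gray-level histogram: maximises the between-class
# variance; returns the gray level t such that the low class is {value <= t}.
# Ties break toward the lower t.
otsu_threshold <- function(hist) {
  p <- hist$counts / hist$total
  z <- hist$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * z)
  mu_t <- mu[length(mu)]
  valid <- w0 > 1e-12 & (1 - w0) > 1e-12
  sigma_b <- rep(-Inf, length(p))
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  hist$levels[which.max(sigma_b)]
}

# Which image borders are NOT the chest wall, given the laterality.
non_chest_border <- function(nr, nc, laterality) {
  list(rows = c(1L, nr),
       col = if (laterality == "L") nc else 1L)
}

# Union of labelled components touching a pixel set given as a logical matrix.
components_touching <- function(labels, touch) {
  ids <- setdiff(unique(labels[touch]), 0L)
  matrix(labels %in% ids, nrow(labels), ncol(labels))
}

largest_component <- function(mask, connectivity = 4L) {
  labels <- .cc_label(mask, connectivity)
  if (max(labels) == 0L) return(mask & FALSE)
  sizes <- tabulate(labels[labels > 0L])
  labels == which.max(sizes)
}

#' Segment the image background
#'
#' Thresholds the image (Otsu by default), then takes as background only the
#' below-threshold components that touch a non-chest-wall border (so dark
#' recesses inside the breast are not misread as background). The breast
#' candidate is the largest connected component of the remainder; at this
#' stage it still contains the pectoral muscle.
#'
#' @param image a [mammogram_image()] (MLO, bright = dense).
#' @param config a [segmentation_config()].
#' @return A list with logical matrices `background` and `candidate`, and the
#'   gray-level `threshold` used.
#' @export
segment_background <- function(image, config = segmentation_config()) {
  stopifnot(inherits(image, "mammogram_image"))
  px <- image$pixels
  nr <- nrow(px); nc <- ncol(px)
  t_bg <- if (config$background_method == "otsu") {
    h <- gray_histogram(as.integer(px), image$max_gray)
    if (sum(h$counts > 0L) < 2L) {
      md_stop("empty image: single-valued histogram, no foreground found",
              "mammodensity_error_empty_image")
    }
    otsu_threshold(h)
  } else {
    config$fixed_background_level
  }
  below <- px <= t_bg
  if (all(below)) {
    md_stop("empty image: no pixels above the background threshold",
            "mammodensity_error_empty_image")
  }
  border <- non_chest_border(nr, nc, image$laterality)
  touch <- matrix(FALSE, nr, nc)
  touch[border$rows, ] <- TRUE
  touch[, border$col] <- TRUE
  labels <- .cc_label(below, 4L)
  background <- components_touching(labels, touch & below)
  fg <- !background
  candidate <- largest_component(fg, 4L)
  if (!any(candidate)) {
    md_stop("empty image: no foreground component",
            "mammodensity_error_empty_image")
  }
  list(background = background, candidate = candidate, threshold = t_bg)
}

#' Detect overlay text in the background region
#'
#' Bright connected components that sit fully inside the background (i.e.
#' above-threshold components other than the breast candidate) and are at
#' least `min_text_component_area` pixels are marked as overlay text.
#'
#' @param image a [mammogram_image()].
#' @param background_mask logical background map from [segment_background()].
#' @param config a [segmentation_config()].
#' @return Logical text mask (possibly empty; never an error).
#' @export
remove_text_overlay <- function(image, background_mask,
                                config = segmentation_config()) {
  fg <- !background_mask
  labels <- .cc_label(fg, 4L)
  if (max(labels) == 0L) return(fg & FALSE)
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes >= config$min_text_component_area)
  keep <- setdiff(keep, which.max(sizes)) # the breast candidate is not text
  matrix(labels %in% keep, nrow(fg), ncol(fg))
}

#' Remove the pectoral muscle by corner region growing
#'
#' In MLO views the pectoral muscle appears as a bright, roughly triangular
#' region in the chest-wall upper corner (top-left for laterality L,
#' top-right for R). A seed block in that corner is sampled; if its mean
#' intensity stands clearly above the candidate's median the region is grown
#' over connected candidate pixels within a noise-adaptive tolerance of the
#' seed mean, constrained to the chest-wall half of the image. An absent
#' pectoral (nothing bright in the corner) yields an empty mask, never an
#' error.
#'
#' @param image a [mammogram_image()].
#' @param breast_candidate logical candidate mask from [segment_background()].
#' @param laterality `"L"` or `"R"`; defaults to the image's.
#' @param config a [segmentation_config()].
#' @return Logical pectoral mask with attribute `pectoral_found`.
#' @export
remove_pectoral <- function(image, breast_candidate,
                            laterality = image$laterality,
                            config = segmentation_config()) {
  stopifnot(inherits(image, "mammogram_image"))
  laterality <- normalize_laterality(laterality)
  px <- image$pixels
  flip <- laterality == "R"
  if (flip) {
    px <- mirror_cols(px)
    breast_candidate <- mirror_cols(breast_candidate)
  }
  nr <- nrow(px); nc <- ncol(px)
  empty <- structure(matrix(FALSE, nr, nc), pectoral_found = FALSE)

  k <- max(3L, round(0.04 * nr))
  seed <- matrix(FALSE, nr, nc)
  seed[seq_len(k), seq_len(k)] <- TRUE
  seed <- seed & breast_candidate
  out <- if (!any(seed)) {
    empty
  } else {
    vals <- as.numeric(px[breast_candidate])
    seed_vals <- as.numeric(px[seed])
    seed_mean <- mean(seed_vals)
    seed_sd <- max(sd(seed_vals), 1)
    if (!is.finite(seed_sd)) seed_sd <- 1
    q <- quantile(vals, c(0.01, 0.5, 0.99), names = FALSE)
    rng <- max(q[3] - q[1], 1)
    if (seed_mean < q[2] + 0.15 * rng) {
      empty # corner not clearly brighter than breast tissue
    } else {
      tol <- max(4 * seed_sd, 0.02 * rng, 2)
      grow <- breast_candidate & px >= seed_mean - tol
      grow[, (ceiling(nc / 2) + 1L):nc] <- FALSE # never the nipple-side half
      grow[(round(0.9 * nr) + 1L):nr, ] <- FALSE
      labels <- .cc_label(grow, 8L)
      ids <- setdiff(unique(labels[seed & grow]), 0L)
      if (length(ids) == 0L) {
        empty
      } else {
        structure(matrix(labels %in% ids, nr, nc), pectoral_found = TRUE)
      }
    }
  }
  if (flip) {
    found <- attr(out, "pectoral_found")
    out <- structure(mirror_cols(out), pectoral_found = found)
  }
  out
}

#' Peel the subcutaneous fat margin
#'
#' Erodes the skin-line boundary of a breast mask inward by `margin` pixels
#' (8-connected erosion). Pixels beyond the image border count as tissue, so
#' the chest-wall edge -- which lies on an image border -- is never eroded.
#'
#' @param breast_mask logical mask.
#' @param margin nonnegative integer; 0 is the identity.
#' @return The eroded logical mask.
#' @export
peel_subcutaneous_fat <- function(breast_mask, margin) {
  stopifnot(is.logical(breast_mask), is.matrix(breast_mask))
  margin <- as.integer(margin)
  if (margin < 0L) md_stop("margin must be nonnegative",
                           "mammodensity_error_spec")
  if (margin == 0L) return(breast_mask)
  out <- .binary_erode(breast_mask, margin)
  if (!any(out)) {
    md_stop("fat peel margin erased the whole mask",
            "mammodensity_error_degenerate_mask")
  }
  out
}

#' Build the breast-envelope segmentation
#'
#' Composes the full masking stage: background removal, pectoral-muscle
#' removal, overlay-text removal and the subcutaneous-fat peel. The image is
#' internally normalised to a chest-wall-left orientation (using the recorded
#' laterality) and the masks are returned in the original orientation, which
#' makes the whole stage laterality-equivariant by construction.
#'
#' @param image a [mammogram_image()] (MLO view).
#' @param config a [segmentation_config()].
#' @return An object of class `segmentation_masks`: logical matrices
#'   `envelope`, `pectoral`, `text`, `background` (pairwise disjoint, tiling
#'   the image) plus a `provenance` list (background threshold, pectoral
#'   found flag, config).
#' @export
build_envelope <- function(image, config = segmentation_config()) {
  stopifnot(inherits(image, "mammogram_image"))
  if (!identical(image$view_position, "MLO")) {
    md_stop(sprintf(
      "unsupported view position '%s': only MLO views are supported",
      image$view_position), "mammodensity_error_unsupported_view")
  }
  work <- if (image$laterality == "R") mirror_mammogram(image) else image

  stage <- function(name, expr) {
    tryCatch(expr, mammodensity_error = function(e) {
      md_stop(sprintf("segmentation stage '%s': %s", name,
                      conditionMessage(e)), class(e)[1])
    })
  }

  bg <- stage("background", segment_background(work, config))
  text <- stage("text", remove_text_overlay(work, bg$background, config))
  pect <- stage("pectoral",
                remove_pectoral(work, bg$candidate, laterality = "L",
                                config = config))
  peeled <- stage("fat_peel",
                  peel_subcutaneous_fat(bg$candidate,
                                        config$fat_peel_margin))
  env0 <- peeled & !pect & !text
  if (!any(env0)) {
    md_stop("segmentation stage 'envelope': empty envelope after masking",
            "mammodensity_error_degenerate_mask")
  }
  envelope <- largest_component(env0, 4L)
  background <- !(envelope | pect | text)

  if (image$laterality == "R") {
    found <- attr(pect, "pectoral_found")
    envelope <- mirror_cols(envelope)
    pect <- structure(mirror_cols(pect), pectoral_found = found)
    text <- mirror_cols(text)
    background <- mirror_cols(background)
  }
  structure(
    list(
      envelope = envelope,
      pectoral = pect,
      text = text,
      background = background,
      provenance = list(
        background_threshold = bg$threshold,
        pectoral_found = isTRUE(attr(pect, "pectoral_found")),
        config = unclass(config)
      )
    ),
    class = "segmentation_masks"
  )
}

#' @export
print.segmentation_masks <- function(x, ...) {
  n <- length(x$envelope)
  cat(sprintf(
    "<segmentation_masks> envelope %.1f%%, pectoral %.1f%%, text %.1f%%, background %.1f%% of %d px\n",
    100 * sum(x$envelope) / n, 100 * sum(x$pectoral) / n,
    100 * sum(x$text) / n, 100 * sum(x$background) / n, n
  ))
  invisible(x)
}
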