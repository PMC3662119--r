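#' Specify a synthetic MLO phantom
#'
#' Describes a synthetic mediolateral-oblique (MLO) mammogram: a half-elliptic
#' breast envelope attached to the chest-wall edge against a dark background,
#' a bright pectoral wedge in the chest-wall upper corner, elliptic
#' fibroglandular (dense) blobs brighter than the fatty tissue, optional
#' bright overlay-text blocks in the background, and additive Gaussian noise.
#' The four-intensity-class model (background < fat < dense <= pectoral) is
#' the simplest world in which envelope masking and histogram thresholding
#' are exercised meaningfully.
#'
#' @param image_height,image_width image size in pixels (at least 128 each).
#' @param laterality `"L"` or `"R"`; the chest wall sits on that image edge.
#' @param true_density target dense-area fraction of the envelope, in
#'   `[0, 1]`. Achieved exactly up to one pixel of rounding (< 0.005).
#' @param pectoral_fraction pectoral wedge area as a fraction of the whole
#'   image, in `(0, 0.3]`; use values near 0 for a "no pectoral" phantom.
#' @param n_dense_blobs intended number of dense blobs; sets the blob size
#'   scale (the painter stops when the target pixel count is met).
#' @param fat_intensity,dense_intensity,pectoral_intensity,background_intensity
#'   mean gray levels of the four classes; must satisfy
#'   `background < fat < dense <= pectoral`.
#' @param noise_sd standard deviation of the additive Gaussian pixel noise,
#'   in gray levels (default 4, i.e. 5% of the default fat--dense gap).
#' @param with_text_overlay place bright glyph-like rectangles in background
#'   corners away from the breast.
#' @param seed integer seed; generation is bit-reproducible for a fixed seed.
#' @param bits_stored stored bit depth (8--16) of the emitted image.
#' @return A list of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(image_height = 256L, image_width = 256L,
                         laterality = "L", true_density = 0.25,
                         pectoral_fraction = 0.08, n_dense_blobs = 12L,
                         fat_intensity = 100L, dense_intensity = 180L,
                         pectoral_intensity = 220L, background_intensity = 10L,
                         noise_sd = 4, with_text_overlay = FALSE,
                         seed = 1L, bits_stored = 8L) {
  spec <- list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    laterality = normalize_laterality(laterality),
    true_density = as.numeric(true_density),
    pectoral_fraction = as.numeric(pectoral_fraction),
    n_dense_blobs = as.integer(n_dense_blobs),
    fat_intensity = as.integer(fat_intensity),
    dense_intensity = as.integer(dense_intensity),
    pectoral_intensity = as.integer(pectoral_intensity),
    background_intensity = as.integer(background_intensity),
    noise_sd = as.numeric(noise_sd),
    with_text_overlay = isTRUE(with_text_overlay),
    seed = as.integer(seed),
    bits_stored = as.integer(bits_stored)
  )
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  if (s$image_height < 128L || s$image_width < 128L) {
    md_stop("phantom images must be at least 128 x 128",
            "mammodensity_error_spec")
  }
  if (is.na(s$true_density) || s$true_density < 0 || s$true_density > 1) {
    md_stop("true_density must lie in [0, 1]", "mammodensity_error_spec")
  }
  if (s$pectoral_fraction <= 0 || s$pectoral_fraction > 0.3) {
    md_stop("pectoral_fraction must lie in (0, 0.3]", "mammodensity_error_spec")
  }
  if (s$n_dense_blobs < 1L) {
    md_stop("n_dense_blobs must be positive", "mammodensity_error_spec")
  }
  ok <- s$background_intensity < s$fat_intensity &&
    s$fat_intensity < s$dense_intensity &&
    s$dense_intensity <= s$pectoral_intensity
  if (!ok) {
    md_stop("intensities must satisfy background < fat < dense <= pectoral",
            "mammodensity_error_spec")
  }
  max_gray <- bitwShiftL(1L, s$bits_stored) - 1L
  if (s$pectoral_intensity > max_gray) {
    md_stop("intensities exceed the stored bit depth", "mammodensity_error_spec")
  }
  if (s$noise_sd < 0) {
    md_stop("noise_sd must be nonnegative", "mammodensity_error_spec")
  }
  invisible(s)
}

# Pixel set of a (possibly rotated) ellipse, as a logical matrix.
ellipse_mask <- function(nr, nc, center_r, center_c, a, b, theta = 0) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dr <- rr - center_r
  dc <- cc - center_c
  u <- dc * cos(theta) + dr * sin(theta)
  v <- -dc * sin(theta) + dr * cos(theta)
  (u / b)^2 + (v / a)^2 <= 1
}

# Half-elliptic breast region attached to the left (chest-wall) edge.
breast_region <- function(nr, nc) {
  cy <- (nr + 1) / 2
  a <- 0.42 * nr
  b <- 0.70 * nc
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((rr - cy) / a)^2 + ((cc - 1) / b)^2 <= 1
}

# Pectoral wedge: a right triangle anchored at the image's top-left corner
# (the chest-wall upper corner in normalised orientation), running off the
# top edge as in a real MLO view.  Legs are chosen steeper than 45 degrees
# and scaled so the triangle covers ~frac of the image area.
pectoral_wedge <- function(nr, nc, frac) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  # area = (s*nr)(s*nc/1.6)/2 = frac*nr*nc  =>  s = sqrt(3.2*frac)
  s <- sqrt(3.2 * frac)
  (cc - 1) / (s * nc / 1.6) + (rr - 1) / (s * nr) < 1
}

#' Generate a synthetic MLO phantom with exact ground truth
#'
#' Renders the image described by a [phantom_spec()] and returns it together
#' with the exact ground-truth masks. Dense blobs are random ellipses painted
#' inside the envelope until the dense pixel count equals
#' `round(true_density * envelope_area)`; when the last blob would overshoot,
#' only its innermost pixels are kept, so the achieved density equals the
#' target to within one pixel (always < 0.005).
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements
#'   \describe{
#'     \item{image}{a [mammogram_image()] (noisy rendering),}
#'     \item{truth}{a `phantom_truth` list: `envelope_mask`, `pectoral_mask`,
#'       `dense_mask`, `text_mask` (logical matrices in the output
#'       orientation) and `true_density`, the achieved
#'       `|dense| / |envelope|` ratio.}
#'   }
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 7, true_density = 0.4))
#' sum(ph$truth$dense_mask) / sum(ph$truth$envelope_mask)
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  validate_phantom_spec(spec)
  nr <- spec$image_height
  nc <- spec$image_width
  with_seed(spec$seed, {
    breast <- breast_region(nr, nc)
    pect <- pectoral_wedge(nr, nc, spec$pectoral_fraction)
    envelope <- breast & !pect
    n_env <- sum(envelope)
    if (n_env < 100L) {
      md_stop("infeasible phantom: envelope region is (almost) empty",
              "mammodensity_error_infeasible")
    }
    target <- round(spec$true_density * n_env)

    dense <- matrix(FALSE, nr, nc)
    if (target >= n_env) {
      dense <- envelope
    } else if (target > 0L) {
      env_idx <- which(envelope)
      blob_area <- max(target / spec$n_dense_blobs, 4)
      r0 <- sqrt(blob_area / pi)
      painted <- 0L
      max_iter <- 50L * spec$n_dense_blobs + 500L
      iter <- 0L
      while (painted < target) {
        iter <- iter + 1L
        if (iter > max_iter) {
          md_stop("infeasible phantom: dense target not reached",
                  "mammodensity_error_infeasible")
        }
        free <- env_idx[!dense[env_idx]]
        if (length(free) == 0L) {
          md_stop("infeasible phantom: no room left for dense blobs",
                  "mammodensity_error_infeasible")
        }
        ctr <- free[sample.int(length(free), 1L)]
        ctr_r <- ((ctr - 1L) %% nr) + 1L
        ctr_c <- ((ctr - 1L) %/% nr) + 1L
        a <- r0 * runif(1, 0.6, 1.4)
        b <- r0 * runif(1, 0.6, 1.4)
        theta <- runif(1, 0, pi)
        blob <- ellipse_mask(nr, nc, ctr_r, ctr_c, a, b, theta) & envelope
        new_idx <- which(blob & !dense)
        if (length(new_idx) == 0L) next
        need <- target - painted
        if (length(new_idx) > need) {
          # keep the innermost pixels so the truncated blob stays blob-like
          nri <- ((new_idx - 1L) %% nr) + 1L
          nci <- ((new_idx - 1L) %/% nr) + 1L
          d2 <- (nri - ctr_r)^2 + (nci - ctr_c)^2
          new_idx <- new_idx[order(d2)][seq_len(need)]
        }
        dense[new_idx] <- TRUE
        painted <- painted + length(new_idx)
      }
    }

    text <- matrix(FALSE, nr, nc)
    if (spec$with_text_overlay) {
      # glyph-like blocks near the non-chest-wall corners of the background
      bh <- max(4L, round(nr / 40))
      bw <- max(10L, round(nc / 8))
      put <- function(r1, c1) {
        rs <- r1:min(r1 + bh - 1L, nr)
        cs <- c1:min(c1 + bw - 1L, nc)
        blk <- matrix(FALSE, nr, nc)
        blk[rs, cs] <- TRUE
        blk & !breast & !pect
      }
      text <- put(6L, nc - bw - 5L) |
        put(nr - bh - 5L, nc - bw - 5L) |
        put(6L + 2L * bh, nc - bw - 5L)
    }

    img <- matrix(spec$background_intensity, nr, nc)
    img[envelope] <- spec$fat_intensity
    img[dense] <- spec$dense_intensity
    img[pect] <- spec$pectoral_intensity
    img[text] <- spec$pectoral_intensity
    if (spec$noise_sd > 0) {
      img <- img + round(rnorm(nr * nc, 0, spec$noise_sd))
    }
    max_gray <- bitwShiftL(1L, spec$bits_stored) - 1L
    img <- pmin(pmax(img, 0L), max_gray)
    img <- matrix(as.integer(img), nr, nc)

    if (spec$laterality == "R") {
      img <- mirror_cols(img)
      envelope <- mirror_cols(envelope)
      pect <- mirror_cols(pect)
      dense <- mirror_cols(dense)
      text <- mirror_cols(text)
    }

    image <- mammogram_image(
      img, laterality = spec$laterality, view_position = "MLO",
      bits_stored = spec$bits_stored,
      source_id = sprintf("phantom-seed%d", spec$seed)
    )
    truth <- structure(
      list(
        envelope_mask = envelope,
        pectoral_mask = pect,
        dense_mask = dense,
        text_mask = text,
        true_density = sum(dense) / sum(envelope)
      ),
      class = "phantom_truth"
    )
    list(image = image, truth = truth, spec = spec)
  })
}

#' Specify a simulated radiologist panel
#'
#' Raters report percent density on the 21-point grid (0, 5, ..., 100):
#' each rating is the truth (in percent) plus a per-rater systematic bias and
#' Gaussian noise, clipped to `[0, 100]` and snapped to the nearest multiple
#' of 5 (grid midpoints round half away from zero, so 32.5 becomes 35).
#'
#' @param n_raters number of raters (default 5, a typical reading panel).
#' @param rater_biases per-rater systematic offsets in percentage points;
#'   recycled to length `n_raters`.
#' @param noise_sd rating noise standard deviation in percentage points
#'   (default 5, one grid step).
#' @param seed integer seed.
#' @return A list of class `rater_model`.
#' @export
rater_model <- function(n_raters = 5L, rater_biases = 0, noise_sd = 5,
                        seed = 1L) {
  n_raters <- as.integer(n_raters)
  if (n_raters < 1L) md_stop("n_raters must be positive",
                             "mammodensity_error_spec")
  if (noise_sd < 0) md_stop("noise_sd must be nonnegative",
                            "mammodensity_error_spec")
  structure(
    list(
      n_raters = n_raters,
      rater_biases = rep_len(as.numeric(rater_biases), n_raters),
      noise_sd = as.numeric(noise_sd),
      seed = as.integer(seed)
    ),
    class = "rater_model"
  )
}

# Nearest multiple of 5, ties rounding half away from zero (inputs are >= 0
# after clipping, so this is floor(x/5 + 0.5) * 5).
snap_to_grid <- function(x) 5 * floor(x / 5 + 0.5)

#' Simulate a radiologist rating panel
#'
#' @param true_densities vector of true density fractions in `[0, 1]`, one
#'   per subject.
#' @param model a [rater_model()].
#' @return A [rater_panel()] (subjects x raters matrix of percentages on the
#'   5%-increment grid).
#' @examples
#' simulate_rater_panel(c(0.1, 0.5), rater_model(noise_sd = 0))$ratings
#' @export
simulate_rater_panel <- function(true_densities, model = rater_model()) {
  if (length(true_densities) == 0L) {
    md_stop("true_densities must be non-empty", "mammodensity_error_spec")
  }
  if (any(true_densities < 0 | true_densities > 1)) {
    md_stop("true densities must lie in [0, 1]", "mammodensity_error_spec")
  }
  n <- length(true_densities)
  k <- model$n_raters
  with_seed(model$seed, {
    eps <- matrix(rnorm(n * k, 0, model$noise_sd), n, k)
    raw <- 100 * matrix(true_densities, n, k) +
      matrix(model$rater_biases, n, k, byrow = TRUE) + eps
    ratings <- snap_to_grid(pmin(pmax(raw, 0), 100))
    rater_panel(ratings,
                subject_ids = sprintf("S%03d", seq_len(n)),
                rater_ids = sprintf("R%d", seq_len(k)))
  })
}
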