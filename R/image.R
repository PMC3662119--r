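#' Construct a mammogram image object
#'
#' The in-memory carrier for a single-view mammogram: an integer gray-level
#' matrix plus the acquisition metadata the density pipeline depends on.
#' By package convention the pixel values are always oriented so that larger
#' value means brighter (denser) tissue; `MONOCHROME1` data are inverted at
#' ingestion (see [read_mammogram()]), never later.
#'
#' @param pixels integer matrix (rows x columns) of nonnegative gray levels.
#' @param laterality `"L"` or `"R"` (which breast; the chest wall sits on the
#'   corresponding image edge). Longer DICOM spellings such as `"LEFT"` are
#'   normalised by their first character.
#' @param view_position projection code, e.g. `"MLO"` or `"CC"`. Only MLO is
#'   supported by the segmentation pipeline.
#' @param bits_stored bit depth of the stored gray scale (8--16). The maximum
#'   representable value `2^bits_stored - 1` defines the histogram range.
#' @param photometric_interpretation `"MONOCHROME2"` (bright = dense, the
#'   normalised convention) or `"MONOCHROME1"`.
#' @param source_id free-text identifier carried into reports.
#' @return An object of class `mammogram_image`.
#' @export
mammogram_image <- function(pixels, laterality, view_position = "MLO",
                            bits_stored = 8L,
                            photometric_interpretation = "MONOCHROME2",
                            source_id = "unknown") {
  if (!is.matrix(pixels) || length(pixels) == 0L) {
    md_stop("pixels must be a non-empty matrix", "mammodensity_error_format")
  }
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || any(pixels < 0L)) {
    md_stop("pixels must be nonnegative and free of NA",
            "mammodensity_error_format")
  }
  bits_stored <- as.integer(bits_stored)
  if (bits_stored < 8L || bits_stored > 16L) {
    md_stop("bits_stored must be in 8..16", "mammodensity_error_format")
  }
  max_gray <- bitwShiftL(1L, bits_stored) - 1L
  if (any(pixels > max_gray)) {
    md_stop("pixel values exceed the stored bit depth",
            "mammodensity_error_format")
  }
  laterality <- normalize_laterality(laterality)
  structure(
    list(
      pixels = pixels,
      laterality = laterality,
      view_position = toupper(trimws(as.character(view_position))),
      bits_stored = bits_stored,
      max_gray = max_gray,
      photometric_interpretation = photometric_interpretation,
      source_id = as.character(source_id)
    ),
    class = "mammogram_image"
  )
}

# DICOM laterality values come in several spellings ("L", "LEFT", " l ");
# normalise by first character after trimming, error on anything else.
normalize_laterality <- function(x) {
  x <- toupper(trimws(as.character(x)))
  if (length(x) != 1L || nchar(x) == 0L) {
    md_stop("laterality must be a single non-empty string (L or R)",
            "mammodensity_error_metadata")
  }
  first <- substr(x, 1L, 1L)
  if (!first %in% c("L", "R")) {
    md_stop(sprintf("unrecognised laterality '%s' (expected L or R)", x),
            "mammodensity_error_metadata")
  }
  first
}

#' @export
print.mammogram_image <- function(x, ...) {
  cat(sprintf(
    "<mammogram_image> %s: %d x %d px, %d-bit, %s %s view, %s\n",
    x$source_id, nrow(x$pixels), ncol(x$pixels), x$bits_stored,
    x$laterality, x$view_position, x$photometric_interpretation
  ))
  invisible(x)
}

#' @export
dim.mammogram_image <- function(x) dim(x$pixels)

#' Mirror a mammogram left-right
#'
#' Flips the pixel columns and swaps the recorded laterality. Used internally
#' to normalise images to a chest-wall-left orientation and in equivariance
#' tests.
#'
#' @param image a [mammogram_image()].
#' @return The mirrored `mammogram_image`.
#' @export
mirror_mammogram <- function(image) {
  stopifnot(inherits(image, "mammogram_image"))
  image$pixels <- mirror_cols(image$pixels)
  image$laterality <- if (image$laterality == "L") "R" else "L"
  image
}
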