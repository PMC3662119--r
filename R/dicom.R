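# Minimal single-frame grayscale DICOM (Part 10) I/O.
#
# Scope: explicit and implicit VR little endian, uncompressed MONOCHROME1/2
# pixel data, 8- or 16-bit unsigned, single frame -- exactly what
# "For Presentation" FFDM density analysis needs.  No pre-installed R package
# provides DICOM parsing, hence this self-contained implementation.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_MG_PRES <- "1.2.840.10008.5.1.4.1.1.1.2" # digital mammography, presentation

# VRs encoded with a 2-byte length in explicit VR; everything else (OB, OW,
# UN, UT, SQ) uses the 4-byte form with 2 reserved bytes.
SHORT_VRS <- c("AE", "AS", "AT", "CS", "DA", "DS", "DT", "FL", "FD", "IS",
               "LO", "LT", "PN", "SH", "SL", "SS", "ST", "TM", "UI", "UL",
               "US")

# tag -> VR dictionary for the elements this package reads/writes (needed to
# decode implicit VR streams).
DICOM_DICT <- c(
  "0008,0016" = "UI", "0008,0018" = "UI", "0008,0060" = "CS",
  "0008,0068" = "CS", "0018,5101" = "CS", "0020,0062" = "CS",
  "0028,0002" = "US", "0028,0004" = "CS", "0028,0010" = "US",
  "0028,0011" = "US", "0028,0100" = "US", "0028,0101" = "US",
  "0028,0102" = "US", "0028,0103" = "US", "7fe0,0010" = "OW"
)

u16_raw <- function(v) {
  v <- as.integer(v)
  v[v > 32767L] <- v[v > 32767L] - 65536L
  writeBin(v, raw(), size = 2L, endian = "little")
}

u32_raw <- function(v) writeBin(as.integer(v), raw(), size = 4L,
                                endian = "little")

pad_even <- function(val, pad) {
  if (length(val) %% 2L == 1L) c(val, pad) else val
}

str_value <- function(s, vr) {
  pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
  pad_even(charToRaw(as.character(s)), pad)
}

# Encode one data element.
dcm_element <- function(group, elem, vr, value, explicit = TRUE) {
  len <- length(value)
  if (explicit) {
    if (vr %in% SHORT_VRS) {
      c(u16_raw(group), u16_raw(elem), charToRaw(vr), u16_raw(len), value)
    } else {
      c(u16_raw(group), u16_raw(elem), charToRaw(vr), as.raw(c(0L, 0L)),
        u32_raw(len), value)
    }
  } else {
    c(u16_raw(group), u16_raw(elem), u32_raw(len), value)
  }
}

#' Write a mammogram as a DICOM file
#'
#' Emits a standard Part-10 file (128-byte preamble, `DICM` magic, file meta
#' group) with uncompressed unsigned pixel data. The instance UID is derived
#' deterministically from the image content so that identical inputs produce
#' byte-identical files.
#'
#' @param image a [mammogram_image()].
#' @param path output file path.
#' @param transfer_syntax `"explicit"` (default) or `"implicit"` VR little
#'   endian.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(image, path, transfer_syntax = c("explicit",
                                                         "implicit")) {
  stopifnot(inherits(image, "mammogram_image"))
  transfer_syntax <- match.arg(transfer_syntax)
  ts_uid <- if (transfer_syntax == "explicit") TS_EXPLICIT_LE else
    TS_IMPLICIT_LE
  explicit <- transfer_syntax == "explicit"

  bits_alloc <- if (image$bits_stored > 8L) 16L else 8L
  px <- as.integer(t(image$pixels)) # DICOM is row-major
  px_raw <- if (bits_alloc == 16L) u16_raw(px) else as.raw(px)
  px_raw <- pad_even(px_raw, as.raw(0L))

  # deterministic pseudo-UID from a cheap content checksum
  chk <- (sum(as.numeric(px) * (seq_along(px) %% 997L)) %% 1e9) +
    nrow(image$pixels)
  uid <- sprintf("1.2.826.0.1.3680043.9999.%.0f", chk)

  el <- function(g, e, vr, value) dcm_element(g, e, vr, value, explicit)
  us <- function(x) u16_raw(x)

  dataset <- c(
    el(0x0008L, 0x0016L, "UI", str_value(UID_MG_PRES, "UI")),
    el(0x0008L, 0x0018L, "UI", str_value(uid, "UI")),
    el(0x0008L, 0x0060L, "CS", str_value("MG", "CS")),
    el(0x0008L, 0x0068L, "CS", str_value("FOR PRESENTATION", "CS")),
    el(0x0018L, 0x5101L, "CS", str_value(image$view_position, "CS")),
    el(0x0020L, 0x0062L, "CS", str_value(image$laterality, "CS")),
    el(0x0028L, 0x0002L, "US", us(1L)),
    el(0x0028L, 0x0004L, "CS",
       str_value(image$photometric_interpretation, "CS")),
    el(0x0028L, 0x0010L, "US", us(nrow(image$pixels))),
    el(0x0028L, 0x0011L, "US", us(ncol(image$pixels))),
    el(0x0028L, 0x0100L, "US", us(bits_alloc)),
    el(0x0028L, 0x0101L, "US", us(image$bits_stored)),
    el(0x0028L, 0x0102L, "US", us(image$bits_stored - 1L)),
    el(0x0028L, 0x0103L, "US", us(0L)),
    dcm_element(0x7FE0L, 0x0010L, if (bits_alloc == 16L) "OW" else "OB",
                px_raw, explicit)
  )

  # file meta group: always explicit VR little endian
  meta_body <- c(
    dcm_element(0x0002L, 0x0001L, "OB", as.raw(c(0L, 1L))),
    dcm_element(0x0002L, 0x0002L, "UI", str_value(UID_MG_PRES, "UI")),
    dcm_element(0x0002L, 0x0003L, "UI", str_value(uid, "UI")),
    dcm_element(0x0002L, 0x0010L, "UI", str_value(ts_uid, "UI"))
  )
  meta <- c(
    dcm_element(0x0002L, 0x0000L, "UL", u32_raw(length(meta_body))),
    meta_body
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, dataset), con)
  invisible(path)
}

rd_u16 <- function(buf, pos) {
  as.integer(buf[pos]) + 256L * as.integer(buf[pos + 1L])
}
rd_u32 <- function(buf, pos) {
  as.integer(buf[pos]) + 256 * as.integer(buf[pos + 1L]) +
    65536 * as.integer(buf[pos + 2L]) + 16777216 * as.integer(buf[pos + 3L])
}

# Parse a raw DICOM stream into a named list tag -> raw value.  Stops cleanly
# at end of buffer; unknown elements are kept as raw so callers can ignore
# them.
parse_elements <- function(buf, pos, end, explicit) {
  out <- list()
  while (pos + 7L <= end) {
    g <- rd_u16(buf, pos); e <- rd_u16(buf, pos + 2L)
    tag <- sprintf("%04x,%04x", g, e)
    if (explicit) {
      vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
      if (vr %in% SHORT_VRS) {
        len <- rd_u16(buf, pos + 6L)
        vstart <- pos + 8L
      } else {
        len <- rd_u32(buf, pos + 8L)
        vstart <- pos + 12L
      }
    } else {
      len <- rd_u32(buf, pos + 4L)
      vstart <- pos + 8L
    }
    if (len < 0 || vstart + len - 1L > end + 1L) {
      md_stop(sprintf("corrupt DICOM element at tag (%s)", tag),
              "mammodensity_error_format")
    }
    out[[tag]] <- if (len > 0L) buf[vstart:(vstart + len - 1L)] else raw(0L)
    pos <- vstart + len
  }
  list(elements = out, pos = pos)
}

dcm_string <- function(v) {
  if (is.null(v)) return(NULL)
  s <- rawToChar(v[v != as.raw(0L)])
  trimws(s)
}
dcm_us <- function(v) if (is.null(v)) NULL else rd_u16(v, 1L)

#' Read a DICOM file (low level)
#'
#' Parses a Part-10 explicit/implicit VR little-endian file into a named list
#' of raw element values keyed by `"gggg,eeee"` tags, plus the transfer
#' syntax. Most users want [read_mammogram()].
#'
#' @param path file path.
#' @return list with `elements` (named list of raw vectors) and
#'   `transfer_syntax`.
#' @export
read_dicom <- function(path) {
  if (!file.exists(path)) {
    md_stop(sprintf("file not found: %s", path), "mammodensity_error_io")
  }
  n <- file.size(path)
  buf <- readBin(path, "raw", n = n)
  if (n < 140L || rawToChar(buf[129:132]) != "DICM") {
    md_stop(sprintf("%s is not a DICOM part-10 file (no DICM magic)", path),
            "mammodensity_error_format")
  }
  pos <- 133L
  # file meta group (0002,xxxx) is always explicit VR LE; its group length
  # element tells us where the dataset starts.
  if (rd_u16(buf, pos) != 2L) {
    md_stop("missing DICOM file meta group", "mammodensity_error_format")
  }
  # (0002,0000) UL group length
  gl_len <- rd_u16(buf, pos + 6L)
  gl <- rd_u32(buf, pos + 8L)
  meta_end <- pos + 8L + gl_len + gl - 1L
  meta <- parse_elements(buf, pos, meta_end, explicit = TRUE)$elements
  ts <- dcm_string(meta[["0002,0010"]])
  explicit <- !identical(ts, TS_IMPLICIT_LE)
  ds <- parse_elements(buf, meta_end + 1L, n, explicit = explicit)$elements
  list(elements = c(meta, ds),
       transfer_syntax = if (explicit) TS_EXPLICIT_LE else TS_IMPLICIT_LE)
}

#' Read a "For Presentation" MLO mammogram from DICOM
#'
#' Reads the pixel array and the two header elements the density pipeline
#' depends on: Image Laterality `(0020,0062)` and View Position `(0018,5101)`.
#' `MONOCHROME1` images are inverted (`value -> max_gray - value`) exactly
#' once here, so all downstream code can assume bright = dense.
#'
#' @param path DICOM file path.
#' @return A [mammogram_image()].
#' @section Errors:
#' Missing `(0018,5101)` or `(0020,0062)` raises a metadata error naming the
#' element; missing pixel data raises a format error; a view position other
#' than MLO raises an unsupported-view error (craniocaudal views are out of
#' scope).
#' @export
read_mammogram <- function(path) {
  d <- read_dicom(path)
  el <- d$elements
  lat_raw <- el[["0020,0062"]]
  if (is.null(lat_raw) || length(lat_raw) == 0L) {
    md_stop("missing DICOM element (0020,0062) Image Laterality",
            "mammodensity_error_metadata")
  }
  vp_raw <- el[["0018,5101"]]
  if (is.null(vp_raw) || length(vp_raw) == 0L) {
    md_stop("missing DICOM element (0018,5101) View Position",
            "mammodensity_error_metadata")
  }
  view <- toupper(dcm_string(vp_raw))
  if (!identical(view, "MLO")) {
    md_stop(sprintf(
      "unsupported view position '%s': only MLO views are supported", view),
      "mammodensity_error_unsupported_view")
  }
  px_raw <- el[["7fe0,0010"]]
  if (is.null(px_raw) || length(px_raw) == 0L) {
    md_stop("missing pixel data (7FE0,0010)", "mammodensity_error_format")
  }
  rows <- dcm_us(el[["0028,0010"]])
  cols <- dcm_us(el[["0028,0011"]])
  bits_alloc <- dcm_us(el[["0028,0100"]])
  bits_stored <- dcm_us(el[["0028,0101"]])
  if (is.null(rows) || is.null(cols) || is.null(bits_alloc)) {
    md_stop("missing image pixel module elements (0028,0010/0011/0100)",
            "mammodensity_error_format")
  }
  if (is.null(bits_stored)) bits_stored <- bits_alloc
  photometric <- dcm_string(el[["0028,0004"]])
  if (is.null(photometric)) photometric <- "MONOCHROME2"

  vals <- if (bits_alloc > 8L) {
    readBin(px_raw, "integer", n = length(px_raw) %/% 2L, size = 2L,
            signed = FALSE, endian = "little")
  } else {
    as.integer(px_raw)
  }
  vals <- vals[seq_len(rows * cols)]
  pixels <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  max_gray <- bitwShiftL(1L, as.integer(bits_stored)) - 1L
  if (identical(photometric, "MONOCHROME1")) {
    pixels <- max_gray - pixels
    photometric <- "MONOCHROME2"
  }
  mammogram_image(
    pixels,
    laterality = dcm_string(lat_raw),
    view_position = view,
    bits_stored = bits_stored,
    photometric_interpretation = photometric,
    source_id = basename(path)
  )
}

#' Write a CSV density report
#'
#' One row per image: source id, the two candidate thresholds and the final
#' threshold, dense and ROI pixel counts, percent density (two fixed decimal
#' places) and BI-RADS category. Column order is fixed so reruns are
#' byte-identical.
#'
#' @param results a list of [compute_density()] results (class
#'   `density_result`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_density_report <- function(results, path) {
  if (length(results) == 0L) {
    md_stop("results must be non-empty", "mammodensity_error_spec")
  }
  if (inherits(results, "density_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(
      source_id = r$source_id,
      threshold_maxentropy = r$threshold_maxentropy,
      threshold_moments = r$threshold_moments,
      threshold_final = r$threshold_final,
      dense_pixels = r$dense_pixels,
      roi_pixels = r$roi_pixels,
      percent_density = sprintf("%.2f", r$percent_density),
      birads_category = r$birads_category,
      stringsAsFactors = FALSE
    )
  }))
  ok <- tryCatch({
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    md_stop(sprintf("cannot write report to %s", path),
            "mammodensity_error_io")
  }
  invisible(path)
}
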