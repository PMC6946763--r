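#' CCM image container
#'
#' A greyscale corneal confocal microscopy (CCM) raster with its physical
#' pixel pitch. Intensities are stored in `[0, 1]`; coordinates throughout
#' the package are 0-based `(row, col)` with row 0 at the top.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]` (rows = image
#'   rows, top row first).
#' @param pixel_size_um Pixel pitch in micrometres per pixel. Either a
#'   single value (isotropic) or a length-2 vector `(row pitch, col pitch)`.
#'   `NA` marks an unknown pitch.
#' @param source_id Opaque provenance string (file path, phantom id, ...).
#' @return An object of class `ccm_image` with fields `pixels`,
#'   `pixel_size_um` (always length 2), `height_px`, `width_px`, `source_id`.
#' @export
ccm_image <- function(pixels, pixel_size_um = NA_real_, source_id = "") {
  nq_check(is.matrix(pixels) && is.numeric(pixels), "pixels",
           "must be a numeric matrix")
  nq_check(nrow(pixels) > 0 && ncol(pixels) > 0, "pixels",
           "zero-sized image")
  rng <- range(pixels, na.rm = TRUE)
  nq_check(rng[1] >= -1e-9 && rng[2] <= 1 + 1e-9, "pixels",
           "intensities must lie in [0, 1]")
  if (length(pixel_size_um) == 1) pixel_size_um <- rep(pixel_size_um, 2)
  nq_check(length(pixel_size_um) == 2 &&
             all(is.na(pixel_size_um) | pixel_size_um > 0),
           "pixel_size_um", "must be positive (or NA when unknown)")
  structure(list(pixels = pmin(pmax(pixels, 0), 1),
                 pixel_size_um = as.numeric(pixel_size_um),
                 height_px = nrow(pixels), width_px = ncol(pixels),
                 source_id = as.character(source_id)),
            class = "ccm_image")
}

#' @export
print.ccm_image <- function(x, ...) {
  pitch <- if (anyNA(x$pixel_size_um)) "unknown pitch" else
    sprintf("%.4g x %.4g um/px", x$pixel_size_um[1], x$pixel_size_um[2])
  cat(sprintf("<ccm_image> %d x %d px, %s, source '%s'\n",
              x$height_px, x$width_px, pitch, x$source_id))
  invisible(x)
}

#' Binary annotation mask
#'
#' @param pixels Matrix coercible to 0/1 (e.g. a logical or 0/255 matrix;
#'   values at or above half the dynamic range become 1).
#' @param pixel_size_um Pixel pitch in micrometres per pixel.
#' @return An object of class `annotation_mask` with integer 0/1 `pixels`.
#' @export
annotation_mask <- function(pixels, pixel_size_um = NA_real_) {
  nq_check(is.matrix(pixels), "pixels", "must be a matrix")
  mx <- max(pixels, 1)
  px <- matrix(as.integer(pixels >= mx / 2), nrow(pixels), ncol(pixels))
  if (length(pixel_size_um) == 1) pixel_size_um <- rep(pixel_size_um, 2)
  structure(list(pixels = px, pixel_size_um = as.numeric(pixel_size_um)),
            class = "annotation_mask")
}

# ---- readers ---------------------------------------------------------------

# EBImage stores rasters x-major (width, height[, channels]); transpose to
# the package's (row, col) convention and collapse RGB by BT.601 luminance.
nq_read_raster <- function(path) {
  nq_check(file.exists(path), "path", sprintf("file not found: '%s'", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "bmp") return(read_bmp_grey(path))
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop(sprintf(
                    "cannot decode '%s': %s", path, conditionMessage(e)),
                    call. = FALSE))
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3) {
    nc <- dim(a)[3]
    a <- if (nc >= 3) {
      0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else {
      a[, , 1]
    }
  }
  t(a)
}

#' Load a CCM image from file
#'
#' Reads TIFF/PNG/JPG (and uncompressed 8/24-bit BMP) rasters, collapses RGB
#' to luminance, rescales to `[0, 1]` and attaches the physical pixel pitch.
#' The pitch is taken from `field_of_view_um` when supplied, else from TIFF
#' resolution metadata when present, else flagged unknown (`NA`).
#'
#' @param path Image file path.
#' @param field_of_view_um Optional length-2 vector `(width um, height um)`
#'   of the captured field of view; the pitch is `field of view / pixels`,
#'   per axis.
#' @return A [ccm_image].
#' @export
load_ccm_image <- function(path, field_of_view_um = NULL) {
  px <- nq_read_raster(path)
  nq_check(nrow(px) > 0 && ncol(px) > 0, "path", "zero-sized image")
  rng <- range(px)
  if (rng[2] > rng[1]) px <- (px - rng[1]) / (rng[2] - rng[1])
  pitch <- c(NA_real_, NA_real_)
  if (!is.null(field_of_view_um)) {
    nq_check(length(field_of_view_um) == 2 && all(field_of_view_um > 0),
             "field_of_view_um", "must be (width um, height um), positive")
    pitch <- c(field_of_view_um[2] / nrow(px), field_of_view_um[1] / ncol(px))
  } else if (tolower(tools::file_ext(path)) %in% c("tif", "tiff")) {
    pitch <- nq_tiff_pitch(path)
  }
  ccm_image(px, pitch, source_id = path)
}

# best-effort pixel pitch from TIFF resolution tags (pixels per unit)
nq_tiff_pitch <- function(path) {
  info <- tryCatch(
    attributes(tiff::readTIFF(path, info = TRUE)),
    error = function(e) NULL)
  if (is.null(info) || is.null(info$x.resolution)) return(c(NA_real_, NA_real_))
  unit.um <- switch(as.character(info$resolution.unit %||% "inch"),
                    "2" = 25400, "inch" = 25400, "3" = 10000, "cm" = 10000,
                    NA_real_)
  if (is.na(unit.um)) return(c(NA_real_, NA_real_))
  c(unit.um / (info$y.resolution %||% info$x.resolution),
    unit.um / info$x.resolution)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a binary annotation mask
#'
#' @param path Mask image file; any greyscale values are binarised at half
#'   the dynamic range (`>= 0.5` after rescaling to `[0, 1]`).
#' @param pixel_size_um Optional pixel pitch to record.
#' @return An [annotation_mask].
#' @export
load_annotation_mask <- function(path, pixel_size_um = NA_real_) {
  px <- nq_read_raster(path)
  annotation_mask(matrix(as.integer(px >= 0.5), nrow(px), ncol(px)),
                  pixel_size_um)
}

# ---- standardisation -------------------------------------------------------

#' Standardise a CCM image to the working pitch and frame
#'
#' Resamples the image by bilinear interpolation so both axes have the
#' target pixel pitch, then centre-crops (if larger) or symmetrically
#' zero-pads (if smaller) to the target square frame. Images already at the
#' target pitch and frame are returned unchanged. Morphometry in micrometres
#' needs a correct pitch, so the pitch always wins over the frame size:
#' anisotropic or off-pitch inputs are resampled first and the frame is
#' adjusted afterwards.
#'
#' @param image A [ccm_image] with known pitch on both axes.
#' @param target_pixel_um Target pitch, micrometres per pixel.
#' @param target_size_px Target frame side in pixels.
#' @return A [ccm_image] at `target_pixel_um` and
#'   `target_size_px x target_size_px`.
#' @export
standardise_ccm <- function(image, target_pixel_um = 1.04,
                            target_size_px = 384L) {
  stopifnot(inherits(image, "ccm_image"))
  nq_check(!anyNA(image$pixel_size_um), "pixel_size_um",
           "unknown pixel pitch; supply field_of_view_um when loading")
  if (all(abs(image$pixel_size_um - target_pixel_um) < 1e-9) &&
      image$height_px == target_size_px && image$width_px == target_size_px) {
    return(image)
  }
  new_h <- max(1L, as.integer(round(image$height_px *
                                      image$pixel_size_um[1] / target_pixel_um)))
  new_w <- max(1L, as.integer(round(image$width_px *
                                      image$pixel_size_um[2] / target_pixel_um)))
  px <- image$pixels
  if (new_h != image$height_px || new_w != image$width_px) {
    res <- EBImage::resize(EBImage::Image(t(px)), w = new_w, h = new_h,
                           filter = "bilinear")
    px <- t(EBImage::imageData(res))
  }
  px <- nq_crop_pad(px, target_size_px)
  ccm_image(pmin(pmax(px, 0), 1), target_pixel_um, image$source_id)
}

# centre-crop or symmetric zero-pad to a square frame; when the excess or
# deficit is odd, the extra pixel goes to the bottom/right
nq_crop_pad <- function(px, side) {
  fit <- function(m, dim_idx) {
    d <- dim(m)[dim_idx]
    if (d == side) return(m)
    if (d > side) {
      off <- (d - side) %/% 2
      idx <- seq.int(off + 1, off + side)
      if (dim_idx == 1) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
    } else {
      pre <- (side - d) %/% 2
      post <- side - d - pre
      if (dim_idx == 1) {
        rbind(matrix(0, pre, ncol(m)), m, matrix(0, post, ncol(m)))
      } else {
        cbind(matrix(0, nrow(m), pre), m, matrix(0, nrow(m), post))
      }
    }
  }
  fit(fit(px, 1), 2)
}

# ---- writers ---------------------------------------------------------------

#' Write an image or mask to an 8-bit greyscale file
#'
#' @param x A [ccm_image], [annotation_mask] or plain matrix in `[0, 1]`.
#' @param path Output path; format follows the extension (png/tiff).
#' @return `path`, invisibly.
#' @export
write_grey_image <- function(x, path) {
  px <- if (inherits(x, "ccm_image")) x$pixels
        else if (inherits(x, "annotation_mask")) x$pixels
        else x
  EBImage::writeImage(EBImage::Image(t(px)), path, bits.per.sample = 8L)
  invisible(path)
}

# ---- minimal BMP reader ----------------------------------------------------

# Uncompressed BI_RGB Windows BMPs only: 8-bit palette or 24-bit, the forms
# CCM exports use. Rows are 4-byte aligned; positive height means bottom-up.
read_bmp_grey <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 2)
  if (!identical(rawToChar(hdr), "BM")) {
    stop(sprintf("cannot decode '%s': not a BMP file", path), call. = FALSE)
  }
  readBin(con, "integer", 2, size = 4)                   # file size, reserved
  offset <- readBin(con, "integer", 1, size = 4)
  dib <- readBin(con, "integer", 1, size = 4)
  w <- readBin(con, "integer", 1, size = 4)
  h <- readBin(con, "integer", 1, size = 4)
  readBin(con, "integer", 1, size = 2)                   # planes
  bpp <- readBin(con, "integer", 1, size = 2)
  comp <- readBin(con, "integer", 1, size = 4)
  if (comp != 0 || !(bpp %in% c(8L, 24L))) {
    stop(sprintf("cannot decode '%s': only uncompressed 8/24-bit BMP supported",
                 path), call. = FALSE)
  }
  bottom_up <- h > 0
  h <- abs(h)
  pal <- NULL
  if (bpp == 8L) {
    seek(con, 14 + dib)
    ncol_pal <- (offset - 14 - dib) %/% 4
    pal_raw <- readBin(con, "raw", ncol_pal * 4)
    pal <- matrix(as.integer(pal_raw), ncol = 4, byrow = TRUE)  # B,G,R,0
    pal <- (0.299 * pal[, 3] + 0.587 * pal[, 2] + 0.114 * pal[, 1]) / 255
  }
  seek(con, offset)
  stride <- ((w * bpp %/% 8 + 3) %/% 4) * 4
  data <- readBin(con, "raw", stride * h)
  out <- matrix(0, h, w)
  for (r in seq_len(h)) {
    row_bytes <- as.integer(data[((r - 1) * stride + 1):((r - 1) * stride + w * bpp %/% 8)])
    vals <- if (bpp == 8L) {
      pal[row_bytes + 1]
    } else {
      b <- row_bytes[seq(1, length(row_bytes), 3)]
      g <- row_bytes[seq(2, length(row_bytes), 3)]
      rr <- row_bytes[seq(3, length(row_bytes), 3)]
      (0.299 * rr + 0.587 * g + 0.114 * b) / 255
    }
    out[if (bottom_up) h - r + 1 else r, ] <- vals
  }
  out
}
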