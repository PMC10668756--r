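#' Intensity image
#'
#' Container for a single-channel fluorescence micrograph. Pixels are stored
#' as an integer matrix with one row per image row, so `pixels[y + 1, x + 1]`
#' is the pixel at 0-based image coordinate `(x, y)`: the origin is the
#' top-left corner, x grows rightward and y downward.
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param bit_depth 8 or 16; all values must lie in `[0, 2^bit_depth - 1]`.
#' @return An object of class `intensity_image` with fields `pixels`,
#'   `width`, `height` and `bit_depth`.
#' @examples
#' img <- intensity_image(matrix(0L, 4, 6), bit_depth = 8)
#' img$width   # 6
#' @export
intensity_image <- function(pixels, bit_depth = 8L) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  px <- round(pixels)
  attributes(px) <- list(dim = dim(px))   # drop reader metadata attributes
  maxval <- 2^bit_depth - 1
  if (any(px < 0) || any(px > maxval)) {
    stop(sprintf("pixel values must lie in [0, %d]", maxval))
  }
  storage.mode(px) <- "integer"
  structure(
    list(pixels = px, width = ncol(px), height = nrow(px),
         bit_depth = as.integer(bit_depth)),
    class = "intensity_image"
  )
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %d x %d px, %d-bit, range [%d, %d]\n",
              x$width, x$height, x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.intensity_image <- function(x) dim(x$pixels)

max_intensity <- function(image) 2^image$bit_depth - 1

stop_io <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cometseg_error")))
}

#' Read a grayscale image
#'
#' Reads an 8- or 16-bit grayscale TIFF or PNG. RGB(A) inputs whose colour
#' channels are identical are collapsed to a single channel; a constant alpha
#' channel is dropped. Genuinely multichannel images are rejected.
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @return An [intensity_image].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path), "cometseg_io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    raw <- tryCatch(tiff::readTIFF(path, info = TRUE, as.is = TRUE),
                    error = function(e) stop_io(sprintf("cannot read TIFF '%s': %s", path, conditionMessage(e)),
                                                "cometseg_io_error"))
    depth <- attr(raw, "bits.per.sample")
    if (is.null(depth)) depth <- 8L
    px <- collapse_channels(raw, path)
    # as.is only applies to single-channel data; doubles are [0, 1] scaled
    if (!is.integer(px)) px <- round(px * (2^depth - 1))
  } else if (ext == "png") {
    raw <- tryCatch(png::readPNG(path),
                    error = function(e) stop_io(sprintf("cannot read PNG '%s': %s", path, conditionMessage(e)),
                                                "cometseg_io_error"))
    depth <- png_bit_depth(path)
    px <- collapse_channels(raw, path)
    px <- round(px * (2^depth - 1))
  } else {
    stop_io(sprintf("unsupported image format '.%s' (use TIFF or PNG)", ext),
            "cometseg_format_error")
  }
  if (!depth %in% c(8, 16)) {
    stop_io(sprintf("unsupported bit depth %s in '%s'", depth, path), "cometseg_format_error")
  }
  intensity_image(px, bit_depth = as.integer(depth))
}

# PNG stores the bit depth in byte 25 of the file (first byte of the IHDR
# data after width and height).
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  if (length(hdr) < 26L) stop_io(sprintf("truncated PNG '%s'", path), "cometseg_io_error")
  as.integer(hdr[25L])
}

collapse_channels <- function(raw, path) {
  if (is.matrix(raw)) return(raw)
  if (length(dim(raw)) != 3L) {
    stop_io(sprintf("unsupported image layout in '%s'", path), "cometseg_format_error")
  }
  nch <- dim(raw)[3L]
  if (nch %in% c(2L, 4L)) raw <- raw[, , -nch, drop = FALSE]  # drop alpha
  nch <- dim(raw)[3L]
  if (nch == 1L) return(raw[, , 1L])
  first <- raw[, , 1L]
  for (k in 2:nch) {
    if (any(raw[, , k] != first)) {
      stop_io(sprintf("'%s' is multichannel with non-identical channels", path),
              "cometseg_format_error")
    }
  }
  first
}

#' Write an intensity image
#'
#' Writes TIFF at the image's own bit depth; PNG output is 8-bit only.
#'
#' @param image an [intensity_image].
#' @param path destination ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "intensity_image"))
  ext <- tolower(tools::file_ext(path))
  scaled <- image$pixels / max_intensity(image)
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = image$bit_depth)
  } else if (ext == "png") {
    if (image$bit_depth != 8L) {
      stop_io("PNG output is 8-bit only; use TIFF for 16-bit images", "cometseg_format_error")
    }
    png::writePNG(scaled, path)
  } else {
    stop_io(sprintf("unsupported output format '.%s'", ext), "cometseg_format_error")
  }
  invisible(path)
}

#' Write a head/tail label mask as 8-bit PNG
#'
#' Encodes background as 0, head pixels as 1, and tail pixels as 2.
#'
#' @param head,tail logical matrices of equal dimensions (tail may be NULL).
#' @param path destination `.png` path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(head, tail, path) {
  lab <- matrix(0L, nrow(head), ncol(head))
  if (!is.null(tail)) {
    if (!all(dim(tail) == dim(head))) stop("head and tail mask dimensions differ")
    lab[tail] <- 2L
  }
  lab[head] <- 1L
  png::writePNG(lab / 255, path)
  invisible(path)
}

#' Read a head/tail label mask written by [write_label_mask()]
#'
#' @param path a label PNG (0 = background, 1 = head, 2 = tail).
#' @return list with logical matrices `head` and `tail`.
#' @export
read_label_mask <- function(path) {
  lab <- round(png::readPNG(path) * 255)
  if (length(dim(lab)) == 3L) lab <- lab[, , 1L]
  list(head = lab == 1, tail = lab == 2)
}
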