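# Images are plain numeric arrays dim = c(height, width, 3), values in [0, 1],
# origin top-left, x right / y down. Pixel (r, c) (1-based) covers the unit
# square [c-1, c) x [r-1, r) in continuous image coordinates, so its center is
# (c - 0.5, r - 0.5). EBImage stores (x, y, channel); convert at the boundary.

#' Read an RGB image
#'
#' Reads PNG, JPEG or TIFF into a numeric `height x width x 3` array with
#' values in `[0, 1]` (origin top-left). Grayscale input is expanded to three
#' identical channels; an alpha channel is dropped.
#'
#' @param path Path to a PNG/JPEG/TIFF file.
#' @return A numeric array `c(height, width, 3)`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("image file not found: ", path), class = "gridquant_missing_input")
  }
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) abort(paste0("unreadable image: ", path, " (", conditionMessage(e), ")"),
                                            class = "gridquant_unreadable_image"))
  from_ebimage(img)
}

#' Write an RGB image
#'
#' Writes to PNG (lossless), JPEG or TIFF, chosen by file extension.
#'
#' @param image A numeric `height x width x 3` array in `[0, 1]`.
#' @param path Output path ending in .png, .jpg/.jpeg or .tif/.tiff.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  check_rgb(image)
  EBImage::writeImage(as_ebimage(image), path)
  invisible(path)
}

check_rgb <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3) {
    abort("expected an RGB raster: a numeric array of dim c(height, width, 3)",
          class = "gridquant_bad_image")
  }
  invisible(image)
}

as_ebimage <- function(image) {
  EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color")
}

from_ebimage <- function(img) {
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 2) {
    dat <- array(rep(dat, 3), dim = c(dim(dat), 3))
  } else if (dim(dat)[3] > 3) {
    dat <- dat[, , 1:3, drop = FALSE]
  } else if (dim(dat)[3] == 1) {
    dat <- array(rep(dat[, , 1], 3), dim = c(dim(dat)[1:2], 3))
  }
  out <- aperm(dat, c(2, 1, 3))
  pmin(pmax(out, 0), 1)
}

# Relative luminance (Rec. 709 weights) of an RGB array -> height x width matrix.
luminance <- function(image) {
  0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3]
}

# 1-based pixel index ranges whose centers fall in the half-open rectangle
# [x0, x1) x [y0, y1), clipped to a width x height image.
pixel_range <- function(lo, hi, n_pix) {
  eps <- 1e-9
  from <- max(1L, as.integer(ceiling(lo + 0.5 - eps)))
  to <- min(n_pix, as.integer(ceiling(hi + 0.5 - eps)) - 1L)
  if (to < from) integer(0) else from:to
}
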