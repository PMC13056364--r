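#' Single-channel micrograph container
#'
#' A thin S3 wrapper around a numeric pixel matrix carrying the bit depth and
#' a channel label (`"fish"` or `"streptavidin"`). All image operations in
#' the package also accept a bare matrix; the wrapper exists so files read
#' from disk remember their provenance.
#'
#' @param pixels Numeric matrix of nonnegative, finite intensities
#'   (rows = image rows).
#' @param bit_depth One of `8`, `16`, or `"float"`.
#' @param channel_label Free-text label, conventionally `"fish"` or
#'   `"streptavidin"`.
#' @return An `image_channel` object (a matrix with attributes).
#' @examples
#' img <- image_channel(matrix(runif(64), 8, 8), "float", "fish")
#' @export
image_channel <- function(pixels, bit_depth = "float", channel_label = "") {
  pixels <- as_pixels(pixels)
  if (!bit_depth %in% list(8, 16, "8", "16", "float")) {
    stop2("bit_depth must be 8, 16 or \"float\"")
  }
  structure(pixels,
            bit_depth = as.character(bit_depth),
            channel_label = channel_label,
            class = c("image_channel", class(pixels)))
}

# Coerce an image argument to a validated plain matrix.
as_pixels <- function(image) {
  if (inherits(image, "Image")) image <- EBImage::imageData(image)
  x <- unclass(image)
  attributes(x) <- attributes(x)["dim"]
  if (!is.matrix(x) || !is.numeric(x)) {
    stop2("image must be a 2-D numeric matrix")
  }
  if (any(!is.finite(x))) stop2("image intensities must be finite")
  if (any(x < 0)) stop2("image intensities must be nonnegative")
  x
}

#' @export
print.image_channel <- function(x, ...) {
  cat(sprintf("<image_channel %s> %d x %d px, bit depth %s, range [%g, %g]\n",
              attr(x, "channel_label"), nrow(x), ncol(x),
              attr(x, "bit_depth"), min(x), max(x)))
  invisible(x)
}

#' Read a grayscale image channel from TIFF or PNG
#'
#' @param path Path to a single-plane grayscale TIFF or PNG file.
#' @param channel_label Label stored on the returned object.
#' @return An [image_channel()]. Intensities are kept on the `[0, 1]` scale
#'   EBImage uses; the declared bit depth is `"float"`.
#' @export
read_channel <- function(path, channel_label = "") {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) > 2L) {
    # collapse trivial extra planes (grayscale images written with a
    # singleton frame dimension)
    dat <- dat[, , 1]
  }
  image_channel(dat, "float", channel_label)
}

#' Write an image channel to disk
#'
#' Images are written as single-channel 16-bit TIFF; boolean masks as 8-bit
#' PNG with foreground = 255.
#'
#' @param image An [image_channel()], matrix, or logical mask matrix.
#' @param path Output path; the extension (`.tif`/`.tiff` or `.png`) selects
#'   the format.
#' @return `path`, invisibly.
#' @export
write_channel <- function(image, path) {
  if (is.logical(image)) {
    x <- matrix(as.numeric(image), nrow(image), ncol(image))
  } else {
    x <- as_pixels(image)
    rng <- range(x)
    if (rng[2] > rng[1]) x <- (x - rng[1]) / (rng[2] - rng[1])
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    EBImage::writeImage(EBImage::Image(x), path, type = "tiff",
                        bits.per.sample = 16L)
  } else if (ext == "png") {
    EBImage::writeImage(EBImage::Image(x), path, type = "png",
                        bits.per.sample = 8L)
  } else {
    stop2("unsupported image extension: ", ext)
  }
  invisible(path)
}
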