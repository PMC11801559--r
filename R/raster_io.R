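#' Construct a raw grayscale image
#'
#' A `raw_image` is the package's I/O boundary type: an integer pixel matrix
#' together with its bit depth and observed maximum intensity. All enhancement
#' code operates on normalized `[0, 1]` matrices obtained via [normalize_image()].
#'
#' @param pixels integer-valued matrix of non-negative intensities.
#' @param bit_depth 8 or 16.
#' @return An object of class `raw_image`: a list with elements `pixels`
#'   (integer matrix), `bit_depth`, and `max_value` (the observed maximum,
#'   the denominator used by per-image-max normalization).
#' @export
raw_image <- function(pixels, bit_depth = 8L) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("image must be at least 2x2", call. = FALSE)
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16", call. = FALSE)
  px <- round(pixels)
  if (any(!is.finite(px))) stop("pixels must be finite", call. = FALSE)
  lim <- 2^bit_depth - 1
  if (any(px < 0) || any(px > lim))
    stop(sprintf("pixels must lie in [0, %d]", lim), call. = FALSE)
  storage.mode(px) <- "integer"
  attributes(px) <- list(dim = dim(px))   # drop codec metadata (e.g. PNG info)
  structure(
    list(pixels = px, bit_depth = bit_depth, max_value = max(px)),
    class = "raw_image"
  )
}

#' @export
print.raw_image <- function(x, ...) {
  cat(sprintf("<raw_image> %d x %d, %d-bit, max %d\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$max_value))
  invisible(x)
}

#' @export
dim.raw_image <- function(x) dim(x$pixels)

is_raw_image <- function(x) inherits(x, "raw_image")

# ---- codecs ------------------------------------------------------------

read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stop("only plain-text (P2) PGM is supported", call. = FALSE)
  nums <- as.numeric(toks[-1])
  w <- nums[1]; h <- nums[2]; maxval <- nums[3]
  px <- matrix(nums[-(1:3)], nrow = h, ncol = w, byrow = TRUE)
  raw_image(px, bit_depth = if (maxval > 255) 16L else 8L)
}

write_pgm <- function(image, path) {
  stopifnot(is_raw_image(image))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image$pixels), nrow(image$pixels)),
               as.character(2^image$bit_depth - 1)), con)
  apply(image$pixels, 1L, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

#' Read a grayscale raster image
#'
#' Supported formats: PNG (8- or 16-bit, via the png package), JPEG, and
#' plain-text PGM (P2). Multi-channel inputs are converted to luminance by
#' channel averaging (some radiograph archives store grayscale as 3-channel).
#'
#' @param path file path; format inferred from extension.
#' @return A [raw_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(read_pgm(path))
  arr <- switch(ext,
    png = png::readPNG(path, info = TRUE),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop(sprintf("unsupported image format: .%s (png/jpeg/pgm supported)", ext),
         call. = FALSE)
  )
  bit_depth <- 8L
  if (ext == "png") {
    # png::readPNG rescales to [0,1] by 2^depth - 1; recover the integer grid
    info <- attr(arr, "info")
    if (!is.null(info) && isTRUE(info$bit.depth == 16)) bit_depth <- 16L
  }
  if (length(dim(arr)) == 3L) arr <- rowMeans(arr, dims = 2L)
  raw_image(round(arr * (2^bit_depth - 1)), bit_depth = bit_depth)
}

#' Write a raw image to disk
#'
#' 8-bit images write losslessly to PNG or plain-text PGM (P2); 16-bit images
#' write to PGM only (the available PNG encoder is 8-bit).
#'
#' @param image a [raw_image()].
#' @param path destination; `.png` or `.pgm`.
#' @export
write_image <- function(image, path) {
  stopifnot(is_raw_image(image))
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(write_pgm(image, path))
  if (ext != "png") stop("write_image supports .png and .pgm", call. = FALSE)
  if (image$bit_depth == 16L)
    stop("16-bit output must use .pgm (PNG encoder is 8-bit)", call. = FALSE)
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' Normalize a raw image to [0, 1]
#'
#' Divides by the image's own observed maximum (so the result attains exactly
#' 1 somewhere), which makes the enhancement invariant to global exposure
#' scaling. Set `by_depth = TRUE` to divide by the bit-depth maximum instead.
#'
#' @param image a [raw_image()].
#' @param by_depth divide by `2^bit_depth - 1` rather than the observed max.
#' @return Numeric matrix in `[0, 1]`.
#' @export
normalize_image <- function(image, by_depth = FALSE) {
  stopifnot(is_raw_image(image))
  if (image$max_value <= 0L)
    stop("cannot normalize an all-zero image", call. = FALSE)
  denom <- if (by_depth) 2^image$bit_depth - 1 else image$max_value
  image$pixels / denom
}

#' Quantize a normalized image to 8 bits
#'
#' Maps `[0, 1]` to `[0, 255]` by `round(values * 255)` with no re-stretching,
#' so a stage whose output maximum is below 1 keeps a sub-255 maximum in the
#' saved file. Rounding is half away from zero (bit-exact contract for tests).
#'
#' @param values numeric matrix in `[0, 1]`.
#' @return A [raw_image()] with `bit_depth = 8`.
#' @export
to_octet <- function(values) {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite values", call. = FALSE)
  if (any(values < 0) || any(values > 1))
    stop("values must lie in [0, 1]", call. = FALSE)
  x <- values * 255
  # round half away from zero (values are non-negative here)
  raw_image(floor(x + 0.5), bit_depth = 8L)
}

assert_norm <- function(values, what = "image") {
  if (!is.matrix(values) || !is.numeric(values))
    stop(sprintf("%s must be a numeric matrix", what), call. = FALSE)
  if (any(!is.finite(values)))
    stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  if (any(values < 0) || any(values > 1))
    stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  invisible(values)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Coerce raw_image / matrix input to the 0-255 intensity scale used by the
# no-reference metrics. Normalized matrices are scaled by 255; raw 8-bit
# pixels pass through; raw 16-bit pixels are rescaled to the 8-bit range.
as_octet_scale <- function(image) {
  if (is_raw_image(image)) {
    px <- image$pixels
    if (image$bit_depth == 16L) px <- px * (255 / 65535)
    return(px)
  }
  assert_norm(image)
  image * 255
}
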