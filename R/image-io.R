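#' Read a single-channel 8-bit grayscale image
#'
#' Reads a PNG or TIFF file into an integer matrix of gray levels in
#' `[0, 255]`. Multi-channel (RGB/RGBA) files are rejected rather than
#' silently converted, and inputs that are not 8-bit are rejected.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return An integer matrix with values in `[0, 255]`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L && dim(a)[3] > 1L) {
      abort("multi-channel image: expected a single-channel grayscale PNG")
    }
    x <- a * 255
    if (max(abs(x - round(x))) > 1e-6) {
      abort("not an 8-bit image: intensities do not map onto 0..255")
    }
    img <- round(x)
  } else if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(a)) == 3L && dim(a)[3] > 1L) {
      abort("multi-channel image: expected a single-channel grayscale TIFF")
    }
    if (max(a) > 255 || min(a) < 0) {
      abort("not an 8-bit image: intensities outside 0..255")
    }
    img <- a
  } else {
    abort(paste0("unsupported image format: .", ext, " (use PNG or TIFF)"))
  }
  img <- matrix(as.integer(img), nrow = nrow(img), ncol = ncol(img))
  validate_gray_image(img)
  img
}

#' Validate a grayscale image matrix
#'
#' Checks the invariants assumed throughout the package: a non-empty numeric
#' matrix of integer-valued intensities in `[0, L-1]`.
#'
#' @param image A matrix of gray levels.
#' @param L Number of gray levels (default 256).
#' @return The image, invisibly, as an integer matrix.
#' @export
validate_gray_image <- function(image, L = 256L) {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort("image must be a numeric matrix")
  }
  if (length(image) == 0L) {
    abort("empty input")
  }
  if (anyNA(image) || any(!is.finite(image))) {
    abort("image contains missing or non-finite values")
  }
  if (any(image != trunc(image))) {
    abort("image intensities must be integers")
  }
  if (min(image) < 0 || max(image) > L - 1) {
    abort(sprintf("image intensities must lie in [0, %d]", L - 1L))
  }
  invisible(matrix(as.integer(image), nrow(image), ncol(image)))
}

#' Write a binary mask as an 8-bit PNG
#'
#' Object pixels (`TRUE`) are written as 255, background as 0.
#'
#' @param mask A logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.matrix(mask), is.logical(mask))
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Write a grayscale image matrix as an 8-bit PNG
#'
#' @param image An integer matrix with values in `[0, 255]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(image, path) {
  image <- validate_gray_image(image)
  png::writePNG(image / 255, path)
  invisible(path)
}
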