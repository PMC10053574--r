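#' Validate a radiograph image matrix
#'
#' Internal checks shared by every pipeline stage: a radiograph is a finite
#' numeric matrix of at least 8 x 8 pixels with intensities in \[0, 1\].
#'
#' @param x object to validate.
#' @param min_dim minimum number of rows and columns.
#' @param arg name used in error messages.
#' @return `x`, invisibly, if valid.
#' @keywords internal
assert_radiograph <- function(x, min_dim = 8L, arg = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (nrow(x) < min_dim || ncol(x) < min_dim) {
    stop(sprintf("`%s` must be at least %d x %d pixels (got %d x %d)",
                 arg, min_dim, min_dim, nrow(x), ncol(x)), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  if (min(x) < -1e-12 || max(x) > 1 + 1e-12) {
    stop(sprintf("`%s` must be normalized to [0, 1] (range %.4g..%.4g)",
                 arg, min(x), max(x)), call. = FALSE)
  }
  invisible(x)
}

#' Min-max normalize intensities to \[0, 1\]
#'
#' Linear rescale `(v - min) / (max - min)`. A constant image maps to all
#' zeros (degenerate range); the operation is idempotent on already
#' normalized images.
#'
#' @param x numeric matrix.
#' @return matrix of the same shape with values in \[0, 1\].
#' @export
#' @examples
#' normalize_intensity(matrix(c(0, 65535), 8, 8))[1, 1:2]
normalize_intensity <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (!all(is.finite(x))) stop("image contains non-finite values", call. = FALSE)
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) {
    warning("degenerate intensity range (constant image); mapped to all zeros",
            call. = FALSE)
    return(array(0, dim(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Read a radiograph from TIFF or PNG
#'
#' Reads a single-channel (or RGB, collapsed to luminance with a warning)
#' image and min-max normalizes it to \[0, 1\]. The original value range is
#' attached as attributes `orig_min` / `orig_max`.
#'
#' @param path file path; format decided by extension (`.tif`, `.tiff`,
#'   `.png`).
#' @return numeric matrix in \[0, 1\].
#' @export
read_radiograph <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format '", ext, "' for ", path, call. = FALSE))
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3] >= 3L) {
      warning("RGB input collapsed to luminance (Rec. 601): ", path, call. = FALSE)
      raw <- 0.299 * raw[, , 1] + 0.587 * raw[, , 2] + 0.114 * raw[, , 3]
    } else {
      raw <- raw[, , 1]
    }
  }
  if (length(raw) == 0L || is.null(dim(raw))) {
    stop("zero-area or non-2D image: ", path, call. = FALSE)
  }
  raw <- matrix(as.numeric(raw), nrow(raw), ncol(raw))
  out <- suppressWarnings(normalize_intensity(raw))
  if (diff(range(raw)) <= 0) {
    warning("degenerate intensity range in ", path, "; mapped to all zeros",
            call. = FALSE)
  }
  attr(out, "orig_min") <- min(raw)
  attr(out, "orig_max") <- max(raw)
  out
}

#' Write a radiograph to TIFF or PNG
#'
#' Values are clipped to \[0, 1\]. TIFF output is 16-bit by default
#' (preserving the enhanced image's dynamic range) or 32-bit with
#' `float = TRUE`; PNG output is 16-bit.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param path output path (`.tif`/`.tiff`/`.png`).
#' @param float write 32-bit high-precision TIFF instead of 16-bit.
#' @return `path`, invisibly.
#' @export
write_radiograph <- function(image, path, float = FALSE) {
  assert_radiograph(image)
  img <- pmin(pmax(image, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(img, path,
      bits.per.sample = if (float) 32L else 16L,
      reduce = TRUE),
    png = png::writePNG(img, path),
    stop("unsupported image format '", ext, "' for ", path, call. = FALSE))
  invisible(path)
}

#' Bundle the three contrast channels of one acquisition
#'
#' The AC (attenuation), DPC (differential phase) and DFC (dark-field)
#' channels of a grating-interferometry acquisition are retrieved
#' simultaneously from the same detector, so they share one shape and need
#' no registration.
#'
#' @param ac,dpc,dfc numeric matrices in \[0, 1\], all the same shape.
#' @return an object of class `tri_contrast` (a named list).
#' @export
tri_contrast <- function(ac, dpc, dfc) {
  assert_radiograph(ac)
  assert_radiograph(dpc)
  assert_radiograph(dfc)
  if (!all(dim(ac) == dim(dpc)) || !all(dim(ac) == dim(dfc))) {
    stop("AC, DPC and DFC must share one shape (co-registered channels)",
         call. = FALSE)
  }
  structure(list(ac = ac, dpc = dpc, dfc = dfc), class = "tri_contrast")
}

#' @export
print.tri_contrast <- function(x, ...) {
  cat(sprintf("<tri_contrast> %d x %d (AC / DPC / DFC)\n",
              nrow(x$ac), ncol(x$ac)))
  invisible(x)
}

as_tri_contrast <- function(x) {
  if (inherits(x, "tri_contrast")) return(x)
  if (is.list(x) && all(c("ac", "dpc", "dfc") %in% names(x))) {
    return(tri_contrast(x$ac, x$dpc, x$dfc))
  }
  stop("cannot interpret input as a tri-contrast set", call. = FALSE)
}
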