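#' Calibrated 2D grayscale image
#'
#' Container for a single-channel intensity raster with a physical pixel
#' scale and an imaging modality tag. Intensities are stored as doubles in
#' `[0, 1]` (8- and 16-bit files are rescaled on load). The coordinate
#' convention throughout the package is: origin at the top-left pixel
#' center, `x` increases along columns (rightward), `y` along rows
#' (downward), both zero-based; pixel `(x, y)` is matrix element
#' `pixels[y + 1, x + 1]`. All geometry is in pixel units; conversion to
#' micrometres happens only in the metrics layer.
#'
#' @param pixels numeric matrix (rows = height, columns = width) of finite,
#'   non-negative intensities.
#' @param scale_um_per_px positive pixel size in micrometres per pixel.
#' @param modality `"fluorescent"` or `"phase"`.
#' @param id image identifier string.
#' @return An object of class `image2d`: a list with fields `pixels`,
#'   `scale_um_per_px`, `modality`, `id`.
#' @export
image2d <- function(pixels, scale_um_per_px, modality = c("fluorescent", "phase"),
                    id = "image") {
  modality <- match.arg(modality)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_validation("pixels must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop_validation("image must have width >= 1 and height >= 1")
  if (!all(is.finite(pixels)))
    stop_validation("all intensities must be finite")
  if (any(pixels < 0))
    stop_validation("all intensities must be non-negative")
  assert_scalar_number(scale_um_per_px, "scale_um_per_px", lower = 0,
                       strict_lower = TRUE)
  structure(
    list(pixels = pixels, scale_um_per_px = scale_um_per_px,
         modality = modality, id = as.character(id)),
    class = "image2d"
  )
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d '%s'> %d x %d px, %.4g um/px, %s\n",
              x$id, ncol(x$pixels), nrow(x$pixels), x$scale_um_per_px,
              x$modality))
  invisible(x)
}

image_width <- function(image) ncol(image$pixels)
image_height <- function(image) nrow(image$pixels)

#' Ordered stack of same-shape image slices
#'
#' @param slices list of numeric matrices, all with identical dimensions.
#' @param scale_um_per_px positive pixel size in micrometres per pixel.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(slices, scale_um_per_px) {
  if (!is.list(slices) || length(slices) < 1L)
    stop_validation("a stack needs at least one slice")
  dims <- lapply(slices, dim)
  if (any(vapply(slices, function(s) !is.matrix(s) || !is.numeric(s), TRUE)))
    stop_validation("all slices must be numeric matrices")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop_validation("all slices must share identical dimensions")
  assert_scalar_number(scale_um_per_px, "scale_um_per_px", lower = 0,
                       strict_lower = TRUE)
  structure(list(slices = slices, scale_um_per_px = scale_um_per_px),
            class = "image_stack")
}

# Collapse an array read from disk to a single-channel matrix by luminance
# average over channels; already-2D input passes through.
collapse_channels <- function(arr) {
  if (is.matrix(arr)) return(arr)
  if (length(dim(arr)) == 3L) {
    nchan <- dim(arr)[3]
    # Alpha channel (4th plane of RGBA) is not luminance; drop it.
    if (nchan == 4L) arr <- arr[, , 1:3, drop = FALSE]
    return(apply(arr, c(1, 2), mean))
  }
  stop_validation("unsupported raster dimensionality: ",
                  paste(dim(arr), collapse = "x"))
}

#' Read a grayscale image from PNG or TIFF
#'
#' Multi-channel rasters are collapsed to one channel by averaging the
#' color channels (alpha, when present, is dropped). The physical pixel
#' scale is always supplied by the caller, never inferred from file
#' metadata.
#'
#' @param path path to a PNG or TIFF file.
#' @param scale_um_per_px positive pixel size in micrometres per pixel.
#' @param modality `"fluorescent"` or `"phase"`.
#' @param id image identifier; defaults to the file name without extension.
#' @return An [image2d] object with intensities in `[0, 1]`.
#' @export
load_image <- function(path, scale_um_per_px,
                       modality = c("fluorescent", "phase"), id = NULL) {
  modality <- match.arg(modality)
  if (!file.exists(path))
    stop_io("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           tif = ,
           tiff = tiff::readTIFF(path),
           stop_io("unsupported image format '", ext, "' for ", path)),
    error = function(e) stop_io("failed to read ", path, ": ",
                                conditionMessage(e))
  )
  px <- collapse_channels(arr)
  if (length(px) == 0L || nrow(px) < 1L || ncol(px) < 1L)
    stop_validation("zero-size raster in ", path)
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  image2d(px, scale_um_per_px, modality, id)
}

#' Read a multi-page TIFF as an image stack
#'
#' @inheritParams load_image
#' @return An [image_stack].
#' @export
load_stack <- function(path, scale_um_per_px) {
  if (!file.exists(path))
    stop_io("cannot read stack: no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop_io("failed to read ", path, ": ",
                                                conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  image_stack(lapply(pages, collapse_channels), scale_um_per_px)
}

#' Write an image to PNG
#'
#' Intensities are clipped to `[0, 1]` before writing.
#'
#' @param image an [image2d].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path) {
  stopifnot(inherits(image, "image2d"))
  px <- pmin(pmax(image$pixels, 0), 1)
  png::writePNG(px, path)
  invisible(path)
}

#' Maximum-intensity projection of an image stack
#'
#' Each output pixel is the maximum over slices at that position, the
#' standard flattening of a confocal z-stack before 2D analysis.
#'
#' @param stack an [image_stack].
#' @param modality modality tag for the projected image.
#' @param id identifier for the projected image.
#' @return An [image2d].
#' @export
max_projection <- function(stack, modality = c("fluorescent", "phase"),
                           id = "projection") {
  modality <- match.arg(modality)
  if (!inherits(stack, "image_stack"))
    stop_validation("stack must be an image_stack")
  px <- Reduce(pmax, stack$slices)
  image2d(px, stack$scale_um_per_px, modality, id)
}

#' Global histogram equalization
#'
#' Maps each intensity through the empirical cumulative distribution of the
#' image's own values, spreading the observed range over the full `[0, 1]`
#' output range. This is the classical global equalization used to
#' intensify low-contrast features before annotation and detection; it is a
#' monotone non-decreasing transform of intensity ranks, so it never
#' reorders pixels. Images whose observed values occupy only part of a
#' 16-bit nominal range are equalized over the observed values, which
#' handles low-occupancy confocal exports without special casing.
#'
#' @param image an [image2d].
#' @return An [image2d] with the same shape, scale, modality and id. A
#'   constant image is returned unchanged with a warning (no contrast to
#'   equalize).
#' @export
equalize_histogram <- function(image) {
  stopifnot(inherits(image, "image2d"))
  px <- image$pixels
  rng <- range(px)
  if (rng[1] == rng[2]) {
    warning("constant image: histogram equalization is a no-op")
    return(image)
  }
  # Empirical CDF evaluated at each pixel; values land in (0, 1] with the
  # maximum mapped to exactly 1.
  out <- matrix(stats::ecdf(px)(px), nrow = nrow(px))
  image2d(out, image$scale_um_per_px, image$modality, image$id)
}
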