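#' Binary region mask
#'
#' A single-channel binary raster (tumor-cluster or T-cell mask) with its
#' calibration. Pixels are addressed with 0-based coordinates, origin at the
#' top-left, x rightward and y downward; internally the raster is stored as
#' an integer matrix indexed `[x + 1, y + 1]`.
#'
#' @param raster Integer/logical matrix, nonzero = foreground, indexed
#'   `[x + 1, y + 1]`.
#' @param role `"tumor"` or `"tcell"`.
#' @param calibration A [calibration()].
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(raster, role = c("tumor", "tcell"),
                        calibration = peristroma::calibration()) {
  role <- match.arg(role)
  stopifnot(is.matrix(raster), inherits(calibration, "calibration"))
  r <- matrix(as.integer(raster != 0), nrow = nrow(raster))
  structure(list(raster = r, role = role, calibration = calibration),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("region_mask (%s): %d x %d px, %d foreground px (%.3g%%), %.4g um/px\n",
              x$role, nrow(x$raster), ncol(x$raster), sum(x$raster),
              100 * mean(x$raster), x$calibration$microns_per_pixel))
  invisible(x)
}

#' Read a binary mask from a single-channel PNG or TIFF
#'
#' Any nonzero pixel is foreground. Multi-channel rasters are rejected.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param calibration A [calibration()].
#' @param role Mask role, `"tumor"` or `"tcell"`.
#' @return A [region_mask()].
#' @export
read_mask <- function(path, calibration = peristroma::calibration(),
                      role = c("tumor", "tcell")) {
  role <- match.arg(role)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported mask format: .", ext, " (use PNG or TIFF)"))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) img <- img[, , 1] else
      stop("multi-channel raster: masks must be single-channel")
  }
  if (length(dim(img)) != 2L) stop("unsupported raster layout")
  if (length(img) == 0L) stop("empty raster")
  # file rasters are [row = y, col = x]; internal storage is [x, y]
  region_mask(t(img != 0), role = role, calibration = calibration)
}

#' Write a binary mask to PNG or TIFF
#'
#' @param mask A [region_mask()] (or plain binary matrix in `[x, y]` layout).
#' @param path Output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  r <- if (inherits(mask, "region_mask")) mask$raster else mask
  img <- t(r != 0) * 1.0           # [y, x] layout, values 0/1
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop("unsupported mask format: .", ext))
  invisible(path)
}

# Pixel area of a mask/level set in mm^2.
px_to_mm2 <- function(n_px, cal) n_px * (cal$microns_per_pixel / 1000)^2
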