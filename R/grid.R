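#' Raster grid specification
#'
#' Describes the common grid every raster of a scene must share: pixel
#' counts, pixel size in metres, a coordinate reference identifier, the
#' lower-left corner of the grid, and the nodata sentinel used on disk.
#' Registration is pixel-centre, rows run top to bottom (row 1 is the
#' northernmost row), matching the dominant raster convention.
#'
#' @param width,height Pixel counts, positive integers.
#' @param pixel_size Pixel edge length in metres (default 30, the optical
#'   band resolution of Landsat 8/9).
#' @param crs_id Coordinate reference identifier string, e.g. an EPSG code.
#' @param xll,yll Coordinates of the lower-left corner of the grid.
#' @param nodata Sentinel value written to file for invalid pixels.
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(100, 80)
#' @export
grid_spec <- function(width, height, pixel_size = 30,
                      crs_id = "EPSG:32644", xll = 0, yll = 0,
                      nodata = -9999) {
  width <- as.integer(width); height <- as.integer(height)
  if (width <= 0L || height <= 0L)
    stop("grid dimensions must be positive", call. = FALSE)
  if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  structure(
    list(width = width, height = height, pixel_size = pixel_size,
         crs_id = crs_id, xll = xll, yll = yll, nodata = nodata),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d px, %g m, %s, origin (%g, %g)\n",
              x$width, x$height, x$pixel_size, x$crs_id, x$xll, x$yll))
  invisible(x)
}

# two grids are the same iff every geometric field matches bit-identically
grids_identical <- function(a, b) {
  isTRUE(a$width == b$width) && isTRUE(a$height == b$height) &&
    identical(a$pixel_size, b$pixel_size) &&
    identical(a$crs_id, b$crs_id) &&
    identical(a$xll, b$xll) && identical(a$yll, b$yll)
}

# a field conforms to a grid when it is a height x width numeric matrix
check_conforms <- function(field, grid, what = "raster") {
  if (!is.matrix(field) || !is.numeric(field))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (nrow(field) != grid$height || ncol(field) != grid$width)
    stop(sprintf("%s is %d x %d but the grid is %d x %d",
                 what, nrow(field), ncol(field), grid$height, grid$width),
         call. = FALSE)
  invisible(TRUE)
}
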