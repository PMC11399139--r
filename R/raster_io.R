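#' Write a raster field to an ESRI ASCII grid
#'
#' Rasters are stored as ESRI ASCII grid (`.asc`), a plain-text format
#' carrying the grid geometry and a nodata sentinel in its header, plus a
#' JSON sidecar (`<path>.json`) recording the coordinate reference
#' identifier and the physical units of the field.  Values are written at
#' full double precision so that a write/read round trip is exact.
#'
#' @param field Numeric matrix conforming to `grid`; `NA` marks nodata.
#' @param grid A [grid_spec()].
#' @param path Output file path (conventionally ending in `.asc`).
#' @param units Optional unit string recorded in the sidecar, e.g.
#'   `"mm/day"` or `"W/m^2"`.
#' @return Invisibly, `path`.
#' @seealso [read_raster()]
#' @export
write_raster <- function(field, grid, path, units = NULL) {
  check_conforms(field, grid, "field")
  header <- c(
    sprintf("ncols %d", grid$width),
    sprintf("nrows %d", grid$height),
    sprintf("xllcorner %.10g", grid$xll),
    sprintf("yllcorner %.10g", grid$yll),
    sprintf("cellsize %.10g", grid$pixel_size),
    sprintf("NODATA_value %.10g", grid$nodata)
  )
  vals <- field
  vals[!is.finite(vals)] <- grid$nodata
  rows <- apply(vals, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  con <- withCallingHandlers(
    tryCatch(file(path, "w"), error = function(e)
      stop("cannot open '", path, "' for writing: ", conditionMessage(e),
           call. = FALSE)),
    warning = function(w) invokeRestart("muffleWarning"))
  on.exit(close(con))
  writeLines(c(header, rows), con)
  sidecar <- list(crs_id = grid$crs_id)
  if (!is.null(units)) sidecar$units <- units
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a raster field from an ESRI ASCII grid
#'
#' @param path Path to an `.asc` file written by [write_raster()] or any
#'   conforming ESRI ASCII grid.  A `<path>.json` sidecar, if present,
#'   supplies the CRS identifier and unit tag.
#' @return List with elements `field` (numeric matrix, `NA` for nodata),
#'   `grid` (a [grid_spec()]) and `units` (string or `NULL`).
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^[A-Za-z_]+\\s", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("ASCII grid header of '", path, "' lacks: ",
         paste(miss, collapse = ", "), call. = FALSE)
  nodata <- hdr$nodata_value %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("'", path, "' has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows, call. = FALSE)
  field <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  field[field == nodata] <- NA_real_
  crs_id <- "unknown"; units <- NULL
  sc_path <- paste0(path, ".json")
  if (file.exists(sc_path)) {
    sc <- jsonlite::read_json(sc_path)
    crs_id <- sc$crs_id %||% crs_id
    units <- sc$units
  }
  grid <- grid_spec(hdr$ncols, hdr$nrows, pixel_size = hdr$cellsize,
                    crs_id = crs_id, xll = hdr$xllcorner,
                    yll = hdr$yllcorner, nodata = nodata)
  list(field = field, grid = grid, units = units)
}
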