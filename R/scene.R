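#' Parse a Landsat MTL metadata file
#'
#' Reads the Collection-2 style `KEY = VALUE` plain-text metadata grammar.
#' Group markers are ignored; quoted values are unquoted; numeric-looking
#' values are converted.
#'
#' @param path Path to the MTL text file.
#' @return Named list of metadata values.
#' @export
read_mtl <- function(path) {
  if (!file.exists(path)) stop("MTL file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    if (key %in% c("GROUP", "END_GROUP")) next
    val <- trimws(paste(kv[-1], collapse = "="))
    val <- gsub('^"|"$', "", val)
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num) && grepl("^[-+0-9.eE]+$", val)) num else val
  }
  out
}

# scene metadata record; doy derived from the acquisition date
scene_meta <- function(acquisition_date, sun_elevation_deg, overpass_time,
                       sensor_id = "OLI_TIRS") {
  date <- as.Date(acquisition_date)
  doy <- as.POSIXlt(date)$yday + 1L
  if (doy < 1L || doy > 366L)
    stop("day of year out of range", call. = FALSE)
  if (!is.finite(sun_elevation_deg) || sun_elevation_deg <= 0 ||
      sun_elevation_deg > 90)
    stop("sun elevation must lie in (0, 90] degrees", call. = FALSE)
  if (overpass_time < 0 || overpass_time >= 24)
    stop("overpass time must lie in [0, 24) hours", call. = FALSE)
  structure(
    list(acquisition_date = date, doy = doy,
         overpass_time = overpass_time,
         sun_elevation_deg = sun_elevation_deg, sensor_id = sensor_id),
    class = "scene_meta"
  )
}

# "HH:MM:SS.sssssZ" -> decimal hours
parse_center_time <- function(x) {
  parts <- as.numeric(strsplit(gsub("Z$", "", x), ":", fixed = TRUE)[[1]])
  parts[1] + parts[2] / 60 + (if (length(parts) > 2) parts[3] / 3600 else 0)
}

#' Assemble a scene from in-memory rasters
#'
#' The low-level constructor behind [read_landsat_scene()] and the
#' synthetic generator.  Enforces the shared-grid contract and propagates a
#' common nodata mask (a pixel invalid in any band, or in the surface
#' temperature raster, is invalid everywhere).
#'
#' @param grid A [grid_spec()].
#' @param meta Scene metadata as returned by the internal constructor
#'   (list with `acquisition_date`, `doy`, `overpass_time`,
#'   `sun_elevation_deg`, `sensor_id`).
#' @param reflectance Named list of matrices `rho2` .. `rho7`, surface
#'   reflectance in `[0, 1]`.
#' @param ts_K Land surface temperature matrix, kelvin.
#' @param aoi_mask Optional logical matrix; `FALSE`/`NA` pixels are
#'   excluded from all computation.
#' @return Object of class `mpt_scene`.
#' @export
mpt_scene <- function(grid, meta, reflectance, ts_K, aoi_mask = NULL) {
  bands <- paste0("rho", 2:7)
  if (!all(bands %in% names(reflectance)))
    stop("reflectance must contain rho2..rho7", call. = FALSE)
  for (b in bands) check_conforms(reflectance[[b]], grid, b)
  check_conforms(ts_K, grid, "ts_K")
  if (!is.null(aoi_mask)) {
    check_conforms(aoi_mask + 0, grid, "aoi_mask")
    aoi_mask <- aoi_mask & !is.na(aoi_mask)
  }
  bad <- !is.finite(ts_K)
  for (b in bands) bad <- bad | !is.finite(reflectance[[b]])
  if (!is.null(aoi_mask)) bad <- bad | !aoi_mask
  for (b in bands) reflectance[[b]][bad] <- NA_real_
  ts_K[bad] <- NA_real_
  ok <- ts_K[!is.na(ts_K)]
  if (length(ok) && (min(ok) < 230 || max(ok) > 350))
    warning("surface temperature outside the plausible 230-350 K range")
  structure(
    list(grid = grid, meta = meta, reflectance = reflectance,
         ts_K = ts_K, aoi_mask = aoi_mask),
    class = "mpt_scene"
  )
}

#' @export
print.mpt_scene <- function(x, ...) {
  cat(sprintf("<mpt_scene> %s (doy %d), %d x %d px, sun elevation %.1f deg\n",
              format(x$meta$acquisition_date), x$meta$doy,
              x$grid$height, x$grid$width, x$meta$sun_elevation_deg))
  cat(sprintf("  valid pixels: %d\n", sum(is.finite(x$ts_K))))
  invisible(x)
}

#' Read a Landsat-style scene from band rasters and MTL metadata
#'
#' Loads six surface-reflectance bands, a co-registered land surface
#' temperature raster and the MTL metadata file onto one shared grid.
#' If the MTL declares `REFLECTANCE_MULT_BAND_n` / `REFLECTANCE_ADD_BAND_n`
#' scaling, the band digital numbers are rescaled to reflectance units;
#' otherwise inputs are taken to be reflectance already.  The nodata mask
#' is the union of every band's mask.
#'
#' @param band_paths Character vector of six raster paths, in band order
#'   2..7, or named `rho2` .. `rho7`.
#' @param mtl_path Path to the MTL text file; must define
#'   `SUN_ELEVATION`, `DATE_ACQUIRED` and `SCENE_CENTER_TIME`.
#' @param lst_path Path to the land surface temperature raster (kelvin).
#' @param aoi_path Optional path to a 0/1 mask raster on the same grid.
#' @return An `mpt_scene` object.
#' @export
read_landsat_scene <- function(band_paths, mtl_path, lst_path,
                               aoi_path = NULL) {
  mtl <- read_mtl(mtl_path)
  for (key in c("SUN_ELEVATION", "DATE_ACQUIRED", "SCENE_CENTER_TIME")) {
    if (is.null(mtl[[key]]))
      stop("MTL metadata missing required key: ", key, call. = FALSE)
  }
  meta <- scene_meta(
    acquisition_date = mtl$DATE_ACQUIRED,
    sun_elevation_deg = mtl$SUN_ELEVATION,
    overpass_time = parse_center_time(as.character(mtl$SCENE_CENTER_TIME)),
    sensor_id = as.character(mtl$SPACECRAFT_ID %||% "OLI_TIRS")
  )
  if (is.null(names(band_paths))) {
    if (length(band_paths) != 6)
      stop("band_paths must list the six bands 2..7", call. = FALSE)
    names(band_paths) <- paste0("rho", 2:7)
  }
  first <- NULL; first_path <- NULL
  reflectance <- list()
  for (b in paste0("rho", 2:7)) {
    r <- read_raster(band_paths[[b]])
    if (is.null(first)) {
      first <- r$grid; first_path <- band_paths[[b]]
    } else if (!grids_identical(first, r$grid)) {
      stop(sprintf("grid mismatch between '%s' and '%s'",
                   first_path, band_paths[[b]]), call. = FALSE)
    }
    band_no <- sub("rho", "", b)
    mult <- mtl[[paste0("REFLECTANCE_MULT_BAND_", band_no)]]
    add <- mtl[[paste0("REFLECTANCE_ADD_BAND_", band_no)]]
    if (!is.null(mult) || !is.null(add))
      r$field <- r$field * (mult %||% 1) + (add %||% 0)
    reflectance[[b]] <- r$field
  }
  lst <- read_raster(lst_path)
  if (!grids_identical(first, lst$grid))
    stop(sprintf("grid mismatch between '%s' and '%s'",
                 first_path, lst_path), call. = FALSE)
  aoi <- NULL
  if (!is.null(aoi_path)) {
    a <- read_raster(aoi_path)
    if (!grids_identical(first, a$grid))
      stop(sprintf("grid mismatch between '%s' and '%s'",
                   first_path, aoi_path), call. = FALSE)
    aoi <- a$field > 0
  }
  mpt_scene(first, meta, reflectance, lst$field, aoi)
}

#' Summary statistics of a raster over its valid, masked pixels
#'
#' @param field Numeric matrix.
#' @param mask Optional logical matrix of the same shape; `TRUE` keeps.
#' @return Data frame with one row: `mean`, `max`, `sd` (sample standard
#'   deviation, `n - 1` denominator) and `n_valid`.
#' @export
scene_summary <- function(field, mask = NULL) {
  v <- as.vector(field)
  if (!is.null(mask)) {
    if (length(mask) != length(v))
      stop("mask does not conform to field", call. = FALSE)
    v <- v[as.vector(mask) & !is.na(as.vector(mask))]
  }
  v <- v[is.finite(v)]
  if (length(v) == 0L)
    stop("no valid pixels to summarise", call. = FALSE)
  data.frame(mean = mean(v), max = max(v),
             sd = if (length(v) > 1L) stats::sd(v) else 0,
             n_valid = length(v))
}

#' Write a scene to disk as band rasters plus a minimal MTL file
#'
#' Writes the six reflectance bands and the surface temperature raster as
#' ASCII grids and a minimal MTL-format metadata file, so a scene built in
#' memory (e.g. by [generate_triangle_scene()]) can exercise the full
#' [read_landsat_scene()] path.
#'
#' @param scene An `mpt_scene`.
#' @param dir Output directory, created if needed.
#' @return Invisibly, a list with `band_paths`, `mtl_path`, `lst_path`.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  band_paths <- character(0)
  for (b in paste0("rho", 2:7)) {
    p <- file.path(dir, paste0(b, ".asc"))
    write_raster(scene$reflectance[[b]], scene$grid, p, units = "reflectance")
    band_paths[b] <- p
  }
  lst_path <- file.path(dir, "lst.asc")
  write_raster(scene$ts_K, scene$grid, lst_path, units = "K")
  mtl_path <- file.path(dir, "MTL.txt")
  hh <- floor(scene$meta$overpass_time)
  mm <- floor((scene$meta$overpass_time - hh) * 60)
  ss <- (scene$meta$overpass_time - hh - mm / 60) * 3600
  writeLines(c(
    "GROUP = LANDSAT_METADATA_FILE",
    sprintf("  DATE_ACQUIRED = %s", format(scene$meta$acquisition_date)),
    sprintf("  SCENE_CENTER_TIME = \"%02d:%02d:%09.6fZ\"", hh, mm, ss),
    sprintf("  SUN_ELEVATION = %.8f", scene$meta$sun_elevation_deg),
    sprintf("  SPACECRAFT_ID = \"%s\"", scene$meta$sensor_id),
    "END_GROUP = LANDSAT_METADATA_FILE"
  ), mtl_path)
  invisible(list(band_paths = band_paths, mtl_path = mtl_path,
                 lst_path = lst_path))
}
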