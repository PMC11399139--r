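#' Run the full scene-to-ET workflow and write all outputs
#'
#' Thin orchestration over [read_landsat_scene()], [mpt()] and
#' [write_raster()]: reads the scene, fits the model, and writes seven
#' rasters (`albedo`, `rn`, `g`, `phi`, `le`, `ef`, `et_d`), the fitted
#' edge model as a JSON sidecar, a per-field summary CSV, and a run
#' manifest with input checksums.  Re-running with identical inputs
#' produces identical outputs; on error, partial outputs of this run are
#' removed.
#'
#' @param config Named list (or path to a YAML/JSON file) with entries:
#'   `bands` (six raster paths, band order 2..7), `mtl`, `lst`,
#'   optionally `aoi`; `ta_K`, `pair_kPa`, one of `ea_kPa` | `tdew_K`,
#'   optionally `kt`; `latitude`; `outdir`; and any [mpt_control()]
#'   parameter to override its default.
#' @return Invisibly, the manifest list.
#' @export
run_scene <- function(config) {
  config <- load_config(config)
  for (key in c("bands", "mtl", "lst", "ta_K", "pair_kPa", "latitude",
                "outdir")) {
    if (is.null(config[[key]]))
      stop("config is missing required field: ", key, call. = FALSE)
  }
  for (p in c(unlist(config$bands), config$mtl, config$lst, config$aoi)) {
    if (!file.exists(p))
      stop("input file not found: ", p, call. = FALSE)
  }
  scene <- read_landsat_scene(unlist(config$bands), config$mtl,
                              config$lst, config$aoi)
  meteo <- meteo_snapshot(ta_K = config$ta_K, pair_kPa = config$pair_kPa,
                          ea_kPa = config$ea_kPa,
                          tdew_K = config$tdew_K,
                          kt = config$kt %||% 1)
  ctl_args <- intersect(names(config), names(formals(mpt_control)))
  control <- do.call(mpt_control, config[ctl_args])
  fit <- mpt(scene, meteo, latitude = config$latitude, control = control)

  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on.exit(if (!is.null(written)) unlink(c(written, paste0(written, ".json"))))

  units <- c(albedo = "unitless", rn = "W/m^2", g = "W/m^2",
             phi = "unitless", le = "W/m^2", ef = "unitless",
             et_d = "mm/day")
  for (f in names(units)) {
    p <- file.path(outdir, paste0(f, ".asc"))
    write_raster(fit$fields[[f]], fit$grid, p, units = units[[f]])
    written <- c(written, p)
  }
  edges_path <- file.path(outdir, "edges.json")
  jsonlite::write_json(
    list(dry_intercept = fit$edges$dry_intercept,
         dry_slope = fit$edges$dry_slope, t_min = fit$edges$t_min,
         bin_width = fit$edges$bin_width, fallback = fit$edges$fallback,
         bins = fit$edges$bins),
    edges_path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  written <- c(written, edges_path)

  sm <- summary(fit, fields = names(units))$table
  sm <- cbind(date = format(fit$meta$acquisition_date), sm)
  summary_path <- file.path(outdir, "summary.csv")
  utils::write.csv(sm, summary_path, row.names = FALSE)
  written <- c(written, summary_path)

  inputs <- c(unlist(config$bands), mtl = config$mtl, lst = config$lst)
  manifest <- list(
    package = "mptet",
    version = as.character(utils::packageVersion("mptet")),
    date = format(fit$meta$acquisition_date),
    inputs = as.list(tools::md5sum(inputs)),
    parameters = fit$control[!vapply(fit$control, is.matrix, TRUE)],
    atmosphere = fit$atmosphere,
    edges = list(dry_intercept = fit$edges$dry_intercept,
                 dry_slope = fit$edges$dry_slope,
                 t_min = fit$edges$t_min),
    diagnostics = fit$diagnostics,
    rasters = basename(written[grepl("\\.asc$", written)])
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  written <- c(written, manifest_path)
  on.exit()  # success: keep outputs
  invisible(manifest)
}

#' Validate paired observed/estimated ET from a CSV file
#'
#' Reads a paired CSV (columns `date`, `observed_mm_day`,
#' `predicted_mm_day`), computes the five validation statistics, and
#' optionally writes the report as JSON.
#'
#' @param pairs_path Path to the paired CSV.
#' @param out Optional path for the JSON report.
#' @return The [et_validation()] report.
#' @export
run_validate <- function(pairs_path, out = NULL) {
  if (!file.exists(pairs_path))
    stop("paired CSV not found: ", pairs_path, call. = FALSE)
  df <- tryCatch(utils::read.csv(pairs_path),
                 error = function(e) stop("cannot parse '", pairs_path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  need <- c("observed_mm_day", "predicted_mm_day")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("paired CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) < 2)
    stop("paired CSV must contain at least 2 rows", call. = FALSE)
  bad <- which(!is.finite(df$observed_mm_day) |
                 !is.finite(df$predicted_mm_day))
  if (length(bad))
    stop("non-numeric or missing value at data line ", bad[1],
         call. = FALSE)
  rep <- et_validation(df$observed_mm_day, df$predicted_mm_day,
                       labels = df$date)
  if (!is.null(out)) {
    jsonlite::write_json(
      list(r2 = rep$r2, rmse = rep$rmse, d = rep$d, nsme = rep$nsme,
           mbe = rep$mbe, n = rep$n,
           conventions = list(sd = "sample (n-1)",
                              mbe = "mean(observed - predicted)")),
      out, auto_unbox = TRUE, digits = NA)
  }
  rep
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML config requires the yaml package", call. = FALSE)
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop("config must be a list or a file path",
                             call. = FALSE)
  config
}
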