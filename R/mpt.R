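#' Control parameters for the MPT fit
#'
#' Collects every tunable of the pipeline with its default.  Defaults
#' follow the Ts-VI triangle literature where the method itself does not
#' fix a value.
#'
#' @param ndvi_bounds Fixed `(NDVI_min, NDVI_max)` for the vegetation
#'   fraction, or `NULL` (default) to use per-scene percentiles.
#' @param ndvi_percentiles Percentiles of valid NDVI used when
#'   `ndvi_bounds` is `NULL` (default 2nd and 98th; robust to outliers).
#' @param bin_width Fr bin width for edge fitting (default 0.05).
#' @param min_bin_count Minimum pixels for a bin to contribute edge
#'   candidates (default 20).
#' @param dry_percentile,wet_percentile Within-bin temperature
#'   percentiles taken as dry and wet candidates (defaults 0.995 and
#'   0.005).
#' @param min_pixels Minimum valid pixels for an edge fit (default 1000).
#' @param min_fr_span Minimum Fr range for an edge fit (default 0.3).
#' @param trim_sd,max_trim_iter Iterative trimming of dry candidates:
#'   drop those more than `trim_sd` residual SDs below the fit, at most
#'   `max_trim_iter` refits (defaults 2 and 5).
#' @param tmax_clamp Minimum dry-wet edge separation, kelvin
#'   (default 0.5).
#' @param alpha_upscale Daily upscaling coefficient (default 1.1).
#' @param daily_energy_mode `"half_sine"` or `"user_supplied"`.
#' @param daylight_hours Daylight length override, hours, or `NULL` to
#'   compute from latitude and day of year.
#' @param user_daily_energy Daily available energy matrix for
#'   `"user_supplied"` mode, MJ m-2 day-1.
#' @return Named list of class `mpt_control`.
#' @export
mpt_control <- function(ndvi_bounds = NULL,
                        ndvi_percentiles = c(0.02, 0.98),
                        bin_width = 0.05, min_bin_count = 20,
                        dry_percentile = 0.995, wet_percentile = 0.005,
                        min_pixels = 1000, min_fr_span = 0.3,
                        trim_sd = 2, max_trim_iter = 5,
                        tmax_clamp = 0.5, alpha_upscale = 1.1,
                        daily_energy_mode = c("half_sine", "user_supplied"),
                        daylight_hours = NULL, user_daily_energy = NULL) {
  structure(
    list(ndvi_bounds = ndvi_bounds, ndvi_percentiles = ndvi_percentiles,
         bin_width = bin_width, min_bin_count = min_bin_count,
         dry_percentile = dry_percentile, wet_percentile = wet_percentile,
         min_pixels = min_pixels, min_fr_span = min_fr_span,
         trim_sd = trim_sd, max_trim_iter = max_trim_iter,
         tmax_clamp = tmax_clamp, alpha_upscale = alpha_upscale,
         daily_energy_mode = match.arg(daily_energy_mode),
         daylight_hours = daylight_hours,
         user_daily_energy = user_daily_energy),
    class = "mpt_control"
  )
}

#' Fit the Modified Priestley-Taylor ET model to a scene
#'
#' Runs the full per-scene pipeline: scalar atmosphere at overpass,
#' broadband albedo and NDVI, clear-sky radiation balance, Ts-Fr
#' triangle edge fit, two-step interpolation of the Priestley-Taylor
#' coefficient, soil heat flux, latent heat flux, evaporative fraction,
#' and half-sine upscaling to daily ET.  No ground observations are
#' required: the only non-image inputs are the reanalysis scalars in
#' `meteo` and the latitude (for daylight length).
#'
#' @param scene An `mpt_scene` from [read_landsat_scene()] or
#'   [generate_triangle_scene()].
#' @param meteo A [meteo_snapshot()].
#' @param latitude Scene-centre latitude, degrees north.
#' @param control A [mpt_control()].
#' @return Object of class `mpt` with components `atmosphere`
#'   (scene scalars including `rs_down` and `rl_down`, W m-2), `edges`
#'   (the fitted [fit_edges()] model), `fields` (named list of per-pixel
#'   matrices: `ndvi`, `fr`, `albedo`, `eps0`, `rl_up`, `rn`, `g`,
#'   `phi`, `le`, `ef`, `et_i`, `et_d`) and `diagnostics`.  Methods:
#'   `print`, `summary`, `coef`, `predict`, `plot`, `residuals`.
#' @examples
#' syn <- generate_triangle_scene(triangle_params(n_rows = 60, n_cols = 60))
#' met <- meteo_snapshot(ta_K = 298, pair_kPa = 101, ea_kPa = 1.5)
#' fit <- mpt(syn$scene, met, latitude = 29,
#'            control = mpt_control(ndvi_bounds = c(0.1, 0.9),
#'                                  min_pixels = 500))
#' fit
#' summary(fit)
#' @export
mpt <- function(scene, meteo, latitude, control = mpt_control()) {
  stopifnot(inherits(scene, "mpt_scene"), inherits(meteo, "meteo_snapshot"))
  cl <- match.call()
  meta <- scene$meta
  atm <- atmosphere_state(meteo, meta$doy, meta$sun_elevation_deg)

  nd <- ndvi(scene$reflectance$rho4, scene$reflectance$rho5)
  bounds <- control$ndvi_bounds %||%
    stats::quantile(nd, control$ndvi_percentiles, na.rm = TRUE,
                    names = FALSE)
  fr <- vegetation_fraction(nd, bounds[1], bounds[2])
  albedo <- broadband_albedo(scene$reflectance)
  eps0 <- surface_emissivity(nd)

  rs_down <- shortwave_down(atm)
  rl_down <- longwave_down(atm$eps_a, meteo$ta_K)
  rl_up <- longwave_up(eps0, scene$ts_K)
  rn <- net_radiation(albedo, rs_down, rl_down, rl_up, eps0)

  # water pixels are kept in every field but excluded from edge fitting
  edges <- fit_edges(scene$ts_K, fr, control,
                     mask = is.finite(nd) & nd > 0)
  phi <- phi_map(scene$ts_K, fr, edges, control$tmax_clamp)

  g <- soil_heat_flux(rn, scene$ts_K, albedo, nd)
  le <- latent_heat_flux(phi, rn, g, atm$delta_kPa_per_C,
                         atm$gamma_kPa_per_C)
  et_i <- instantaneous_et(le)
  ef <- evaporative_fraction(le, rn, g)

  n_day <- control$daylight_hours %||% daylight_hours(latitude, meta$doy)
  energy_d <- daily_available_energy(
    rn, g, meta$overpass_time, n_day,
    mode = control$daily_energy_mode,
    user_energy = control$user_daily_energy
  )
  et_d <- daily_et(ef, energy_d, control$alpha_upscale)

  fields <- list(ts_K = scene$ts_K,
                 ndvi = nd, fr = fr, albedo = albedo, eps0 = eps0,
                 rl_up = rl_up, rn = rn, g = g, phi = phi, le = le,
                 ef = ef, et_i = et_i, et_d = et_d,
                 daily_energy = energy_d)
  diagnostics <- list(
    ndvi_bounds = bounds,
    daylight_hours = n_day,
    n_le_clipped = attr(le, "n_clipped"),
    n_ef_invalid = attr(ef, "n_invalid"),
    edge_fallback = edges$fallback
  )
  structure(
    list(call = cl, meta = meta, grid = scene$grid, meteo = meteo,
         atmosphere = c(unclass(atm),
                        list(rs_down = rs_down, rl_down = rl_down)),
         edges = edges, control = control, latitude = latitude,
         fields = fields, diagnostics = diagnostics),
    class = "mpt"
  )
}

#' @export
print.mpt <- function(x, ...) {
  cat("Modified Priestley-Taylor ET fit\n")
  cat(sprintf("  scene: %s (doy %d), %d x %d px\n",
              format(x$meta$acquisition_date), x$meta$doy,
              x$grid$height, x$grid$width))
  cat(sprintf("  dry edge Tmax(Fr) = %.2f %+.2f Fr K, wet edge %.2f K%s\n",
              x$edges$dry_intercept, x$edges$dry_slope, x$edges$t_min,
              if (x$edges$fallback) " (fallback)" else ""))
  s <- scene_summary(x$fields$et_d)
  cat(sprintf("  daily ET: mean %.2f, max %.2f, sd %.2f mm/day (n = %d)\n",
              s$mean, s$max, s$sd, s$n_valid))
  invisible(x)
}

#' Summary statistics of every fitted field
#'
#' @param object An `mpt` fit.
#' @param fields Character vector of field names to summarise (default
#'   all).
#' @param ... Unused.
#' @return Data frame with one row per field: `field`, `mean`, `max`,
#'   `sd` (sample SD), `n_valid`.
#' @export
summary.mpt <- function(object, fields = names(object$fields), ...) {
  rows <- lapply(fields, function(f) {
    s <- scene_summary(object$fields[[f]])
    cbind(field = f, s)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(date = object$meta$acquisition_date, table = out,
                 edges = object$edges),
            class = "summary.mpt")
}

#' @export
print.summary.mpt <- function(x, digits = 4, ...) {
  cat(sprintf("MPT scene summary, %s\n", format(x$date)))
  tab <- x$table
  tab$mean <- signif(tab$mean, digits); tab$max <- signif(tab$max, digits)
  tab$sd <- signif(tab$sd, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mpt <- function(object, ...) coef(object$edges)

#' Predict the PT coefficient, evaporative fraction or daily ET
#'
#' Evaluates the fitted triangle interpolation at new
#' (surface temperature, vegetation fraction) pairs.
#'
#' @param object An `mpt` fit.
#' @param ts_K Surface temperatures, kelvin.
#' @param fr Vegetation fractions, same length.
#' @param type `"phi"` (default), `"ef"`, or `"et_d"` (uses the scene
#'   mean daily available energy).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.mpt <- function(object, ts_K, fr,
                        type = c("phi", "ef", "et_d"), ...) {
  type <- match.arg(type)
  phi <- phi_map(ts_K, fr, object$edges, object$control$tmax_clamp)
  if (type == "phi") return(phi)
  atm <- object$atmosphere
  ef <- phi * atm$delta_kPa_per_C /
    (atm$delta_kPa_per_C + atm$gamma_kPa_per_C)
  if (type == "ef") return(ef)
  e_d <- scene_summary(object$fields$daily_energy)$mean
  daily_et(ef, e_d, object$control$alpha_upscale)
}

#' Dry-edge fit residuals
#'
#' @param object An `mpt` fit.
#' @param ... Unused.
#' @return Residuals of the dry-edge candidates about the fitted line,
#'   kelvin, named by bin centre.
#' @export
residuals.mpt <- function(object, ...) {
  b <- object$edges$bins
  r <- b$t_dry - (object$edges$dry_intercept +
                    object$edges$dry_slope * b$centre)
  names(r) <- format(b$centre)
  r
}

#' Plot the Ts-Fr triangle with fitted edges
#'
#' Scatter of (vegetation fraction, surface temperature) over a random
#' subsample of pixels, overlaid with the fitted dry edge (decreasing
#' line), the wet edge (horizontal) and the per-bin edge candidates.
#'
#' @param x An `mpt` fit.
#' @param max_points Subsample size for the scatter (default 5000).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.mpt <- function(x, max_points = 5000, ...) {
  b <- x$edges$bins
  f <- as.vector(x$fields$fr); ts <- as.vector(x$fields$ts_K)
  ok <- which(is.finite(f) & is.finite(ts))
  if (length(ok) > max_points) ok <- sample(ok, max_points)
  frs <- seq(0, 1, length.out = 101)
  ylim <- range(c(ts[ok], b$t_dry, b$t_wet, x$edges$t_min), na.rm = TRUE)
  graphics::plot(f[ok], ts[ok], pch = ".", col = "grey50",
                 xlim = c(0, 1), ylim = ylim + c(-1, 1),
                 xlab = "fraction of vegetation Fr",
                 ylab = "surface temperature (K)",
                 main = "Ts-Fr triangle edges", ...)
  graphics::points(b$centre, b$t_dry, pch = ifelse(b$used_in_fit, 19, 1),
                   col = "firebrick")
  graphics::points(b$centre, b$t_wet, pch = 17, col = "steelblue")
  graphics::lines(frs, x$edges$dry_intercept + x$edges$dry_slope * frs,
                  col = "firebrick", lwd = 2)
  graphics::abline(h = x$edges$t_min, col = "steelblue", lwd = 2)
  graphics::legend("topright", bty = "n",
                   legend = c("dry candidates", "wet candidates",
                              "dry edge", "wet edge"),
                   col = c("firebrick", "steelblue", "firebrick",
                           "steelblue"),
                   pch = c(19, 17, NA, NA), lty = c(NA, NA, 1, 1))
  invisible(x)
}
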