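#' Soil heat flux from the mid-day G/Rn ratio
#'
#' Empirical near-mid-day ratio
#' `G/Rn = (Ts_C / alpha) (0.0038 alpha + 0.0074 alpha^2) (1 - 0.98 NDVI^4)`
#' with the surface temperature in Celsius, then `G = (G/Rn) Rn`.  The
#' ratio is clipped to `[0, 0.5]`; pixels with zero albedo become nodata
#' (division guard).
#'
#' @param rn Net radiation matrix, W m-2.
#' @param ts_K Surface temperature matrix, kelvin.
#' @param albedo Broadband albedo matrix.
#' @param ndvi NDVI matrix.
#' @return `G` matrix, W m-2, with attribute `ratio` (the clipped G/Rn).
#' @export
soil_heat_flux <- function(rn, ts_K, albedo, ndvi) {
  ts_c <- ts_K - 273.15
  a <- albedo
  a[a == 0] <- NA_real_
  ratio <- (ts_c / a) * (0.0038 * a + 0.0074 * a^2) * (1 - 0.98 * ndvi^4)
  ratio <- pmin(pmax(ratio, 0), 0.5)
  g <- ratio * rn
  attr(g, "ratio") <- ratio
  g
}

#' Latent heat flux (Priestley-Taylor form)
#'
#' `LE = phi (Rn - G) Delta / (Delta + gamma)` per pixel.  Where the
#' available energy is negative the product is negative; it is clipped to
#' zero and the number of clipped pixels recorded in the `n_clipped`
#' attribute.
#'
#' @param phi Priestley-Taylor coefficient matrix in `[0, 1.26]`.
#' @param rn,g Net radiation and soil heat flux matrices, W m-2.
#' @param delta Saturation-vapour-pressure slope, kPa per degC.
#' @param gamma Psychrometric constant, kPa per degC.
#' @return `LE` matrix, W m-2.
#' @export
latent_heat_flux <- function(phi, rn, g, delta, gamma) {
  if (delta <= 0 || gamma <= 0)
    stop("delta and gamma must be positive", call. = FALSE)
  le <- phi * (rn - g) * delta / (delta + gamma)
  n_clipped <- sum(le < 0, na.rm = TRUE)
  le <- pmax(le, 0)
  attr(le, "n_clipped") <- n_clipped
  le
}

#' Instantaneous evapotranspiration from latent heat flux
#'
#' `ETi = 3600 LE / lambda` with the latent heat of vaporization in
#' J kg-1 (`2.45e6`), converting W m-2 to millimetres of water per hour.
#'
#' @param le Latent heat flux matrix, W m-2.
#' @return `ETi` matrix, mm per hour.
#' @export
instantaneous_et <- function(le) {
  3600 * le / (.const$lambda_MJ_per_kg * 1e6)
}

#' Evaporative fraction
#'
#' `EF = LE / (Rn - G)`: the share of available energy spent on
#' evaporation, assumed near-constant through daylight hours.  By the
#' Priestley-Taylor form this equals `phi Delta / (Delta + gamma)`
#' exactly.  Pixels with non-positive available energy become nodata; the
#' count is recorded in the `n_invalid` attribute.
#'
#' @param le,rn,g Latent heat flux, net radiation and soil heat flux
#'   matrices, W m-2.
#' @return `EF` matrix, unitless.
#' @export
evaporative_fraction <- function(le, rn, g) {
  avail <- rn - g
  bad <- !is.na(avail) & avail <= 0
  avail[bad] <- NA_real_
  ef <- le / avail
  attr(ef, "n_invalid") <- sum(bad)
  ef
}

#' Daylight length from latitude and day of year
#'
#' Standard sunset-hour-angle formula: solar declination
#' `delta = 0.409 sin(2 pi doy / 365 - 1.39)`, sunset hour angle
#' `ws = acos(-tan(lat) tan(delta))`, daylight `N = 24 ws / pi` hours.
#'
#' @param latitude_deg Latitude, degrees (positive north).
#' @param doy Day of year.
#' @return Daylight length, hours.
#' @export
daylight_hours <- function(latitude_deg, doy) {
  lat <- latitude_deg * pi / 180
  decl <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  x <- pmin(pmax(-tan(lat) * tan(decl), -1), 1)
  24 / pi * acos(x)
}

#' Daily available energy by half-sine upscaling
#'
#' The instantaneous available energy `Rn - G` observed at overpass is
#' assumed to follow a half-sine arc over the daylight period,
#' `E(t) = E_peak sin(pi (t - sunrise) / N)`, zero at sunrise and sunset.
#' The peak is recovered from the overpass value and the overpass time,
#' and the arc integrated analytically:
#' `(Rn - G)_d = E_peak (2 N 3600 / pi) 1e-6` MJ m-2 day-1.  The daily
#' mean soil heat flux is taken as zero (daily soil-heat closure), so the
#' overpass `Rn - G` is the only per-pixel input.  Solar noon is assumed
#' at hour 12 of local solar time, sunrise at `12 - N/2`.
#'
#' @param rn,g Net radiation and soil heat flux matrices at overpass,
#'   W m-2.
#' @param overpass_time Local solar time of overpass, decimal hours.
#' @param daylight_hours Daylight length `N`, hours.
#' @param mode `"half_sine"` (default) or `"user_supplied"`.
#' @param user_energy Daily available energy matrix, MJ m-2 day-1,
#'   required when `mode = "user_supplied"`.
#' @return Daily available energy matrix, MJ m-2 day-1.
#' @export
daily_available_energy <- function(rn, g, overpass_time, daylight_hours,
                                   mode = c("half_sine", "user_supplied"),
                                   user_energy = NULL) {
  mode <- match.arg(mode)
  if (mode == "user_supplied") {
    if (is.null(user_energy))
      stop("user_supplied mode requires user_energy", call. = FALSE)
    return(user_energy)
  }
  n <- daylight_hours
  sunrise <- 12 - n / 2
  t_rel <- overpass_time - sunrise
  if (t_rel <= 0 || t_rel >= n)
    stop(sprintf(paste0("overpass at %.2f h falls outside daylight ",
                        "(sunrise %.2f h, %.1f h day)"),
                 overpass_time, sunrise, n), call. = FALSE)
  sine <- sin(pi * t_rel / n)
  e_peak <- (rn - g) / sine
  e_peak * (2 * n * 3600 / pi) * 1e-6
}

#' Daily evapotranspiration from the evaporative fraction
#'
#' `ETd = alpha EF (Rn - G)_d / lambda` in mm day-1, with
#' `lambda = 2.45` MJ kg-1 converting energy to water depth (1 MJ m-2
#' evaporates 1/2.45 mm).  The coefficient `alpha` (default 1.1)
#' compensates the systematic low bias of plain evaporative-fraction
#' upscaling.
#'
#' @param ef Evaporative fraction matrix.
#' @param daily_energy Daily available energy matrix, MJ m-2 day-1.
#' @param alpha_upscale Upscaling coefficient (default 1.1).
#' @return `ETd` matrix, mm day-1.
#' @export
daily_et <- function(ef, daily_energy, alpha_upscale = 1.1) {
  alpha_upscale * ef * daily_energy / .const$lambda_MJ_per_kg
}
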