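#' Overpass-time meteorology snapshot
#'
#' Scalar near-surface meteorology at satellite overpass, typically
#' extracted from a reanalysis product (e.g. ERA5) at the scene centre.
#' Actual vapour pressure may be given directly or derived from dewpoint
#' via the Tetens curve; one of the two must be supplied.
#'
#' @param ta_K 2 m air temperature, kelvin.
#' @param pair_kPa Surface air pressure, kilopascal.
#' @param ea_kPa Actual vapour pressure, kilopascal (optional).
#' @param tdew_K Dewpoint temperature, kelvin (optional; used when
#'   `ea_kPa` is absent).
#' @param kt Atmospheric clearness coefficient in `(0, 1]`; 1 for clean
#'   air, down to 0.5 for extremely turbid or polluted air.
#' @return Object of class `meteo_snapshot`.
#' @examples
#' meteo_snapshot(ta_K = 298.15, pair_kPa = 101.3, tdew_K = 283.15)
#' @export
meteo_snapshot <- function(ta_K, pair_kPa, ea_kPa = NULL, tdew_K = NULL,
                           kt = 1) {
  if (!is.finite(ta_K) || ta_K < 240 || ta_K > 330)
    stop("air temperature must lie in [240, 330] K", call. = FALSE)
  if (!is.finite(pair_kPa) || pair_kPa < 50 || pair_kPa > 110)
    stop("air pressure must lie in [50, 110] kPa", call. = FALSE)
  if (kt <= 0 || kt > 1)
    stop("clearness coefficient kt must lie in (0, 1]", call. = FALSE)
  if (is.null(ea_kPa)) {
    if (is.null(tdew_K))
      stop("supply either ea_kPa or tdew_K", call. = FALSE)
    ea_kPa <- vapour_pressure_from_dewpoint(tdew_K)
  }
  if (ea_kPa < 0) stop("vapour pressure must be non-negative", call. = FALSE)
  structure(
    list(ta_K = ta_K, pair_kPa = pair_kPa, ea_kPa = ea_kPa,
         tdew_K = tdew_K, kt = kt),
    class = "meteo_snapshot"
  )
}

#' Inverse squared relative Earth-Sun distance
#'
#' `dr = 1 + 0.033 cos(2 pi doy / 365)`; dimensionless, ranging from about
#' 0.97 (aphelion) to 1.03 (perihelion).
#'
#' @param doy Day of year, 1-366.
#' @return `dr`, unitless.
#' @export
inverse_relative_distance <- function(doy) {
  if (any(doy < 1 | doy > 366))
    stop("day of year must lie in [1, 366]", call. = FALSE)
  1 + 0.033 * cos(doy * 2 * pi / 365)
}

#' Cosine of the solar incidence angle from sun elevation
#'
#' For a horizontal surface the incidence angle is the solar zenith angle,
#' so `cos(theta) = cos(pi/2 - elev) = sin(elev)`.
#'
#' @param sun_elevation_deg Sun elevation above the horizon, degrees, as
#'   reported in the scene metadata.  Converted to radians here and only
#'   here.
#' @return `cos(theta)`, unitless.
#' @export
cos_incidence <- function(sun_elevation_deg) {
  if (any(!is.finite(sun_elevation_deg)) ||
      any(sun_elevation_deg <= 0 | sun_elevation_deg > 90))
    stop("sun elevation must lie in (0, 90] degrees (daytime scene)",
         call. = FALSE)
  cos(pi / 2 - sun_elevation_deg * pi / 180)
}

#' Actual vapour pressure from dewpoint (Tetens)
#'
#' `ea = 0.6108 exp(17.27 Td / (Td + 237.3))` with `Td` in Celsius: the
#' saturation vapour pressure evaluated at the dewpoint.
#'
#' @param tdew_K Dewpoint temperature, kelvin.
#' @return `ea`, kPa.
#' @export
vapour_pressure_from_dewpoint <- function(tdew_K) {
  if (any(!is.finite(tdew_K)) || any(tdew_K < 220 | tdew_K > 330))
    stop("dewpoint must lie in [220, 330] K", call. = FALSE)
  td <- tdew_K - 273.15
  0.6108 * exp(17.27 * td / (td + 237.3))
}

#' Precipitable water in the atmospheric column
#'
#' `W = 0.14 ea Pair + 2.1`, millimetres.
#'
#' @param ea_kPa Actual vapour pressure, kPa.
#' @param pair_kPa Surface air pressure, kPa.
#' @return `W`, mm.
#' @export
precipitable_water <- function(ea_kPa, pair_kPa) {
  if (any(ea_kPa < 0))
    stop("vapour pressure must be non-negative", call. = FALSE)
  0.14 * ea_kPa * pair_kPa + 2.1
}

#' Clear-sky beam transmissivity
#'
#' `tau_B = 0.98 exp[-0.00146 Pair / (Kt cos theta) - 0.075 (W / cos theta)^0.4]`
#'
#' @param pair_kPa Surface air pressure, kPa.
#' @param kt Clearness coefficient, `(0, 1]`.
#' @param cos_theta Cosine of the solar incidence angle, `> 0`.
#' @param w_mm Precipitable water, mm.
#' @return `tau_B`, unitless.
#' @export
beam_transmissivity <- function(pair_kPa, kt, cos_theta, w_mm) {
  if (any(cos_theta <= 0))
    stop("cos_theta must be positive (sun above the horizon)", call. = FALSE)
  0.98 * exp(-0.00146 * pair_kPa / (kt * cos_theta)
             - 0.075 * (w_mm / cos_theta)^0.4)
}

#' Diffuse transmissivity from beam transmissivity
#'
#' Piecewise linear in `tau_B` with the branch switch at 0.15:
#' `tau_D = 0.35 - 0.36 tau_B` for `tau_B >= 0.15`, else
#' `tau_D = 0.18 + 0.82 tau_B`.
#'
#' @param tau_b Beam transmissivity in `(0, 1)`.
#' @return `tau_D`, unitless.
#' @export
diffuse_transmissivity <- function(tau_b) {
  if (any(tau_b <= 0 | tau_b >= 1))
    stop("tau_b must lie in (0, 1)", call. = FALSE)
  ifelse(tau_b >= 0.15, 0.35 - 0.36 * tau_b, 0.18 + 0.82 * tau_b)
}

#' Broadband shortwave transmissivity
#'
#' The sum of the beam and diffuse components.
#'
#' @param tau_b,tau_d Beam and diffuse transmissivities.
#' @return `tau_sw`, unitless.
#' @export
broadband_transmissivity <- function(tau_b, tau_d) tau_b + tau_d

#' Effective atmospheric emissivity
#'
#' `eps_a = 0.85 (-ln tau_sw)^0.09`, the empirical clear-sky emissivity
#' driven by the broadband transmissivity.
#'
#' @param tau_sw Broadband transmissivity in `(0, 1)`.
#' @return `eps_a`, unitless.
#' @export
atmospheric_emissivity <- function(tau_sw) {
  if (any(tau_sw <= 0 | tau_sw >= 1))
    stop("tau_sw must lie in (0, 1)", call. = FALSE)
  0.85 * (-log(tau_sw))^0.09
}

#' Psychrometric constant
#'
#' `gamma = Cp P / (eps lambda)` with `Cp = 1.013e-3` MJ kg-1 degC-1,
#' `eps = 0.622` and `lambda = 2.45` MJ kg-1; proportional to pressure.
#'
#' @param pair_kPa Air pressure, kPa.
#' @return `gamma`, kPa per degC.
#' @export
psychrometric_constant <- function(pair_kPa) {
  .const$cp * pair_kPa / (.const$mw_ratio * .const$lambda_MJ_per_kg)
}

#' Slope of the saturation vapour pressure curve
#'
#' `Delta = 4098 [0.6108 exp(17.27 T / (T + 237.3))] / (T + 237.3)^2`
#' with `T` in Celsius, evaluated at the air temperature.
#'
#' @param t_K Temperature, kelvin.
#' @return `Delta`, kPa per degC.
#' @export
svp_slope <- function(t_K) {
  if (any(!is.finite(t_K)) || any(t_K < 240 | t_K > 330))
    stop("temperature must lie in [240, 330] K", call. = FALSE)
  tc <- t_K - 273.15
  4098 * (0.6108 * exp(17.27 * tc / (tc + 237.3))) / (tc + 237.3)^2
}

#' Scalar atmospheric state at overpass
#'
#' Bundles every scene-level scalar of the clear-sky radiation balance:
#' Earth-Sun distance factor, incidence cosine, precipitable water,
#' beam/diffuse/broadband transmissivity, atmospheric emissivity, the
#' psychrometric constant, and the saturation-vapour-pressure slope at
#' air temperature.
#'
#' @param meteo A [meteo_snapshot()].
#' @param doy Day of year.
#' @param sun_elevation_deg Sun elevation, degrees.
#' @return Object of class `atmosphere_state`: list with `dr`,
#'   `cos_theta`, `w_mm`, `tau_b`, `tau_d`, `tau_sw`, `eps_a`,
#'   `gamma_kPa_per_C`, `delta_kPa_per_C`.
#' @export
atmosphere_state <- function(meteo, doy, sun_elevation_deg) {
  stopifnot(inherits(meteo, "meteo_snapshot"))
  dr <- inverse_relative_distance(doy)
  ct <- cos_incidence(sun_elevation_deg)
  w <- precipitable_water(meteo$ea_kPa, meteo$pair_kPa)
  tb <- beam_transmissivity(meteo$pair_kPa, meteo$kt, ct, w)
  td <- diffuse_transmissivity(tb)
  tsw <- broadband_transmissivity(tb, td)
  structure(
    list(dr = dr, cos_theta = ct, w_mm = w, tau_b = tb, tau_d = td,
         tau_sw = tsw, eps_a = atmospheric_emissivity(tsw),
         gamma_kPa_per_C = psychrometric_constant(meteo$pair_kPa),
         delta_kPa_per_C = svp_slope(meteo$ta_K)),
    class = "atmosphere_state"
  )
}

#' @export
print.atmosphere_state <- function(x, ...) {
  cat("<atmosphere_state>\n")
  cat(sprintf("  dr %.4f  cos(theta) %.4f  W %.2f mm\n",
              x$dr, x$cos_theta, x$w_mm))
  cat(sprintf("  tau_b %.4f  tau_d %.4f  tau_sw %.4f  eps_a %.4f\n",
              x$tau_b, x$tau_d, x$tau_sw, x$eps_a))
  cat(sprintf("  gamma %.4f  Delta %.4f kPa/degC\n",
              x$gamma_kPa_per_C, x$delta_kPa_per_C))
  invisible(x)
}
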