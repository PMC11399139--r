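#' Broadband surface albedo from six reflectance bands
#'
#' Weighted sum of Landsat bands 2-7 surface reflectance:
#' `alpha = 0.254 rho2 + 0.149 rho3 + 0.147 rho4 + 0.311 rho5 +
#' 0.103 rho6 + 0.036 rho7`.  The weights sum to 1, so a spectrally flat
#' surface returns its flat reflectance exactly.
#'
#' @param reflectance Named list of matrices `rho2` .. `rho7` (e.g.
#'   `scene$reflectance`).
#' @return Albedo matrix, unitless; nodata propagated from any band.
#' @export
broadband_albedo <- function(reflectance) {
  w <- c(rho2 = 0.254, rho3 = 0.149, rho4 = 0.147,
         rho5 = 0.311, rho6 = 0.103, rho7 = 0.036)
  out <- 0
  for (b in names(w)) out <- out + w[[b]] * reflectance[[b]]
  out
}

#' Clear-sky incoming shortwave radiation
#'
#' `Rs_down = Gsc cos(theta) dr tau_sw` with `Gsc = 1367` W m-2.  A scene
#' scalar: the overpass sun geometry and atmosphere are uniform over the
#' (district-scale) grid.
#'
#' @param atm An [atmosphere_state()], or a list with `cos_theta`, `dr`,
#'   `tau_sw`.
#' @return `Rs_down`, W m-2.
#' @export
shortwave_down <- function(atm) {
  .const$gsc * atm$cos_theta * atm$dr * atm$tau_sw
}

#' Incoming longwave radiation
#'
#' Stefan-Boltzmann with the effective atmospheric emissivity:
#' `RL_down = eps_a sigma Ta^4`.
#'
#' @param eps_a Effective atmospheric emissivity.
#' @param ta_K Near-surface air temperature, kelvin.
#' @return `RL_down`, W m-2 (scene scalar).
#' @export
longwave_down <- function(eps_a, ta_K) {
  eps_a * .const$sigma * ta_K^4
}

#' Broadband surface emissivity from NDVI
#'
#' `eps0 = 1.009 + 0.047 ln(NDVI)` for vegetated/soil pixels
#' (`NDVI > 0`).  Pixels with `NDVI <= 0` are treated as water and
#' assigned a standard broadband water emissivity.  Because the logarithm
#' diverges as NDVI approaches zero, the result is clipped below at
#' `min_emissivity`.
#'
#' @param ndvi NDVI matrix in `[-1, 1]`.
#' @param water_value Emissivity assigned to `NDVI <= 0` pixels
#'   (default 0.985).
#' @param min_emissivity Lower clip for near-zero NDVI (default 0.9).
#' @return Surface emissivity matrix, clipped to
#'   `[min_emissivity, 1.009]`.
#' @export
surface_emissivity <- function(ndvi, water_value = 0.985,
                               min_emissivity = 0.9) {
  out <- ndvi
  pos <- !is.na(ndvi) & ndvi > 0
  out[pos] <- 1.009 + 0.047 * log(ndvi[pos])
  out[!is.na(ndvi) & ndvi <= 0] <- water_value
  out <- pmin(pmax(out, min_emissivity), 1.009)
  out[!is.finite(ndvi)] <- NA_real_
  out
}

#' Outgoing longwave radiation
#'
#' `RL_up = eps0 sigma Ts^4` per pixel.
#'
#' @param eps0 Surface emissivity matrix.
#' @param ts_K Land surface temperature matrix, kelvin.
#' @return `RL_up` matrix, W m-2.
#' @export
longwave_up <- function(eps0, ts_K) {
  eps0 * .const$sigma * ts_K^4
}

#' Per-pixel net radiation
#'
#' `Rn = (1 - alpha) Rs_down + RL_down - RL_up - (1 - eps0) RL_down`.
#' The last term is the fraction of incoming longwave reflected by the
#' surface.  Scalars broadcast over the grid.
#'
#' @param albedo Albedo matrix.
#' @param rs_down Incoming shortwave, W m-2 (scalar).
#' @param rl_down Incoming longwave, W m-2 (scalar).
#' @param rl_up Outgoing longwave matrix, W m-2.
#' @param eps0 Surface emissivity matrix.
#' @return `Rn` matrix, W m-2.
#' @export
net_radiation <- function(albedo, rs_down, rl_down, rl_up, eps0) {
  (1 - albedo) * rs_down + rl_down - rl_up - (1 - eps0) * rl_down
}
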