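#' Physical constants used throughout the energy balance
#'
#' Fixed constants of the radiation balance and Priestley-Taylor
#' formulation: the solar constant, the Stefan-Boltzmann constant, the
#' specific heat of air at constant pressure, the molecular weight ratio of
#' water vapour to dry air, the latent heat of vaporization, the maximum
#' Priestley-Taylor coefficient, and the daily-upscaling coefficient.
#'
#' @return Named list with elements `gsc` (W m-2), `sigma` (W m-2 K-4),
#'   `cp` (MJ kg-1 degC-1), `mw_ratio` (unitless), `lambda_MJ_per_kg`
#'   (MJ kg-1), `phi_max` (unitless), `alpha_upscale` (unitless).
#' @examples
#' physical_constants()$gsc
#' @export
physical_constants <- function() {
  list(
    gsc              = 1367,      # solar constant, W m-2
    sigma            = 5.67e-8,   # Stefan-Boltzmann, W m-2 K-4
    cp               = 1.013e-3,  # specific heat of air, MJ kg-1 degC-1
    mw_ratio         = 0.622,     # Mw water vapour / dry air
    lambda_MJ_per_kg = 2.45,      # latent heat of vaporization
    phi_max          = 1.26,      # Priestley-Taylor ceiling
    alpha_upscale    = 1.1        # daily upscaling coefficient
  )
}

# internal shorthand
.const <- list(
  gsc = 1367, sigma = 5.67e-8, cp = 1.013e-3, mw_ratio = 0.622,
  lambda_MJ_per_kg = 2.45, phi_max = 1.26, alpha_upscale = 1.1
)

`%||%` <- function(a, b) if (is.null(a)) b else a
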