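#' Parameters of the synthetic Ts-Fr triangle scene generator
#'
#' Defines the ground truth of a generated scene: the true dry edge
#' `Tmax(Fr) = dry_intercept_K + dry_slope_K * Fr`, the true wet-edge
#' temperature, the distribution of vegetation fraction across pixels,
#' and the temperature noise.
#'
#' @param n_rows,n_cols Grid size in pixels.
#' @param dry_intercept_K Dry-edge temperature at `Fr = 0`, kelvin.
#' @param dry_slope_K Dry-edge slope, kelvin per unit `Fr`, `<= 0`.
#' @param t_min_K Wet-edge temperature, kelvin, `< dry_intercept_K`.
#' @param fr_distribution `"uniform"` or `"beta"`.
#' @param beta_shape Length-2 shape parameters when
#'   `fr_distribution = "beta"`.
#' @param ts_noise_sd_K Gaussian noise added to the placed temperatures,
#'   kelvin, `>= 0`.
#' @param seed Random seed; fixed seed gives a bit-identical scene.
#' @return List of class `triangle_params`.
#' @export
triangle_params <- function(n_rows = 200, n_cols = 200,
                            dry_intercept_K = 320, dry_slope_K = -15,
                            t_min_K = 295,
                            fr_distribution = c("uniform", "beta"),
                            beta_shape = c(2, 2),
                            ts_noise_sd_K = 0.5, seed = 1L) {
  fr_distribution <- match.arg(fr_distribution)
  if (dry_slope_K > 0) stop("dry_slope_K must be <= 0", call. = FALSE)
  if (dry_intercept_K <= t_min_K)
    stop("dry edge must lie above the wet edge", call. = FALSE)
  if (ts_noise_sd_K < 0) stop("ts_noise_sd_K must be >= 0", call. = FALSE)
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         dry_intercept_K = dry_intercept_K, dry_slope_K = dry_slope_K,
         t_min_K = t_min_K, fr_distribution = fr_distribution,
         beta_shape = beta_shape, ts_noise_sd_K = ts_noise_sd_K,
         seed = as.integer(seed)),
    class = "triangle_params"
  )
}

# fixed endmember spectra for bands 2,3,6,7 (soil -> full vegetation);
# red and NIR are derived analytically from the target NDVI so that the
# NDVI -> Fr path inverts exactly
.endmembers <- list(
  soil = c(rho2 = 0.12, rho3 = 0.16, rho6 = 0.25, rho7 = 0.20),
  veg  = c(rho2 = 0.04, rho3 = 0.06, rho6 = 0.12, rho7 = 0.07)
)
.ndvi_soil <- 0.1
.ndvi_veg <- 0.9

#' Generate a synthetic Landsat-like scene with known ground truth
#'
#' Emulates the populated Ts-Fr triangle of a vegetation-gradient
#' district scene.  Per pixel: vegetation fraction `Fr` is drawn from the
#' configured distribution; a true Priestley-Taylor coefficient is drawn
#' uniformly in `[1.26 Fr, 1.26]` (every pixel lies inside the
#' triangle); the two-step interpolation is inverted to place the
#' surface temperature between the true edges,
#' `Ts = Tmax(Fr) - ((phi - phi_min) / (1.26 - phi_min)) (Tmax(Fr) - Tmin)`,
#' and Gaussian noise added.  Six reflectance bands are synthesised by
#' linear soil-vegetation mixing between fixed endmember spectra, with
#' red and NIR solved from the implied NDVI
#' (`0.1 + 0.8 sqrt(Fr)`), so that the NDVI and vegetation-fraction
#' operations recover `Fr` exactly when scaled with bounds `(0.1, 0.9)`.
#'
#' @param params A [triangle_params()].
#' @return List with `scene` (an `mpt_scene`) and `truth` (list:
#'   `phi_true`, `fr_true`, `ts_noise_free_K`, `edges_true`).
#' @examples
#' out <- generate_triangle_scene(triangle_params(n_rows = 50, n_cols = 50))
#' range(out$truth$phi_true)
#' @export
generate_triangle_scene <- function(params = triangle_params()) {
  stopifnot(inherits(params, "triangle_params"))
  set.seed(params$seed)
  np <- params$n_rows * params$n_cols
  fr <- switch(params$fr_distribution,
    uniform = stats::runif(np),
    beta = stats::rbeta(np, params$beta_shape[1], params$beta_shape[2])
  )
  phi_min <- .const$phi_max * fr
  phi_true <- stats::runif(np, phi_min, .const$phi_max)
  tmax <- params$dry_intercept_K + params$dry_slope_K * fr
  denom <- .const$phi_max - phi_min
  ratio <- ifelse(denom > 1e-9, (phi_true - phi_min) / denom, 1)
  ts0 <- tmax - ratio * (tmax - params$t_min_K)
  ts <- ts0 + stats::rnorm(np, 0, params$ts_noise_sd_K)

  # band synthesis: mixing weight w = sqrt(Fr), target NDVI linear in w
  w <- sqrt(fr)
  ndvi_t <- .ndvi_soil + (.ndvi_veg - .ndvi_soil) * w
  tot <- 0.44 + 0.16 * w                # rho4 + rho5, soil -> vegetation
  shape <- function(v) matrix(v, params$n_rows, params$n_cols)
  reflectance <- list(
    rho4 = shape(tot * (1 - ndvi_t) / 2),
    rho5 = shape(tot * (1 + ndvi_t) / 2)
  )
  for (b in names(.endmembers$soil)) {
    reflectance[[b]] <-
      shape(.endmembers$soil[[b]] * (1 - w) + .endmembers$veg[[b]] * w)
  }
  grid <- grid_spec(params$n_cols, params$n_rows, pixel_size = 30,
                    crs_id = "EPSG:32644", xll = 500000, yll = 3200000)
  meta <- scene_meta(acquisition_date = "2023-03-15",
                     sun_elevation_deg = 50, overpass_time = 10.5,
                     sensor_id = "SYNTHETIC")
  scene <- mpt_scene(grid, meta, reflectance, shape(ts))
  truth <- list(phi_true = shape(phi_true), fr_true = shape(fr),
                ts_noise_free_K = shape(ts0),
                edges_true = structure(
                  list(dry_intercept = params$dry_intercept_K,
                       dry_slope = params$dry_slope_K,
                       t_min = params$t_min_K,
                       bin_width = NA_real_, fallback = FALSE,
                       bins = NULL, n_pixels = np),
                  class = "edge_model"))
  list(scene = scene, truth = truth)
}

#' Generate paired observed/predicted daily ET series
#'
#' Stand-in for a lysimeter validation series: observed values follow a
#' seasonal ramp from 1.3 to 3.7 mm day-1 (the December-to-April range of
#' daily means in an irrigated winter-crop district), and predictions are
#' the observations plus a fixed bias and Gaussian noise.
#'
#' @param n Number of pairs, `>= 2`.
#' @param bias Added to predictions, mm day-1.
#' @param noise_sd Gaussian noise SD on predictions, mm day-1.
#' @param seed Random seed.
#' @return Data frame with columns `date`, `observed_mm_day`,
#'   `predicted_mm_day`.
#' @export
generate_validation_pairs <- function(n = 8, bias = 0, noise_sd = 0,
                                      seed = 1L) {
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  set.seed(as.integer(seed))
  observed <- seq(1.3, 3.7, length.out = n)
  predicted <- observed + bias + stats::rnorm(n, 0, noise_sd)
  data.frame(
    date = format(seq(as.Date("2022-12-17"), by = "2 weeks",
                      length.out = n)),
    observed_mm_day = observed,
    predicted_mm_day = predicted
  )
}
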