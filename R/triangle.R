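#' Normalized difference vegetation index
#'
#' `NDVI = (rho5 - rho4) / (rho5 + rho4)` from the red and near-infrared
#' bands.  Pixels with a zero denominator become nodata.
#'
#' @param rho4 Red reflectance matrix.
#' @param rho5 Near-infrared reflectance matrix.
#' @return NDVI matrix in `[-1, 1]`.
#' @export
ndvi <- function(rho4, rho5) {
  den <- rho5 + rho4
  out <- (rho5 - rho4) / den
  out[den == 0] <- NA_real_
  out
}

#' Fraction of vegetation from NDVI
#'
#' `Fr = ((NDVI - NDVI_min) / (NDVI_max - NDVI_min))^2`, clipped to
#' `[0, 1]`.  The bounds are the bare-soil and full-canopy NDVI values;
#' by default the fitting routine takes them as per-scene percentiles
#' (see [mpt_control()]), but fixed values may be supplied.
#'
#' @param ndvi NDVI matrix.
#' @param ndvi_min,ndvi_max Scaling bounds, `ndvi_max > ndvi_min`.
#' @return `Fr` matrix in `[0, 1]`.
#' @export
vegetation_fraction <- function(ndvi, ndvi_min, ndvi_max) {
  if (!is.finite(ndvi_min) || !is.finite(ndvi_max) || ndvi_max <= ndvi_min)
    stop("ndvi_max must exceed ndvi_min", call. = FALSE)
  f <- (ndvi - ndvi_min) / (ndvi_max - ndvi_min)
  pmin(pmax(f, 0), 1)^2
}

#' Fit the dry and wet edges of the Ts-Fr triangle
#'
#' Across a scene, land surface temperature plotted against vegetation
#' fraction forms a triangular scatter: the upper, decreasing boundary
#' (the dry edge) traces maximal water stress at each canopy cover, the
#' lower, nearly horizontal boundary (the wet edge) traces unstressed,
#' well-watered conditions.  This routine fits both edges empirically:
#'
#' 1. partition `Fr` in `[0, 1]` into bins of width `bin_width`;
#' 2. in each bin with at least `min_bin_count` pixels, record the
#'    `dry_percentile` temperature as a dry-edge candidate and the
#'    `wet_percentile` temperature as a wet-edge candidate;
#' 3. fit the dry edge by least squares through the dry candidates,
#'    iteratively dropping candidates more than `trim_sd` residual
#'    standard deviations *below* the line (shadowed or mixed bins) and
#'    refitting, at most `max_trim_iter` times;
#' 4. take the wet-edge temperature `t_min` as the median wet candidate
#'    over bins with centre `Fr >= 0.5` (high-cover bins approach the
#'    unstressed state);
#' 5. if the fitted dry slope is positive (no triangle structure), fall
#'    back to a horizontal dry edge at the global `dry_percentile`
#'    temperature and flag the scene.
#'
#' @param ts_K Surface temperature matrix or vector, kelvin.
#' @param fr Vegetation fraction, same shape.
#' @param control A [mpt_control()] list supplying `bin_width`,
#'   `min_bin_count`, `dry_percentile`, `wet_percentile`, `min_pixels`,
#'   `min_fr_span`, `trim_sd`, `max_trim_iter`.
#' @param mask Optional logical mask; only `TRUE` pixels enter the fit
#'   (water pixels are excluded upstream by [mpt()]).
#' @return Object of class `edge_model`: `dry_intercept` (K at Fr = 0),
#'   `dry_slope` (K per unit Fr, typically negative), `t_min` (K),
#'   `bin_width`, `fallback` flag and a `bins` diagnostics data frame
#'   (centre, count, dry/wet candidate temperatures, kept-in-fit flag).
#' @export
fit_edges <- function(ts_K, fr, control = mpt_control(), mask = NULL) {
  ts <- as.vector(ts_K); f <- as.vector(fr)
  keep <- is.finite(ts) & is.finite(f)
  if (!is.null(mask)) keep <- keep & as.vector(mask) & !is.na(as.vector(mask))
  ts <- ts[keep]; f <- f[keep]
  if (length(ts) < control$min_pixels)
    stop(sprintf(paste0("edge fit needs at least %d valid pixels ",
                        "(got %d); enlarge the area of interest"),
                 control$min_pixels, length(ts)), call. = FALSE)
  if (diff(range(f)) < control$min_fr_span)
    stop(sprintf(paste0("vegetation-fraction span %.3f is below the ",
                        "minimum %.2f; the Ts-Fr scatter is too narrow ",
                        "to resolve a triangle — enlarge the area of ",
                        "interest"),
                 diff(range(f)), control$min_fr_span), call. = FALSE)

  breaks <- seq(0, 1, by = control$bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  idx <- findInterval(f, breaks, rightmost.closed = TRUE)
  centres <- (breaks[-length(breaks)] + breaks[-1]) / 2
  n_bin <- tabulate(idx, nbins = length(centres))
  t_dry <- t_wet <- rep(NA_real_, length(centres))
  for (k in which(n_bin >= control$min_bin_count)) {
    tk <- ts[idx == k]
    qs <- stats::quantile(tk, c(control$wet_percentile,
                                control$dry_percentile), names = FALSE)
    t_wet[k] <- qs[1]; t_dry[k] <- qs[2]
  }
  cand <- which(is.finite(t_dry))
  if (length(cand) < 2)
    stop("fewer than two populated Fr bins; cannot fit a dry edge",
         call. = FALSE)

  # iteratively trimmed least squares on the dry candidates
  used <- rep(TRUE, length(cand))
  for (it in seq_len(control$max_trim_iter)) {
    fit <- stats::lm.fit(cbind(1, centres[cand[used]]), t_dry[cand[used]])
    co <- fit$coefficients
    res_all <- t_dry[cand] - (co[1] + co[2] * centres[cand])
    sd_res <- stats::sd(res_all[used])
    if (!is.finite(sd_res) || sd_res == 0) break
    drop_new <- used & (res_all < -control$trim_sd * sd_res)
    if (!any(drop_new) || sum(used) - sum(drop_new) < 2) break
    used <- used & !drop_new
  }
  fit <- stats::lm.fit(cbind(1, centres[cand[used]]), t_dry[cand[used]])
  dry_intercept <- unname(fit$coefficients[1])
  dry_slope <- unname(fit$coefficients[2])

  fallback <- FALSE
  if (dry_slope > 0) {
    fallback <- TRUE
    dry_slope <- 0
    dry_intercept <- unname(stats::quantile(ts, control$dry_percentile,
                                            names = FALSE))
  }

  hi <- cand[centres[cand] >= 0.5 & is.finite(t_wet[cand])]
  t_min <- if (length(hi)) stats::median(t_wet[hi])
           else stats::median(t_wet[cand], na.rm = TRUE)

  bins <- data.frame(centre = centres[cand], n = n_bin[cand],
                     t_dry = t_dry[cand], t_wet = t_wet[cand],
                     used_in_fit = used)
  structure(
    list(dry_intercept = dry_intercept, dry_slope = dry_slope,
         t_min = t_min, bin_width = control$bin_width,
         fallback = fallback, bins = bins, n_pixels = length(ts)),
    class = "edge_model"
  )
}

#' @export
print.edge_model <- function(x, ...) {
  cat("<edge_model> Ts-Fr triangle edges\n")
  cat(sprintf("  dry edge: Tmax(Fr) = %.2f %+.2f Fr  [K]%s\n",
              x$dry_intercept, x$dry_slope,
              if (x$fallback) "  (horizontal fallback)" else ""))
  cat(sprintf("  wet edge: Tmin = %.2f K\n", x$t_min))
  cat(sprintf("  fitted on %d pixels in %d bins (%d kept)\n",
              x$n_pixels, nrow(x$bins), sum(x$bins$used_in_fit)))
  invisible(x)
}

#' @export
coef.edge_model <- function(object, ...) {
  c(dry_intercept = object$dry_intercept, dry_slope = object$dry_slope,
    t_min = object$t_min)
}

#' Per-pixel Priestley-Taylor coefficient by two-step interpolation
#'
#' Between the fitted edges, the coefficient is interpolated linearly in
#' temperature at each vegetation fraction:
#' `phi = ((Tmax_i - Ts) / (Tmax_i - Tmin)) (phi_max - phi_min_i) + phi_min_i`
#' with `Tmax_i = dry_intercept + dry_slope * Fr` (the dry edge at the
#' pixel's cover), `phi_max = 1.26` and `phi_min_i = 1.26 Fr`.  A pixel on
#' the wet edge attains 1.26; the dry bare-soil corner attains 0.  Pixels
#' outside the triangle are clipped into `[0, 1.26]`.  `Tmax_i` is clamped
#' to at least `t_min + tmax_clamp` so the denominator never degenerates
#' where the edges nearly touch at high cover.
#'
#' @param ts_K Surface temperature matrix, kelvin.
#' @param fr Vegetation fraction matrix.
#' @param edges An [fit_edges()] result (or any list with
#'   `dry_intercept`, `dry_slope`, `t_min`).
#' @param tmax_clamp Minimum dry-wet separation, kelvin (default 0.5).
#' @return `phi` matrix in `[0, 1.26]`.
#' @export
phi_map <- function(ts_K, fr, edges, tmax_clamp = 0.5) {
  tmax <- pmax(edges$dry_intercept + edges$dry_slope * fr,
               edges$t_min + tmax_clamp)
  phi_min <- .const$phi_max * fr
  phi <- ((tmax - ts_K) / (tmax - edges$t_min)) *
    (.const$phi_max - phi_min) + phi_min
  pmin(pmax(phi, 0), .const$phi_max)
}
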