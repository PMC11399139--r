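# Independent scalar evaluators of every equation-level formula, coded
# directly from the printed forms and kept separate from the package
# implementation.  Used for oracle-equivalence tests on random inputs.

oracle <- list(
  dr        = function(doy) 1 + 0.033 * cos(doy * 2 * pi / 365),
  cos_theta = function(elev_deg) sin(elev_deg * pi / 180),
  tetens_ea = function(tdew_K) {
    td <- tdew_K - 273.15
    0.6108 * exp(17.27 * td / (td + 237.3))
  },
  w         = function(ea, pair) 0.14 * ea * pair + 2.1,
  tau_b     = function(pair, kt, ct, w)
    0.98 * exp(-0.00146 * pair / (kt * ct) - 0.075 * (w / ct)^0.4),
  tau_d     = function(tb) if (tb >= 0.15) 0.35 - 0.36 * tb
                           else 0.18 + 0.82 * tb,
  eps_a     = function(tsw) 0.85 * (-log(tsw))^0.09,
  gamma     = function(pair) 1.013e-3 * pair / (0.622 * 2.45),
  delta     = function(t_K) {
    tc <- t_K - 273.15
    4098 * (0.6108 * exp(17.27 * tc / (tc + 237.3))) / (tc + 237.3)^2
  },
  albedo    = function(r) 0.254 * r[1] + 0.149 * r[2] + 0.147 * r[3] +
                          0.311 * r[4] + 0.103 * r[5] + 0.036 * r[6],
  rs_down   = function(ct, dr, tsw) 1367 * ct * dr * tsw,
  rl        = function(eps, t_K) eps * 5.67e-8 * t_K^4,
  eps0      = function(nd) {
    if (nd <= 0) return(0.985)
    min(max(1.009 + 0.047 * log(nd), 0.9), 1.009)
  },
  rn        = function(a, rs, rld, rlu, e0)
    (1 - a) * rs + rld - rlu - (1 - e0) * rld,
  g_ratio   = function(ts_C, a, nd)
    min(max((ts_C / a) * (0.0038 * a + 0.0074 * a^2) *
              (1 - 0.98 * nd^4), 0), 0.5),
  fr        = function(nd, lo, hi)
    min(max((nd - lo) / (hi - lo), 0), 1)^2,
  phi       = function(ts, fr, a, b, tmin, clamp = 0.5) {
    tmax <- max(a + b * fr, tmin + clamp)
    pmin <- 1.26 * fr
    min(max(((tmax - ts) / (tmax - tmin)) * (1.26 - pmin) + pmin, 0), 1.26)
  },
  le        = function(phi, avail, d, g) phi * avail * d / (d + g),
  et_i      = function(le) 3600 * le / 2.45e6,
  et_d      = function(ef, e_d, alpha) alpha * ef * e_d / 2.45,
  r2        = function(y, yh) {
    n <- length(y)
    num <- sum((y - mean(y)) * (yh - mean(yh))) / n
    sy <- sqrt(sum((y - mean(y))^2) / n)
    syh <- sqrt(sum((yh - mean(yh))^2) / n)
    (num / (sy * syh))^2
  },
  rmse      = function(y, yh) sqrt(sum((y - yh)^2) / length(y)),
  d_index   = function(y, yh)
    1 - sum((y - yh)^2) /
      sum((abs(yh - mean(y)) + abs(y - mean(y)))^2),
  nsme      = function(y, yh)
    1 - sum((y - yh)^2) / sum((y - mean(y))^2),
  mbe       = function(y, yh) sum(y - yh) / length(y)
)

# small helper: a fully valid scene + meteorology for pipeline tests
make_test_fit <- function(n = 80, noise = 0.5, seed = 42,
                          bounds = c(0.1, 0.9), ...) {
  syn <- generate_triangle_scene(
    triangle_params(n_rows = n, n_cols = n, ts_noise_sd_K = noise,
                    seed = seed, ...))
  met <- meteo_snapshot(ta_K = 298, pair_kPa = 101, ea_kPa = 1.5)
  fit <- mpt(syn$scene, met, latitude = 29,
             control = mpt_control(ndvi_bounds = bounds,
                                   min_pixels = min(1000, n * n / 2)))
  list(syn = syn, met = met, fit = fit)
}

expect_rel_equal <- function(actual, expected, tol = 1e-10) {
  denom <- pmax(abs(expected), 1e-300)
  expect_lt(max(abs(actual - expected) / denom), tol)
}
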