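---
title: "Methods: triangle-based Priestley-Taylor ET mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triangle-based Priestley-Taylor ET mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mptet)
```

## The model and its assumptions

`mptet` maps daily crop evapotranspiration from a single clear-sky
optical/thermal scene plus scalar reanalysis meteorology. The latent
heat flux is the Priestley-Taylor form

$$LE = \phi\,(R_n - G)\,\frac{\Delta}{\Delta + \gamma},$$

which deliberately avoids the sensible heat flux and its aerodynamic
resistances. Everything therefore hinges on four quantities, each
computed per pixel or per scene:

* **Net radiation** $R_n = (1-\alpha)R_{s\downarrow} + R_{L\downarrow}
  - R_{L\uparrow} - (1-\varepsilon_0)R_{L\downarrow}$, with broadband
  albedo as a fixed-weight sum over bands 2-7 (weights sum to exactly
  1), clear-sky shortwave $G_{sc}\cos\theta\,d_r\tau_{sw}$, a beam +
  diffuse transmissivity split with a clearness coefficient $K_t$
  (default 1, clean air), and Stefan-Boltzmann longwave terms.
  $R_{s\downarrow}$ and $R_{L\downarrow}$ are *scene scalars*: the sun
  geometry and the reanalysis air column are taken uniform over a
  district-scale grid. This is appropriate for flat terrain only.
* **Soil heat flux** from the empirical near-mid-day ratio
  $G/R_n = (T_{s,°C}/\alpha)(0.0038\alpha + 0.0074\alpha^2)
  (1 - 0.98\,\mathrm{NDVI}^4)$. The surface temperature enters in
  Celsius: in kelvin the ratio would exceed 1 for any ordinary scene,
  contradicting both the crop-field range the formula was derived for
  and the 0.04-0.18 scene means a realistic run produces. The ratio is
  clipped to $[0, 0.5]$ as a guard for extreme bare hot pixels.
* **The PT coefficient** $\phi$ by two-step linear interpolation in the
  Ts-Fr triangle (next section), spanning 0 (dry bare soil) to 1.26
  (well-watered).
* **Daily upscaling**: the evaporative fraction
  $EF = LE/(R_n - G) = \phi\,\Delta/(\Delta+\gamma)$ is assumed
  constant over daylight; daily available energy is integrated
  analytically from a half-sine arc (below); and
  $ET_d = \alpha_u\,EF\,(R_n-G)_d/\lambda$ with $\alpha_u = 1.1$
  compensating the systematic low bias of plain EF upscaling, and
  $\lambda = 2.45$ MJ kg$^{-1}$ converting energy (MJ m$^{-2}$) to
  water depth (mm). For the instantaneous conversion
  $ET_i = 3600\,LE/\lambda$ the latent heat is used in J kg$^{-1}$
  ($2.45\times10^6$) so that W m$^{-2}$ becomes mm h$^{-1}$; the two
  unit conventions are kept strictly inside their respective functions.

Key assumptions, then: clear sky, flat terrain, a uniform air column,
mid-day overpass, daily soil-heat closure ($G_d \approx 0$), and a
scene heterogeneous enough to populate the Ts-Fr triangle.

## Edge fitting in the Ts-Fr triangle

The triangle method needs the scene's *dry edge* (upper, decreasing
bound of surface temperature vs. vegetation fraction) and *wet edge*
(lower, near-horizontal bound). Only the scatter itself is observable,
so the edges are a fitted model — the heart of the package, exposed as
`fit_edges()` and wrapped by the `mpt()` fitting function with the
usual `coef`/`predict`/`plot`/`residuals` surface.

The algorithm: bin Fr into widths of 0.05; in every bin holding at
least 20 pixels take the 99.5th within-bin temperature percentile as a
dry-edge candidate and the 0.5th as a wet-edge candidate; fit the dry
edge by least squares through the candidates, iteratively dropping any
candidate more than 2 residual standard deviations *below* the line
(bins contaminated by shadow, water or cloud edges depress candidates;
nothing physical pushes them above) and refitting, at most 5 times.
The wet-edge temperature is the median wet candidate over bins with
centre $Fr \ge 0.5$, where pixels approach the unstressed state. If
the fitted dry slope comes out positive there is no triangle structure
to exploit; the fit falls back to a horizontal dry edge at the global
99.5th percentile and flags the scene. Percentiles rather than
extremes, trimming, and the fallback are all robustness choices; the
defaults follow the Ts-VI triangle literature and are exposed in
`mpt_control()`.

Preconditions: at least 1000 valid pixels spanning an Fr range of at
least 0.3. Scenes narrower than that cannot support a two-edge fit and
raise an error suggesting a larger area of interest.

Two numerical guards in the interpolation itself: $T_{max}(Fr)$ is
clamped to at least $T_{min} + 0.5$ K so the denominator cannot
degenerate where the fitted edges nearly touch at high cover, and the
result is clipped to $[0, 1.26]$ for pixels outside the fitted
triangle (hotter than the dry edge or cooler than the wet edge).

The wet edge is modelled as a constant (horizontal line). An
Fr-dependent wet edge is a conceivable refinement, but the scatter's
lower bound is nearly flat in practice and a constant keeps the
interpolation's wet-edge limit exact.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `ndvi_percentiles` | 2nd/98th | — | per-scene NDVI bounds for Fr; percentiles resist outliers. Fixed bounds via `ndvi_bounds` when the scene's extremes are known. |
| `bin_width` | 0.05 | Fr | 20 bins balance per-bin population against edge resolution |
| `min_bin_count` | 20 | pixels | below this, within-bin percentiles are noise |
| `dry_percentile` / `wet_percentile` | 0.995 / 0.005 | — | near-extremes robust to a few bad pixels |
| `trim_sd`, `max_trim_iter` | 2, 5 | — | one-sided candidate trimming (see above) |
| `tmax_clamp` | 0.5 | K | minimum dry-wet separation in the denominator |
| `kt` | 1.0 | — | clean air; lower for turbid/dusty atmospheres |
| `alpha_upscale` | 1.1 | — | EF-method bias compensation in daily upscaling |
| `daylight_hours` | computed | h | sunset-hour-angle formula from latitude and day of year; overridable |

Water pixels (NDVI $\le 0$) are excluded from edge fitting — they
would contaminate the wet edge — but still receive $\phi$ and ET like
any pixel. Their surface emissivity is set to 0.985, a standard
broadband water value; the logarithmic NDVI-emissivity formula applies
only for NDVI $> 0$ and is clipped below at 0.9 near NDVI
$\to 0^+$, where the logarithm diverges.

## Half-sine daily energy

Instantaneous available energy is assumed to follow
$E(t) = E_{peak}\sin(\pi (t - t_{sunrise})/N)$ over a daylight period
of $N$ hours, zero at sunrise and sunset, peaking at solar noon
(assumed 12:00 local solar time, sunrise at $12 - N/2$). $E_{peak}$ is
recovered from the overpass observation and the overpass time, and the
arc integrates in closed form to $E_{peak}\,2N\cdot3600/\pi$ J m$^{-2}$.
With constant EF this makes the integral of $ET_i$ over the day equal
$ET_d/\alpha_u$ exactly — a unit-consistency identity the test suite
verifies numerically. An overpass outside daylight is an error, and a
`user_supplied` mode passes through an externally computed daily
energy raster instead. Scene metadata records the overpass as local
solar time; real Landsat metadata stores UTC, so users at longitudes
far from their time meridian should set the overpass time explicitly.

## The synthetic scene generator

`generate_triangle_scene()` emulates the one thing the method needs
from real data: a populated Ts-Fr triangle with known truth. Fr is
drawn per pixel (uniform by default), a true $\phi$ is drawn uniformly
in $[1.26\,Fr,\ 1.26]$ so every pixel lies inside the triangle, the
interpolation is inverted to place Ts between a true dry edge
($320 - 15\,Fr$ K by default) and wet edge (295 K), and Gaussian noise
(SD 0.5 K by default, the order of a thermal retrieval error) is
added. Six reflectance bands come from linear soil-vegetation mixing
between fixed endmember spectra, with red and NIR solved analytically
from the implied NDVI ($0.1 + 0.8\sqrt{Fr}$) so that the NDVI →
vegetation-fraction path inverts Fr *exactly* under bounds
$(0.1, 0.9)$ — generator errors never masquerade as pipeline errors.
The default 200×200 grid with the edges above yields district-like
flux magnitudes (mean $R_n \approx 480$ W m$^{-2}$, $G/R_n$ scene
means in the 0.04-0.18 band, daily ET of 1-6 mm).

What the generator does **not** emulate: clouds and cloud shadows,
sensor noise and striping in the reflectance bands, mixed water/urban
land cover, topographic temperature gradients, and atmospheric
heterogeneity. Passing recovery tests on synthetic scenes therefore
demonstrates the correctness and stability of the fitting machinery —
not retrieval accuracy on real imagery, which additionally depends on
LST quality, cloud masking and the flat-terrain assumption.

Test and acceptance runs use 224×224 (≈50k pixels, ten seeds) for
noisy edge-recovery checks and 200×200 for noise-free inversion; these
sizes populate all 20 Fr bins densely while keeping a full
generate-fit-verify cycle around a second.

## Validation statistics

Five statistics compare paired observed/estimated ET: R² (squared
Pearson correlation, population-moment form), RMSE ($n$ denominator),
Willmott's agreement index
$d = 1 - \sum(y-\hat y)^2 / \sum(|\hat y - \bar y| + |y - \bar y|)^2$
with the square applied per term of the denominator sum (the standard
Willmott form), Nash-Sutcliffe efficiency, and mean bias error
computed as $\mathrm{mean}(y - \hat y)$ — note that under this sign
convention a *negative* MBE means overestimation. The convention is
recorded in the JSON report. Degenerate inputs (constant series) raise
errors rather than returning NaN.

## Known limitations

* Flat-terrain only: no topographic correction of incidence angle or
  air temperature; elevation gradients bias both $R_n$ and the
  triangle.
* Clear-sky only: no cloud masking is built in; the area-of-interest
  mask must exclude clouds.
* The LST raster is an input; its retrieval (and the thermal band's
  resampling from 100 m to 30 m) happens upstream.
* Edge fitting needs scene heterogeneity; small or homogeneous areas
  of interest fail the Fr-span precondition by design.
* Rasters are exchanged as ESRI ASCII grids with a JSON sidecar for
  CRS and units — simple, text-based and lossless, at the cost of
  larger files than a compressed binary format.
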