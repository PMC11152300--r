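# circmag

Circular statistics for geomagnetic cues in animal movement tracks.

Migratory birds are believed to read the Earth's magnetic field — its
**declination** D (angle of the horizontal field east of geographic
north) and **inclination** I (dip of the field below the horizontal) —
when choosing where to fly next. Testing this statistically is a
directional-data problem twice over: both the response (the bird's
per-segment travel direction θ) and the candidate covariates (D, I, or
their changes along the route) live on the circle, where ordinary
correlation and regression are meaningless. `circmag` provides the full
chain of tools for this analysis, for movement ecologists and
biostatisticians working with Movebank-style GPS tracks:

- **Geodesy** — great-circle central angles (haversine form of
  `cos θ = sin φ_A sin φ_B + cos φ_A cos φ_B cos ΔL`), forward azimuths,
  and per-segment direction series from timed (lat, lon) tracks.
- **Geomagnetic field synthesis** — the scalar potential
  `V = a Σ_n Σ_m (a/r)^(n+1) (g_n^m cos mλ + h_n^m sin mλ) P̆_n^m(sin φ)`
  and its vector field (north/east/down components), evaluated from
  Schmidt semi-normalised Gauss coefficient sets with linear (optionally
  quadratic) secular variation, read from and written to WMM-style
  `.COF` text files.
- **Circular statistics** — the von Mises density
  `f(θ) = e^{κ cos(θ−μ)} / (2π I₀(κ))`, its distribution function,
  sampler and maximum-likelihood fit; Watson's U² goodness-of-fit
  statistic `W² = Σ[(U_(i) − (2i−1)/2n) − (Ū − ½)]² + 1/(12n)` with
  Monte-Carlo / parametric-bootstrap critical values; the
  circular-circular correlation
  `r = Σ sin(θᵢ−θ̄) sin(Mᵢ−M̄) / √(Σ sin²(θᵢ−θ̄) Σ sin²(Mᵢ−M̄))`
  and its asymptotic z test of `H₀: ρ_c = 0`.
- **Circular-circular regression** — `E(cos β | α)` and `E(sin β | α)`
  fitted as trigonometric polynomials of degree m on a shared design
  matrix, with predicted direction `atan2(ĝ₂, ĝ₁)`, residual dispersion
  matrix, a BIC-style degree selector, and a model association `ρ`
  (circular correlation of observed and fitted directions).
- **Synthetic data** — seeded generators for coefficient sets and for
  spherical-dead-reckoning tracks whose headings are von Mises draws,
  optionally coupled to the local field angles with known strength, so
  every stage of the pipeline is testable with planted ground truth.
- **Pipeline** — `read_tracks()` → `direction_series()` →
  `magnetic_covariates()` → Watson / correlation / regression per
  species, a results table with CSV/JSON writers, ggplot2 helpers, and a
  thin command-line front end (`inst/cli/circmag.R`).

All functions take and return tibbles or plain vectors and compose with
the pipe. Angles are radians internally; geographic coordinates and
field angles cross the package boundary in degrees.

## Worked example

Simulate a field, a track whose headings are coupled to inclination
with strength 0.7, and run the full per-species analysis:

```r
library(circmag)

coef <- synthetic_coefficients("randomized", n_max = 8, seed = 42)
sim <- simulate_coupled_track(
  n_points = 400, coeffs = coef, coupling = 0.7,
  covariate = "inclination", covariate_mode = "point",
  species = "synthetic-heron", seed = 7
)
results <- run_analysis(
  sim$track, coef,
  analysis_config(covariate_mode = "point", n_boot = 500, seed = 1)
)
dplyr::glimpse(results)
#> Rows: 1
#> Columns: 15
#> $ species         <chr> "synthetic-heron"
#> $ n_segments      <int> 399
#> $ watson_u2       <dbl> 0.1241929
#> $ watson_critical <dbl> 0.09846132
#> $ watson_reject   <lgl> TRUE
#> $ r_inclination   <dbl> 0.5215865
#> $ z_inclination   <dbl> 9.511574
#> $ p_inclination   <dbl> 1.877992e-21
#> $ rho_inclination <dbl> 0.5216028
#> $ r_declination   <dbl> 0.3933362
#> $ z_declination   <dbl> 7.533207
#> $ p_declination   <dbl> 4.950887e-14
#> $ rho_declination <dbl> 0.4000378
#> $ degree          <int> 1
#> $ skip_reason     <chr> NA
```

Reading the row: the track has 399 direction segments. The planted
inclination coupling is found — the circular correlation between the
birds' bearings and the inclination along the route is `r = 0.52` with
`z = 9.5` (p ≈ 2e-21), and the degree-1 circular-circular regression
reproduces it as `ρ = 0.52`. Declination also registers (`r = 0.39`)
because declination and inclination co-vary across this synthetic
field. The Watson test rejects a *single* von Mises distribution for
the bearings (`U² = 0.124` above its bootstrap critical value 0.098) —
expected here, since coupled headings are a von Mises *mixture* along
the magnetic gradient:

```r
theta <- direction_series(sim$track)$theta
vm_mle(theta)
#> von Mises MLE: mu = 1.8636 rad, kappa = 3.0810 (n = 399, Rbar = 0.8158)
```

`plot_track(sim$track)`, `plot_rose(theta)` and `plot_results(results)`
draw the track, the bearing rose and the per-species correlation
summary; `write_results(results, "results.json", format = "json")`
stores the table with its full configuration echo, byte-reproducibly
given the master seed.

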