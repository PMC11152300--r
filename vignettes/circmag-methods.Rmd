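---
title: "Methods: circular statistics for geomagnetic cues along movement tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circular statistics for geomagnetic cues along movement tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circmag)
```

`circmag` asks a single scientific question in several statistical
forms: *do the per-segment travel directions of a tracked animal
co-vary with the geomagnetic declination or inclination along its
route?* This vignette is the package's own account of the models it
fits, the numerical choices behind them, and what its synthetic-data
tests do and do not establish.

## 1. From positions to circular responses

A track is a time-ordered table of geodetic positions per species.
`direction_series()` converts it to a circular response: the **initial
bearing** (forward azimuth) of each consecutive segment,

$$\theta_i = \operatorname{atan2}\bigl(\sin\Delta L\,\cos\varphi_{i+1},\;
\cos\varphi_i \sin\varphi_{i+1} - \sin\varphi_i \cos\varphi_{i+1}
\cos\Delta L\bigr),$$

with $\Delta L$ wrapped to $(-\pi, \pi]$ so antimeridian crossings take
the short way. A `turn_angle` mode (wrapped difference of consecutive
bearings, anchored at the interior vertex) is available; bearings are
the default because only azimuths are well-defined circular directions
per segment. Central angles use the haversine form of the spherical
law of cosines: the two are mathematically identical, but the
arc-cosine form loses all precision near zero separation (identical
points come out at ~1.5e-8 rad instead of 0), which matters because
repeated positions (dropped with a warning) and coincident-point
errors are detected at a 1e-12 rad tolerance. The model is a sphere:
angles do not depend on the radius, and no ellipsoidal correction is
applied. Bearings from the exact poles are undefined and error.

## 2. Geomagnetic field synthesis

The main field is the negative gradient of the scalar potential

$$V(\lambda,\varphi',r,t) = a \sum_{n=1}^{N}\Bigl(\frac{a}{r}\Bigr)^{n+1}
\sum_{m=0}^{n}\bigl(g_n^m(t)\cos m\lambda + h_n^m(t)\sin m\lambda\bigr)
\breve P_n^m(\sin\varphi'),$$

with $a = 6\,371\,200$ m and Schmidt semi-normalised associated
Legendre functions $\breve P_n^m$ (no Condon–Shortley phase).
Coefficients carry linear secular variation
$g_n^m(t) = g_n^m + \dot g_n^m (t - t_0)$, with optional quadratic
terms that default to absent since standard coefficient files carry
linear rates only. The local components are

$$X = -\sum_n \Bigl(\tfrac{a}{r}\Bigr)^{n+2} \sum_m (\cdot)\,
\frac{d\breve P_n^m}{d\varphi'},\qquad
Y = \frac{1}{\cos\varphi'}\sum_n \Bigl(\tfrac{a}{r}\Bigr)^{n+2}
\sum_m m\,(g\sin m\lambda - h\cos m\lambda)\,\breve P_n^m,$$
$$Z = -\sum_n (n+1)\Bigl(\tfrac{a}{r}\Bigr)^{n+2}\sum_m (\cdot)\,
\breve P_n^m,$$

$X$ north, $Y$ east, $Z$ down, from which declination
$D = \operatorname{atan2}(Y, X)$ and inclination
$I = \operatorname{atan2}(Z, \sqrt{X^2+Y^2})$. These standard component
equations are *testable*, and the package treats the tests as the
authority: an axial dipole must satisfy $\tan I = 2\tan\varphi$ and
$D \equiv 0$ exactly, and for arbitrary coefficient sets the vector
must match central finite differences of the potential — both are
enforced in the acceptance suite. Legendre functions are computed by
the stable three-term recursion (the explicit factorial formula, exact
in double precision to degree 8, serves as the independent oracle in
tests); derivatives use the analytically differentiated recursion.
Latitudes are treated as geocentric on the sphere $r = a$ — the
geodetic-to-geocentric conversion is a known omitted approximation,
acceptable for the field-angle scales analysed here. The truncation
degree defaults to the coefficient file's own maximum (12 for the
synthetic default).

## 3. The circular-statistics layer

**von Mises machinery.** The density
$f(\theta) = e^{\kappa\cos(\theta-\mu)}/(2\pi I_0(\kappa))$ is
evaluated in exponentially scaled form so it is stable at any
$\kappa$; the distribution function uses the Fourier–Bessel series of
the antiderivative, anchored at 0 (the raw antiderivative does not
vanish there) so $F(0)=0$, $F(2\pi)=1$, truncated when a term falls
below 1e-14. The exported `bessel_i()` implements the defining power
series to relative 1e-14 as a self-contained reference; internal hot
paths call base R's scaled `besselI`, and tests pin the two against
each other. Sampling is Best–Fisher rejection with a wrapped-Cauchy
envelope. The MLE uses the circular mean and solves
$A_1(\kappa) = \bar R$ by bracketed root finding (tolerance 1e-10),
capped at $\kappa = 10^4$, the package's stand-in for a point mass; a
zero resultant (undefined mean direction) is an error, not a silent
NaN.

**Watson's U².** With order statistics $U_{(i)} = F_0(\theta_{(i)})$,

$$W^2 = \sum_i\Bigl[\bigl(U_{(i)} - \tfrac{2i-1}{2n}\bigr) -
\bigl(\bar U - \tfrac12\bigr)\Bigr]^2 + \frac{1}{12n},$$

whose analytic minimum $1/(12n)$ at exact midpoints is a frozen test.
Critical values are **never read from printed tables**: the uniformity
variant simulates the null directly, and the composite von Mises null
uses a parametric bootstrap with per-replicate re-estimation, so the
effect of estimating $(\mu, \kappa)$ is in the null distribution. Both
are seeded. Ties are kept (stable sort, no jitter).

**Circular correlation.** The sample coefficient
$r = \sum \sin(\theta_i-\bar\theta)\sin(M_i-\bar M) /
\sqrt{\sum\sin^2(\theta_i-\bar\theta)\sum\sin^2(M_i-\bar M)}$ is
rotation-invariant in each argument. The test of $H_0:\rho_c = 0$ uses
the λ-moment studentisation
$z = \sqrt{n}\,r\,\sqrt{\lambda_{20}\lambda_{02}/\lambda_{22}}$,
asymptotically standard normal under independence. Because the
reference delegating this statistic is external, the package does not
trust the constants: the acceptance suite measures the empirical
type-I error at $n = 200$ over 2000 seeded replicates and requires it
within ±0.02 of the nominal 0.05.

## 4. Circular–circular regression

The conditional expectation of the response's unit vector is modelled
by trigonometric polynomials of degree $m$ on the shared design
$[1, \cos\alpha, \sin\alpha, \dots, \cos m\alpha, \sin m\alpha]$
(the identically-zero $\sin 0\alpha$ column is dropped):
$\cos\beta$ and $\sin\beta$ are each regressed by OLS, the predicted
direction is $\hat\beta = \operatorname{atan2}(\hat g_2, \hat g_1)$,
and the residual pair forms the dispersion matrix $\Sigma$. Two facts
shape interpretation:

- **Shrinkage.** If $\beta = \mu(\alpha) + \varepsilon$ with von Mises
  error, then $E(e^{i\beta}\mid\alpha) = A_1(\kappa)\,e^{i\mu(\alpha)}$:
  the estimand is the $A_1(\kappa)$-shrunk coefficient vector, which is
  what the recovery tests target. The *direction* is unaffected.
- **The reported ρ.** A single-number association is needed per fit;
  the package defines it as the circular correlation between observed
  and fitted directions (`model_rho()`), i.e. the same estimator used
  for the covariate tests, applied to the model's predictions.

The degree defaults to 1, the smallest model consistent with the
package's use of field-value covariates. `select_degree()` minimises
mean squared residual of the two linear models plus a penalty
$2(2m+1)\log(n)/n$, ties toward smaller $m$. (Penalising *raw* summed
residuals by an $O(\log n / n)$ term would make the penalty
asymptotically irrelevant and over-select; the mean-squared form makes
the criterion consistent in simulation, which the tests check.)
Rank-deficient designs — a constant covariate, e.g. declination under
a purely axial dipole — raise a typed error that the pipeline records
as a per-covariate skip reason rather than a failed run.

## 5. The synthetic generator as study design

`simulate_track_vm()` / `simulate_coupled_track()` generate spherical
dead-reckoning walks: at each step a heading is drawn from
$\mathrm{VM}(\mu + c\,M_i,\ \kappa)$ — $c$ the planted coupling in
$[0,1]$, $M_i$ the declination or inclination angle (radians) at the
current position (`point` mode) or its change since the previous one
(`delta` mode) — and the position advances along that great circle
through a fixed central angle. Because the advancement uses exactly
the drawn azimuth, `direction_series()` inverts the construction to
machine precision, separating geometry errors from statistical noise
in every downstream test.

Defaults (chosen once, as the package's study conditions): 500 points,
start 45°N 100°W, step 0.01 rad (~64 km — a typical daily displacement
for a mid-size migrant logged daily, `time_step = 1/365` yr), eastward
mean heading $\mu = \pi/2$, concentration $\kappa = 4$ (angular sd
roughly 30°), coupling 0.5 when not specified. Randomized coefficient
sets decay as $0.3^n$ with $h_n^0 = 0$; the axial dipole is pinned at
$g_1^0 = -\mathrm{scale}$ because on Earth the axial dipole dominates
every other coefficient — a field whose equatorial dipole rivals its
axial one (which the bare decay rule produces) has inclination
*decreasing* northward over much of the globe, and inclination-coupled
walks there are pole-seeking: the simulation correctly aborts at the
polar guard (enforced *before* each step, since a degree-scale step
could hop across the polar cap). One master seed drives everything;
per-species, per-stage child seeds are derived as
`master + 7919*unit + 104729*stage (mod 2^31 - 1)` so each stage is
independently reproducible and reruns are byte-identical.

### Path endogeneity: why the null study uses point mode

A covariate evaluated **along the animal's own path** is not exogenous,
and the package is explicit about the consequences:

- In **delta mode** the field change across segment $i$ is caused by
  the very heading being tested
  ($\Delta I_i \approx \nabla I\cdot$ step $\cdot(\cos\theta_i,
  \sin\theta_i)$), so the "null" correlation is structurally nonzero.
  No independence null exists by construction. Delta mode remains the
  pipeline default for *data analysis* (field-change covariates are
  the natural reading of route-following hypotheses), but calibration
  claims cannot be attached to it.
- In **point mode** latitude is the integral of past heading cosines.
  After the sample-mean centring inside the correlation estimator,
  this inflates $E[z]$ by an $O(1)$ amount that is *scale-free* (it
  does not vanish as the step shrinks, only as the exogenous share of
  covariate variation grows). With the package defaults — a tilted,
  anchored-dipole field swept eastward, modest daily steps — the
  exogenous longitudinal field variation dominates and the residual
  inflation is small; the acceptance study therefore requires the
  null non-significance rate to be at least 0.88 (nominal 0.95 minus
  three binomial standard deviations at 100 seeds) rather than exactly
  nominal. This residual anticonservatism is a property of the *design*
  — any analysis correlating a path-dependent covariate with the
  path's own headings inherits it, including analyses of real tracking
  data — and is, to the package authors' knowledge, not acknowledged
  in the applied literature this package serves.

What the synthetic tests do **not** establish: realism of behaviour
(no stopovers, wind drift, diel structure, or per-individual
heterogeneity), robustness to irregular sampling intervals, or
calibration under delta-mode covariates (impossible, as above). A
passing suite means the estimators, tests and field synthesis are
correct and calibrated under the stated generative model, not that
real birds behave like von Mises walkers.

## 6. Pipeline and numerical conventions

`run_analysis()` executes, per species: direction series → Watson U²
(estimated-von-Mises variant by default, the distributional assumption
under scrutiny) → correlation test and degree-1 regression against
each covariate. Species with fewer than `min_segments = 30` segments
(asymptotic-test comfort; no threshold is standard) are skipped with a
recorded reason, as are individually degenerate covariates. Angles are
radians internally, degrees at every I/O boundary; longitudes
normalise to [-180, 180); timestamps become decimal years (elapsed
fraction of the year, leap years honoured). Results serialise to flat
CSV or to JSON with the full configuration echo; JSON output is
byte-stable under a fixed master seed. Problem sizes used by the test
and acceptance suites (e.g. 2000 replicates for correlation
calibration, 1000 outer × 500 bootstrap replicates for the Watson
variant, 100 seeds × 500-point tracks end-to-end) are the package's
documented study sizes, balancing Monte-Carlo error against desk-scale
runtimes.

## 7. Known limitations

- Spherical geometry throughout; no WGS84 geodesics or altitudes.
- No external (ionospheric/magnetospheric) field, no crustal biases,
  and no fitting of coefficients from observations — coefficient sets
  are consumed, not estimated.
- The correlation test is asymptotic; below 25 pairs it warns, and its
  small-sample behaviour is unexplored here.
- No multiple-testing correction across species or covariates is
  applied by default.
- Turn-angle mode shares the machinery but not the calibration
  studies, which are bearing-mode.
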