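---
title: "Trimodal modelling of CT muscle radiodensity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trimodal modelling of CT muscle radiodensity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntra)
```

## The problem

A single mid-thigh CT cross-section summarizes the composition of aging
skeletal muscle: fat attenuates X-rays less than water, muscle more, so the
distribution of Hounsfield unit (HU) values over the soft-tissue pixels
carries information about myosteatosis, atrophy and connective-tissue
infiltration that a single mean HU or a fat/lean area split compresses away.
This package models the *entire* radiodensitometric distribution and asks
how much extra correlation with clinical function that buys.

The soft-tissue HU axis splits into three domains: fat at
[-200, -10] HU, loose connective / water-equivalent tissue at [-9, 40] HU,
and muscle at [41, 200] HU. The pixel distribution is modelled as a
*quasi*-probability density — a sum of two skewed and one standard Gaussian
component, one per tissue type:

$$\sum_{i=1}^{3} \varphi(x; N_i, \mu_i, \sigma_i, \alpha_i)
  = \sum_{i=1}^{3} \frac{N_i}{\sigma_i\sqrt{2\pi}}
    \, e^{-\,(x-\mu_i)^2 / 2\sigma_i^2}
    \, \operatorname{erfc}\!\Big(\frac{\alpha_i (x-\mu_i)}{\sigma_i\sqrt{2}}\Big)$$

Each component integrates to its amplitude $N_i$ (the odd erf term
integrates to zero), so the amplitudes are tissue mass fractions when the
curve is fitted to a unit-area density. The central connective component is
assumed unskewed, $\alpha_2 \equiv 0$, leaving $3+3+3+2 = 11$ free
parameters. Note the sign convention: the erfc form means *positive*
$\alpha$ skews a component to the *left* — the opposite of the usual
skew-normal shape parameter. All reported skewnesses follow the erfc
convention literally; `sample_component()` uses shape $-\alpha$ internally
so that sampling and density agree.

## Pipeline stages and the choices behind them

### Radiodensity

Raw scanner values are calibrated to HU by the affine map
`HU = CT * 2.26625 - 190` (`ct_to_hu()`), applied exactly once — the
`pixel_set` unit flag exists to prevent double transformation. The
calibration pair is scanner-specific and overridable.

Histograms use 128 uniform bins over [-200, 200] HU by default: 128 bins is
the conventional CT assessment resolution, and the range is exactly the
union of the three tissue domains. Out-of-range pixels are counted and
reported, never silently dropped.

Smoothing into an empirical density uses a Gaussian kernel on the bin
counts with bandwidth two bin widths (6.25 HU at defaults), renormalized at
the range edges so mass is conserved exactly. A Gaussian kernel is the
simplest integral-conserving nonparametric smoother; the bandwidth is an
analysis choice and is recorded on the output. The kernel adds its variance
($\approx 39\,\mathrm{HU}^2$) to each component, so fitted widths are
biased slightly upward; locations and amplitudes are unaffected
(convolution preserves component means and masses), which is why the
recovery guarantees below are stated for $\mu$ and $N$. Density
normalization defaults to unit area; a count-scaled mode is available so
amplitudes can proxy areas directly.

### Trimodal fitting

The 11 parameters are estimated by bound-constrained nonlinear least
squares on the smoothed density at the bin centers, i.e. minimizing
$\sum_b (d_b - \varphi(x_b))^2$. The historical description of this fit
used a generalized-reduced-gradient spreadsheet solver; the estimator is
defined by the objective and constraints, not the solver brand, and here a
Levenberg–Marquardt minimizer with box bounds (`minpack.lm::nls.lm`) is
used. Default bounds: $N_i \in [0, \text{total mass}]$, $\mu_i$ confined to
its tissue domain (this enforces the $\mu_1 < \mu_2 < \mu_3$ ordering and
prevents component-label switching), $\sigma_i \in [\text{bin width}, 100]$
HU, $\alpha_{1,3} \in [-20, 20]$.

Initialization is moment-based per domain: amplitude = density mass in the
domain, location = domain centroid, width = domain standard deviation
floored at one bin width, skewness 0; empty domains get a floored amplitude
(`1e-6`) and the domain midpoint, so degenerate inputs still start.
Restarts jitter this initialization with a seeded generator and the best
solution by SSE is kept; `fit_ntra()` defaults to 4 restarts, while the
cohort pipeline uses 2 — on smoothed 128-bin densities the domain
initialization is close enough that restarts almost never change the
optimum, and at $10^3$ subjects the saving matters. Non-convergence is
flagged (`converged = FALSE`), never silently accepted. Convergence
tolerance is $10^{-10}$ on the objective; fit quality is reported as
$R^2 = 1 - \mathrm{SSE}/\mathrm{TSS}$ of the target curve.

### Standard CT metrics

The comparison metrics are computed exactly as conventionally defined:
lean pixels are those with HU strictly above the fat threshold (default
-10 HU, the upper edge of the fat domain — the "maximal density of fat");
lean area = lean pixel count x pixel area, fat area = remaining in-range
pixels x pixel area, lean attenuation = mean HU of lean pixels (flagged
undefined, not zero, when no pixel qualifies). Because whether "average HU"
means the lean-only or whole-section mean is ambiguous in common usage,
both `lean_mean_hu` and `avg_hu` are emitted.

### Discretization

Continuous covariates are discretized into $k$ classes with $k$ from
Sturges' formula $k = \lceil \log_2 n + 1 \rceil$; both the raw value and
the ceiling are returned because the raw values (11.4 for 1327 men, 11.8
for 1835 women) are themselves used to justify a common $k = 12$ across
strata. The 1-D k-means problem is solved *exactly* by dynamic programming
over the sorted values — optimal 1-D clusters are contiguous intervals, so
the DP attains the global within-cluster-SSE optimum and is deterministic,
removing all seed sensitivity of iterative k-means. An L1 (medoid)
objective is available as an option. Age, whose truncated range makes
distance-based clustering uninformative, is stratified by equal frequency:
sizes differ by at most one, larger bins first.

### Binned regression

Within each covariate bin, the covariate and every imaging parameter are
aggregated by the mean (the aggregation statistic is configurable in
concept; the mean is the default and the only validated mode). Simple OLS
fits per (covariate, parameter) pair use the covariate as the independent
axis. Parameters whose binned $R^2 \ge 0.85$ are selected per covariate
(`>=` at the boundary, on $R^2$ by default with an $|R|$ option, since both
readings of the selection rule circulate). The multiple regression then
takes the covariate as the dependent variable against the selected
parameters' bin means.

Two guards apply to the multiple fit. Predictors enter in order of
decreasing simple-fit $R^2$ and are capped at $\lfloor (k-1)/2 \rfloor$ for
$k$ bins: with 12 observations a saturated model would leave one residual
degree of freedom and an overall F-test with essentially no power, so the
standard observations $\ge 2\,\times$ predictors rule is applied (override
via `max_predictors`). Columns that would make the design rank deficient
are dropped and recorded (`dropped_collinear`) — with a fixed pixel count
per subject, fat and lean area are exactly complementary, a degeneracy real
cohorts do not have. No multiple-testing correction is applied; the number
of tests performed is reported alongside the raw p-values.

## The synthetic cohort

No public accession exists for the motivating cohort, so the generator is
the package's ground-truth instrument. It uses a single latent health
factor $h \sim U(0,1)$ per subject: the trimodal parameters shift linearly
in $h$ (muscle amplitude up, fat amplitude down, connective location up
with health — the qualitative directions observed in aging cohorts), pixels
are drawn from the resulting mixture with component probabilities
$N_i/\sum N_j$, and the six clinical covariates are affine in $h$ plus
Gaussian noise with physiologically plausible intercepts, slopes and units
(gait speeds 0.7–1.2 and 1.0–1.7 m/s, timed up-and-go 9–14 s, knee
extension strength 250–400 N, cholesterol 5.0–6.4 mmol/L, BMI 25–31
kg/m²; signs follow the clinical directions, e.g. up-and-go time falls as
health rises). Noise standard deviations are set to roughly 10–15% of each
covariate's health-driven range — strong but not noiseless coupling, so the
binned analysis has something real to recover. Defaults are 1000 subjects
at 10^4 pixels each, sized so a full cohort round trip stays at desk scale.
Age is uniform on 66–96 years and sex Bernoulli(0.42), matching an
elderly cohort's composition; both are generated independent of $h$.

What the generator does *not* emulate: image space (no anatomy, no partial
volume structure, no contouring errors), multi-factor physiology (one
latent factor drives everything, so covariates are mutually correlated by
construction), and cohort-specific distributions of the covariates.
Passing tests therefore demonstrate that the pipeline recovers what it
assumes — trimodal mixtures and linear couplings — not that real muscle
obeys those assumptions.

## Numerical choices and degenerate inputs

- `erfc` is evaluated via the normal CDF (`2 * pnorm(-x * sqrt(2))`),
  accurate over the full parameter box.
- Histogram bins are half-open `[left, right)` with the last bin closed;
  an inverted range or empty pixel set is rejected before computation.
- A density that is identically zero is rejected by the fitter ("no mass to
  fit"); all-below-threshold sections flag the lean mean as undefined.
- In the DP clustering, `k` larger than the number of distinct values is
  rejected; ties are handled by the prefix-sum costs exactly.
- Equal-frequency ties keep stable sort order; larger bins precede smaller.
- All randomness flows from explicit seeds: the cohort from `spec$seed`,
  fit restarts from the fit `seed`, so identical configurations reproduce
  byte-identical output tables (the run manifest hashes every output).

## Problem sizes used in validation

The shipped validation suite runs parameter recovery over 50 seeded
ground-truth parameter sets at $10^5$ pixels each (median absolute location
error $\le 2$ HU, median relative amplitude error $\le 5\%$), exhaustive
enumeration checks of the DP clustering at $n \le 12$, and one full cohort
round trip at the default 1000 subjects — sizes chosen to exercise the
asymptotics the method relies on while keeping a complete run at desk
scale.

## Known limitations

- Fitted widths inherit the smoothing kernel's variance; compare widths
  only across subjects analyzed with the same bandwidth.
- Skewness estimates are the least identifiable of the 11 parameters on
  smoothed densities; location and amplitude carry the recovery
  guarantees.
- The erfc sign convention for skewness is internal-consistent but
  opposite to the standard skew-normal shape parameter; exported values
  must be interpreted under this convention.
- Whether fitting should target density-normalized or count-scaled curves
  is application-dependent; both modes exist, the density mode is the
  validated default.
- Fascial-plane contouring, bone exclusion and scanner calibration are out
  of scope: the pipeline consumes already-delineated soft-tissue pixel
  sets.
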