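# ntra

Quantitative muscle-quality analysis of mid-thigh CT cross-sections in R.

Aging skeletal muscle loses mass and quality: fat infiltrates the muscle
bundle (myosteatosis), connective tissue accumulates, and the whole
Hounsfield-unit (HU) pixel distribution of a thigh cross-section shifts and
reshapes. Conventional CT metrics compress that distribution into a mean HU
value and fat/lean cross-sectional areas. `ntra` instead models the entire
radiodensitometric distribution — nonlinear trimodal regression analysis —
and provides the full statistical pipeline for correlating the resulting
parameters with clinical covariates such as gait speed, timed up-and-go,
leg strength, cholesterol and BMI.

The package is aimed at researchers working on sarcopenia and body
composition who have per-subject soft-tissue pixel values (already
delineated, e.g. by fascial-plane contouring) and a covariate table.

## The model

The soft-tissue HU distribution is modelled as a quasi-probability density,
the sum of two skewed and one standard Gaussian component over the three
tissue domains — fat [-200, -10] HU, loose connective / water-equivalent
tissue [-9, 40] HU, muscle [41, 200] HU:

```
sum_{i=1..3}  N_i / (sigma_i * sqrt(2*pi))
              * exp(-(x - mu_i)^2 / (2 * sigma_i^2))
              * erfc(alpha_i * (x - mu_i) / (sigma_i * sqrt(2)))
```

with amplitude `N_i` (the component's probability mass), location `mu_i`,
width `sigma_i` and skewness `alpha_i`; the central connective component is
unskewed (`alpha_2 = 0`), giving 11 free parameters. The model is fitted to
the smoothed 128-bin histogram of each subject by bound-constrained
nonlinear least squares, with each location confined to its tissue domain.

Downstream, clinical covariates are discretized into k classes (Sturges'
formula, exact 1-D k-means), imaging parameters are averaged within bins,
and binned simple regressions feed a selection rule (R² ≥ 0.85) and a
multiple regression with an overall F-test.

Because the motivating cohort data are not public, the package ships a
synthetic-cohort generator (`cohort_spec()`, `generate_cohort()`) with a
latent health factor linearly coupled to both the trimodal parameters and
the covariates — every stage of the pipeline is validated against its
ground truth.

## Worked example

```r
library(ntra)

# a small synthetic cohort: 60 subjects, 5000 pixels each
spec   <- cohort_spec(n_subjects = 60, pixels_per_subject = 5000, seed = 42)
cohort <- generate_cohort(spec)

# one subject: histogram -> smoothed density -> trimodal fit
h   <- smooth_histogram(build_histogram(cohort$pixels[[1]]))
fit <- fit_ntra(h, seed = 1)
fit
#> <ntra_fit> R^2 = 0.999970, SSE = 8.413e-08, 42 iterations, converged
#> <ntra_params> (11 free parameters, alpha[2] fixed at 0)
#>            fat connective  muscle
#> N       0.1991     0.1930  0.6078
#> mu    -59.9136    20.8456 46.3562
#> sigma  22.6605    13.4552 13.5246
#> alpha  -1.8819     0.0000  0.0014
```

The fitted amplitudes say 20% of this subject's soft-tissue mass is fat,
19% connective/water-equivalent and 61% muscle; locations and widths place
and scale each tissue peak on the HU axis, and the skewnesses capture the
inward-sloping asymmetry of the fat and muscle peaks (erfc convention:
positive alpha skews left). `standard_metrics()` gives the conventional
counterparts (fat/lean area, lean mean attenuation).

Cohort level:

```r
params <- fit_cohort(cohort$pixels, seed = 1)    # one row per subject
corr   <- correlate_cohort(params, cohort$covariates)
corr
#> <cohort_correlation> 90 simple regressions over 6 covariates; 43 pass the 0.85 rule
corr$multiple$gsn
#> <binned_mlm> multiple R = 0.9910, F(3, 3) = 54.616, p = 0.00407
```

Per-covariate bins, simple-fit slopes/R², the selection incidence table and
the multiple-regression ANOVA are all in `corr`. `run_pipeline()` wraps the
same steps around CSV input/output and writes a manifest with content
hashes; `inst/cli/ntra.R` exposes `simulate` and `run` subcommands for
shell use.

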