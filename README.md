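# ludosim

Organ-level internal dosimetry for Lu-177 radiopharmaceutical therapy,
built to answer a practical question: when the standard multi-time-point
dosimetry (MTPD) workflow — several quantitative SPECT/CT scans per
treatment cycle, a fitted time–activity curve, an integral — is replaced
by the Hänscheid single-time-point approximation (STPD), how large are
the dose errors, and do they erode the correlation of absorbed dose with
clinical outcome (PSA decline, anemia grade, overall survival)? The
package is aimed at medical-physics and biostatistics users who want the
whole comparison pipeline — kinetics, doses, error metrics, outcome
statistics — as tested, reusable functions rather than a one-off
analysis script.

## The models in brief

An organ's activity concentration is fitted per patient and cycle as
`c(t) = A1·exp(−λ1·t) − A2·exp(−λ2·t)` (uptake–washout, `λ2 > λ1`; the
terminal effective half-life is `Teff = ln2/λ1`) or as a plain
mono-exponential. The reference dose integrates the fit,

    MTPD = (Σ ±Ai/λi) · K ,   K = 3.6e9 · E[MeV] · 1.602e−13 · 1e3  Gy per MBq·h/g,

with `E = 0.147` MeV of locally deposited energy per Lu-177 decay. The
single-time-point dose replaces the integral with `c(t)·2t/ln2`. For
mono-exponential washout sampled at `t = x·Teff` the two are related
exactly by

    STPD / MTPD = 2^(1−x) · x ,

which is why only scans with `0.75·Teff < t < 2.5·Teff` (error ≤ 11.61%)
enter the STPD arm, using organ-wise population half-lives. STPD–MTPD
discrepancies are tabulated per organ and cycle as RMSE, mean percentage
error (MPE) and relative percentage difference (RPD); dose–outcome links
are tested with Spearman correlations, compared between methods by the
Fisher Z-transformed test `Z = (atanh ρ1 − atanh ρ2)/√(1/(n1−3)+1/(n2−3))`,
and survival is modelled by univariate Cox regression on total tumor
dose. A seeded synthetic-cohort generator stands in for patient data, so
every stage is exercisable and testable offline; see the methods
vignette (`vignettes/dosimetry-error-tolerance.Rmd`) for assumptions and
design choices.

## Worked example

```r
library(ludosim)

coh   <- generate_cohort(cohort_config(n_patients = 10, seed = 42))
fits  <- fit_cohort_kinetics(coh$activity)
doses <- compute_doses(fits, coh$activity)

round(attr(doses, "pop_teff"), 1)
#> bone_marrow     kidneys       liver      spleen       tumor
#>        27.9        33.4        38.6        31.4        42.7

rep <- compare_methods(doses)
head(rep$metrics[rep$metrics$organ == "tumor", ], 3)
#>    organ cycle  n     rmse       mpe        rpd
#> 25 tumor     1 10 3.177585 0.7330458 -0.1353462
#> 26 tumor     2 10 3.593478 1.6792199  1.3776042
#> 27 tumor     3 10 4.729754 2.1818908  1.9484989

run_comparison_analysis(doses, coh$outcomes)
#> <dosimetry_outcome_report>
#>   PSA decline ~ MTPD: rho = -0.486, p = 0.000148 (n = 56)
#>   PSA decline ~ STPD: rho = -0.476, p = 0.000207 (n = 56)
#>     Fisher Z = -0.06, p = 0.95
#>   anemia grade ~ MTPD: rho = 0.724, p = 2.79e-10 (n = 56)
#>   anemia grade ~ STPD: rho = 0.709, p = 9.61e-10 (n = 56)
#>     Fisher Z = 0.16, p = 0.87
#>   U-test (MTPD by response): U = 354.0, p = 0.00681
#>   U-test (STPD by response): U = 358.0, p = 0.00507
#>   Cox MTPD_total: HR = 1.052, p = 0.119
#>   Cox log_MTPD_total: HR = 76.325, p = 0.0884
#>   Cox STPD_total: HR = 1.054, p = 0.116
#>   Cox log_STPD_total: HR = 92.185, p = 0.0971
```

Reading the output: the fitted population effective half-lives sit near
the generator's configured organ values (tumor ~45 h, marrow ~30 h);
tumor STPD tracks MTPD within a few percent inside the scan window
(small MPE); cumulative tumor dose correlates negatively with PSA
decline rate for *both* methods with no significant difference between
the two correlations (Fisher p ≈ 0.95) — the error-tolerance pattern the
pipeline is designed to quantify; marrow dose correlates positively with
anemia grade; and responders (PSA decline ≥ 50%) received significantly
higher tumor doses (U-test).

The same stages run from the shell over CSV files:

```sh
Rscript inst/cli/ludosim.R simulate --seed 42 --out run/
Rscript inst/cli/ludosim.R fit --activity run/activity.csv --out run/
Rscript inst/cli/ludosim.R dose --fits run/fits.csv --activity run/activity.csv \
    --cycles run/cycles.csv --out run/
Rscript inst/cli/ludosim.R compare --doses run/doses.csv --out run/
Rscript inst/cli/ludosim.R correlate --doses run/doses.csv \
    --outcomes run/outcomes.csv --out run/
```

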