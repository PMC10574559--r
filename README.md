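# tracheidzone

Model-based division of conifer tree rings into earlywood (EW), transition
wood (TW) and latewood (LW) from per-cell anatomical measurements.

## The idea

For every tracheid in a radial file, two traits are measured: the radial
cell diameter `D` and the cell wall thickness `CWT` (both in micrometres).
Classical zonation rules (Mork's criteria) draw a fixed line on the ratio
`CWT/D` — the same line for every species and site. This package implements
a statistical alternative:

1. **Normalize** each radial file to a common cell count so rings with
   different cell numbers can be averaged (tracheidogram normalization).
2. **Standardize** `D` and `CWT` by their dataset means, giving
   dimensionless indices `D_i` and `CWT_i` that both average 1.
3. Convert each cell to an **indexed slope angle**
   `phi_i = atan(CWT_i / D_i) * 180 / pi` (degrees). Earlywood cells (wide,
   thin-walled) sit well below 45°, latewood cells (narrow, thick-walled)
   well above.
4. Fit the marginal distribution of `phi_i` with a **13-parameter
   mixture**: a four-parameter beta for EW, a four-parameter beta for LW,
   and a generalized normal (shape ≥ 2, from normal to near-uniform) for
   the transition wood that bridges them. Amplitudes sum to one.
5. Check adequacy with a Pearson **chi-squared test**: 50 equal-width bins,
   outskirt bins with expected counts under 5 merged inward, degrees of
   freedom `m − 13 − 1` for `m` final bins.
6. Derive **zonation thresholds** from the fitted model: the angle at the
   transition-wood center, back-transformed to the raw `CWT/D` scale with
   the species trait means, gives a species-specific two-zone threshold
   `k`; density intersections or mixture percentiles give three-zone
   boundaries; amplitudes give zone proportions (half the transition mass
   to each side).

The fitted thresholds are species-specific where Mork's `1/6` and `1/4`
(`mork_threshold()`) are not. Three species presets reconstructed from
published per-zone statistics are included (`species_profile()`:
`"picea_obovata"`, `"pinus_sibirica"`, `"pinus_sylvestris"`), together with
a synthetic-data generator for simulation studies.

## Worked example

Simulate a spruce-like dataset, standardize it, fit the mixture, and
derive thresholds. Everything below is actual output.

```r
library(tracheidzone)

prof  <- species_profile("picea_obovata", n_trees = 3, rings_per_tree = 20)
cells <- build_dataset(prof, seed = 7)
head(cells[, 1:6], 4)
#>   tree_id year row_id rank     D_um   CWT_um
#> 1       1 2001      1    1 37.64262 1.603451
#> 2       1 2001      1    2 36.75932 1.766205
#> 3       1 2001      1    3 29.91005 1.506251
#> 4       1 2001      1    4 33.69503 1.813992

st <- standardize_cells(normalize_dataset(cells))
st$summary
#>       trait       mean         min        max
#> 1      D_um 28.0997112  5.08295556 49.9527220
#> 2    CWT_um  2.6894185  1.11696813  6.9669900
#> 3     CWT/D  0.1199432  0.03559018  0.4006079
#> 4   phi_deg  6.7756930  2.03830685 21.8314275
#> 5       D_i  1.0000000  0.18088996  1.7776952
#> 6     CWT_i  1.0000000  0.41531957  2.5905191
#> 7 CWT_i/D_i  1.2531961  0.37185504  4.1856503
#> 8 phi_i_deg 44.1227506 20.39790462 76.5632510

fit <- fit_tracheid_mixture(st$cells$phi_i,
                            d_mean = mean(st$d_mean),
                            cwt_mean = mean(st$cwt_mean))
print(fit)
#> Tracheid slope-angle mixture fit (method: ls+mle )
#>   n = 1192 angles; logLik = -4639.45
#> Tracheid slope-angle mixture model 
#>   amplitudes: EW 51.0%  TW 28.1%  LW 20.9%
#>   EW beta : alpha 5.004 beta 24.726 on (17.71, 87.26) deg
#>   TW gnorm: mu 51.42 deg  scale 14.686  shape 1.17e+07 (near-uniform)
#>   LW beta : alpha 21.077 beta 6.123 on (36.78, 79.42) deg
#>   standardization means: D 28.10 um, CWT 2.69 um
#>   chi-squared: 32.15 on 36 df (m = 50 bins), p = 0.653 -> adequate

summary(fit)
#> Per-zone distribution characteristics 
#>  zone amplitude_pct mean_deg median_deg mode_deg sigma_deg ratio_mean
#>    EW          51.0     29.4       28.9     27.8      4.69      0.054
#>    TW          28.1     51.4       51.4     51.4      8.48      0.120
#>    LW          20.9     69.8       70.1     70.8      3.35      0.260
#>  ratio_median ratio_mode
#>        0.0528     0.0504
#>        0.1200     0.1200
#>        0.2646     0.2741
#> Two-zone split at TW center: EW 65.1%, LW 34.9%
#> Adequacy: chi-squared 32.15 on 36 df, p = 0.653

two_zone_threshold(fit$model)
#> Zone thresholds (method: tw-center )
#>   two-zone: phi = 51.42 deg, k = CWT/D = 0.120

table(predict(fit, type = "zone", newdata = st$cells$phi_i))
#> 
#>  EW  TW  LW 
#> 583 382 227
```

The fitted transition component here sits at the near-uniform limit of the
generalized normal (a very large shape is a flat plateau on
`mu ± scale`) — a common and legitimate outcome for the diffuse transition
zone. With a simulated dataset of this size (about 1,200 cells) the
amplitudes carry substantial sampling error; the component means and the
derived thresholds are much more stable. See the vignette
(`vignettes/tracheid-zonation.Rmd`) for the model, the fitting strategy,
and the identifiability discussion.

Other entry points: `fit_tracheid_mixture(method = "ls")` for binned least
squares only, `fit_min_chi2()` for minimum-chi-squared refinement,
`chi2_calibration()` for a simulation check of the adequacy test,
`three_zone_boundaries()` / `classify_ring()` for per-cell zonation with
optional enforcement of the EW → TW → LW ordering along a ring, and
`zone_report()` for per-zone tables on both the angle and `CWT/D` scales.
A command-line front end is installed at `inst/cli/tracheidzone.R`
(subcommands `simulate`, `summarize`, `fit`, `classify`).

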