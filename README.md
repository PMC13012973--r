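# sgpAge — segmental Greulich-Pyle bone age assessment

Pediatric bone age is conventionally read from a hand radiograph by
matching it to the nearest standard of the Greulich-Pyle (GP) atlas, a
discrete per-sex grid of ages `G`. But the hand does not mature uniformly:
short bones (metacarpals + phalanges), carpals, and the wrist (distal
radius + ulna) follow different hormonal schedules, and a single full-hand
age can hide those differences. `sgpAge` is an R implementation of a
*segmental* GP workflow for researchers in automated skeletal-maturity
assessment: it segments a radiograph into the three regions, predicts a
continuous age per segment and for the full hand with small convolutional
regressors, and fuses the estimates with the segmental-GP rule

```
C_i   = alpha * Seg_Avg_i + (1 - alpha) * fh_i
SGP_i = snap_G(C_i),    alpha* = argmin_alpha sum_i (snap_G(C_i) - y_i)^2
```

where `Seg_Avg` is the mean of the three segment predictions, `fh` the
full-hand prediction, `y` the GP ground truth, `snap_G` nearest-class
snapping onto the grid, and `alpha*` is fitted per sex by a grid sweep
over `[0, 1]`.

Because clinical cohorts are not redistributable, the package ships a
synthetic hand-phantom generator (exact masks, independently controllable
segment maturities, a domain-shift transform, and prediction tables with a
known generative fusion weight) on which the entire pipeline — U-Net-style
segmentation with test-time batch-norm adaptation, mask refinement,
frozen-backbone transfer learning, fusion, and the agreement-statistics
suite (MAD, Bland-Altman, quadratic-weighted Cohen's kappa) — is trained
and verified end-to-end on one CPU. See the methods vignette
(`vignettes/segmental-gp-methods.Rmd`) for the models and the design
decisions.

## Worked example

Fit the fusion weight on a synthetic prediction table with a known
generative weight of 0.3, and compare SGP against the snapped full-hand
prediction alone:

```r
library(sgpAge)
scale <- default_gp_scale("male")
tab <- generate_prediction_table(n = 2000, alpha0 = 0.3,
                                 noise_sd_fh = 6, noise_sd_seg = 6,
                                 scale, seed = 7)
fm <- fit_alpha(tab, scale)
fm
#> <fusion_model> male: alpha* = 0.35 (101-point sweep, min SSE 68337.0)

evaluate_agreement(sgp_predict(tab, fm), tab$y, scale, snap_pred = TRUE)
#> <agreement_report> n=2000
#>   MAD 3.47 mo | RMSE 5.85 mo | r2 0.992
#>   bias -0.05 mo (LoA -11.75 .. 11.64, 373 high-error)
#>   kappa 0.996 | exact 60.2% | within +/-1 class 97.5%

evaluate_agreement(snap_to_gp(tab$fh, scale), tab$y, scale, snap_pred = TRUE)
#> <agreement_report> n=2000
#>   MAD 7.42 mo | RMSE 10.01 mo | r2 0.976
#>   bias -0.25 mo (LoA -20.27 .. 19.77, 87 high-error)
#>   kappa 0.987 | exact 34.6% | within +/-1 class 80.7%
```

The sweep recovers a weight near the generative 0.3, and fusing the
segment average with the full-hand prediction halves the MAD (7.42 to 3.47
months) while raising exact-class agreement from 35% to 60%. The full
image pipeline is one call:

```r
mf <- run_pipeline(pipeline_config(seed = 1))
mf
#> <sgp_run_manifest> seed 1, 34 stages, 38.0s
#>   male: alpha* = 0.31, MAD fullhand 6.50 / sgp 6.75
#>   female: alpha* = 0.00, MAD fullhand 5.24 / sgp 5.06
```

which simulates source and domain-shifted target cohorts per sex, trains
the segmenter and the four age models, adapts them to the target, fits the
per-sex fusion weights and writes agreement reports for every model.

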