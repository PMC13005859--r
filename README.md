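# salientime

Links trial-wise fMRI dynamics to subjective time. In a naturalistic
timing experiment, participants watch silent office or city videos of
8–24 s while BOLD series are recorded (TR = 0.8 s, 360 cortical regions
grouped into seven functional networks), then report the perceived
duration on a 0–40 s scale. The package implements three analysis routes
over such data, plus a synthetic cohort generator with planted ground
truth that stands in for raw scans:

1. **Salient-event accumulation.** For each network, frame-to-frame
   BOLD change `Δ_TP = Σ_v (X_TP,v − X_TP−1,v)` is z-scored and compared
   to a decaying stochastic criterion
   `ϑ(t) = (ϑmax + ϑmin)·e^(−t) + ϑmin + ε`, `ε ~ N(0, 0.05)`, which
   resets after each detection. Accumulated counts feed a support-vector
   regression of video duration (10-fold CV); predictions are converted
   to a normalized duration bias `bias_tk = (x_tk − x̄_t)/x̄_t` and
   tested against human bias (one-tailed OLS on the slope) and for a
   scene effect (mixed-model likelihood-ratio test,
   `bias ~ 1 + scene + (1 | subject)`, χ² on 1 df). A 50×50 robustness
   sweep over `ϑmin ∈ [−3, 0]`, `ϑmax ∈ [0, 2.5]` (2,500 cells per
   network) maps where the association survives.
2. **Masked LSTM sequence model.** A two-layer LSTM over zero-padded,
   true-length-masked trial series with masked temporal mean pooling and
   a linear head, trained with MSE under leave-one-subject-out CV;
   scene classification is scored by rank-based AUC.
3. **Functional-connectivity elastic net.** Trial-wise Pearson FC
   (upper triangle; 64,620 edges at 360 regions) predicts bias or
   duration under LOSO with a nested 10×10 hyperparameter grid, with a
   random-window control that isolates the trial-length confound and a
   duration→model-bias reconstruction.

See `vignettes/salient-time-analysis.Rmd` for the models, parameter
choices, calibration properties and limitations.

## Worked example

```r
library(salientime)

# a small synthetic cohort: 8 subjects, 14 regions, 2 trials per condition
cfg <- synth_config(n_subjects = 8, n_regions = 14, trials_per_condition = 2,
                    seed = 42)
cohort <- generate_cohort(cfg)

# human normalized bias and the scene effect
hb <- human_bias(cohort)
mean_bias_by_scene(hb)
#>    scene   mean_bias        sem n_subjects
#> 1   city  0.04898277 0.01750598          8
#> 2 office -0.04898277 0.01750598          8
print(scene_effect_lrt(hb))
#> Scene effect on bias: 0.098 +/- 0.033 [0.033, 0.163], chisq(1) = 8.56,
#> p = 0.00343 (singular fit)

# salient-event accumulation (pooled z-scoring, discriminative criterion)
events <- accumulate_events(cohort$trials, cfg$network_labels,
                            criterion_params(theta_min = 0, theta_max = 2,
                                             seed = 42),
                            zscope = "pool")

# SVR duration decoding from the visual-network counts, then the
# association between model bias and human bias
b <- cohort$behavior
preds <- fit_predict_duration_cv(events$counts[, "vis"], b$duration_s,
                                 b[, c("subject", "trial", "scene")],
                                 seed = 42, network = "vis")
print(bias_regression(hb, model_bias(preds)))
#> bias_human ~ 0.0000 + 0.5273 x bias_model; one-tailed p(beta1 > 0) = 2.13e-09,
#> r = 0.444, n = 160
```

Reading the output: city videos are overestimated and office videos
underestimated by about ±5 % relative to each subject's category mean,
and the scene effect on bias is significant (χ²(1) = 8.56, p = 0.003;
the singular flag records that the random-intercept variance is ~0,
which is expected for demeaned bias). Salient events accumulated in the
visual (timer) network, pushed through the duration SVR and converted
to a model bias, correlate with the human bias (r = 0.44, one-tailed
p ≈ 2e-9) — the generator's planted event/report coupling is recovered
end to end. Running the same regression on the silenced control network
gives a null result.

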