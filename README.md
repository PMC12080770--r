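# hrvFatigue

Grading and predicting occupational fatigue during graded exercise from
heart-rate-variability (HRV) recordings.

Physically demanding work — the motivating case is firefighting — induces
fatigue that degrades reaction speed and decision making. This package
implements a complete fatigue-assessment pipeline for the standard
graded-treadmill study design (subjects walk stages of increasing speed; RR
intervals are recorded throughout, and a Borg 6–20 RPE rating and a simple
reaction time are taken after each stage):

1. **HRV features.** From each stage's RR-interval series, the ten standard
   HR/HRV features: mean RR, HR, SDNN, RMSSD, LF and HF band power
   (0.04–0.15 / 0.15–0.40 Hz, Welch periodogram on the 4 Hz cubic-spline
   resampled tachogram), LF/HF, Poincaré SD1, SD2 and SD2/SD1.
2. **Composite fatigue index.** Entropy weighting of the min-max normalized
   reaction time *R* and Borg rating *B*: per feature *j*,
   `p_ij = x''_ij / Σ_i x''_ij`, `e_j = −(1/ln n) Σ_i p_ij ln p_ij`,
   `g_j = 1 − e_j`, `w_j = g_j / Σ g`; then `F = w_R R + w_B B ∈ [0, 1]`.
   The published study weights `F = 0.39 R + 0.61 B` ship as reference
   constants.
3. **Fatigue grading.** Seeded multi-restart Lloyd K-means on the (R, B)
   plane, silhouette-based scan of K = 2…10, per-cluster [min, max]
   thresholds, weighted combination into F bands, and consolidation of
   overlapping bands into the final grading
   (mild F ∈ [0, 0.27), moderate [0.27, 0.66), severe [0.66, 1]).
4. **Prediction.** A 10-8-1 feedforward network (tanh hidden layer, linear
   output, inputs and target mapminmax-scaled to [−1, 1]) trained by
   full-batch gradient descent with an adaptive step, mapping the ten HRV
   features to F; evaluated by MAE/MSE/RMSE/R² on a 19:2 hold-out split and
   by 5-fold cross-validation.
5. **Synthetic cohort.** A protocol-faithful generator (6 subjects × 7
   four-minute stages, 4 km/h + 1 km/h per stage → 42 observations) with
   known latent fatigue (heart-rate-reserve fraction), so every stage of the
   pipeline is testable end to end without subject data.

## Worked example

```r
library(hrvFatigue)

cohort <- simulateCohort(protocolConfig(seed = 1))
rri <- rrSeries(cohort)[[7]]          # subject 1, final stage
rri
#> RRISeries: subject subj1, stage 7, 672 beats (239.7 s)
#>   mean RR 356.7 ms, HR 168.2 bpm

round(hrvFeatures(rri), 3)
#> rri_mean       hr     sdnn    rmssd       lf       hf    lf_hf      sd1
#>  356.680  168.218   21.633   11.414  345.243   75.194    4.591    8.071
#>      sd2  sd2_sd1
#>   29.487    3.654
```

By the last stage this subject's heart rate is high, overall variability
(SDNN) is low and LF/HF is elevated — the expected signature of heavy
exertion. Deriving the cohort's entropy weights:

```r
obs <- observations(cohort)
ew  <- computeWeights(cbind(reaction_time = obs$rt_ms,
                            borg = as.numeric(obs$borg)))
ew
#> EntropyWeights over 42 samples
#>            reaction_time   borg
#> entropy           0.9554 0.9368
#> difference        0.0446 0.0632
#> weight            0.4138 0.5862
```

The Borg ratings are more dispersed than the reaction times, so they carry
the larger weight — the same ordering as the published 0.39/0.61 reference
weights. The full pipeline (features → index → grading → network):

```r
report <- runPipeline(pipelineConfig(seed = 1), outDir = "pipeline-out")
report$best_k
#> [1] 2
round(report$evaluation$cv$pooled$r2, 4)
#> [1] 0.9571
round(report$evaluation$cv$mean$mae, 4)
#> [1] 0.0414
```

The silhouette scan peaks at K = 2 (two broad fatigue regimes), and the
10-8-1 network predicts the composite index from the ten HRV features with
a cross-validated R² around 0.95 on the default synthetic cohort —
i.e. only a few percent of the index variance is left unexplained, the
regime the generator's noise levels are calibrated to. Artifacts
(`features.csv`, `weights.json`, `indexed.csv`, `thresholds.json`,
`model.json`, `report.json`) are written to `outDir` and reruns with the
same seed are byte-identical.

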