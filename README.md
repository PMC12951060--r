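# pulseharmonics

Left–right asymmetry of the fingertip pulse waveform as a noninvasive
marker of coronary lesion severity.

Coronary lesion complexity is graded angiographically by the SYNTAX
score, with ≥ 22 marking intermediate/high complexity — an invasive,
equipment-heavy assessment. `pulseharmonics` implements the full analysis
chain behind a noninvasive alternative: simultaneous two-hand
photoplethysmography (PPG), per-beat Fourier decomposition of each pulse
into harmonic orders 0–11 of the heartbeat

    f(x) = A0 + Σ_{n=1..11} An · cos(2πnx/L − θn),

record-level amplitude/phase/energy indices **Cn = mean(An/A0)**,
**Pn = circular mean(θn)**, **Dn = mean Parseval energy fraction** with
beat-to-beat coefficients of variation (CnCV, …), signed and absolute
left-minus-right differences (ΔCn, |ΔCn|, …) as predictors, and
sex-stratified logistic regression with forward / backward / stepwise
AIC model selection, validated by ROC/AUC, Hosmer–Lemeshow calibration
and bootstrap internal resampling.

The clinical recordings behind the emulated study are not public, so the
package ships a seeded synthetic cohort generator reproducing its
composition (249 male subjects with 32 events, 99 female with 13) and
waveform structure; every reported number is computed at run time. It is
aimed at biostatisticians and biosignal researchers who want a
reproducible, testable reference implementation of this class of
analysis.

## Worked example

```r
library(pulseharmonics)

cfg <- study_config(
  cohort      = cohort_config(n_male = 50, n_female = 40,
                              n_events_male = 10, n_events_female = 8),
  acquisition = acquisition_config(duration = 12),
  n_resamples = 40, seed = 21)
report <- run_pipeline(cfg, quiet = TRUE)
print(report)
```

```
Study report (seed 21 )

[male] n = 50, events = 10 | forward selection, AIC = 19.39
  apparent AUC = 0.995 | HL = 0.16 (P = 1.00) | bootstrap AUC = 0.971 [0.911, 0.990]
  !! events-per-variable advisory: 5 parameters exceed 10 events / 10 = 1.0 (EPV = 2.0 < 10)
   term Coefficient       SE tStat P Value sig
 absdC2     3195.54  3264.41  0.98    0.33    
 absdD2   -15675.91 16668.53 -0.94    0.35    
    dD5   -12297.55 12851.94 -0.96    0.34    
 absdC6     1803.76  1950.59  0.92    0.36    
  dD7CV       13.99    14.83  0.94    0.35    

[female] n = 40, events = 8 | forward selection, AIC = 17.49
  apparent AUC = 0.996 | HL = 0.18 (P = 1.00) | bootstrap AUC = 0.959 [0.872, 0.992]
  !! events-per-variable advisory: 4 parameters exceed 8 events / 10 = 0.8 (EPV = 2.0 < 10)
   term Coefficient     SE tStat P Value sig
  dD5CV      106.74  88.78  1.20    0.23    
 absdC5     1014.09 896.38  1.13    0.26    
  dD4CV      -96.60  83.32 -1.16    0.25    
 absdP7       -5.44   5.07 -1.07    0.28    
```

Reading the output: the forward search won on AIC in both strata; the
apparent AUC is heavily optimistic at 8–10 events — the bootstrap mean
AUC and its percentile interval quantify that — and the
events-per-variable advisory flags the overfitting regime explicitly
(inflated coefficients and Wald SEs are its signature). The coefficient
table follows the Coefficient / SE / tStat / P Value reporting schema
with stars at P < 0.05.

The same stages are available as individual functions
(`generate_cohort()`, `generate_subject_waveforms()`, `segment_beats()`,
`beat_harmonics()`, `summarize_record()`, `inter_hand_differences()`,
`fit_logistic()`, `forward_select()` / `backward_eliminate()` /
`stepwise_select()`, `auc()`, `hosmer_lemeshow()`,
`bootstrap_validate()`), and the full-scale study is scripted as a
numbered workflow:

```sh
Rscript analysis/01_simulate_cohort.R    # cohort metadata + example waveforms
Rscript analysis/02_extract_features.R   # 348 subjects -> results/features.csv
Rscript analysis/03_fit_models.R         # per-sex AIC searches -> coefficient tables
Rscript analysis/04_validate_models.R    # ROC, Hosmer-Lemeshow, 2000-resample bootstrap
```

Outputs land under `results/` as plain CSV/JSON.

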