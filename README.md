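# preictal

Seizure advisory algorithms for chronic intracranial EEG, with
chance-predictor-corrected evaluation.

Implantable brain monitors can follow a patient with refractory epilepsy for
months and drive a wearable indicator of seizure likelihood — red (high),
white (moderate), blue (low). The hard part is statistical: an alarm that is
on a fraction ρ of the time "catches" a fraction ρ of seizure onsets even if
its warnings are independent of the seizures, so decades of seizure
prediction claims failed to beat that benchmark. `preictal` implements the
full desk-scale workflow of such an advisory system for methods work:

* **Synthetic chronic records** — months of multichannel 1/f iEEG-like
  signal with a refractory-thinned Poisson seizure process, calibrated
  pre-ictal band-power signatures, ictal bursts, antiepileptic-drug (AED)
  pharmacokinetics with optional feature coupling, and unreliable patient
  diaries. Everything downstream is testable without any data download.
* **The feature bank** — per channel and epoch, band-pass filters times
  scalar analyzers (mean absolute amplitude, average power, line length);
  16 channels × 6 filters × 3 analyzers = the 288-feature master set.
* **Per-patient training** — `sas_train()` labels pre-ictal vs interictal
  epochs, screens out AED-sensitive features, runs forward selection and
  backward elimination (≤ 16 features) under 10-fold *block-wise*
  cross-validation, and fits a regularized linear discriminant returning a
  seizure likelihood per epoch.
* **The advisory state machine** — likelihood thresholds with a minimum
  warning duration, causal display lag, dwell smoothing; plus the trial's
  event-handling rules (8-hour cluster collapsing, 2–12/month eligibility
  screening, leading seizures, data-collection completion).
* **Evaluation against chance** — with onset-inside-warning crediting, a
  chance predictor at time-under-warning ρ has sensitivity ρ, and the
  capture count of n events is Binomial(n, ρ). The package reports
  sensitivity S, the improvement S − ρ, one-sided binomial tests for the
  red and blue states, episode-based blue negative predictive value, the
  high-vs-moderate likelihood ratio (with the `ALL` sentinel), and the
  validation gates (red: S > 0.65 and above chance; blue: FNR below
  chance).
* **The trial summary table** — the 15-patient first-in-man patient table
  ships as a fixture, and every derived cell (diary/EEG discrepancy ratios,
  the 0.06–13.51 extremes, all average-row values) is recomputed from the
  per-patient entries.

## Worked example

Train on one simulated month and advise prospectively on an independent,
held-out month from the same patient configuration:

```r
library(preictal)
cfg <- desk_config(effect_size = 2, seed = 3)   # 30-day records, planted signature
res <- run_prospective(cfg)
summary(res$algorithm)
print(res$evaluation)
```

```
<sas_algorithm> v1: 1 feature(s), CV balanced accuracy 0.669
  thresholds: high 0.8048 / low 0.3876 (targets 25% red, 45% blue)
  trained on 37086 epochs (231 preictal / 36855 interictal)
  forward-selection path:
 step feature_id     score
    1         15 0.6689243
<red_performance>
  sensitivity 11/13 = 84.6% at 25.1% time in red (chance 25.1%)
  improvement over chance 0.595, p = 1.172e-05
  advance warnings (min): 14.6, 13.0, 6.6, 5.6, 10.1, 15.5, 11.1, 9.2, 6.2, 23.7, 17.8
<blue_performance>
  FNR 0/13 = 0.0% at 34.4% time in blue; NPV 100.0%
  p (fewer than chance) = 0.004178
  likelihood ratio (high vs moderate): 8.85
<validation_verdict>
  red  PASS
  blue PASS
  advance to advisory phase: yes
```

Reading this: selection found the planted signature feature (id 15 is
channel 1, band 5, line length). On the held-out month the algorithm caught
11 of 13 onsets (84.6%) while lit red only 25.1% of the time; a chance
predictor at that duty cycle would average 25.1% sensitivity, so the
improvement is +0.595 with a binomial tail probability of 1.2 × 10⁻⁵. No
onset occurred in a blue state, NPV 100%, and both validation gates pass.

The trial table side:

```r
tp <- trial_patients()
summarize_trial(tp)
#> <trial_summary> 15 patients
#>   mean age 44.5; prior resection 6 (40%)
#>   seizure frequency/month: diary 5.07 (n=14) vs iEEG 29.53 (n=14)
#>   discrepancy ratio range 0.06-13.51
#>   phases completed: data collection 14 (93%), validation 11 (73%), advisory 10 (67%)
#>   mean sensitivity CCS 66% (n=10), CES+CCS 61% (n=10); blue NPV 99.6% (n=5)
#>   mean time in high 23% (n=10), low 45% (n=5); LR 5.1 / 3.9 (n=8)
```

A thin command-line front end (`inst/scripts/sas-pipeline.R`) exposes
`simulate`, `extract`, `train`, `advise`, `evaluate` and `report`
subcommands over persisted intermediates (EDF signals, CSV events and
features, JSON algorithms), so a pipeline is resumable stage by stage.

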