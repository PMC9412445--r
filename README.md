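# attentionBCI

Simulation, calibration and offline evaluation of a **passive
attention-aware brain-computer interface**: a pipeline that classifies
*internally* versus *externally* directed attention from four-channel
consumer EEG (Muse-style montage TP9/AF7/AF8/TP10 at 256 Hz) and adapts
an application by pausing its display updates while the user is lost in
thought. It is aimed at BCI researchers and engineers who want to
prototype or stress-test such a closed loop without collecting human
EEG.

## The model

1. **Features.** Every 100 ms, an FFT over a 256-sample Hamming window
   (the most recent second, windows overlapping 90%) yields log10 band
   powers for delta (1–4 Hz), theta (4–8), alpha (7.5–13), beta (13–30)
   and gamma (30–44) on each of the 4 electrodes: a 20-dimensional
   feature vector at 10 Hz. A 400 s calibration session gives 4000
   vectors.
2. **Classifier.** A person-dependent two-class linear discriminant with
   pooled within-class covariance Σ and empirical priors π:

   ```
   w = Σ⁻¹(μ_int − μ_ext),   s(x) = w'x − w'(μ_int + μ_ext)/2 + log(π_int/π_ext)
   ```

   predicting *internal* iff s(x) > 0. Calibration quality is 5-fold
   cross-validated accuracy (shuffled folds by default; leakage-safe
   contiguous folds provided).
3. **Pause rule.** A sliding vote over the last n = 40 predictions
   (4 s): pause iff ≥ 60% (≥ 24/40) are internal — deliberately biased
   toward *not* pausing. Warm-up counts as unpaused.
4. **Closed loop.** A simulated application schedules update events
   every 0.3–3 s and suspends them while paused (deferred, not
   dropped).
5. **Evaluation.** Per-phase accuracy against phase-derived ground
   truth, 5-bin correction for trials with rereading episodes,
   run-length pause-block segmentation with 3/10/30 s length
   categories, paused-time percentages and Pearson/Spearman
   correlations.

A seeded synthetic generator produces labeled sessions — band-power
frames drawn from a Gaussian log-power model with a right-parietal
alpha increase during internal attention, or raw 256 Hz signal built
from band-limited noise — plus Muse-style stream corruption (missing
samples, timestamp jitter, delay). See the methods vignette
(`vignettes/attention-bci-methods.Rmd`) for every modeling choice.

## Worked example

```r
library(attentionBCI)

plan  <- makeSessionPlan(4, 50, 50, seed = 1)   # 8 phases, 400 s
sess  <- synthesizeBandPower(plan)
sess
#> BandPowerSession: 4000 frames (400.0 s at 10 Hz)
#>   labels: external 2008, internal 1992, none 0
#>   features: 20 (tp9_delta, tp9_theta, tp9_alpha ...)

crossValidate(sess, k = 5)
#> CalibrationResult: 5-fold shuffled CV on 4000 vectors
#>   mean accuracy 0.8375 (folds: 0.840 0.820 0.829 0.851 0.848)

model <- trainAttentionLda(sess)
model
#> AttentionLda: 20 features, priors ext 0.502 / int 0.498
#>   largest |weights|: tp10_alpha (5.03), tp9_alpha (2.55), af7_alpha (0.895)

sim <- runLoop(sess, model)
summarizeEvents(sim$events, sim$duration_s)[c("updateCount", "pausedFraction")]
#> $updateCount
#> [1] 129
#>
#> $pausedFraction
#> [1] 0.48175
```

The session holds 4000 frames because 400 s × 10 Hz frames fit exactly
(the first second is left-edge padded); the 2008/1992 label split comes
from boundary frames' ties going to external. Cross-validated accuracy
near 84% reflects the generator's default effect size (an alpha shift
of ~2 noise SDs, largest at TP10 — which is why `tp10_alpha` dominates
the learned weights). In the closed loop, roughly the internal half of
the session is paused, so about half the scheduled 0.3–3 s updates are
suppressed or deferred.

A command-line interface wraps the same functions:

```sh
abci=$(Rscript -e 'cat(system.file("scripts", "abci", package = "attentionBCI"))')
$abci simulate --out session.csv --seed 1
$abci train    --session session.csv --model model.json
$abci run      --session session.csv --model model.json --timeline tl.csv
$abci evaluate --session session.csv --model model.json --timeline tl.csv --out eval.json
$abci report   --eval eval.json
```

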