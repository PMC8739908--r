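# termaecg

Single-lead ECG analysis for R: delineation of the R, P and T waves by
**two-event-related moving averages (TERMA)** fused with a **fractional
Fourier transform (FrFT)** enhancement step, followed by autoregressive
(AR) beat features and supervised arrhythmia classification.  The
package is aimed at biomedical-signal researchers who want a tested,
scriptable implementation of this detection/classification chain, with
a synthetic-ECG generator providing exact ground truth so every stage
can be validated without downloading clinical databases.

## The method

An incoming record is bandpassed (zero-phase, 5–40 Hz for detection)
and freed of baseline wander by a dyadic discrete wavelet transform:
with the db4 wavelet, whose centre-frequency factor is
*R*<sub>c</sub> ≈ 0.7, the pseudofrequency of scale *a* is

&nbsp;&nbsp;&nbsp;&nbsp;*R*<sub>a</sub> = *R*<sub>c</sub> · *f*<sub>s</sub> / 2<sup>*a*</sup>,

so at *f*<sub>s</sub> = 360 Hz the 0.5 Hz drift band is reached at
scale 9; the coefficients at and below that band are zeroed and the
signal rebuilt.  The cleaned signal is rotated slightly in the
time–frequency plane with a discrete FrFT of order α = 0.01 and squared,
which accentuates the sharp QRS deflections.  Two moving averages — an
event-scale window *W*₁ (97 ms, QRS-sized) and a cycle-scale window
*W*₂ (611 ms, beat-sized) — are compared: samples where the event
average exceeds the cycle average plus an offset γ = β·μ (μ the mean of
the enhanced signal, β = 0.08) form *blocks of interest*, and each block
at least *W*₁ wide contributes one R peak (the argmax of the enhanced
signal).  For P and T the QRS is first blanked (30 samples before to 60
after each R at 360 Hz, i.e. 0.083/0.166 s), the remainder re-enhanced,
and a P-scale average (*W*₃ = 100 ms) is compared against a QT-scale
average (*W*₄ = 400 ms) with no offset; candidate blocks are assigned as
P or T by their PR / RT gaps to the neighbouring R peaks.

Beats are then segmented (250 ms windows — 65 samples at the 260 Hz
classification rate), normalised to [−1, 1], and each group of two
consecutive beats is summarised by the coefficients of an AR(*j*) model

&nbsp;&nbsp;&nbsp;&nbsp;*k*(*v*) = Σ<sub>f=1..j</sub> *x*<sub>f</sub> *k*(*v*−*f*) + ε(*v*),

with *j* chosen at the knee of the prediction-error curve (typically 2
or 3).  AR coefficients plus RR/PR/RT intervals feed an SVM with the
radial kernel *K*(x, y) = exp(−‖x−y‖²/2σ²) (or LDA/QDA/KNN/MLP), and
performance is reported as sensitivity *Se* = TP/(TP+FN), positive
predictivity +P = TP/(TP+FP) and failure rate (FN+FP)/TP for detection
(a detection is true within 30 ms of the annotation), and accuracy /
recall / precision / F1 for classification over the classes
regular, PVC, APC, LBBB, RBBB and PACE.

## Worked example

```r
library(termaecg)

# 30 s of synthetic ECG at 360 Hz: 60 bpm, 0.05 mV noise, baseline wander
cfg <- synth_config(duration_s = 30, heart_rate = 60, noise_std = 0.05,
                    baseline_wander_amp = 0.15, seed = 42)
sim <- generate_ecg(cfg)

# detect R, P and T (TERMA blocks of interest + FrFT enhancement)
det <- detect_all_peaks(sim$record)
det$peaks
#> <peak_set> R: 30, P: 30 (0 missing), T: 30 (0 missing)

# score against the generator's ground truth at the 30 ms tolerance
ev <- evaluate_peaks(det$peaks, sim$truth, fs = 360)
round(sapply(ev, function(w) unlist(w$metrics)), 4)
#>                       r p t
#> sensitivity           1 1 1
#> positive_predictivity 1 1 1
#> failure_rate          0 0 0

# AR features on the classification chain (0.5-35 Hz, 260 Hz)
rc <- resample_record(bandpass_filter(sim$record,
        bandpass_spec(0.5, 35, "butter_fir_combo")), 260)
r260 <- round((det$peaks$r - 1) * 260 / 360) + 1
head(extract_features(rc, peak_set(r = r260), ar_order = 3), 3)
#>      ar1     ar2    ar3     rr pr rt
#> 1 2.8312 -2.7443 0.9106 1.0269 NA NA
#> 2 2.8112 -2.7087 0.8946 1.0077 NA NA
#> 3 2.8234 -2.7303 0.9042 1.0115 NA NA

curve <- prediction_error_curve(rc$samples[(r260[1] - 32):(r260[2] + 32)], 10)
select_order_knee(curve)
#> [1] 2
```

All 30 beats are found with every wave inside the 30 ms tolerance, and
the knee of the AR error curve lands at order 2 — the model size at
which two-beat ECG groups are well summarised.

A command-line front end wrapping the same functions is installed at
`inst/cli/ecg` with subcommands `simulate`, `detect`, `features`,
`classify`, `eval` and `run`:

```sh
Rscript inst/cli/ecg simulate --out rec --duration 30 --seed 1
Rscript inst/cli/ecg detect --input rec --format wfdb --out peaks.csv
Rscript inst/cli/ecg run --input rec --format wfdb --outdir out/
```

Records are read and written as WFDB pairs (`.hea`/`.dat`, formats 16
and 212, with MIT-style `.atr` annotations) or as plain CSV
(`index,mv` plus a stated sampling frequency).

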