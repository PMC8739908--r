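---
title: "TERMA + FrFT ECG delineation and AR-feature classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TERMA + FrFT ECG delineation and AR-feature classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termaecg)
```

This vignette is the package's own account of the science it
implements: the signal model, the detection and feature chain, the
tunable parameters with their defaults and units, the numerical design
choices that were genuinely open, and the limits of what the synthetic
tests demonstrate.

## Signal model and preprocessing

A single-lead ECG is a quasi-periodic train of beats, each composed of
a P wave (atrial depolarisation), the dominant QRS complex and a T wave
(ventricular repolarisation), riding on sub-1 Hz baseline wander and
broadband noise.  Detection operates on a cleaned copy of the record
produced by two steps:

* **Zero-phase bandpass.**  A 4th-order Butterworth bandpass, applied
  forward and backward (`signal::filtfilt`), for the 5–40 Hz detection
  band; or a Butterworth high-pass (0.5 Hz) plus a 12th-order FIR
  low-pass (35 Hz) for the classification chain.  Zero-phase filtering
  was chosen because any group delay would translate detected peaks and
  eat directly into the 30 ms scoring tolerance.

* **Wavelet baseline removal.**  The record is decomposed with the db4
  pyramidal DWT down to the scale whose *pseudofrequency*
  $R_a = R_c f_s / 2^a$ reaches the drift band.  The centre-frequency
  factor $R_c$ is computed from the wavelet function itself (cascade
  algorithm, spectral peak): $R_c \approx 0.71$ for db4, so at
  $f_s = 360$ Hz scale 9 gives $R_a \approx 0.49 \to 0.5$ Hz.  Both the
  scale-9 approximation *and* the scale-9 detail are zeroed before
  reconstruction.  The detail band matters: it is centred exactly on
  the 0.5 Hz pseudofrequency where most respiratory drift lives, and
  db4's short (8-tap) filters leak considerable sub-band energy across
  the 0.35 Hz approximation edge — zeroing the approximation alone
  leaves roughly half the RMS of a 0.3 Hz drift and nearly all of a
  0.5 Hz drift in place, while zeroing both reduces a 0.3 Hz drift to
  under 10 % RMS.

The DWT is periodised (exactly orthonormal, so
decompose-then-reconstruct is an identity to machine precision); the
record is padded by symmetric reflection up to a multiple of $2^a$ and
truncated back after reconstruction, so edges behave like a symmetric
extension while perfect reconstruction is preserved.

## FrFT enhancement

The enhancement stage computes $|\mathcal{F}^\alpha x|^2$ with a small
fractional order ($\alpha = 0.01$ by default): a slight rotation in the
time–frequency plane followed by squaring, which disproportionately
boosts the tall, sharp QRS deflections over the smoother P and T waves
while keeping time localisation.

Two discretisations of $\mathcal{F}^\alpha$ live behind one surface:

* **Eigenvector method** (default for $n \le 1024$): Hermite-like
  eigenvectors of a periodic tridiagonal matrix that commutes with the
  DFT, purified by exact projection onto the four DFT eigenspaces, with
  fractional eigenvalue powers $e^{-i\pi k\alpha/2}$.  This
  discretisation is *exactly* unitary, *exactly* additive in the order,
  equals the unitary DFT at order 1 and the identity at order 0, and is
  periodic with period 4 — all to machine precision.  The basis costs
  $O(n^3)$ once per length (cached) and each transform $O(n^2)$.

* **Chirp decomposition** (default for longer records): sinc
  interpolation, chirp multiplication, chirp convolution by FFT, chirp
  multiplication, at $O(n\log n)$.  The textbook form of this algorithm
  places even-length signals on a half-integer-offset grid that is
  inconsistent with its own integer-order special cases; the
  implementation here aligns the fractional path to the integer grid,
  after which the method is numerically exact on time–frequency
  concentrated signals and percent-level accurate (unitarity ~$10^{-3}$,
  additivity ~$10^{-2}$) on broadband noise.  Bandpassed ECG is smooth,
  which is why the chirp path is entirely adequate for detection.

The two methods are *different* discretisations and agree only
approximately at fractional orders (to about 3 % at $\alpha = 0.01$);
tests of the exact algebraic properties therefore target the eigen
path, and smooth-signal behaviour the chirp path.

## TERMA detection

For R peaks the enhanced signal $s$ is averaged over an event-scale
window $W_1$ and a cycle-scale window $W_2$, and blocks of interest are
the maximal runs where
$\mathrm{MA}_{event} > \mathrm{MA}_{cycle} + \beta\mu$ (with $\mu$ the
mean of $s$) that are at least $W_1$ wide.  Each block yields one R
peak, the argmax of $s$ inside it; blocks closer than a 200 ms
refractory span (a physiological lower bound on RR) are merged keeping
the stronger peak.  Because $\mathrm{MA}_{event}$,
$\mathrm{MA}_{cycle}$ and $\beta\mu$ all scale with the squared signal,
the detector is invariant to amplitude scaling, and zero-phase
filtering makes it translation-covariant.

For P and T the QRS is blanked — samples from 30 before to 60 after
each R at 360 Hz (83.3/166.7 ms; stored in milliseconds so behaviour is
rate-independent) are set to zero — the remainder is re-enhanced, and a
peak-scale average ($W_3$, the P duration of a fit individual) is
compared *directly* against a wave-scale average ($W_4$, the QT
interval): no offset term.  Candidates (block argmaxes) are assigned as
P when the gap to the following R is within the PR window, as T when
the gap from the preceding R is within the RT window; when both admit a
candidate the tighter relative gap wins, ties to T, and at most one P
and one T survive per RR interval (nearest wins).

Parameters, defaults and rationale:

| parameter | default | unit | rationale |
|---|---|---|---|
| `w1_ms` | 97 | ms | QRS-complex duration scale |
| `w2_ms` | 611 | ms | heartbeat duration scale |
| `w3_ms` | 100 | ms | P duration, fit individual (100 ± 20 ms) |
| `w4_ms` | 400 | ms | QT interval, fit individual (400 ± 40 ms) |
| `beta` | 0.08 | – | threshold offset factor (hit-and-miss tuned) |
| `frft_alpha` | 0.01 | – | enhancement rotation order |
| `blank_pre_ms`, `blank_post_ms` | 83.3, 166.7 | ms | 30/60 samples at 360 Hz |
| `pr_window_ms` | 300 | ms | generous cover of P-to-R gaps |
| `rt_window_ms` | 450 | ms | covers T within the QT interval |
| `refractory_ms` | 200 | ms | physiological minimum RR |
| `pt_floor` | 1e-4 | – | relative P/T amplitude floor (below) |
| `match_tol_ms` | 30 | ms | scoring tolerance |

Two details were genuinely open and deserve their reasoning:

* **P/T amplitude floor.**  With no offset term the
  $\mathrm{MA}_{peak} > \mathrm{MA}_{wave}$ comparison is scale-free,
  so even the numerical residue left after blanking would form blocks
  on a signal with no P or T waves at all.  Candidates must therefore
  exceed `pt_floor` times the median squared R amplitude.  The floor is
  *relative*, so amplitude invariance is preserved; at its default
  ($10^{-4}$) it rejects far QRS tails and transform ringing while
  passing P waves down to about 1 % of the R amplitude.

* **Per-wave detection bands.**  The 5 Hz high-pass of the detection
  band renders the broad T wave biphasic; under noise the enhanced
  argmax then flips between the two lobes (tens of ms of error).
  Conversely the gentle 0.5 Hz high-pass of the classification chain
  preserves the T but leaves the blanked QRS with large shoulders whose
  Gibbs ringing drowns the small P wave.  `detect_all_peaks()` and the
  pipeline therefore delineate R and P on the 5–40 Hz chain and T on
  the 0.5–35 Hz chain — each wave on the band where its morphology
  survives.  On the synthetic conditions below this yields
  Se = +P = 1.0 for R, P and T up to 5 % noise, and ≈ 0.95 at 10 %.
  `detect_pt_peaks()` itself stays a single-record operation.

## AR features and order selection

Each group of two consecutive beats (non-overlapping, trailing partial
group dropped) is represented by the samples from the first beat's
250 ms segment start to the second's segment end, de-meaned, and fitted
with an AR model.  Burg is the default estimator: it is standard for
short segments, always yields a stationary model, and its
reflection-coefficient recursion makes the prediction-error curve
non-increasing in the order — which the knee selector relies on.  The
knee is the order with maximum perpendicular distance to the chord
joining the error curve's endpoints, ties resolving to the smaller
order; on processed synthetic two-beat groups it lands at order 2–3.
One subtlety: on a *noise-free decaying* recursion Burg does not
reproduce the generating coefficients exactly (its backward-error term
is nonzero on such data), while the least-squares fit without
demeaning does, to machine precision; `fit_ar()` exposes both the
`method` and a `demean` switch for this reason.

The feature vector per group is the AR coefficients plus the RR
interval within the group and the PR and RT intervals of the group's
first beat (absent waves give `NA`, encoded as zero for classifiers —
absence of a P wave is itself discriminative for ventricular ectopy).
A morphology mode (per-beat 65-sample normalised waveform next to three
RR characteristics) is available behind `type = "morphology"`; note the
printed feature-dimension bookkeeping in the source literature for this
layout is internally inconsistent (3 + 65 ≠ 62), so the mode documents
its own 68-dimensional layout.

## Classification and metrics

`train_beat_classifier()` performs a seeded, stratified 70/30 split,
standardises features on the training set, and fits SVM-RBF (default;
$\sigma$ from the median pairwise distance heuristic, box constraint
1, one-vs-one for multiclass), LDA, QDA, KNN ($k = 3$) or a
single-hidden-layer MLP.  Detection quality uses
$Se = TP/(TP+FN)$, $+P = TP/(TP+FP)$ and failure rate $(FN+FP)/TP$;
undefined ratios are reported as missing rather than zero.
Classification metrics use the standard confusion-matrix definitions of
recall (over FN) and precision (over FP) — the printed source formulas
swap the two denominators, but the same document defines sensitivity
over FN and uses it interchangeably with recall, so the standard
reading is implemented.  Macro averaging is the default.

## The synthetic generator

`generate_ecg()` emulates what the chain needs and no more: beats as
sums of Gaussian-shaped waves with centres snapped to the sample grid
(so the ground truth is analytic — the R index *is* the argmax of the
noiseless QRS), per-beat class morphologies (wide QRS without P for
PVC, early beat with altered P for APC, widened/attenuated QRS for the
bundle-branch blocks, a narrow stimulus spike for PACE), i.i.d.
Gaussian RR jitter (σ = 2 % of the period), sinusoidal sub-1 Hz
baseline wander and additive white noise.  Defaults: 360 Hz sampling,
60 bpm, 0.02 mV noise, 0.1 mV wander at 0.33 Hz, P/R/T amplitudes
0.15/1.0/0.3 mV (configurable; the source material never states test
amplitudes).

What it does **not** emulate — and therefore what passing tests do not
show about clinical data: non-Gaussian wave shapes (notched QRS,
biphasic or inverted T with any geometry), muscle-artifact and
electrode-motion noise (coloured, transient), atrial fibrillation or
other non-quasi-periodic rhythms, multi-lead projection effects, and
annotation conventions of real databases.  Synthetic separability of
the six classes is by construction; the held-out SVM accuracy
criterion is a property of the pipeline's plumbing, not a clinical
claim.

## Problem sizes and numerical choices

The test and acceptance runs use desk-scale problems chosen as
reasonable study conditions: 30-beat records for detection exactness,
20 seeds at 10 % noise for robustness, 50 replicates of $n = 10^4$
AR(2) simulations for estimator calibration, and six single-class
records of ≈ 200 beats each (≈ 3.5 min at 60 bpm) for the
classification check.  Other numerics: moving averages are centred
with zero padding and odd-forced windows (+1 sample when even, so
"centred" is exact); block runs equal in width to $W_1$ are kept
(strict equality would reject essentially everything); peak matching is
greedy one-to-one nearest within 30 ms; constant segments normalise to
all-zeros with a flag; degenerate inputs (flat signals, empty peak
sets, non-stationary AR coefficients, classes with fewer than two
members) raise errors or return empty results rather than guessing.

## Known limitations

Single-lead only; no QRS onset/offset or U-wave delineation; the
wavelet baseline removal assumes the drift sits below ~0.7 Hz; T-wave
delineation through the 5–40 Hz band alone degrades under noise (use
the dual-band front end); the chirp FrFT path's algebraic properties
are approximate on broadband signals; and WFDB support is the minimal
subset needed here (formats 16/212, MIT annotations), not a general
reader.
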