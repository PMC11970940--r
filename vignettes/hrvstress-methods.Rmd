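---
title: "Quantifying mental stress from PPG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mental stress from PPG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvstress)
```

# The measurement problem

Photoplethysmography (PPG) measures blood-volume pulsations optically at the
fingertip; each systolic peak marks a heartbeat. The beat-to-beat (RR)
intervals fluctuate under autonomic control, and summary statistics of that
fluctuation — heart-rate variability (HRV) — shift in characteristic
directions under acute mental stress: mean RR falls (heart rate rises),
vagally mediated high-frequency variability is suppressed, and the LF/HF
spectral balance tilts sympathetic. `hrvstress` implements the full chain
from raw PPG samples to a three-level stress score: signal conditioning,
beat detection, a 34-parameter HRV feature set computed every 30 s, a CART
classifier over those features, and protocol-level aggregation with
questionnaire regressions. A synthetic-data module generates every input the
chain needs, so the whole pipeline is testable without hardware or
participant data.

# Signal conditioning

Raw PPG windows (30 s at 100 Hz by default) are high-pass filtered with an
order-2 Butterworth at 0.5 Hz, applied forward and backward so the filter
has zero phase: beat times must not be shifted by filter delay. The filter
is preceded by odd-reflection padding of about three filter time constants
(`3 * fs / cutoff` samples), which keeps startup transients out of the
window; without that padding, transients from zero initial conditions leak
several hundred samples into a 30-s window at a 0.5 Hz cutoff.

Each filtered window is normalized by its maximum absolute value, mapping it
to $[-1, 1]$. Published descriptions of this pipeline disagree between a
$[-1, 1]$ and a $[0, 1]$ normalization; we follow the methods-level
statement (divide by the maximum) and apply the fixed peak threshold of 0.5
on that scale. Note that max-abs normalization guarantees the largest
excursion is exactly $\pm 1$ but does not force the minimum to $-1$; a
min-max alternative would change threshold semantics and is deliberately
not offered. An all-zero (flatline) window cannot be normalized and is
carried through the pipeline as invalid rather than producing NaN.

# Beat detection

A peak is an integer sample index that is a local maximum with normalized
amplitude at least the threshold (0.5), subject to a 250 ms refractory
period that caps detectable heart rate at 240 bpm and suppresses double
detections on dicrotic notches — of two candidates inside the refractory
interval the taller wins. Before localization the trace is smoothed with a
50 ms moving average (well below the systolic upstroke time); this is the
usual guard against a single noisy sample pulling the argmax a few samples
off the true peak, which at 100 Hz translates directly into 10-ms-scale RR
errors. There is no sub-sample interpolation: RR intervals are quantized at
$1000 / f_s$ ms (10 ms at 100 Hz), an accepted and documented resolution
limit of the design.

RR intervals are adjacent peak differences. Optional physiologic cleaning
(300–2000 ms bounds, `clean_rr()`) is available but off in the default
pipeline, which mirrors a system that performs no artifact rejection.
Windows are processed independently; no RR interval spans a window
boundary.

# The 34 HRV parameters

Per 30-s window with at least 10 beats, `extract_features()` computes:

* **Time domain (11)** — mean RR, median RR, SDNN, RMSSD, SDSD, SDNN/RMSSD,
  HR ($60000/\overline{RR}$, so HR times mean RR is exactly 60000), pNN25,
  pNN50, excess kurtosis, skewness. SDNN and SDSD use the sample SD
  (denominator $n-1$), the convention of mainstream HRV tooling; kurtosis
  is Fisher excess (normal $\to$ 0); both moments use the classical
  $g_1, g_2$ definitions.
* **Relative time domain (8)** — the same statistics on
  $u_i = RR_i/\overline{RR} - 1$. This makes `rel_mean_rr` identically 0
  and `rel_sdnn` the coefficient of variation, and leaves all shape
  statistics scale-invariant. No positive affine normalization can flip the
  sign of skewness, so a relative skewness cannot systematically differ in
  sign from the raw skewness; published tables that show such a flip must
  use some other, unstated normalization — the formula here is the
  documented, reproducible choice.
* **Frequency domain (11)** — the tachogram (RR value at the time of its
  closing beat) is cubic-spline interpolated at 4 Hz, mean-removed, and its
  one-sided PSD estimated with Hann-windowed Welch averaging: one
  full-length segment for short windows (a periodogram), 120-s segments
  with 50 % overlap for long recordings. Band powers are trapezoidal
  integrals with interpolated band edges over VLF 0.003–0.04, LF 0.04–0.15
  and HF 0.15–0.4 Hz. Total power TF is defined as the band sum
  VLF + LF + HF, so percentages sum to 100; normalized units remove VLF:
  $LF_{nu} = 100\,LF/(TF - VLF)$, hence $LF_{nu} + HF_{nu} = 100$ whenever
  LF + HF > 0. Inside a 30-s window the spectral resolution
  ($\Delta f \approx 0.034$ Hz, Hann mainlobe $\approx 2\Delta f$) cannot
  resolve the 0.037-Hz-wide VLF band; VLF is integrated anyway for fidelity
  to the 30-s recompute cycle and the window is flagged `vlf_unresolved`.
* **Nonlinear (4)** — Poincaré SD1 $= \mathrm{SDSD}/\sqrt{2}$ and SD2
  $= \sqrt{2\,\mathrm{SDNN}^2 - \mathrm{SDSD}^2/2}$ (numerically negative
  arguments clipped to 0 and flagged); sample entropy with $m = 2$,
  $r = 0.2\,\mathrm{SD}$, self-matches excluded, strict inequality, both
  template sets restricted to the first $n-m$ positions (the canonical
  definition — conventions vary, so this is spelled out); and Higuchi's
  fractal dimension on the beat-indexed RR sequence with $k_{max} = 8$,
  suited to ~35-beat windows. When no length-$(m+1)$ template pair matches,
  SampEn is right-censored; `sample_entropy()` reports `Inf` with a flag,
  and `extract_features()` substitutes the finite upper bound
  $-\ln\!\big(2/((n-m-1)(n-m))\big)$ so feature rows remain usable for
  modeling. Degenerate windows (constant RR) cascade to zeros with flags,
  never NaN.

A note on bookkeeping: the named SDNN/RMSSD entry is the ratio of the two
statistics. The naming follows the field's tables even though published
per-phase tables sometimes print it inconsistently.

# The stress classifier

A CART over the 34 features with three classes (0 none, 1 moderate,
2 severe), grown under maximum depth 10, minimum 10 rows to split, minimum
5 rows per leaf, Gini impurity. Splits are found by `rpart` with surrogate
and competitor bookkeeping disabled, then extracted into a plain node
table; prediction is the package's own deterministic root-to-leaf descent
over that table (tested to agree exactly with `rpart`'s predictions), and
the node table serializes losslessly to a JSON model archive together with
the canonical feature order and hyperparameters, so feature-order
mismatches at predict time are impossible. Leaf ties break toward the lower
class. Class imbalance is not reweighted. Evaluation reports accuracy,
per-class precision/recall/F1 and the confusion matrix; zero-support or
zero-prediction classes report 0 with a flag rather than NaN.

Decision-tree stress classifiers trained on the public SWELL-KW
knowledge-work corpus have been reported to reach near-perfect
window-level accuracy. Such numbers depend on the external dataset and on
split granularity — window-level splitting of overlapping HRV windows
leaks subjects across folds — so this package bundles no SWELL data and
asserts nothing about it; labeled feature CSVs from any corpus can be fed
in through `read_feature_csv()`. What the tests assert is classifier
*recovery* on the package's own synthetic classes (held-out accuracy
$\ge 0.95$ at $n = 600$), a property of the implementation.

# Synthetic data: what it emulates and what it does not

`generate_rr()` builds beat times iteratively with the interval opened at
beat time $t$ equal to
$\mu + A_{LF}\sin(2\pi f_{LF} t) + A_{HF}\sin(2\pi f_{HF} t) + \varepsilon$,
$\varepsilon \sim N(0, \sigma)$, defaults $f_{LF} = 0.1$, $f_{HF} = 0.25$
Hz. The first beat is at $t = 0$ and beats are appended while the next time
stays within the requested duration. Sinusoid-plus-noise directly controls
the band powers the spectral features must recover; it is *not* an integral
pulse frequency modulation model, and it has no respiration coupling or
nonstationarity — passing tests show estimator correctness, not performance
on ambulatory recordings.

`render_ppg()` places one asymmetric pulse per beat (piecewise Gaussian:
rise $\sigma = 0.12 w$, decay $\sigma = 0.25 w$ for pulse width $w$,
default 0.35 s), peak exactly on the beat time with unit amplitude, plus DC
offset, sinusoidal baseline wander and white noise. There is no dicrotic
notch and no morphology variability, so beat detection on these waveforms
is easier than on real PPG; the refractory logic is exercised by noise, not
by true secondary waves.

The three class profiles encode the two most robust stress directions only:
mean RR 800/760/720 ms and LF/HF amplitude pairs 20/40, 35/30, 50/18 ms for
classes 0/1/2, interval noise 10 ms, per-window jitter of ±30 ms on the
mean and ±20 % on amplitudes. All other 32 features vary as consequences,
as in real data. An optional subject-level `susceptibility` in $[0,1]$
shifts a whole profile toward the stressed direction (up to −60 ms mean RR,
±30 % on LF/HF amplitudes), modeling stable between-subject reactivity; the
protocol demonstrations tie it to a synthetic DASS-21 stress score.

The default six-phase session (Rest 1, Stroop 1, Rest 2, Stroop 2, Rest 3,
Relax; 300/300/600/300/600/600 s; true classes 0,1,0,2,0,0) yields exactly
90 thirty-second windows.

# Protocol aggregation and statistics

`run_pipeline()` applies the window chain and model per 30-s step; failures
invalidate single windows, never the session. `phase_scores()` assigns each
window to the phase containing its start and reports both the raw sum of
labels and the normalized score (sum / windows, in $[0,2]$); questionnaire
regressions use raw sums ("total stress"), matching the convention of
summed phase scores. `dass_regression()` regresses per-subject phase-score
sums (over all phases, baseline, Stroop, recovery or relaxation subsets) on
DASS-21 stress scores by OLS.

Adjacent phases are compared with a paired two-sided Wilcoxon signed-rank
test by default (HRV parameters are skewed; a paired $t$ is available).
With fewer than 6 pairs the exact small-sample distribution cannot reach
$p < 0.05$, which the output notes. No multiplicity correction is applied
by default, matching common practice in per-parameter phase tables; Holm is
available via `p_adjust = "holm"`. Under a continuous null the exact test's
discreteness makes the realized type-I rate slightly conservative
(~0.04–0.05 at $n = 25$); the calibration test asserts $0.05 \pm 0.02$.

# Numerical and scale choices

* Problem sizes in the shipped tests and the acceptance script were chosen
  as the smallest that make each property stable: 100 seeded series for
  oracle equivalence, 8-point HR sweep, 4 two-minute records for RR
  regression, 300-s series for spectral recovery, $n = 600$ for classifier
  recovery, 25 synthetic subjects for protocol direction and questionnaire
  regression, 1000 replicates for test calibration.
* All generators are bit-reproducible given (spec, seed); sub-seeds are
  derived with double-precision modular arithmetic kept below $2^{31}$.
* Oracle tests compare against independent brute-force implementations
  (explicit moment sums, $O(n^2)$ template counting, a direct DFT) at
  $10^{-9}$ relative, with an absolute floor for identically-zero
  quantities where relative error is ill-posed.

# Known limitations

* RR quantization at 10 ms (100 Hz) bounds the accuracy of
  short-difference statistics (RMSSD, SD1) on low-variability series.
* The VLF band is not resolvable in 30-s windows (flagged, see above).
* The synthetic PPG's simplified morphology overstates real-world beat
  detection performance; motion artifacts and adaptive filtering are out of
  scope.
* The classifier ships without any claim about external corpora; an
  ingest path for user-supplied labeled feature CSVs exists
  (`read_feature_csv()`), but no external data are bundled.
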