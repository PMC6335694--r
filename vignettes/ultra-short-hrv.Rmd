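---
title: "Validating ultra-short HRV features as surrogates of 5-minute features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating ultra-short HRV features as surrogates of 5-minute features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Short-term heart rate variability (HRV) analysis is conventionally performed
on nominal 5-minute excerpts of normal-to-normal (NN) interbeat intervals.
Wearable and real-time applications push towards much shorter windows
(3, 2, 1 minutes, 30 seconds), but a feature computed on a shortened window
is not automatically interchangeable with its 5-minute counterpart: the
estimate may change its distribution, lose its contrast between conditions,
or decorrelate from the benchmark. Borrowing the logic of surrogate
endpoints in clinical research, an ultra-short feature should only stand in
for the 5-minute benchmark after passing explicit consistency *and*
agreement criteria.

`ushrv` implements that validation chain for the mental-stress setting
(paired rest and stress recordings per subject):

1. **Quality gating.** The fraction of intervals delimited by two
   normal-labelled beats (NN/RR ratio) must reach 90%; recordings below the
   threshold are excluded, not corrected. The boundary is inclusive and the
   first interval's opening beat (before the record) is assumed normal.
2. **Segmentation.** From each 5-min NN excerpt, one *central* window per
   candidate scale, plus disjoint *consecutive* windows at the shortest
   retained scale. Windows live on cumulative time, an interval belongs to
   the window containing its *ending* beat, and windows are half-open
   `[start, end)` — which makes consecutive windows an exact partition.
3. **Feature extraction.** The 23-feature catalogue below, with per-scale
   computability masking.
4. **Surrogate gate.** Per feature and scale, a paired Wilcoxon signed-rank
   test encodes the stress-vs-rest trend; Spearman correlation screens each
   ultra-short feature against its 5-min value within each phase. A feature
   passes only if its trend is significant with the benchmark's direction at
   every retained scale *and* `rho > 0.7` with `p < 0.05` at every retained
   scale in both phases. Bland–Altman bias and limits of agreement are
   reported as advisory evidence only.
5. **Classification harness.** A person-independent 60/40 subject split,
   relevance (Wilcoxon) and redundancy (Spearman clusters) feature selection
   on the benchmark features, a five-family model grid tuned by 3-fold
   person-independent cross-validation maximising AUC, and a frozen
   benchmark-trained model assessed on the shorter scales.

## The feature catalogue and masking

Time domain: MeanNN, StdNN (ms), MeanHR, StdHR (bpm, from the instantaneous
rate `60000 / NN_i`), RMSSD (ms), NN50, pNN50. Frequency domain (AR
spectrum of the tachogram): LF (0.04–0.15 Hz), HF (0.15–0.4 Hz), total
power (0–0.4 Hz) in ms², and LF/HF. Non-linear: Poincaré SD1/SD2,
approximate and sample entropy, Grassberger–Procaccia correlation dimension
D2, DFA exponents α1/α2, and recurrence statistics (REC, determinism,
mean/max diagonal line length, line-length Shannon entropy).

Not every feature is meaningful on a short window. Spectral estimates need
recordings at least ten times the wavelength of the band's lower edge, so
LF, LF/HF and total power require ≥ 2 min and HF ≥ 1 min; approximate
entropy is unreliable below 3 min; the remaining non-linear features run
out of samples below 1 min. The mask is therefore 23/23/22/19/9 computable
features at 300/180/120/60/30 s, and masked entries are explicit `NA`s with
a `computable` flag — never silent zeros.

```{r}
library(ushrv)
sapply(c(300, 180, 120, 60, 30),
       function(s) sum(computability_mask(s)$computable))
```

## Numerical choices

**Variance convention.** All descriptive features use the population
(divide-by-N) variance. SD1 is defined through the *uncentred* second
moment of successive differences, `SD1^2 = mean(diff(x)^2) / 2`, so the
identity `SD1 == RMSSD / sqrt(2)` is exact for every input rather than
approximate under stationarity; `SD2^2 = 2 var(x) - mean(diff(x)^2) / 2`,
floored at zero.

**AR spectra.** The tachogram is resampled at 4 Hz by cubic spline,
linearly detrended, and an order-16 Burg AR model is fitted. Band powers
are trapezoid integrals of the one-sided AR density. Because an almost
noise-free oscillation drives the AR poles arbitrarily close to the unit
circle, the integration grid is refined with log-spaced points around each
pole frequency (spacing tied to the pole's distance from the circle);
uniform grids alone under-resolve those near-delta peaks and can lose most
of a band's power. A 40 ms, 0.25 Hz tone recovers its theoretical
`A²/2 = 800 ms²` HF power to within a few percent. Order 16 and 4 Hz are
common toolkit defaults; both are configurable through `hrv_params()`.

**Entropies.** Template length `m = 2`, tolerance `r = 0.2 · SD`, Chebyshev
distance; sample entropy excludes self-matches, approximate entropy
includes them. Both are validated against naive O(n²) counting oracles to
1e-12.

**DFA.** Integrated, mean-centred profile, linear detrend in
non-overlapping boxes, α1 over boxes 4–16 and α2 over 16–64 beats. Raw
DFA-1 at such small boxes over-estimates the exponent (the exact
white-noise expectation of the fitted slope over 4–16 is 0.583, not 0.5),
so each `F(n)` is normalised by the analytic white-noise expectation for
its box size — the standard finite-size correction, computed exactly from
`tr((I - H) C)` rather than by shuffling. After correction the white-noise
exponent is 0.50 ± 0.06 per series and an integrated random walk reads
≈ 1.42.

**Correlation dimension.** Embedding dimension 10, delay 1, Euclidean
norm. The scaling region of `log C(r)` vs `log r` is chosen automatically:
sliding 10-point windows on a 30-point log-spaced grid restricted to the
unsaturated part of the correlation sum (`C ≤ 0.5`), keeping the window
with the best linear fit and a positive slope. A long sinusoid (a limit
cycle) reads D2 ≈ 1; constant series are flagged non-computable.

**Recurrence.** Embedding 10, delay 1, threshold `sqrt(m) · SD` on the
Euclidean norm, minimum line length 2, line of identity excluded from the
diagonal statistics, line-length entropy in nats (configurable to bits).

**Wilcoxon signed-rank.** Zero differences are dropped; `n ≤ 15` uses exact
enumeration of all `2^n` sign assignments of the tie-averaged ranks (so
tied absolute differences remain exact), larger `n` the normal
approximation with continuity and tie corrections. Exact ties of the
condition medians encode as an "up" trend by convention.

**Gate conventions.** "Same behaviour" means: significant at the benchmark
*and* significant with the identical code at each retained scale. The
`rho > 0.7` threshold is strict. A scale is retained when at least
`min_pass = 3` features behave coherently with the benchmark there — a
configurable rule that reproduces the exclusion of the 30-s scale on the
shipped reference tables (6 coherent features at 60 s versus 2 at 30 s).
No multiple-testing correction is applied by default, matching the
published procedure the gate mirrors; users can apply `p.adjust` to the
trend table when they prefer.

## The classifier harness

Stress is the positive class. Features are z-scored with training-fold
statistics only; nothing from the test folder touches selection,
standardisation or model choice (a permutation test in the suite checks
this). Continuous scores per family: fraction of stress votes among the k
nearest neighbours, LDA posterior probability of stress, tree leaf stress
proportion, oriented SVM decision value, MLP output activation; hard labels
at 0.5 (0 for the SVM margin). AUC is the tie-aware Mann–Whitney rank
statistic, hence invariant under monotone score transforms.

Two families deserve a note. The MLP is implemented in-package as the
classical single-hidden-layer (3 logistic units) perceptron trained by
per-instance gradient descent with momentum, because that is the
formulation whose learning-rate (0.3–0.9) and momentum (0.2–1) grid the
model specification exposes. The tree family uses `rpart` (CART with the
information split); its pruning-strength grid is expressed as a
C4.5-style confidence factor and mapped monotonically onto the
cost-complexity parameter (`cp = 0.01 + 0.5 (0.5 - conf)`), with the
minimum-leaf setting mapped to `minbucket`.

## What the synthetic cohort does and does not emulate

`generate_cohort()` draws, per subject and condition, a mean interval,
LF (0.10 Hz) and HF (0.25 Hz) oscillation amplitudes and a white-noise SD,
then synthesises `RR_i = μ + A_LF sin(2π·0.10·t) + A_HF sin(2π·0.25·t) + ε`
beat by beat (modulators evaluated at the interval's start, cumulative
beat times, 330 s so a full 300-s excerpt survives trimming). Defaults
describe healthy young adults: rest `μ = 850 ms, A_LF = 35, A_HF = 30,
σ = 25`; stress `μ = 700, A_LF = 40, A_HF = 13, σ = 18`; between-subject
SDs 60/8/7/5 ms. The stress contrasts reproduce the canonical directions —
shorter MeanNN, lower StdNN and HF, higher MeanHR and StdHR (the raised
LF amplitude and the quadratic effect of the shorter mean interval on the
instantaneous rate outweigh the reduced noise). `inject_non_nn_beats()`
relabels a fraction of beats as ectopic, perturbing each into a premature
short–long couplet, to exercise the NN/RR gate (a beat rate `q` removes
about `2q` of the intervals).

The generator gives controlled band powers and trends, which is what the
pipeline's tests need. It does **not** emulate respiratory sinus arrhythmia
dynamics coupled to a breathing signal, 1/f background structure,
circadian drift, or genuinely non-linear heart-period dynamics — so
passing tests demonstrate the pipeline's correctness on signals with known
structure, not the physiological realism of any particular feature value.
Real recordings also arrive with annotation errors and non-stationarity
that the gate only partially models.

## Problem sizes used by the test-suite

The suite validates entropy/recurrence implementations against brute-force
oracles on series up to n = 200; DFA calibrations average 50 series of 300
samples; the end-to-end cohort check uses 40 subjects at four scales for
three features; the null-calibration check uses 200 cohorts of 12 subjects
at the 1-min scale with time-domain features. These sizes keep every check
well-conditioned while the whole suite runs in a few minutes on one core.

## Known limitations

* The exact AR order, detrending and spectral integration used by any
  particular commercial toolkit are not reproduced bit-for-bit; defaults
  are declared and configurable instead.
* The automatic D2 scaling-region search is a heuristic; on short, noisy
  excerpts the estimate is best treated as a comparative index.
* The shipped reference tables encode published group-level evidence
  (trend codes and correlation coefficients), not subject-level data, so
  the gate — but not the feature extractor — can be exercised against them.
* The C4.5-style tree grid is emulated with CART cost-complexity pruning;
  confidence factors are comparable across runs of this package, not with
  other toolkits' C4.5 implementations.
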