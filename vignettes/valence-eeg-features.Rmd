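---
title: "Comparing EEG features for valence emotion recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing EEG features for valence emotion recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegvalence)
```

## The problem

Emotional valence — the pleasantness axis of the circumplex emotion model —
leaves measurable traces in scalp EEG, and a large literature ranks
candidate features for decoding it: time-domain statistics, band power and
its variants, phase- and amplitude-coupling networks, and hemispheric
asymmetries. `eegvalence` implements a complete, reproducible version of
that comparison machinery: a feature battery across five domains, an
important-electrode analysis built on minimum-redundancy maximum-relevance
(mRMR) selection, and the cross-validated classification protocols used to
score features — all driven by a seeded synthetic-EEG generator, because the
emotion-EEG recordings such studies are built on are typically not publicly
deposited.

Two recording layouts are modelled throughout:

* an **emotional-picture layout**: 62 channels (10-10 positions, 27
  homologous left/right pairs + 8 midline electrodes), 600 Hz, 2 s epochs,
  five valence classes (extremely negative EN, moderately negative MN,
  neutral, moderately positive MP, extremely positive EP), 30 trials per
  class per subject;
* a **music-video layout**: the standard 32-channel montage, 128 Hz, 60 s
  trials with continuous 1–9 valence/arousal self-ratings, analyzed as
  high/low valence after rating-window sample selection.

## The feature battery

All features operate on an `epoch_set` — a labelled
`epochs x channels x samples` array in microvolts with montage metadata.

**Time domain, per electrode** (`extract_features(..., families = "time")`):
population standard deviation
$\delta = \sqrt{\tfrac1N \sum_n (x(n) - \bar x)^2}$; mean absolute first-
and second-order differences
$\tfrac1{N-1}\sum |x(n{+}1) - x(n)|$, $\tfrac1{N-2}\sum |x(n{+}2) - x(n)|$,
and both normalized by $\delta$; Higuchi fractal dimension (slope of
$\log L(k)$ against $\log k$ for the normalized curve lengths
$L(k)$, $k = 1..k_{\max}$); approximate entropy and sample entropy with
Chebyshev distance.

**Frequency domain**: Welch band power spectral density (mean PSD over the
band's bins, µV²/Hz) and short-time-Fourier band power (total $|S(n,f)|^2$
over band bins and frames, µV²), per band per electrode.

**Time–frequency**: differential entropy, defined here as
$\mathrm{DE} = \ln \sum_{n,f \in \text{band}} |S(n,f)|^2$ — the natural
logarithm of the STFT band power. The identity
`differential_entropy(x) == log(band_power(x))` is exact in the package and
is asserted by the test suite. The log base is a convention; base-2 would
shift every DE value by a constant factor and affect no comparison.

**Brain networks**: per band, a symmetric electrode-by-electrode matrix by
one of three coupling measures — Pearson correlation, magnitude-squared
coherence $|P_{xy}|^2 / (P_{xx} P_{yy})$ averaged over band bins, and the
phase-locking value $|\langle e^{i(\phi_x - \phi_y)} \rangle_t|$ of
analytic-signal phases — summarized by four weighted-graph properties:
node-averaged clustering coefficient (Onnela cube-root form), characteristic
path length, node-averaged local efficiency, and global efficiency.

**Spatial asymmetry**: for every per-electrode base feature and every
homologous pair, differential asymmetry $\mathrm{DA} = f_l - f_r$ and
rational asymmetry $\mathrm{RA} = f_l / f_r$.

The registry (`feature_registry()`) enumerates every column
deterministically; with the six-band scheme and all families enabled the
battery covers the ~110-feature space of the comparison literature (8 time
+ 2 x 6 frequency + 6 DE per electrode, 12 network-property groups per
band, and 27-pair DA/RA per base feature). The exact decomposition of a
"110 features" count is not standardized in the field, so the registry
documents our enumeration rather than forcing a total.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| entropy embedding `m` | 2 | field-standard for ApEn/SampEn on short epochs |
| entropy tolerance `r` | 0.2 × Std | field-standard; scales with signal amplitude |
| Higuchi `k_max` | 8 | N > 2·k_max holds for every supported epoch length; slope fitted by OLS in log-log space (the k→∞ limit form is not computable on finite data) |
| Welch window / overlap | 1 s / 50% Hamming | ≥3 segments on a 2 s epoch; 1 Hz resolution resolves the 1–4 Hz delta band |
| STFT window / overlap | 0.5 s / 50% Hamming | 7 frames on a 2 s epoch — a genuine time-frequency decomposition at 2 Hz resolution |
| band edges | inclusive both sides | shared edges (8 Hz in theta and alpha) count in both bands, matching the printed band tables |
| band-pass realization | zero-phase Butterworth, order-2 high-pass + order-8 low-pass | the 0.1 Hz corner sits at a normalized frequency of ~3·10⁻⁴ where higher-order IIR high-passes are numerically unstable; the steep low-pass gives >26 dB rejection of a 100 Hz tone; zero-phase (forward–backward) filtering avoids latency distortion of time-domain features |
| mRMR variant | MID (difference), 8 equal-frequency bins | the common default; equal-frequency binning makes mutual information invariant under monotone transforms; `variant = "miq"` is available |
| SVM | C-SVC, linear kernel, C = 1 | the LibSVM default for a linear C-SVC |
| other classifiers | KNN k = 5; RF 100 trees; Gaussian NB; LDA; boosted stumps 50 rounds | library-conventional defaults, frozen for reproducibility |

Processing order is fixed as filter → average reference → baseline
correction; the operations commute with epoch subsetting, and re-referencing
before baseline correction would only shift baselines that are subtracted
anyway, so the order is a convention, documented here once.

## The synthetic generator: what it emulates, what it does not

Each simulated epoch is a sum of

1. a 1/f^α background (α = 1 by default), realized by spectrally shaping
   white Gaussian noise — this reproduces the canonical EEG spectral slope
   without modelling physiology;
2. band-limited oscillators: one sinusoid per band with per-epoch random
   frequency (uniform within the band) and per-epoch, per-channel random
   phase; an optional shared-phase mode locks phases within designated
   channel pairs so phase-locking and coherence features have recoverable
   ground truth;
3. white sensor noise (2 µV by default).

Class structure is injected as multiplicative *power* factors on named
(band, channel) combinations. A master seed plus a fixed per-subject offset
makes every epoch bit-reproducible.

The reference cohort (`esd_recovery_spec()`) used by the acceptance analysis
injects a graded high-gamma effect at four frontal/temporal electrodes
(F3, F4, T7, T8): power factors 3, 1.75, 1, 0.57, 0.33 across the five
valence classes — a factor-3 contrast between the extreme-negative class and
neutral, a monotone ladder mirroring the reported association between
high-frequency power and valence extremity. Two generator choices deserve
justification:

* *A graded ladder rather than a single-class effect.* With only one class
  perturbed, the other four classes are identically distributed and
  five-class accuracy is capped near 40%; a monotone per-class ladder is
  both the more realistic model of a valence continuum and the only design
  under which "clearly above chance" five-class recovery is a meaningful
  claim.
* *Effect-band oscillator at 3 µV.* The 1/f background carries ~5 µV² in
  the 50–80 Hz band; a 1 µV oscillator (1 µV² power) would be buried, and
  every recovery question would be vacuous. At 3 µV (9 µV²) the injected
  rhythm dominates its band, and class contrasts are detectable at
  single-epoch level.

What the generator does **not** emulate: ocular/muscle artifacts (hence the
artifact-removal stage is a documented pass-through hook), volume
conduction and the resulting spatial correlation structure, non-stationary
drifts, and inter-subject variability in effect topography (every subject
carries the effect at the same electrodes, only the noise differs). Passing
recovery tests therefore demonstrates that the pipeline measures what it
claims on data with known structure — not that real recordings would yield
the same feature ranking. One visible consequence: because the injected
effect is spatially punctate and nothing spreads it across the scalp, the
58 non-injected channels contribute pure noise, and the top-16 electrode
subset can *out-perform* the full montage in cross-validation at these
sample sizes — on real recordings, where volume conduction distributes
signal, the full montage typically wins by a small margin instead. The
recovery claim tested is directional: restricting to the selected 16
electrodes costs at most a few accuracy points.

## Numerical choices and degenerate inputs

* Entropies use counts with ≤ r (inclusive); approximate entropy includes
  template self-matches, sample entropy excludes them. A constant sequence
  short-circuits both to 0; a sequence with no template matches at
  dimension m+1 makes sample entropy undefined and returns `NA` with a
  warning rather than +∞.
* Zero-variance channels: normalized differences and fractal dimension are
  flagged `NA` per epoch during extraction; Pearson rows are zeroed with a
  warning.
* Graph analysis takes |w| (Pearson networks can carry negative weights,
  and the weighted-graph properties require non-negative weights), treats
  zero weights as absent edges, uses edge length 1/w for shortest paths,
  computes CPL over reachable pairs (with a warning when disconnected) and
  counts unreachable pairs as zero contribution to efficiencies. CC and
  local efficiency normalize weights by the matrix maximum
  (Rubinov–Sporns convention).
* RA for signed base features is passed through with its sign; a zero
  right-hemisphere value gives a per-epoch `NA` flag, never a silent
  infinity.
* Ties in mRMR scores and electrode counts break toward the lowest column
  index / montage order — reproducibility over arbitrariness.
* EDF stores 16-bit integers; the round trip is exact in labels and sample
  counts and accurate to ~1/32768 of the per-channel physical range in
  values. The internal container (float64 + JSON sidecar) is lossless and
  is the preferred interchange format; it exists because EDF cannot carry
  epoch/label structure cleanly.

## Design choices that were genuinely open

* **Which pairs feed DA/RA**: all per-electrode time, frequency and
  time–frequency features, with a configurable subset — the comparison
  literature reports asymmetries of difference features, fractal dimension
  and band DE, implying the general construction.
* **mRMR scope**: ranking runs per feature type over that feature's
  per-electrode columns (so "important electrodes" are defined per
  feature), matching how per-feature electrode maps are reported.
* **"Sampled 4 times"**: the one-vs-rest protocol draws 4 balanced
  30-vs-30 subsamples of the mixed rest class; an unbalanced variant is
  available (`balanced = FALSE`).
* **DAC**: implemented as linear discriminant analysis.
* **Feature standardization**: z-scored with training-fold statistics only;
  whether the original protocols standardized is unstated, but leakage-free
  standardization is the defensible default and is canary-tested
  (permuted labels → chance accuracy).
* **DEAP-layout pairs**: the 32-channel montage admits 14 geometrically
  valid homologous pairs; the pair list is config-overridable.

## Problem sizes

The test suite and the acceptance analysis run the recovery study at 10
subjects × 150 epochs (62 channels, 2 s at 600 Hz), rank electrodes on
high-gamma differential entropy, and cross-validate with a linear SVM —
sizes chosen so the full analysis completes in minutes on one CPU while
keeping 30 trials per class per subject, the trial count of the emulated
design. Formula-level checks use brute-force oracles at N ≤ 200 (entropies)
and 6-node graphs (network properties), where exhaustive computation is
exact and fast.

## Known limitations

* Directed connectivity (Granger, partial directed coherence) is out of
  scope; only the three undirected networks are implemented.
* The EDF reader supports uniform sampling rates only; BDF/BrainVision/FIF
  dialects are not handled.
* Absolute feature-timing values are hardware-bound; `timing_table()`
  reports medians and a relative ordering, and only ordinal relations are
  tested.
* The synthetic generator's limitations listed above bound what any green
  test here says about real EEG.

## A worked example

```{r example, eval = FALSE}
spec <- esd_recovery_spec(n_subjects = 3, seed = 1)
fms <- lapply(1:3, function(s)
  extract_features(generate_subject(spec, s), families = "timefreq"))

sel <- select_electrodes(fms, "timefreq", "de", band = "high_gamma",
                         sizes = c(4, 16))
sel$sets[["4"]]          # recovered electrodes
autoplot(sel)            # electrode-frequency chart

res <- crossval_accuracy(fms[[1]], classifiers = "svm_linear",
                         seed = 7, task = "five_class")
glance(res)              # mean +/- sd fold accuracy
```
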