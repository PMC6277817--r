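---
title: "Profiling single theta cycles by their nested spectral components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling single theta cycles by their nested spectral components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During locomotion, the rodent hippocampal CA1 local field potential (LFP)
is dominated by a 5–12 Hz theta rhythm, and faster transient oscillations
— beta (~22 Hz), slow gamma (~35 Hz), two mid-gamma bands (~54 and
~80 Hz) and fast/ripple-band gamma (>100 Hz) — occur *nested within*
individual theta cycles, each locked to its own theta phase and present
in only a subset of cycles.  Averaging over minutes of recording hides
this cycle-by-cycle structure.  `thetanest` implements an unsupervised,
single-cycle framework: every theta cycle is described by the spectrum of
its nested content, and recurring spectral motifs ("theta-nested spectral
components", tSCs) are discovered blind, without predefined frequency
bands.  Downstream statistics then ask what the expression of each tSC in
a cycle implies for spiking, ensemble identity, offline reactivation,
laminar currents, and behavior.

## The pipeline

1. **Band splitting by EEMD** (`eemd()`, `classify_imfs()`).  Ensemble
   empirical mode decomposition breaks the raw LFP into intrinsic mode
   functions (IMFs) by iterative sifting with added white noise.  Unlike
   linear filters, EMD keeps an asymmetric theta waveform in a single
   mode, so the supra-theta residue is largely free of the harmonics that
   plague filter-based cross-frequency analysis.  IMFs are classified by
   their amplitude-weighted mean Hilbert frequency: low (< 5 Hz), theta
   ([5, 12] Hz, boundaries inclusive), supra-theta (> 12 Hz); band
   composites are sums of whole IMFs.
2. **Cycle detection** (`detect_theta_cycles()`).  Candidate theta
   extrema must exceed the Hilbert envelope of the low-frequency
   composite; a cycle is a trough–trough span of 71–200 ms around one
   candidate peak (largest peak if several), during locomotion faster
   than 2 cm/s.  Theta phase (`theta_phase()`) is piecewise-linear
   between anchors: trough −180°, ascending zero −90°, peak 0°,
   descending zero +90°, trough +180° — a waveform-based phase that does
   not assume sinusoidality.
3. **Spectral signatures** (`spectral_signatures()`).  Complex Morlet
   amplitudes (10–200 Hz, 1-Hz steps, width ω₀ = 5) of the supra-theta
   signal, averaged trough-to-trough, give one 191-dimensional
   amplitude vector per cycle.
4. **tSC extraction** (`extract_tscs()`).  Signatures are centered,
   reduced to 5 principal components, whitened, and unmixed with
   FastICA.  The stored tSC weight vectors are the ICA *mixing patterns*
   mapped back to frequency space — the spectral shape each component
   contributes to the data — signed so that the mean projection onto the
   raw signatures is positive, and ordered by ascending peak frequency.
   The per-cycle *strength* of a tSC is the inner product of the cycle's
   signature with the component (`tsc_strength()`); "strong" cycles
   exceed a robust threshold, `2·MAD/0.6745` above the median strength
   (`tsc_threshold()`), i.e. two robust standard deviations.

Downstream modules quantify: spike-probability change by theta phase in
strong-tSC cycles with a per-phase ANOVA across components and animals
(`spike_probability_change()`, `spc_significance()`); spike coupling to
the tSC-frequency IMF with a theta-phase-preserving circular-shift null
(`phase_coupling()`); cross-validated prediction of per-cycle strengths
from ensemble spike counts with full-pipeline shift nulls
(`fit_tsc_glm()`, `shift_null()`); sharp-wave/ripple detection and
co-firing reactivation regressions (`detect_swr()`, `cofiring()`,
`reactivation_strength()`, `delta_swr_regression()`); current source
density and its laminar phase–amplitude profiles (`csd()`,
`layer_profiles()`); and task-stage models with baseline normalization,
speed and recording-day covariates, matched-cycle controls and
predefined-band (Butterworth) comparisons (`baseline_zscore()`,
`stage_anova()`, `band_amplitude_control()`).

## Design choices in the ICA step

Three choices here were genuinely open and deserve their rationale.

**Patterns, not filters.**  An ICA solution has two dual bases: unmixing
filters (rows of W acting on whitened data) and mixing patterns (columns
of the estimated mixing matrix).  Only the patterns live on the scale of
the data and look like spectra with a single bump at the component's
frequency; back-projecting the *filters* through the whitening
`1/σ` amplifies the low-variance principal components and puts the
weight vector's argmax in the wrong place.  We verified this numerically
against an independent FastICA implementation on identical input: with
patterns, all five planted burst families are recovered at their
frequencies; with filters, peaks duplicate and drift.

**Skewness contrast.**  Per-cycle strengths of a burst family are
one-sided: zero in the ~80% of cycles without the burst, positive
otherwise.  The dominant non-Gaussianity of such a source is *skewness*,
to which the customary logcosh and kurtosis contrasts are blind (they
are even functions of the source).  At desk scale (~950 cycles from
120 s — an order of magnitude fewer than a full recording session) this
matters: with logcosh, on some simulated datasets *no* random restart
isolated the 35-Hz family, while a label-informed oracle rotation of the
same 5-PC space did, proving the failure was the contrast and not the
subspace.  With the skewness contrast (g(u) = u²), every restart on
those datasets recovered all five families.  `contrast = "logcosh"`
remains available; when skew-contrast iteration finds no stable fixed
point (sources with little skewness), the fit falls back to logcosh with
a warning.

**Consensus over restarts.**  FastICA is an optimization with local
optima.  `extract_tscs()` therefore runs `n_restarts = 30` seeded
restarts, pools the resulting patterns, clusters them by absolute cosine
similarity (average linkage), and keeps each cluster's centrotype, with
a per-component stability index (mean within-cluster minus
between-cluster similarity) recorded in the model.  This is the Icasso
strategy familiar from EEG/MEG ICA.  A single plain fit is available
with `n_restarts = 1`.

## The synthetic world

Real recordings are not distributed with this package, so every analysis
is exercised on synthetic data whose ground truth is known
(`ground_truth()`, `generate_lfp()`, `generate_spikes()`,
`generate_behavior()`, `generate_rest()`).  The default world
(`default_ground_truth()`) is:

| parameter | default | why |
|---|---|---|
| theta frequency | 8 Hz | center of the locomotor theta band |
| theta asymmetry (asc/desc) | 0.8 | shorter ascending limb, as in CA1 |
| burst families | 22, 35, 54, 80, 169 Hz | the five canonical tSC peak frequencies |
| preferred theta phases | −144°, −72°, 0°, 72°, 144° | distinct and evenly spaced; identifiability requires distinctness, not particular values |
| occurrence probability | 0.2 per cycle per family, independent | sparse nesting |
| burst amplitude | 0.25 × theta amplitude | transient deflections visible against theta but not dominating it |
| burst envelope SD | 1.5 cycles of the family frequency | enough oscillation cycles for a defined frequency; shorter envelopes become broadband blips |
| background | 1/f power spectrum | typical LFP spectrum |
| supra-theta SNR | 2 | total burst variance / noise variance above 12 Hz |
| spike model | Poisson, rate = base × von-Mises(theta phase) × von-Mises(family fast phase, in occupied cycles) × (1 + slope·speed) | the modulations the analyses assume |
| SWR rest epochs | 150-Hz Gaussian-windowed ripples; in-window counts = private Poisson + thinned shared Poisson factor | outer-product co-activation with analytically known pairwise r (`rest_pair_correlation()`) |

The theta-phase spike gain is normalized to preserve each unit's mean
rate, but the fast-phase gain deliberately is not: a coupled unit fires
I₀(κ)-fold more in cycles where its family occurs (≈27% at κ = 1), which
is the count-level ensemble signature the GLM analyses decode.

The generator reproduces the *statistical structures the pipeline
assumes* — phase-locked transient bursts, 1/f noise, phase- and
rate-modulated spiking, co-activation inside ripples — and nothing else.
It does not emulate volume conduction, electrode artifacts, theta
frequency drift, place fields beyond a speed gain, interneurons, or
non-stationary behavior states.  A green test therefore establishes that
the implementation does what the method claims under the method's own
assumptions; it says nothing about robustness to the pathologies of real
recordings.

One cautionary result from building this world: we tried capping the
burst envelope at a quarter theta period so that low-frequency bursts
stay strictly inside one cycle, and recovery of the 22-Hz family got
*worse* — with less than about one oscillation cycle under the envelope
the burst loses its spectral identity.  The 22-Hz family's envelope
(SD ≈ 68 ms) genuinely bleeds into neighboring cycles; this is the main
reason its cycle labels are the hardest to recover (signature–label
correlation ≈ 0.64 vs ≈ 0.93 for the other families).

## Numerical choices

* **EEMD**: noise SD 0.2 × SD(signal); ensemble size 100 by default
  (tests and the acceptance protocol use 30 — at this SNR the recovered
  components are indistinguishable and a run fits in tens of seconds);
  complementary ±noise pairs so that IMFs + residual reconstruct the
  input *exactly* at any ensemble size; sifting stops at the pointwise
  Cauchy criterion Σ(Δh)²/h² < 0.2 or 10 sweeps (on long signals the
  criterion never triggers first, giving the canonical fixed-10-sift
  behavior); envelopes are natural cubic splines through extrema with
  two extrema mirrored past each end; plateau extrema (ties from
  symmetric sampling) count once, at their midpoint.
* **Mean IMF frequency**: amplitude-weighted mean of the Hilbert
  instantaneous frequency, negative excursions clipped at zero.  Whether
  to weight by amplitude was an open point; weighting is robust to
  low-amplitude phase slips, which is what matters for band assignment.
* **Morlet transform**: frequency-domain window `2·exp(−(sω−ω₀)²/2)`,
  ω₀ = 5, so a unit tone yields unit amplitude at its own frequency;
  FFT convolution with ≥1 s zero padding.
* **Cycle resolution**: consecutive candidate troughs are scanned left
  to right; a shared trough between neighboring cycles is allowed, with
  half-open spans `[trough, trough)` keeping samples uniquely assigned.
* **Phase-preserving coupling null**: each spike keeps its theta phase
  and is re-assigned to a random cycle of the subset; the sample index
  is found by inverting the piecewise-linear phase map of the target
  cycle, and the tSC phase is re-read there.  2000 shifts, 99.9th
  percentile, eligibility > 100 spikes.
* **"GLM"**: identity-link Gaussian (ordinary least squares) — targets
  are z-scored continuous strengths and performance is Pearson r.
  Cross-validation is a random 10-fold partition; fold statistics
  (means/SDs for z-scoring) come from the training folds only.  The
  shift null re-runs the *full* cross-validation per shift.  The
  implementation solves centered normal equations with the training
  Gram matrix obtained by downdating the full Gram matrix, which keeps
  a 250-shift null under a second at test sizes; it is verified against
  a plain `lm()` oracle per fold.
* **SWR power**: RMS in an 8-ms sliding window (≈ one ripple cycle;
  the window length is exposed), summed over channels, z-scored per
  rest epoch, no smoothing before peak picking; 7 SD threshold; 100-ms
  event windows; 50-ms minimum peak separation keeping the larger peak.
* **CSD**: the second-spatial-difference formula is implemented in its
  Laplacian form `−(V[n−1] − 2V[n] + V[n+1])` (a linear depth profile
  gives zero, a common offset cancels); a printed variant with the
  opposite sign on `V[n+1]` circulates in the literature and is
  available via `formula = "printed"`, but it is not reference-free and
  is not the default.
* **Degenerate inputs**: all-identical strengths give threshold =
  that value; pairs with zero count variance or < 5 spikes are masked
  out of co-firing; constant strength vectors error in the GLM;
  zero-SD baselines error in `baseline_zscore()`; cycles extending past
  the signal are dropped with a warning; an empty cycle subset errors.
* **Zones**: positions snap to the nearest track point; goal/departure
  membership uses geodesic (along-track) distance ≤ 20 cm, barriers use
  Euclidean distance ≤ 10 cm; overlapping definitions resolve
  goal > departure > barrier (configurable by calling with different
  tolerances).
* **Stage model**: cycle-level regression with stage dummies (baseline
  reference), speed, and recording-day dummies; a day-averaged summary
  can be derived from the same outputs but the model itself is fit at
  cycle level.

## What the acceptance protocol measures

`scripts/acceptance.R` runs the full pipeline end to end on the default
synthetic world 20 times (120 s at 1250 Hz per run, EEMD ensemble 30)
and reports the median peak frequency of each of the five extracted
components, ranked ascending.  The five medians are the package's
recovery of the five planted family frequencies; at this SNR they come
out within 1–2 Hz of 22/35/54/80 Hz and within a few Hz at 169 Hz
(the Morlet bandwidth at 169 Hz is ±34 Hz, so single-Hz accuracy there
is not expected and not required).

## Known limitations

* EEMD mode mixing is reduced, not eliminated; near-theta bursts
  (< ~20 Hz) can partially merge with the theta IMF at low SNR.
* The consensus ICA stabilizes the solution across seeds but cannot
  create information: with < ~500 cycles or heavily overlapping
  families the components degrade gracefully into mixtures.
* The wavelet grid's 1-Hz step overstates precision above ~100 Hz,
  where the Morlet bandwidth spans tens of Hz.
* The synthetic behavior model has no place fields; spatial information
  analyses are exercised on constructed occupancy/rate maps, not on the
  walk generator.
* `speed_controls()` condition comparisons use equal regressor counts
  but make no small-sample bias correction beyond that.
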