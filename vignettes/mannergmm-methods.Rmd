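---
title: "Methods: manner-grouped GMM-UBM detection of parkinsonian speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: manner-grouped GMM-UBM detection of parkinsonian speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mannergmm)
```

## The problem and the modelling idea

Parkinson's disease degrades speech motor control selectively: plosive
closures weaken towards frication (spirantization), the vowel formant
space contracts, and articulation slows. A detector that models all
speech frames with one density blurs these class-specific effects
together. The framework implemented here instead conditions the
modelling on the *manner of articulation* of each frame's underlying
phone — plosive, fricative, affricate, liquid, nasal or vowel, as given
by a forced alignment — and measures how detectable the disease is from
each manner class alone. Beyond raw detection accuracy, the pattern of
accuracies across manner classes is itself the scientific output: it
says *where* in the phonetic inventory the disease is most visible.

## Front-end

Audio is peak-normalized and, when sampled above 16 kHz, low-pass
filtered and resampled to 16 kHz (`load_and_normalize()`; source rates
below 16 kHz are rejected rather than upsampled, since upsampling would
fabricate bandwidth the analysis assumes). Frames are 15 ms with a
7.5 ms shift (50 % overlap) under a Hamming window. Each frame passes
through the perceptual linear prediction chain: power spectrum,
trapezoidal critical-band integration on the Bark scale, equal-loudness
pre-emphasis, optional RASTA band-pass filtering of the log band
energies, the intensity-loudness power law (cube root), an
autoregressive model of order `F` fitted by Levinson–Durbin, and the
cepstral recursion keeping `c1..cF`. Delta and delta-delta trajectories
are appended with a 5-tap antisymmetric regression FIR (taps
proportional to −2,−1,0,1,2, normalized by 10, edges replicated), so
the feature dimension is `D = 3F` with `F` on the grid 10–20 in steps
of 2.

Three choices here were genuinely open and are worth recording:

* **`c0` is excluded** from the static vector, keeping `D = 3F` a clean
  function of the coefficient grid and removing the energy term that
  per-utterance amplitude normalization already tries to neutralize.
* **Equal-loudness pre-emphasis is applied before the RASTA filter.**
  With this ordering a stationary input decays to exactly zero cepstra
  once the filter settles (the band-pass removes any constant
  log-spectrum, leaving a flat auditory spectrum and hence a white AR
  model), and multiplying the waveform by a constant gain perturbs the
  features only transiently. Both properties are asserted in the tests;
  placing the weighting after the exponential would instead leave a
  fixed nonzero cepstral offset.
* **"Normalization" is read as per-utterance peak amplitude
  normalization**; no feature-space mean/variance normalization is
  applied anywhere.

The RASTA filter is the standard band-pass (numerator
0.2, 0.1, 0, −0.1, −0.2 over a 0.94 pole) run with zero initial state;
its transient means the first ~1–2 s of a recording carry
initialization effects, which is immaterial for utterance-mean scores
but is why the front-end tests assert steady-state behaviour on the
tail of the signal.

## Phonemic grouping

Alignments are read from Praat TextGrid interval tiers or CTM files.
Phone labels map to manner classes through an editable table whose
default covers the Spanish inventory (Quilis-style taxonomy): plosives
p t k b d g; fricatives f θ s ʂ x ʝ β ð ɣ; affricate tʃ; liquids l ʎ ɾ
r ř; nasals m n ɲ ŋ; vowels a e i o u plus the glides j w; silence and
pauses map to `other`. Two conventions deserve mention. The
spirantized approximants β ð ɣ are classed by their surface manner
(fricative) rather than their canonical phoneme (plosive), because the
grouping operates on acoustic segments; the table is user-replaceable
for the opposite convention. Glides are grouped with vowels, matching
their behaviour in diphthongs.

A frame belongs to a segment when its **center time** falls in the
half-open interval `[start, end)`. With 50 %-overlapped frames a
boundary frame necessarily contains material from two phones; the
center-time rule assigns every frame to exactly one phone, making the
class-wise frame subsets a partition of the utterance (asserted as a
property test); there is no consensus treatment of boundary frames, so
the unambiguous rule was chosen.

## GMM-UBM classification

A diagonal-covariance mixture with `G ∈ {4, 8, …, 256}` components is
fitted to pooled background frames by EM (`fit_gmm()`): seeded
k-means++ initialization with a short Lloyd refinement, then at most 25
iterations or a relative log-likelihood change below 1e-6. Variances
are floored at 1e-3 of the global per-dimension variance, which
prevents collapse on scarce groups (nasal frames can be rare) at the
cost of a formally non-monotone EM step; the per-iteration
log-likelihood trace is stored and tested non-decreasing to 1e-8.

Class models are Reynolds-style MAP adaptations of the UBM
(`map_adapt()`): with occupancies `n_g` from the UBM posteriors, each
mean moves to `α_g E_g[x] + (1 − α_g) μ_g`, `α_g = n_g/(n_g + r)`.
Means-only adaptation with relevance factor `r = 16` is the default,
following standard speaker-verification practice; there is no single
canonical choice here, so weight and variance adaptation are also
implemented and switchable via `map_config()`. Mixture
log-densities are evaluated in log-sum-exp form and stay finite for
any finite input.

## Scoring, calibration and decisions

An utterance's score under class `c` is the mean frame log-likelihood,
Λ_u^c = (1/N) Σ_n log p(x_n | Γ^c); the decision statistic is the
log-likelihood ratio Λ_u = Λ_u^PD − Λ_u^Ctrl. The threshold λ is placed at the equal-error-rate point of the
calibration scores — the per-utterance Λ_u of the *training-fold*
speakers scored against that fold's adapted models, the only reading
that leaks no test data. Where FPR and FNR have no exact crossing, λ is
the midpoint of the score interval minimizing |FPR − FNR| and the EER
is their average there; ties between intervals break toward the smaller
EER, then the lower threshold. Decisions use the strict rule: Λ_u > λ
accepts the PD hypothesis, a tie goes to control. Speaker scores are
the mean of the speaker's utterance LLRs — the natural aggregation,
and what fusion consumes. Metrics are reported at speaker level by
default, with utterance-level results also computed; fold decisions are
pooled into a single confusion matrix per cell rather than averaging
per-fold accuracies, which is more stable when folds hold only one or
two speakers per class.

Utterances left with zero frames after grouping are flagged
unscorable, excluded from metrics and counted, never silently scored.

## Fusion and metrics

Scores from 2–5 manner groupings sharing the same (F, G) are fused per
speaker with a logistic regression fitted by damped Newton/IRLS under a
small fixed ridge penalty (1e-4). The penalty exists to keep separable,
collinear or constant score tuples well-posed; it also penalizes the
intercept, which makes the fit exactly antisymmetric under a label
flip (a tested invariant). The fused score is the linear predictor
(log-odds), so downstream thresholding is unchanged. Accuracy is
reported in percent with a 95 % Wald binomial halfwidth
`1.96·√(p̂(1−p̂)/n)·100`; the Wald form is documented precisely so users
can substitute Wilson intervals if preferred. AUC is the Mann–Whitney
rank statistic with ties counted one half.

## Evaluation protocols

Cross-validation is speaker-disjoint and class-stratified: speakers are
shuffled within class (seeded) and dealt round-robin into 11 folds, and
an assertion inside the fold loop guarantees no speaker appears on both
sides. The four approaches differ only in where grouping is applied:
`baseline` nowhere, `raw_phon` on the adaptation/testing corpus,
`phon_phon` on both, `phon_raw` on the UBM corpus only — in which case
every test frame is scored and no segment of the adaptation-testing
material is discarded (the frame accounting for this is itself a test).
Cross-corpora validation pools two corpora for adaptation and
calibration and tests exclusively on the third, cycling through three
rounds. `select_best()` reproduces the grid-max reporting convention
(best accuracy, ties to AUC, then smaller G, then smaller F); being a
maximum over a grid it is optimistic, which is why the acceptance
quantities are reported for fixed (F, G) instead.

## The synthetic corpus generator

Real parkinsonian corpora are access-restricted, so the package ships a
generator (`sim_spec()` / `generate_corpus()`) that emulates their
structure: per-speaker utterances built from an ordered segment grammar
(a DDK-like plosive–vowel cycle, or a TDU-like cycle with fricatives,
nasals and liquids), manner-labelled alignment intervals that exactly
tile each utterance, and class-conditional emissions with a
controllable, class-localized patient effect.

In feature mode each manner class emits diagonal-Gaussian frames (one
per 7.5 ms hop) around a fixed class mean; speakers carry a random
offset (default sd 0.2 feature units) emulating inter-speaker
variability; the PD effect shifts the targeted class's mean along the
first feature dimension by `mean_shift` standard deviations and scales
its variance by `var_scale`. The default class means are a fixed,
seed-independent set, so corpora generated with different seeds are
draws from one population — the property cross-corpora experiments
require; the seed drives only the sampling, through a single RNG stream
consumed in fixed order (determinism is tested byte-for-byte through
the whole pipeline). Waveform mode synthesizes crude source-filter
segment templates (harmonic stacks for sonorants, differenced noise for
fricatives, closure-plus-burst for plosives) at 16 kHz, with the effect
injected as frication noise during the segment — a spirantization-like
degradation — and exists to exercise the DSP front-end end to end.

What the generator does **not** emulate bounds what passing tests
show: there is no prosody, no coarticulation beyond hard segment
boundaries, no alignment errors, no channel or recording variability,
no severity gradation, and the patient effect is a clean parametric
shift rather than the heterogeneous, speaker-dependent degradation of
real dysarthria. Green end-to-end tests therefore certify the
machinery — grouping, adaptation, calibration, protocol hygiene and the
effect-localization logic — not clinical performance on real speech.

## Problem sizes and numerical choices

The bundled experiments use feature-mode corpora of 20 + 20 speakers
with 5 utterances each (TDU-like grammar, dimension 10, G = 8, 11
folds) for cross-validation, three 10 + 10-speaker DDK-style corpora
for cross-corpora rounds, and a 15 + 15-speaker background corpus for
the UBM — sizes chosen to match the scale of the clinical corpora the
method targets while keeping a full run in the order of a minute.
Numerical guards worth knowing: band energies are floored at 1e-40
before the log, Levinson–Durbin returns zero coefficients for
non-positive zero-lag autocorrelation (silent frames), EM occupancies
are floored at 1e-10, MAP occupancies at 1e-300 (a component with no
posterior mass keeps its UBM parameters exactly), and model
serialization prints doubles with 17 significant digits for bit-exact
round-trips.

## Known limitations

The Rasta-PLP implementation follows the published recipe but no two
PLP implementations agree bit-for-bit (filterbank edges, FFT size,
RASTA initialization); the tests therefore cross-check against an
independently coded reference implementation rather than against an
external tool. Results on a given corpus depend on the MAP and EM
hyperparameters (`r`, schedule, initialization), so exact numeric
agreement between independent implementations of this kind of system
should not be expected even on identical data. The Wald interval is
anti-conservative for small n and accuracies near the boundary. The
fusion split in the acceptance script is a seeded split-half over
speakers; a fully nested per-fold fusion would be costlier and is left
to users who need it.
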