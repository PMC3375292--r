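---
title: "Measuring vocal signature information in vampire bat contact calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring vocal signature information in vampire bat contact calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

All three vampire bat species (*Desmodus rotundus*, *Diaemus youngi*,
*Diphylla ecaudata*) produce tonal, downward frequency-modulated contact
calls when isolated from group members. Because these species groom and
share food with specific partners, their contact calls are a natural
place to look for individual vocal signatures. Two complementary
questions arise:

1. **How much identity information does a call carry?** Quantified in
   bits per note, following Beecher's information analysis of animal
   signature systems.
2. **How reliably can a new note be assigned** to the right individual,
   colony, population, sex, or species? Quantified by cross-validated
   discriminant function analysis (DFA), with a permutation scheme
   (pDFA) wherever the factor of interest sits above a nested control
   factor, so that pseudo-replication from repeated notes of the same
   individual cannot inflate significance.

`batsig` implements the full chain — synthetic call generation,
spectrogram measurement, information analysis, discriminant tests — as
one seeded, testable pipeline. Real recordings of this kind are not
publicly deposited, so the package ships a generator that plays the role
of the recording session: every downstream stage is exercised against
data whose ground truth is known exactly.

## The synthetic call model

A note is synthesized as a sum of up to four partials. The fundamental
contour is a monotone piecewise-cubic (PCHIP) interpolant through anchor
points (relative position, frequency); monotone interpolation is used so
that perturbed anchors can never produce an upward bulge that would
violate the downward-sweep character of these calls (linear
interpolation is available as an option). Harmonic amplitudes are fixed
offsets in dB relative to the fundamental. The amplitude envelope uses
raised-cosine onset/offset ramps over the first and last 10% of the
note — real calls fade in and out, and an abrupt edge would smear
broadband energy across the spectrogram. Partials that would cross the
Nyquist frequency are muted exactly where they would alias, with a short
taper.

Species defaults reproduce the published per-species means: duration
(9.1 / 18.6 / 11.5 ms for *Desmodus* / *Diaemus* / *Diphylla*),
fundamental frequency at the start, 50% and 90% positions (e.g.
36.2 / 23.4 / 19.3 kHz for *Desmodus*), relative harmonic intensities
(harmonics dominate the fundamental in *Desmodus* and *Diphylla*, the
fundamental dominates in *Diaemus*), the note-count mixture (9% single /
75% double / 16% triple for *Diaemus*), and the 21.5 ms mean inter-note
interval. The published tables give no anchor at the very end of the
note (end frequencies were explicitly unreliable there), so the default
contour extends past the 90% point with a shallow 0.3 kHz terminal drop;
the terminal upturn implied by positive slopes at the 90% position is
deliberately not modeled.

Hierarchical variance enters as Gaussian random effects added to each
acoustic parameter: one draw per colony, one per individual, one per
note, with configurable standard deviations per parameter. Notes of one
call share the call's individual effect but receive independent note
effects. The Gaussian form is an assumption — the source material
reports no within-individual distributional shape — and it is the main
caveat on transferring conclusions to real recordings: real calls show
bimodality, drift across sessions, and amplitude-dependent structure
that this generator does not emulate. Passing tests therefore
demonstrate that the *measurement and inference chain* is correct, not
that real vampire bats carry any particular number of bits.

Default effect sizes (0.4 / 0.8 / 1.5 kHz colony / individual / note
standard deviations on contour frequencies, with proportional choices
for duration and harmonic intensity) put the repeatability of a single
measurement near 0.26, inside the 0.14–0.34 range reported for these
calls; they were chosen once, on that criterion, and are not tuned to
any downstream test. With these defaults wild and captive populations
share the same variance structure, so the real-data finding that wild
individuals are *more* distinct than captive ones is not built in — a
deliberate neutrality, since nothing is known about the mechanism.

## Spectrogram measurements

Spectrograms use 0.5 ms Blackman windows (125 samples at the 250 kHz
sampling rate) zero-padded to 512-point FFTs — 488 Hz bin spacing — with
50% overlap, matching the published measurement protocol. Each annotated
note yields exactly 36 measurements: duration (from the annotation
marks, as in hand labeling); fundamental frequency at the start and at
10–90% into the note; frequency of most energy (FME) and its time for
the fundamental and harmonics 1–3; slope and concavity of the
fundamental at 20–80% in 10% steps; and the intensity of harmonics 1–3
relative to the fundamental.

The fundamental tracker is necessarily an original design (the original
measurement program is not described internally): within a search band,
each frame's candidate is the **lowest-frequency local maximum within
20 dB of the frame's band maximum** — the fundamental is the lowest
partial but, in two of the three species, not the strongest — and the
track grows outward from the most confident frame under a continuity
constraint of at most 3 bins (≈1.5 kHz) per frame step, with 3-point
parabolic interpolation for sub-bin precision. The per-frame track is
resampled onto the 10-position grid by linear interpolation, with linear
extrapolation at the note edges (the first window is centered 0.25 ms
into the note, so position 0 is always a short extrapolation).

Harmonic bands are frame-local: partial *k* is searched in
`k·f0(t) ± f0(t)/2`, so the bands tile the spectrum without overlap.
Frames whose band would cross Nyquist are skipped for that partial; a
partial with no usable frame at all is reported missing and flagged.
Relative harmonic intensity compares band peak magnitudes; because both
partials are measured at their own FME — which settles in the
slow-sweeping part of the note where chirp smearing is negligible — the
round trip recovers configured offsets to well under 1 dB.

Slope at position *p* is the central difference of the track over
±10% of the duration; concavity is the second central difference. The
36-vector follows the measurement-table convention of slopes at 20–80%;
published per-species summaries also quote slopes at 10/50/90%, which
can be produced from the track but do not enter the standard vector.
Known accuracy behavior: mid-note frequencies are recovered to a small
fraction of a bin; the note start is the least accurate measurement
(steepest sweep, inside the onset ramp) — the same region described as
error-prone in hand measurement.

Selection rules mirror the study design: only first notes of calls, at
least 30 ms after any previous note; only unclipped notes with peak
amplitude in 10–99% of full scale; individuals contribute at least 45
notes (a 44-note individual is dropped, a 45-note individual kept).

## Information analysis

The number of components is chosen by parallel analysis: observed
correlation-matrix eigenvalues are compared with the 95th percentile of
eigenvalues from 1000 standard-normal datasets of identical shape
(O'Connor's defaults; a permutation null is available), counting from
the first component until the first failure. PCA is computed on the
correlation matrix — the 36 measurements mix ms, kHz, kHz/ms and dB, so
covariance PCA would be dominated by unit choices. The retained loadings
are varimax-rotated with Kaiser normalization, and per-note scores use
the Bartlett weighted-least-squares estimator with uniquenesses from the
rotated solution.

For each component, a random-intercept model with the declared nested
factors (species ⊃ colony ⊃ individual) is fitted by REML (`lme4`);
variance components are non-negative by construction and boundary
estimates are flagged as truncated. On balanced one-way designs the
REML estimate equals the classical ANOVA moment estimator
`(MS_between − MS_within)/n₀` whenever the latter is non-negative — the
package carries that closed form (`anova_vce()`) as an independent
cross-check, and the test suite enforces agreement to 1e-6.

Per component, the signature (between-signaler) variance `S_B²` is the
sum of the components of the declared signature factors — colony and
individual by default, so a species-level analysis does not count
species-typical structure as individual signature. With residual
(within-individual) variance `S_w²` and total `S_T² = S_B² + S_w²`:

* information: `H_i = log2(S_T / S_w)` — a ratio of standard deviations,
  equal to `½·log2(S_T²/S_w²)`; the source text writes the within
  variance with an inconsistent symbol at one point, read here as
  `S_w²`;
* total signature information: `H_s = Σ H_i` (valid because rotated
  components are near-orthogonal);
* repeatability: `r_i = S_B² / (S_B² + S_w²)`.

Factor-level percentage attribution weights each factor's per-component
variance share by the component's share of total variance, normalized so
factors plus residual sum to 100%.

One open design choice: when information is computed for a population
subset, components are re-extracted on the subset by default (reusing
globally extracted components is a flag), since the original procedure
does not state which was done.

## Discriminant tests

`lda_fit()` is a conventional linear DFA: equal priors, pooled
within-class covariance, per-class and overall rates for both
resubstitution ("training notes") and leave-one-out cross-validation
("testing notes"), Wilks' Λ = det(W)/det(T) on log scale (36×36 SSCP
determinants overflow otherwise), and Bartlett's approximation
`X² = −(n − 1 − (p+g)/2)·ln Λ` with `p(g−1)` degrees of freedom — the
specific χ² form chosen here, since only "a χ² approximation" is on
record. The structure matrix reports pooled within-group correlations of
each measurement with each discriminant score.

`pdfa()` handles nested data. Observed stage: an equal number of
training notes is drawn from every subject (`auto` = ⌊2/3 of the
smallest subject's count⌋), discriminant functions are fitted to
classify the *test factor*, held-out notes are classified, and rates are
averaged over `n_dfa_reps` redraws. Null stage: test-factor labels are
reshuffled over subjects (each subject's notes stay together; level
sizes are preserved) and the **identical** observed-stage procedure is
run per permutation — running the same statistic on observed and
permuted data is what makes the test exact under exchangeability, and
the type-I calibration test depends on it. The p-value is the proportion
of null rates at least as large as the observed rate, without the
+1/(N+1) correction (available by flag). Classification targets the test
factor directly, on raw measurements rather than PC scores — the
conventional reading of the original analyses, which used PCs only for
the information calculation.

The familywise error rate over the nine standard tests is controlled by
the Holm step-down correction (`stats::p.adjust`). Two scalar helpers
round out the published comparisons: a pooled two-sample t-test on
per-individual rates, and a χ²(1) outlier test
`(candidate − mean)²/variance` — the named test is uncited in the
source, so this squared-standardized-deviation form is a declared
assumption, and the printed value it accompanied is not reproducible
because its inputs were never printed.

## Numerical choices and degenerate inputs

* Time intervals are half-open `[start, end)`, seconds from recording
  start; relative positions are fractions of the annotated duration.
* A configuration whose perturbations cannot keep the sweep downward
  after 100 note-level redraws is rejected (variance too large for the
  profile) rather than silently clipped.
* SNR is defined as peak note power over broadband noise power; the
  default 30 dB leaves extraction within two bins of the noiseless
  case.
* If every class mean coincides (a degenerate fixture), the DFA reports
  Λ = 1 with chance-level predictions instead of failing inside the
  eigendecomposition.
* Variables collinear to machine precision abort the PCA with the
  offending columns named; the mild collinearity among slopes,
  concavities and contour frequencies is tolerated (the discriminant
  solver handles it, and the full 36-variable set is the documented
  protocol).
* Seeds: one global seed per run; stage seeds are derived modulo 2³¹
  so large user seeds cannot overflow R's integer range.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the same methods at sizes
chosen to exercise every code path with comfortable statistical margins:
variance-component recovery uses 50 signalers × 20 notes × 3 components
over 200 replicates (at fewer than ~30 signalers the O(1/g) Jensen bias
of the log-ratio estimator would be comparable to the Monte-Carlo
standard error and the comparison would measure bias, not correctness);
pDFA calibration uses 200 runs of 8 subjects × 12 notes with 200
permutations; the planted-effect power check uses 18 subjects in 3
groups, where the probability that a random subject permutation
reproduces the separating partition is ~3.5·10⁻⁷, so a zero p-value in
every run is the correct expectation. The demonstration pipeline runs
17 individuals × 50 calls.

## Known limitations

* The generator's Gaussian, session-free variance model understates the
  structure of real within-individual variation; absolute H_s values
  from synthetic runs are not comparable to published estimates from
  real recordings (which came from unavailable audio and are not
  reproducible by construction).
* FME-related measurements are emergent properties of the synthesized
  spectrum, not directly parameterized; the generator guarantees contour
  and harmonic-offset truth, nothing else.
* Wild and captive populations are statistically identical under the
  defaults, so analyses contrasting them serve as API demonstrations,
  not as recreations of the published contrast.
* Possible systematic differences of *Diaemus* second notes are exposed
  as an optional offset but default to none, there being no published
  parameterization.
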