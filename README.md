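# batsig

Vocal signature analysis of vampire bat contact calls.

When isolated, all three vampire bat species (*Desmodus rotundus*,
*Diaemus youngi*, *Diphylla ecaudata*) produce tonal, downward
frequency-modulated contact calls. `batsig` is for bioacousticians who
want to quantify how much identity information such calls carry and how
reliably new notes can be assigned to an individual, colony, population,
sex, or species — and for methodologists who want that whole chain
testable against data with known ground truth.

The package implements, end to end:

* **Synthetic call generation** — downward FM notes with up to three
  measured harmonics, species-typical parameter means, nested Gaussian
  random effects (colony ⊃ individual ⊃ note) on every acoustic
  parameter, single/double-note call structure with ~21.5 ms inter-note
  intervals, configurable SNR; written as 250 kHz 16-bit WAV plus an
  annotation CSV, or analyzed in memory.
* **Spectrogram measurement** — 0.5 ms Blackman windows zero-padded to
  512-point FFTs (488 Hz bins, 50% overlap); per note, the standard 36
  measurements: duration, fundamental frequency at 10 positions,
  frequency of most energy (FME) and its time for the fundamental and
  harmonics 1–3, slope and concavity at 20–80%, and relative harmonic
  intensities. Selection rules: first notes only, ≥30 ms from the
  previous note, unclipped (10–99% amplitude), ≥45 notes per individual.
* **Signature information capacity** — parallel analysis for component
  retention, correlation-matrix PCA with varimax rotation and Bartlett
  scores, REML variance components (`lme4`) per component, and Beecher's
  information statistic per component
  `H_i = log2(S_T/S_w)` with `S_T² = S_B² + S_w²`, summed to the total
  signature information `H_s = Σ H_i` (bits per note); repeatability
  `r_i = S_B²/(S_B² + S_w²)`; factor-weighted percentage variance
  attribution.
* **Discriminant tests** — conventional LDA with leave-one-out
  cross-validation, Wilks' Λ with Bartlett's χ² approximation, canonical
  structure matrices; permuted DFA (pDFA) for nested designs (test
  factor shuffled over subjects, each subject's notes held together);
  Holm correction; group-rate t-test and a χ² outlier test.

## Worked example

```r
library(batsig)

cfg <- run_config(notes_per_individual = 50, min_notes = 40,
                  tests = c(1, 5, 8), n_dfa_reps = 2,
                  n_permutations = 50, seed = 1)
report <- run_pipeline(cfg)
print(report)
```

```
<run_report>
  850 notes analyzed from 17 individuals (0 dropped by filters)
  4 PCs retained; H_s = 0.44 bits; mean repeatability 0.14
  variance attribution (%): species 48.0, colony 2.2, individual 6.6, residual 43.3
  test1: 100% of test notes correct, p = 0
  test5: LOO 58%, Wilks' lambda = 0.186, p = 2.57e-25
  test8: LOO 58%, Wilks' lambda = 0.0929, p = 4.46e-56
```

Reading this: the generator simulated four populations (captive and wild
*Desmodus*, captive *Diaemus*, wild *Diphylla*), synthesized and
measured every note, and kept 850 well-separated first notes. Parallel
analysis retained 4 varimax components; the REML variance decomposition
attributes ~48% of retained variance to species differences and ~7% to
individual identity, leaving individuals with `H_s ≈ 0.4` bits of
signature information per note at repeatability 0.14 — individual
signatures exist but most variance is within-individual, which is
exactly the structure the generator was configured to produce. Species
assignment controlling for individual (test 1, pDFA) is perfect with a
permutation p of 0; individual assignment within the captive *Desmodus*
colony (test 5) classifies 58% of held-out notes against a 25% chance
rate, and within captive *Diaemus* (test 8) 58% against ~17% chance
here.

The scripts under `analysis/` run the same stages as a narrative
workflow — `01_simulate_dataset.R` (writes WAV + annotations under
`scratch/`, summary under `results/`), `02_extract_features.R`,
`03_signature_information.R`, `04_discriminant_tests.R` — each printing
what it found and writing its tables under `results/`.

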