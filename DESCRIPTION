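Package: batsig
Title: Vocal Signature Analysis of Vampire Bat Contact Calls
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying individual, colony, population and species
    vocal signatures in the downward frequency-modulated contact calls of
    vampire bats (Desmodus rotundus, Diaemus youngi, Diphylla ecaudata).
    Simulates annotated call recordings with a nested (species/colony/
    individual) variance structure, extracts the standard 36 spectrogram
    measurements per note (fundamental contour, slopes, concavities,
    frequencies and times of maximum energy, relative harmonic intensities),
    estimates Beecher signature information capacity in bits via parallel
    analysis, varimax-rotated principal components with Bartlett scores and
    REML variance components, and tests signature strength with conventional
    leave-one-out discriminant function analysis and permuted DFA for nested
    designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    lme4,
    signal,
    pracma,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
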