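Package: mannergmm
Title: Manner-of-Articulation Grouped GMM-UBM Detection of Parkinsonian Speech
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects Parkinson's disease from speech with a GMM-UBM
    (Gaussian mixture model / universal background model) classifier built
    on Rasta-PLP cepstral features and phonemic grouping: frames are
    selected by the manner of articulation (plosive, fricative, liquid,
    nasal, vowel) of their force-aligned phone. Provides the acoustic
    front-end (16 kHz normalisation, Rasta-PLP with delta and delta-delta
    coefficients), Praat TextGrid and CTM alignment readers, a
    phone-to-manner mapping, diagonal-covariance GMM estimation with MAP
    adaptation, log-likelihood-ratio scoring with equal-error-rate
    threshold calibration, logistic-regression score fusion, evaluation
    metrics, speaker-disjoint cross-validation and cross-corpora
    protocols, and a seeded synthetic-corpus generator for end-to-end
    experiments when clinical corpora are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
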