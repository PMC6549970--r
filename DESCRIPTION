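Package: songvar
Title: Population-Level Song Variability from Repertoire Kullback-Leibler Divergence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying population-level variability of learned
    birdsong. Extracts frame-wise acoustic features (amplitude, pitch, mean
    frequency, frequency and amplitude modulation, Wiener entropy, pitch
    goodness) from mono WAV recordings, segments songs into syllables,
    removes cage noise by a minimum-duration rule and trimmed k-means
    clustering, measures dissimilarity between birds' syllable repertoires as
    the Kullback-Leibler divergence between two-dimensional feature
    densities, and summarizes per-parameter divergences with principal
    components and penalized linear mixed models (population fixed effect,
    template and target bird random effects). Includes a synthetic song
    generator with known ground truth for end-to-end validation and a
    manifest-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    lme4,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
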