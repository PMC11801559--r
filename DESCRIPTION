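Package: radenhance
Title: Two-Stage Contrast and Sharpness Enhancement for Radiographs
Version: 0.1.0
Authors@R:
    person("radenhance", "maintainers", email = "radenhance@example.org",
           role = c("aut", "cre"))
Description: Enhancement of low-contrast grayscale radiographs (e.g. shoulder
    X-rays) in two stages: a tissue-attenuation contrast stage that estimates
    and subtracts a "removable" high-attenuation component from local
    intensity extrema before stretching the dynamic range, followed by an
    interval type-II fuzzy-set sharpening stage that fuses upper and lower
    membership bounds with a variance-parameterised Hamacher t-conorm and a
    max-preserving gamma correction. Includes formula-based no-reference
    quality metrics (average gradient, information entropy) with a pluggable
    registry for external learned metrics, a seeded synthetic radiograph
    phantom generator for download-free testing, and a command-line pipeline
    with ablation and batch modes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jpeg,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
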