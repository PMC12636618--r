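Package: percept
Title: Stimulus-Computable Perceptual Uncertainty via Mixture Density Readouts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for modeling perceptual uncertainty directly from auditory
    stimuli. Implements mixture density network readouts trained by maximum
    likelihood (von Mises mixtures over sound-source azimuth and elevation;
    Gaussian mixtures over log fundamental frequency), a gammatone-filterbank
    cochleagram front end, posterior summaries used as model confidence
    (Monte Carlo MAP estimates, highest-posterior-density interval widths,
    front/back entropy, mode-local posterior variance), an inverse-CDF mapping
    from uncertainty to discrete post-decision wagers, seeded synthetic
    stimulus generators (tones, noises, harmonic complexes, toy binaural
    scenes), virtual psychophysical experiments, and the psychometric
    statistics used to analyze them (absolute error, MAD precision, d-prime,
    cumulative-normal threshold fits, bootstrap confidence intervals, and
    attenuation-corrected correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    signal,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
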