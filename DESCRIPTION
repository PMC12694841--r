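Package: blinkr
Title: Spontaneous Eye-Blink Biomarkers from the Vertical Electrooculogram
Version: 0.1.0
Authors@R:
    person("blinkr", "maintainers", email = "blinkr@example.org",
           role = c("aut", "cre"))
Description: Extracts spontaneous eye blinks from vertical electrooculogram
    (VEOG) recordings and turns them into four per-segment indices: blink
    rate (BR, blinks per minute), blink amplitude (BA, mean peak voltage in
    microvolts), and their coefficients of variation (BRV over inter-blink
    intervals, BAV over peak amplitudes). Provides signal ingest from EDF or
    delimited text, bipolar derivation, zero-phase Butterworth band-pass
    filtering (0.5-20 Hz), thresholded peak detection with a refractory
    interval (100 microvolt / 250 ms defaults), segment-wise metric
    computation, a ground-truthed synthetic VEOG and cohort generator
    (gamma-renewal blink timing, lognormal amplitudes, Gaussian-copula
    subject-level structure), and the statistical layer used in anxiety
    biomarker studies: Pearson correlation matrices, random-intercept linear
    mixed models with Satterthwaite denominator degrees of freedom and
    marginal R-squared, Sobel and bootstrap mediation tests, and Welch's t.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lme4,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
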