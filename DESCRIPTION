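Package: hrvbal
Title: Heart Rate Variability Preprocessing and Bidimensional
    Autonomic-Balance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing beat-to-beat (RR) interval recordings
    collected across stress/recovery protocols: artifact detection and
    correction with adaptive quartile-deviation thresholds, smoothness-priors
    detrending, 4 Hz cubic-spline resampling, Welch spectral estimation with
    LF/HF band integration, and a bidimensional autonomic-balance analysis
    built on the combined oscillatory power LHFP = LF + HF and the bounded
    normalized-difference index LHFND = (LF - HF)/(LF + HF). Includes an
    integral-pulse-frequency-modulation (IPFM) simulator for three-phase RR
    recordings with ground-truth artifacts, a latent two-factor jury-rating
    simulator, and a statistics layer (repeated-measures ANOVA with Pillai's
    trace, Greenhouse-Geisser correction and covariate-adjusted pairwise
    contrasts; varimax PCA; exact one-dimensional two-cluster K-means;
    paired t, chi-square and correlation utilities).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
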