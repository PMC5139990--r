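Package: robustbg
Title: Robust Generalized Linear Model Background Estimation for
    Diffraction Shoeboxes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation of the X-ray background under Bragg reflection
    shoeboxes from photon-counting detectors.  Implements a robust
    Poisson generalized linear model with a Huber-weighted
    quasi-likelihood score and Fisher-consistency correction, solved by
    iteratively reweighted least squares, for constant and log-planar
    background models.  Also provides the traditional outlier-rejection
    strategies used by integration programs (truncation, sigma clipping,
    Tukey fences, plane fitting with rejection, and a normality-based
    iterative trim), a synthetic shoebox simulator with ground truth
    (Poisson backgrounds, peaks, hot pixels and zingers), and diagnostic
    analyses: truncated-mean bias, normalized background differences,
    index-of-dispersion outlier selection, Poisson median-bound checks
    and zero-background pathology rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
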