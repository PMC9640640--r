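Package: alcorrect
Title: Axial-Length Correction and Lens-Constant Calibration for IOL Power
    Formulas
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying systematic axial-length (AL) measurement
    bias in optical biometry and its effect on intraocular lens (IOL)
    power calculation. Implements the published thin-lens vergence
    formulas (SRK/T, Hoffer Q, Holladay 1, and the AL-switched Combo
    method), retrospective refractive prediction-error back-calculation,
    lens-constant optimization by mean-error zeroing, a linear
    axial-length correction (ALc) regression, the accompanying
    statistical protocol (exact Kolmogorov-Smirnov normality, paired and
    one-sample t-tests, Friedman test with Bonferroni post-hoc,
    Bland-Altman agreement, noncentral-t paired sample-size
    calculation), and a synthetic biometry cohort generator emulating
    the phakic, aphakic and pseudophakic measurement modes of a partial
    coherence interferometry biometer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), nortest, jsonlite
Config/testthat/edition: 3
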