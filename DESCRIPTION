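Package: tanninspec
Title: NIR Spectral Calibration of Walnut Kernel Tannin with Wavelet
    Features and Interpretable Random Forests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A chemometrics workflow for calibrating tannin content
    (mg/g) of walnut kernels against near-infrared reflectance spectra
    (4000-10000 cm-1). Provides a synthetic spectra generator that
    emulates the statistical structure of kernel reflectance under
    different orchard management modes, a bank of derivative and
    logarithmic spectral transforms, continuous wavelet decomposition
    with a gaus4 mother wavelet at dyadic scales, Pearson-correlation
    characteristic-band selection, Monte-Carlo cross-validation outlier
    screening built on a NIPALS partial least squares core, random
    forest calibration evaluated by R2/RMSE/RPD, and Shapley-value
    feature attribution with an exact enumeration oracle.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
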