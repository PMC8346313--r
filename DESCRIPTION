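Package: echoenhance
Title: Convolutional Enhancement and Rule-Based Diagnosis for Cardiac Ultrasound Images
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A three-stage convolutional network for speckle denoising of
    grayscale cardiac ultrasound images, trained by mini-batch stochastic
    gradient descent on a pixel mean-squared-error loss, with an optional
    semi-supervised discriminator objective built from numerically stable
    log-sum-exp losses. Includes peak signal-to-noise ratio (PSNR) and
    structural similarity (SSIM) image-quality scoring, a synthetic
    cardiac-phantom and patient-cohort generator for fully reproducible
    testing, and rule-based positivity criteria for chronic heart failure
    echocardiographic indices and AWGS sarcopenia, together with
    diagnostic concordance arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
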