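Package: fusbmi
Title: Closed-Loop Functional Ultrasound Brain-Machine Interface Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and decoding closed-loop functional
    ultrasound (fUS) brain-machine interface sessions. Provides a synthetic
    power-Doppler session generator with direction-tuned hemodynamic
    responses, streaming preprocessing (rolling voxel-wise z-score and
    pillbox spatial smoothing), class-wise PCA + LDA two-class decoders and
    an eight-direction multicoder, the online training and retraining
    protocol with cross-session pretraining, rigid intensity-based image
    alignment, cumulative-accuracy and angular-error performance traces with
    binomial and permutation chance envelopes, and searchlight information
    mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    MASS,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
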