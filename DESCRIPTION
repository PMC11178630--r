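Package: biopsyplan
Title: Simulation and Learning of Targeted Transperineal Prostate Biopsy
    Sampling Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An episodic simulator of targeted transperineal template-guided
    prostate biopsy over 3D binary gland and lesion masks, together with the
    machinery to learn needle sampling strategies in it. Provides a synthetic
    phantom generator and NIfTI mask input/output, a 13x13 brachytherapy
    template grid with needle rasterization, a Markov decision process
    environment with integer clinical rewards, simulation of intra-procedure
    mismatch (rigid target registration error and Gaussian-spline free-form
    deformation), two clinically motivated expert sampling policies,
    behavioural cloning and proximal policy optimisation for training policy
    networks, and clinical biopsy outcome metrics (hit rate, cancer core
    length, normalised core length, needle coverage and the core-length
    correlation coefficient) with paired statistical comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
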