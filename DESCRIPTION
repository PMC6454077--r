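Package: ctmpi
Title: Temporal Sampling Bias in Dynamic CT Myocardial Perfusion Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates dynamic contrast-enhanced CT myocardial perfusion
    acquisitions of an ex-vivo perfused heart and quantifies how the temporal
    sampling rate of the scan mode biases maximum-upslope myocardial blood
    flow (MBF) estimates. Provides a gamma-variate arterial input function
    generator, a one-compartment tissue kinetics model with extraction
    fraction, ECG-triggered shuttle / non-shuttle and continuous acquisition
    timing models, maximum-upslope and Patlak K1 estimators with the
    extraction-fraction flow correction F = K1/E, a synthetic 4D short-axis
    image phantom with AHA 16-segment labels, and a factorial experiment
    driver with median/IQR summaries, paired scan-mode contrasts and
    flow-MBF correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    RNifti
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'aif.R'
    'tissue.R'
    'phantom.R'
    'sampling.R'
    'estimators.R'
    'patlak.R'
    'phantom-image.R'
    'config.R'
    'io.R'
    'experiment.R'
    'summary.R'
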