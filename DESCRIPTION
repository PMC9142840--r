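Package: nloiquant
Title: Quantitative Analysis of Multimodal Nonlinear Optical Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying label-free multimodal nonlinear optical
    imaging (NLOI) data combining two- and three-photon autofluorescence
    (2PF, 3PF) with second- and third-harmonic generation (SHG, THG).
    Implements Fourier-domain collagen fiber orientation analysis of SHG
    images with an alignment-ratio statistic, pixel-wise optical redox
    ratio (ORR = 2PF/(2PF + 3PF)) metabolic profiling under segmentation
    masks, per-channel intensity profiling, and longitudinal analysis of
    tissue degradation and drug response (intensity decay, lateral drift,
    ORR trajectories). A synthetic multichannel scene generator with known
    ground truth (fiber orientations, per-cell redox ratios, decay rates,
    drift, drug-response profiles) supports validation and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    tools,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    tiff,
    png,
    EBImage,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
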