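Package: fluxdry
Title: Disentangling Soil and Atmospheric Dryness Effects on Ecosystem Photosynthesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to separate the sensitivities of ecosystem gross primary
    production (GPP) and its stomatal and biochemical components to soil
    water content (SWC) versus vapor pressure deficit (VPD) from
    eddy-covariance flux-tower records. Includes a synthetic multi-site
    flux-tower simulator with an analytically differentiable GPP response
    surface (ground truth for validation), FLUXNET2015-dialect CSV input
    and output, quality-control and growing-season filters, big-leaf
    Penman-Monteith inversion of canopy conductance, windowed
    light-response-curve fits of maximum assimilation rate, Farquhar
    inversion of maximum carboxylation rate with Bernacchi kinetics,
    standardized multiple regression, feed-forward neural-network
    perturbation sensitivities aggregated on 10 x 10 percentile bins of SWC
    and VPD, a conditional SWC/VPD decomposition with radiation
    normalization, and variant-comparison uncertainty grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    data.table,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nnet,
    mgcv
Config/testthat/edition: 3
RoxygenNote: 7.3.3
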