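Package: idasense
Title: Indicator Displacement Assay Modelling and Chemosensor Array Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models competitive host-guest binding equilibria underlying
    indicator displacement assays (IDA), with a focus on boronic acid /
    catechol dye / saccharide systems. Provides an exact speciation solver
    for the three-component 1:1 equilibrium, nonlinear least-squares
    estimation of indicator and guest binding constants from UV-vis
    titration isotherms, a synthetic-data generator emulating a 384-well
    cross-reactive colorimetric array (four dye channels, replicate noise,
    injected outliers), and the chemometric pipeline used to read such
    arrays: studentized outlier exclusion, per-channel ANOVA contribution,
    linear discriminant analysis with leave-one-out jackknife validation,
    and PCA plus support-vector regression for quantifying binary sugar
    mixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
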