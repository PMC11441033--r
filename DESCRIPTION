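Package: aortaflow
Title: Ascending Aortic Haemodynamics from 4D Flow Velocity Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies ascending-aortic haemodynamics from time-resolved
    three-dimensional velocity fields of the kind produced by 4D flow cardiac
    magnetic resonance. Computes wall shear stress (WSS) by near-wall velocity
    fitting, time-averaged WSS, the oscillatory shear index, axial and
    circumferential WSS components, and normalized flow displacement in seven
    equidistant analysis planes between the aortic valve and the
    brachiocephalic trunk. Includes synthetic flow phantoms with analytically
    known wall shear stress, a synthetic cohort generator with planted group
    differences and rank correlations, and the downstream case-control and
    biomarker-correlation statistics (Kolmogorov-Smirnov-gated Student t or
    Mann-Whitney tests, Pearson or Spearman correlation, Fisher's exact test,
    and Benjamini-Hochberg false-discovery-rate control).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    igraph,
    nortest,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
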