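Package: octaquant
Title: Quantitative Microvascular Analysis of En-Face OCT Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the retinal microvasculature in en-face optical
    coherence tomography angiography (OCTA) images. Angiograms are binarized
    and skeletonized, and four parameters are computed per image: box-counting
    fractal dimension (FD), vessel density (VD), skeletal density (SD), and
    vessel diameter index (VDI). A synthetic angiogram generator produces
    healthy, branch-occlusion and central-occlusion capillary networks with
    ground truth, and a cohort simulator produces eye-level tables with
    between-eye correlation. Cohort statistics include Gaussian generalized
    estimating equations with exchangeable working correlation and robust
    sandwich covariance, Pan's QIC, the Jonckheere-Terpstra ordered trend
    test with tie correction and permutation option, point-biserial
    correlation, and Snellen-to-logMAR acuity conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    stats,
    tiff,
    png,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
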