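Package: polarQuant
Title: Quantification of Reversible Perfusion Defects on Myocardial Polar Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying reversible (ischemic) perfusion defects on
    myocardial-perfusion SPECT polar maps (bullseye plots). Provides the polar
    sampling geometry with area weights and a 17-segment anatomical model;
    two-stage automatic defect delineation (stress defects by seeded active
    contours of circular topology, then strictly reversible sub-regions by
    smoothing and thresholding of the rest-stress difference image); defect
    extent as percent of the left ventricle and 17-segment summed difference
    scores (SDS, SD%); a synthetic-study generator with parametric ground-truth
    defects and multi-rater extent panels; and the observer-agreement layer:
    two-way random-effects intraclass correlation with F-based confidence
    intervals, between-observer standard deviation from variance components,
    Bland-Altman limits of agreement, exact Wilcoxon signed-rank tests, and
    balanced-design method contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, jsonlite, withr, png
Suggests: testthat (>= 3.0.0), lme4, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'polar-core.R'
    'segment-model.R'
    'synthetic-data.R'
    'delineation.R'
    'quantify.R'
    'agreement.R'
    'io.R'
    'cli.R'
    'table1.R'
    'polarQuant-package.R'
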