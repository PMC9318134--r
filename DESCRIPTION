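Package: ihcquant
Title: Manual and Digital Quantification of Immunostained Tissue Area
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the stained-area fraction of immunohistochemistry
    (IHC) images by two routes: stereological point counting on a
    systematic sampling grid (default 594 points) and color-range pixel
    selection seeded on sampled stain colors with a fuzziness tolerance.
    Includes a synthetic IHC image generator with exact ground-truth
    masks in clean ("GOOD") and noisy-background ("NOISE") regimes,
    method-agreement statistics (one-way intraclass correlation with
    Fleiss-style classification, Bland-Altman limits of agreement,
    Pearson correlation), cohort-comparison statistics (D'Agostino-
    Pearson normality, Mann-Whitney, Wilcoxon signed-rank), and a study
    runner that replays a full two-observer, two-timepoint agreement
    design on synthetic fields.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
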