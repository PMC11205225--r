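Package: conemosaic
Title: Foveal Cone Mosaic Density Metrics and Intervisit Reproducibility
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the foveal cone photoreceptor mosaic from cone
    coordinate lists derived from adaptive optics scanning light
    ophthalmoscope (AOSLO) images. Builds Voronoi-bounded adaptive-window
    density matrices, extracts peak cone density (PCD), the cone density
    centroid (CDC), the 80th-percentile isodensity contour area and the
    PCD-CDC offset, aligns two visits at their CDC locations to form
    difference maps and binned cross-section profiles, and runs cohort
    reproducibility statistics (percent change, Shapiro-Wilk, paired t,
    Pearson with Fisher-z intervals, Bland-Altman limits of agreement).
    Includes a synthetic foveal mosaic generator with a revisit model so
    the whole pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
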