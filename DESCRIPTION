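Package: vacuoquant
Title: Quantification of Hepatocyte Vacuolar Degeneration in H&E Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Digital analysis of vacuolar degeneration in hematoxylin-eosin
    stained liver micrographs. Segments white lesion regions by per-channel
    Otsu thresholding with logical channel fusion and small-object removal,
    computes per-region shape descriptors (area, perimeter, major axis
    length, eccentricity, circularity) and per-image predictor vectors,
    compares group-level region distributions (pooled estimators,
    Anderson-Darling normality, two-sample Kolmogorov-Smirnov), and runs an
    exhaustive linear-discriminant search over all non-empty predictor
    subsets in five classification schemes with Pareto reporting. Includes a
    seeded synthetic-histology generator with planted elliptical vacuoles
    and ground truth, so the full pipeline is testable without source
    slides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    png,
    yaml,
    jsonlite,
    nortest
Suggests:
    testthat (>= 3.0.0),
    MASS,
    EBImage,
    optparse
Config/testthat/edition: 3
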