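Package: pmscore
Title: Quantitative Edge-Irregularity Analysis of Parenchymal Organ Margins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the nodularity of a parenchymal organ border on 2D
    grayscale (CT-like) images. Inside a fixed-size region of interest the
    border is extracted with a Canny edge detector, a low-flexibility
    least-squares cubic spline ("average boundary line") is fitted along the
    border's principal axis, and the pancreatic margin score (PMS) is the
    root-mean-square deviation of the border from that line, in pixels.
    Includes a synthetic two-phase phantom generator with exactly known border
    roughness for validation, batch scoring over paired region manifests, and
    the accompanying statistics layer: paired t-test, ROC curve with AUROC,
    and Youden-optimal threshold selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
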