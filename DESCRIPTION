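Package: pvq
Title: Vascular Pulsatility and Perivascular Clearance Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for studies of vascular pulsation and
    perivascular clearance in the mouse brain. Extracts vessel diameter
    traces from two-photon line-scan kymographs and computes absolute and
    relative vascular-wall pulsatility indices over 3000-ms epochs;
    measures mask-based immunofluorescence metrics (smooth-muscle and
    amyloid coverage of vessel walls, collagen-IV vascular density,
    parenchymal plaque burden, line intensity profiles); maps tracer-based
    clearance read-outs (periarterial drainage artery counts, whole-slice
    CSF-influx signal, penetrating-vessel counts, dorsal/lateral/ventral
    regional analysis with cortical linearization); and fits the
    amyloid-burden versus influx regression. A synthetic-data module
    generates ground-truth-annotated kymographs, slice images and regional
    tables so every stage is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    stats,
    tiff,
    yaml,
    jsonlite,
    tools,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
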