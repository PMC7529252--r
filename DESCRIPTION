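Package: meioconj
Title: Segregation Models and Assays for Alternative Homolog Conjunction in
    Drosophila Male Meiosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact enumeration and Monte Carlo simulation of chromosome
    transmission through the two meiotic divisions of Drosophila males under
    configurable homolog-conjunction scenarios, together with the assays used
    to test such models: classification and aggregation of per-nucleus
    X/Y FISH signal counts (including the 0/RG diagnostic ratio for meiosis II
    sister segregation), quantification of DNA-content variability in
    spermatid cysts from fluorescence images (local-mean thresholding,
    watershed splitting, size/circularity particle filtering), normalization
    of single-dot intensity time courses, and scanning of protein sequences
    for the separase cleavage consensus [E/D]XXR and the [L/V/I/M]PE docking
    motif with in-silico non-cleavable mutations and alignment-based
    conservation scoring. Seeded synthetic-data generators produce FISH count
    tables, cyst images with ground truth, motif-planted protein sets and
    intensity traces for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    EBImage,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
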