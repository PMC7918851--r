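Package: cafsens
Title: Quantifying Fibroblast-Modulated Cisplatin Sensitivity in Head and
    Neck Cancer Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for coculture clonogenic assays of head and
    neck squamous cell carcinoma (HNSCC) cells with patient-derived
    cancer-associated fibroblasts (CAFs). Segments trypan-blue-stained
    colonies from plate images by CIELAB b-channel thresholding and computes
    covered-area fractions; derives a log2 "sensitizing ratio" contrasting
    cisplatin response under coculture against non-cocultured controls;
    computes relative gene expression by the comparative Ct method with dual
    housekeeping genes and a pairwise per-CAF baseline; closes the platinum
    mass balance from ICP-MS concentration readings to estimate cisplatin
    uptake and efflux; and provides the statistical layer (t-tests, Pearson
    expression-phenotype correlation, two-component PCA, hierarchical
    clustering, isotype-gated CD90 positivity). A synthetic-data generator
    with known ground truth (planted colony masks, planted log2 fold
    changes, planted uptake fractions) makes every stage testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    stats,
    utils,
    tools,
    png,
    withr,
    jsonlite
Suggests:
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
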