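Package: immunosen
Title: Immunosenescence Markers from qPCR and CDR3 Spectratyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies immunosenescence markers in cohort studies of
    HIV-infected young adults and healthy controls: thymic and bone marrow
    output from TREC/KREC duplex real-time PCR (standard-curve fitting,
    efficiency, triplicate quality control, copies per ml of blood), relative
    telomere length as the monochrome-multiplex qPCR T/S ratio, and T-cell
    receptor beta-chain repertoire diversity from CDR3 spectratype peak
    tables (four-category clonality classification and generalized Hamming
    distance perturbation scoring against a healthy-control reference with
    mean+2SD/mean+3SD flagging). Includes a synthetic cohort generator with
    known ground truth that emulates the study design (group structure,
    category mixes, telomere shift, copula-induced clinical correlations) and
    the nonparametric statistical layer (Kruskal-Wallis with Dunn post-hoc,
    Pearson correlations, Table-1 style summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    patchwork
Config/testthat/edition: 3
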