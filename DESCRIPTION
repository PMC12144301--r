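Package: ubistoich
Title: Stoichiometry-Resolved Analysis of Protein Ubiquitylation
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of post-translational modification (PTM)
    sites, centred on lysine ubiquitylation (K-epsilon-GG remnant) profiling
    of two-group designs such as young versus old brain. Implements
    protein-abundance correction of modified-peptide quantities (per-condition
    median correction factors, multi-protein summing), plain and
    empirical-Bayes moderated two-sample statistics with Benjamini-Hochberg
    and Storey q-value multiplicity control, TMT PSM filtering and median
    summarization into protein quantities, cross-species PTM-site liftover by
    optimal local alignment with a lysine-conservation call, intervention
    response classification of matched contrasts, AQUA spike-in absolute
    quantification of ubiquitin-chain linkages with the derived polyubiquitin
    fraction, and rank-based gene-set enrichment (weighted Kolmogorov-Smirnov
    with permutation normalization) plus hypergeometric over-representation.
    A synthetic-data module generates every input format with recorded ground
    truth so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, DifferentialExpression, Software
RoxygenNote: 7.3.3
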