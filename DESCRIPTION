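Package: rbpshift
Title: Multi-Omic Analysis of Perturbed RNA-Binding-Protein Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how a small-molecule inhibitor of an
    RNA-binding protein rewires its target landscape across omics layers.
    Implements input-normalised eCLIP peak significance calling,
    differential-binding-peak (DBP) detection by two-way ANOVA interaction
    testing on RPM-normalised cluster counts, gene-level aggregation of
    binding changes, RNA-seq differential expression with a
    baseMean-dependent fold-change filter, permutation-FDR testing of
    label-free proteomics intensities, Boltzmann melt-curve (CETSA) fitting
    with melting-temperature confidence intervals, and cross-omic
    concordance and over-representation analysis. A synthetic-data module
    generates every input with planted ground truth so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    DESeq2
Config/testthat/edition: 3
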