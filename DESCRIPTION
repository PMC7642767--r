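Package: cytokmer
Title: Genome Size Estimation from Flow Cytometry and K-Mer Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating nuclear DNA content (C-values) of insects
    and other eukaryotes. Implements internal-standard calibrated genome size
    estimation from flow cytometry fluorescence histograms (Gaussian peak
    fitting, peak classification, CV-based quality control, replicate
    aggregation), canonical k-mer counting and spectrum-based estimation of
    genome size, repeat content and heterozygosity, an internal-standard
    registry with suitability ranges and selection logic, classical group
    comparisons (pooled t, one-way ANOVA, Tukey HSD), and phylogenetic signal
    statistics (Pagel's lambda by maximum likelihood, Blomberg's K with a
    permutation test) for C-value evolution on a tree. Synthetic-data
    generators for fluorescence events, k-mer spectra, sequencing reads and
    Brownian-motion traits on birth-process trees make every stage testable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    withr,
    Rcpp,
    jsonlite,
    yaml,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phytools
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
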