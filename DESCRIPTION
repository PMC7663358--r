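Package: toxsig
Title: Common Toxicant-Induced Metabolic Signatures from Transcriptomics,
    Metabolomics and Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying metabolic signatures shared across
    hepatotoxicant exposures. Implements differential statistics for plasma
    metabolite tables (minimum-value imputation, Welch t-tests,
    Benjamini-Hochberg FDR), cross-condition concordance analysis of log
    fold-change profiles (Pearson correlation, average-linkage hierarchical
    clustering), aggregated fold-change (AFC) pathway scoring and absolute
    aggregated fold-change (AAFC) injury-module activation with permutation
    z-scores, and TIMBR-style metabolite production scoring on a
    gene-protein-reaction annotated stoichiometric network via weighted
    flux-minimization linear programs, optionally constrained by metabolic
    flux analysis estimates. A synthetic-data generator produces toy networks
    and omics/flux datasets with known ground truth so the full pipeline can
    be exercised and benchmarked end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
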