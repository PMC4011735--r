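Package: tagdge
Title: Tag-Based Digital Gene Expression Analysis with Synthetic Truth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis of NlaIII/MmeI tag-based digital gene
    expression (DGE) libraries of the kind used for silkworm hemocyte
    transcriptome profiling. Provides a synthetic-data generator with planted
    fold-change truth, CATG+17 reference tag-library construction, clean-tag
    filtering, tag-to-gene mapping with at most one mismatch, RPKM
    quantification, an exact conditional test of equal expression between two
    libraries with Benjamini-Hochberg FDR and fold-change calling,
    hypergeometric term enrichment with Bonferroni or Q-value correction,
    sequencing-saturation and gene-body coverage QC, and 2^-ddCt qPCR
    relative-quantification with DGE concordance reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
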