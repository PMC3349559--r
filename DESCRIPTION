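Package: tagdge
Title: Tag-Based Digital Gene Expression Analysis with the Audic-Claverie Exact Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for SAGE-style digital gene expression (DGE) profiling:
    extraction of NlaIII/MmeI 21-bp reference tags from assembled unigenes,
    raw tag cleaning with a full read-accounting ledger, bounded-mismatch
    tag mapping, tags-per-million and RPKM normalisation, the
    Audic-Claverie exact test with Benjamini-Hochberg FDR control across
    staged multi-library comparison designs, intersection and extreme-ratio
    screening, trend clustering, hypergeometric GO/KO term enrichment with
    Bonferroni correction, and a seeded synthetic-data generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
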