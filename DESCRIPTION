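Package: hccmine
Title: Literature Mining of Hepatocellular Carcinoma Metastasis Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible text-mining pipeline for the hepatocellular
    carcinoma (HCC) metastasis literature. Parses MEDLINE flat-file abstract
    corpora, recognizes gene mentions by dictionary matching against an
    alias lexicon, counts sentence-level gene frequencies and gene-phenotype
    co-occurrences, partitions gene sets between etiology arms (HBV vs HCV)
    with corpus-size normalization, performs hypergeometric gene-set
    over-representation analysis, builds the induced experimental
    protein-protein interaction network with degree ranking, and clusters
    the co-occurrence matrix by complete-linkage hierarchical clustering.
    Seeded synthetic-data generators with machine-readable ground truth
    support end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
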