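Package: pathlink
Title: Phenotype-Pathway Clustering and Shared-Pathway Disease Networks
    from GWAS Summaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether the genes implicated by a phenotype's
    genome-wide-association (GWAS) SNPs cluster into curated pathways more
    than expected by chance. SNP associations are mapped to genes, each
    phenotype-pathway pair is scored by the number of phenotype genes in
    the pathway, and significance is assessed against a pooled empirical
    null built by repeatedly drawing random gene sets of the same size
    from the pathway universe. A nested pseudo-phenotype simulation
    calibrates the number of significant associations expected genome-wide
    under the null, and phenotypes sharing significant pathways are joined
    into weighted disease-disease networks. Includes a synthetic-data
    generator (pathway databases, gene annotations, GWAS-catalog-style
    tables with planted signal) so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    yaml,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite,
    optparse
Config/testthat/edition: 3
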