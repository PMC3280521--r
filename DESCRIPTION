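Package: nudiannot
Title: Annotation and Comparative Genomics of Circular dsDNA Insect Virus Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating circular double-stranded DNA virus genomes of
    the nudivirus/baculovirus clade and comparing them against close relatives.
    Provides ORF enumeration on both strands of a circular genome with a
    hexamer log-odds coding-potential filter, nested-ORF and overlap
    resolution, tandem direct-repeat discovery by consensus scoring,
    degenerate protein/DNA motif scanning (including upstream promoter-motif
    search, Kyte-Doolittle hydropathy segments and conserved-cysteine
    profiling), two-genome comparison (gene parity/colinearity, windowed
    percent identity over a global alignment, baculovirus core-gene audits,
    gene-neighborhood layout comparison), distance-based phylogenetics
    (p-distances, neighbor joining, bootstrap supports, concatenated gene
    sets, outgroup rooting), and a synthetic-genome generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
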