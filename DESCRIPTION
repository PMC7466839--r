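Package: plastocomp
Title: Comparative Chloroplast Genome Analysis
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Comparative analysis of chloroplast genomes (plastomes):
    quadripartite structure detection and inverted-repeat/single-copy junction
    reporting, microsatellite (SSR), imperfect tandem and dispersed repeat
    detection, collinear pairwise alignment with SNP/indel calling, windowed
    tandem-mutation co-occurrence statistics (Spearman rank correlation and
    Mann-Whitney U tests on 150 bp bins), per-locus nucleotide diversity (Pi)
    with hotspot ranking, Nei-Gojobori (1986) Ka/Ks, relative synonymous codon
    usage (RSCU) and codon-position base composition, and neighbor-joining
    phylogeny from p-distances. Includes a synthetic plastome generator with
    planted repeats and tandem-enriched mutations so the whole pipeline is
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
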