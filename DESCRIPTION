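Package: evescreen
Title: Discovery and Small-RNA Profiling of Endogenous Viral Elements from
    Shotgun Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An iterative read-recruitment and targeted-assembly screen for
    discovering endogenous viral elements (EVEs) and their flanking regions in
    repeat-rich host genomes, together with strand-resolved small-RNA signature
    profiling (piRNA/siRNA size distributions, positional nucleotide
    frequencies, 5'-uridine bias, ping-pong overlap statistics), DNA
    coverage-based presence and multicopy-flank inference, and a ground-truthed
    synthetic-data generator emulating the sequencing libraries such analyses
    consume. The recruitment stage is a seed-and-extend ungapped local aligner
    with Karlin-Altschul E-value filtering; assembly is a deterministic de
    Bruijn unitig assembler over canonical k-mers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    Rsamtools,
    withr,
    optparse
Config/testthat/edition: 3
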