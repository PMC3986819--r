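Package: neophase
Title: Haplotype-Resolved Reconstruction of Neo-Sex Chromosome Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Separates the transcripts of two barely diverged homologous
    chromosomes (a neo-X/neo-Y pair) from a mixed male transcriptome assembly.
    Male and female genomic reads are mapped against male transcripts, variant
    sites are categorized by their sex-specific allele patterns, and
    transcripts are rewritten into Y-specific (or X-specific) haplotypes,
    keeping only RNA-supported regions that carry diagnostic variants.
    Downstream annotations include open-reading-frame disruption (frameshifts
    and premature termination codons), 3'UTR metrics, allele-resolved
    expression via EM read assignment (FPKM), uncorrected divergence with
    alignment block filtering, and coverage-based screens for gene loss and
    silencing. A self-contained simulator with full ground truth makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    tools,
    Biostrings,
    stringi
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
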