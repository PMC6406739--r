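Package: retroload
Title: Retroelement-Linked Transcription Factor Binding Load on Genes and Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the contribution of retroelements (SINE, LINE, LTR/ERV)
    to the transcription-factor-binding-site (TFBS) regulation of human genes
    and molecular pathways. Assigns ChIP-seq peak summits to RepeatMasker
    repeat intervals and to 10 kb transcription-start-site neighborhoods,
    computes per-gene GRE/NGRE and per-pathway PII/NPII regulatory-load
    scores, classifies repeat families into evolutionary age fractions by
    mean divergence from consensus, selects extreme (RRE-enriched and
    RRE-deficient) genes and pathways by a least-squares regression-line and
    Euclidean-distance rule, tests gene-class and term enrichment with exact
    hypergeometric and EASE-modified Fisher tests, and assesses confidence by
    gene-label permutation. Includes a synthetic-data generator emitting the
    standard file formats (UCSC rmsk, refGene, narrowPeak, bedGraph, GMT)
    with planted structure so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
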