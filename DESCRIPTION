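Package: prophager
Title: Prophage Curation, Typing and Release Quantification for Poly-Lysogenic Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to curate candidate prophage regions in annotated bacterial
    chromosomes and characterize them. Candidate hits are merged and confirmed
    by conformance to the five classical phage functional modules
    (lysogeny control, DNA replication, packaging and capsid, tail, lysis),
    categorized from completeness scores with defect-based overrides
    (split or truncated integrases, missing terminase/portal, intron-split
    genes, misoriented late genes, mosaic regions), typed for virion
    morphology from tail-gene content and for lysogeny-switch architecture
    (lambda-like CI/Cro, ICEBs1-like ImmR/ImmA, Mu-like C/Ner) from gene
    synteny and promoter orientation, and screened for accessory genes
    (restriction-modification, toxin-antitoxin, diversity-generating and
    host-adaptation factors). A DNase-protection qPCR module quantifies
    spontaneously released encapsidated phage DNA by the 2^-ddCq method. A
    synthetic-data generator plants known prophage architectures with ground
    truth, and a packaged fixture encodes the 15-prophage Clostridium
    clostridioforme LM41 study genome for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    methods,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
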