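Package: mitolineage
Title: Mitochondrial DNA Heteroplasmy Surveillance Across Cell-Line Lineages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quality control of induced pluripotent stem cell (iPSC) lines
    by deep mitochondrial DNA sequencing. Calls low-frequency mtDNA single
    nucleotide variants from per-position allele-count pileups with
    depth, detection-limit, mono-allelic and Fisher strand-bias filters;
    separates private variants from haplogroup-defining motifs; annotates
    functional consequences on the rCRS gene map with the vertebrate
    mitochondrial genetic code; classifies variant segregation
    (transmitted, unique, non-transmitted) across the
    fibroblast-to-iPSC-to-neuronal-precursor lineage; and runs the
    accompanying group statistics. A Wright-Fisher bottleneck/drift
    simulator generates lineage-structured synthetic pileups with known
    truth so every stage is testable without raw reads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    GenomicRanges,
    IRanges,
    Rsamtools,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
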