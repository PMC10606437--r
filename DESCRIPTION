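Package: circulome
Title: Characterization of Extrachromosomal Circular DNA Circulomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the extrachromosomal circular DNA
    (eccDNA) complement of sequenced samples, as studied in weed populations
    contrasting herbicide-resistant and -sensitive phenotypes. Provides
    readers for the standard interchange formats (FASTA, PAF, BED, GFF3,
    tabular protein-domain annotations), rotation-aware greedy collapsing of
    circular sequences into non-redundant representatives at an identity
    threshold, per-sample circulome summary tables and length distributions,
    genome-window density maps with hotspot calling, a label-permutation test
    for gene and transposable-element density around eccDNA origins, set
    algebra over per-sample protein-domain catalogs, overlap classification
    against quantitative trait locus intervals, protein homology screening
    with Karlin-Altschul statistics, and a synthetic eccDNA-excision
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
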