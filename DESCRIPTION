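Package: lakphage
Title: Discovery and Comparative Genomics of Lak-Type Megaphages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational characterisation of huge (>540 kb)
    'Lak'-type bacteriophages from gut metagenomes: open reading frame
    prediction under alternative genetic codes and inference of stop-codon
    reassignment (translation table 15, TAG to glutamine) from coding-density
    gain; windowed codon-usage profiling and detection of TAG-free genomic
    regions; heuristic tRNA detection including suppressor (CTA-anticodon)
    tRNAs and tRNA introns; CRISPR array detection on host scaffolds with
    spacer-to-protospacer matching for host assignment; fragment-based
    average nucleotide identity, anchor-chain synteny, and identity-block
    segmentation of aligned genome populations (a recombination signal);
    exact-seed read mapping with SNP calling, zero-SNP read fractions,
    variant-frequency trajectories and recombinant-read detection; and a
    fully seeded synthetic-data generator producing phage genomes, CRISPR
    hosts, mosaic populations and reads with complete ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
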