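Package: panfam
Title: Pan-Genome Gene Family Analysis for Plant Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs and characterises a plant gene family across a
    pan-genome of inbred-line assemblies. Starting from per-genome profile-HMM
    domain hits, genome annotations and sequences, the package filters family
    members, computes physicochemical protein properties, refines orthogroups
    by pairwise protein identity, classifies orthogroup occupancy into core,
    softcore, shell and variable sets with bootstrap and closed-form saturation
    curves, estimates pairwise Ka/Ks by the Nei-Gojobori (1986) counting method
    on protein-guided codon alignments, scans promoter regions for IUPAC
    cis-regulatory motifs, detects tandem duplications by annotation rank,
    intersects genes with association-signal windows, summarises haplotype
    frequencies across breeding clusters, and profiles FPKM expression.
    A seeded synthetic pan-genome generator with planted ground truth supports
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
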