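Package: phyloscreen
Title: Motif-HMM Screening, Curation and Comparative Analysis of Protein
    Channel Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for comparative genomics of membrane-protein
    families such as the slow (SLAC/SLAH) and quick (ALMT/QUAC) plant anion
    channels: profile hidden Markov models built from motif seed alignments
    and used to screen proteomes with an at-least-one-motif E-value rule;
    identity-based semi-automatic curation (low-identity and duplicate
    removal, group fragmentation, reference-anchored group selection); UPGMA
    clustering on pairwise-identity distances with bootstrap support,
    robust-block selection and conservation-zone segmentation; LCA gene
    tree/species tree reconciliation with duplication and loss inference and
    duplication-loss-minimizing rooting; alignment-projected Kyte-Doolittle
    hydropathicity profiles with clade averaging, gap masking and
    transmembrane-segment calling; and a three-criterion screen for
    group-specifically conserved phosphorylation sites. A birth-death
    protein-family simulator with planted domain architecture provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    phytools,
    stats,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
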