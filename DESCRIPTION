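Package: acdminer
Title: Mining and Characterization of Small Heat Shock Proteins in
    Transcriptome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery and characterization of small heat shock proteins
    (sHsps) in nucleotide transcript assemblies. Provides six-frame ORF
    translation, detection of the alpha-crystallin domain (ACD) by
    anchored degenerate motifs combined with position-specific scoring,
    monomeric/dimeric architecture calls, physicochemical profiling
    (length, molecular weight, isoelectric point, GRAVY), rule-based
    assignment of monomeric sHsps to subclusters, nuclear localization
    signal scanning, beta-strand-anchored alignment of ACD cores,
    p-distance neighbor-joining trees with bootstrap supports, and a
    seeded synthetic-transcriptome generator with ground truth for
    end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
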