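Package: exonforge
Title: Exon Array Design from Fragmented Genome Assemblies and Field-Trial
    Variety Selection
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing an exon microarray from a fragmented,
    gene-enriched genome assembly: cleaning of genome survey sequence (GSS)
    reads with a conservation-checked accounting ledger (vector, contaminant
    and organellar screens, length and ambiguity filters, end trimming),
    soft-masking of simple and complex repeats, integration of heterogeneous
    evidence tracks (gene predictions, transcript alignments, protein
    homology, conservation) into non-overlapping scored consensus exonic
    regions, an EST-contig branch with six-frame ORF detection, strand
    inference and redundancy removal, and probe selection with probeset
    accounting. Also implements the accompanying field-trial statistics for
    variety selection: spatial correction of plot data by penalized
    regression splines, environment scaling, GGE (genotype main effect plus
    genotype-by-environment interaction) biplot decomposition, ideal-cultivar
    ranking and variety contrasts. Seeded synthetic-data generators with
    ground-truth labels make the whole pipeline testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    mgcv,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: Sequencing, Microarray, GenePrediction, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
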