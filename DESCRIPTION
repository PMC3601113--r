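Package: plastoscope
Title: Plastid Transcriptome Profiling, C-to-U RNA Editing Detection and
    Chloroplast Genome Structure Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing chloroplast (plastid) genomes and their
    transcriptomes from RNA-seq alignments: strand-aware C-to-U RNA editing
    site calling from base pileups with codon and amino-acid change
    annotation, genome-wide transcription coverage profiling and
    polycistronic transcription-unit delineation, intron splicing detection
    from gapped alignments, quadripartite (LSC/IRb/SSC/IRa) genome structure
    detection by exact inverted-repeat search, and indel cataloguing between
    aligned plastomes.  A seed-deterministic simulator generates annotated
    circular plastomes, transcription units, planted editing sites, partially
    spliced introns and sequencing reads together with machine-readable
    truth, so every stage of the pipeline can be validated end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
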