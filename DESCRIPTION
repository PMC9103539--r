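Package: ernascreen
Title: Candidate Enhancer-RNA Screening in a Defined Genomic Locus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A screening pipeline for candidate enhancer RNAs (eRNAs) within
    a single genomic locus. Enhancer peak positions are expanded into
    fixed-width candidate windows, RNA-seq reads are placed on the locus by
    an ungapped seed-and-verify mapper allowing a configurable number of
    mismatches, and candidate regions pass through a filtering funnel:
    elimination of regions with no aligned reads, merging of overlapping
    covered regions, delineation of densely covered sub-regions, exclusion
    of sub-regions overlapping interspersed repeats (SINE/LINE/LTR/DNA),
    and intersection with long non-coding RNA annotation. The package also
    provides a Spearman co-expression screen with ranked gene-list export,
    relative-expression quantification for qPCR (delta-delta-Ct), viability
    normalization with Wilcoxon and Student's t tests, and a fully seeded
    synthetic-data generator that emits standard FASTA/FASTQ/BED/GTF/SAM/TSV
    files with recorded ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
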