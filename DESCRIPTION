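Package: rdnamethyl
Title: Variant-Resolved Cytosine Methylation Analysis of 35S rDNA from Bisulfite Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for allele-specific cytosine
    methylation of plant 35S ribosomal DNA. Generates synthetic L- and S-type
    rDNA units with realistic intergenic-spacer architecture (promoter elements,
    tandem repeats, satellite blocks, diagnostic SNPs), per-molecule methylomes
    with context-specific rates (CG, CWG, CCG, CHH subtypes), and
    bisulfite-converted sequencing reads with a hidden truth table. Provides
    conversion-safe SNP assignment of bisulfite reads to rDNA variants,
    CyMate-style per-cytosine and per-read methylation profiling, the D_s-a
    silent-versus-active difference statistic with Mann-Whitney U and Student's
    t comparisons, per-cytosine positional-variability analysis,
    genome-versus-transcriptome variant proportions with specific-transcription
    ratios, and in-silico CAPS restriction genotyping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
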