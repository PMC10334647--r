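Package: hapscaf
Title: Chromosome-Level Scaffolding and Phasing of Diploid Assemblies
    with Hi-C and Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Merges homologous contig pairs of a partially phased diploid
    assembly into consensus contigs, scaffolds them to chromosome scale
    using long-read links and iterative Hi-C end-graph joining, detects
    erroneous joins and misassemblies from binned Hi-C contact maps via
    between-class-variance separation scores, and phases the resulting
    scaffolds into two haplotypes using long-read and Hi-C link evidence.
    Includes a seed-deterministic diploid genome simulator (SNVs, small
    indels, inversions, power-law Hi-C contacts, long reads, paired
    ends) with full truth tracking, and assembly evaluation metrics
    (N50, phasing accuracy, truth-based misassembly and switch-error
    counts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
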