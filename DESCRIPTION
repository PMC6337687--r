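Package: ssrpolykit
Title: Microsatellite Mining, Primer Design, In Silico PCR, and
    Length-Polymorphism Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mines perfect and compound microsatellite (SSR) loci from
    genome or transcriptome FASTA, designs ranked PCR primer pairs from
    500 bp flanking sequence with melting-temperature scoring, runs in
    silico PCR (e-PCR) across re-sequenced genotypes or heterologous
    species, and calls allele-length polymorphism, cross-species
    transferability, paralogy, and intron-junction problems. Includes a
    seeded synthetic-genome generator with planted repeat loci for
    parameter-recovery testing, a simulated gel-electrophoresis view,
    and a command-line interface tying the stages together.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
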