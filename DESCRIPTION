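Package: t6finder
Title: Discovery, Annotation and Classification of Type VI Secretion
    System Loci in Bacteroidales Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An in-silico pipeline for mining annotated bacterial genomes for
    type VI secretion system (T6SS) loci. Candidate loci are seeded by
    co-localization of VgrG and ClpV sentinel profile hits, expanded by a
    second, self-trained profile pass that recovers loci split across draft
    contigs, and their proteins are clustered at percent-identity/coverage
    cutoffs, assigned to Tss/Tag/effector families, and classified into the
    three conserved Bacteroidales genetic architectures (GA1-GA3). Loci are
    tested for association with integrative conjugative elements (ICE) via
    tra-gene proximity and patterns, and ICE DNA relatedness between strains
    is profiled with a blastn-like seed-and-extend HSP scan. A seeded
    synthetic-genome generator with ground-truth records makes every stage
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
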