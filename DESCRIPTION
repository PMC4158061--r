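Package: rnaseq2protdb
Title: Build Customized Proteomic Search Databases from RNA-Seq Evidence
Version: 0.1.0
Authors@R:
    person("Proteogenomics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to convert RNA-Seq derived evidence into protein FASTA
    databases for mass-spectrometry searching. Builds single amino acid
    polymorphism (SAP) polypeptide databases from annotated missense variants,
    splice-junction polypeptide databases from novel junctions via three-frame
    translation, and transcript-abundance (TPM) reduced reference databases.
    Also assembles search databases (contaminants, reversed-sequence decoys),
    filters identified peptides against a reference proteome to isolate novel
    peptides, and ships a deterministic synthetic-data generator with a
    machine-readable ground-truth manifest for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
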