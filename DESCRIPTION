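Package: NterMiner
Title: N-Terminal Proteogenomics: Peptide Libraries, FDR Scoring and
    Translation-Initiation-Site Annotation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for N-terminomics-driven proteogenomics. Builds
    genome-wide, protease-specific N-terminal peptide target-decoy
    databases from six-frame translations (with near-cognate CUG/GUG
    starts and downstream AUG truncations) and spliced gene models,
    subtracting a reference proteome and contaminants with Ile/Leu
    equivalence. Aggregates peptide-spectrum matches from multiple
    search engines into engine-independent FDR scores and combined FDR
    scores with multistage filtering. Classifies identified N termini
    by modification state and N-terminal methionine excision
    compliance, places novel translation initiation sites (TIS) on the
    genome relative to annotation, matches ribosome-profiling TIS
    calls, scores TIS sequence context by summed nucleotide
    frequencies, and tests start-codon conservation in whole-genome
    alignments. Includes seeded simulators for genomes, PSM tables and
    alignments so every stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    seqinr,
    withr
Config/testthat/edition: 3
biocViews: Proteomics, Proteogenomics, Genetics, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'NterMiner-package.R'
    'methods.R'
    'genome-io.R'
    'orf-discovery.R'
    'ntpep-library.R'
    'psm-fdr.R'
    'nt-annotation.R'
    'tis-context.R'
    'maf-io.R'
    'conservation.R'
    'synth-data.R'
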