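Package: somaclone
Title: Somatic Mutation Discovery and Characterization in Cloned Animals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate somatic mutations from donor/clone variant
    calls produced by somatic cell nuclear transfer (SCNT) cloning studies,
    and characterizes them: a filtering cascade (clone-specific heterozygous
    sites, read-depth threshold, cross-clone intersection, population
    allele-frequency annotation), coding-effect annotation, 96-channel
    trinucleotide-context substitution spectra with reference-signature
    comparison, per-gene mutation rates, and aging-gene / gene-set
    over-representation statistics (chi-squared with Yates continuity
    correction, hypergeometric test, Benjamini-Hochberg FDR). Includes a
    deterministic synthetic-data generator that emits every input format the
    pipeline consumes together with a ground-truth manifest.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
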