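Package: PCompFusion
Title: Per-Sample Differential Expression and Consensus Fusion Calling
    for Transcriptomes with Complex Structural Variants
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Two analysis pipelines for total RNA-Seq of biologically
    heterogeneous cohorts, such as leukemia cases with chromothripsis,
    where every sample carries a private expression profile and no
    replicate group exists. PComp calls genes differentially expressed in
    a single sample by fitting ordinary least-squares regressions with
    99.9% pointwise prediction bands for every sample pair, requiring a
    gene to fall outside the band on the same side in all pairs, and
    confirming each candidate with a one-sample t-test against the
    remaining samples. A fusion-gene meta-caller filters the reports of
    three fusion callers (EricScript, JAFFA, FusionCatcher) to their
    high-confidence subsets, keeps fusions supported by at least two
    callers, flags read-through and recurrent artifacts, and validates
    consensus fusions against genomic-array breakpoints within a
    +/- 100 kb window. A seeded synthetic-data generator produces count
    matrices with private spikes, a toy genome annotation, caller
    reports with planted truths, and array segments for end-to-end
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, DifferentialExpression, StructuralVariation,
    GeneFusionDetection, RNASeq, Software
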