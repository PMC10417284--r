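Package: cfMethSim
Title: Library-Preparation Bias Simulation and Tissue-of-Origin
    Deconvolution for cfDNA Methylomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanistic simulation of cell-free DNA (cfDNA) methylation
    sequencing with single-stranded (ssLP) and double-stranded (dsLP)
    library preparation, including jagged 5' overhangs and end-repair
    fill-in with unmethylated cytosines, together with the downstream
    analyses these artifacts distort: within-read M-bias profiles,
    global CpG/CHH methylation, enzymatic-conversion spike-in QC, the
    Jagged Index-Unmethylated (JI-U), individual-CpG-site
    tissue-of-origin deconvolution by bounded least squares with an
    undetermined fraction, and fragment-level U/X/M deconvolution by
    non-negative least squares against a marker-block atlas.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    mgcv
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: DNAMethylation, Epigenetics, Sequencing, Software
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'atlas.R'
    'cfMethSim-package.R'
    'compare.R'
    'deconv-fragment.R'
    'deconv-site.R'
    'jagged.R'
    'methprofile.R'
    'pat-io.R'
    'scenario.R'
    'simulate.R'
    'solvers.R'
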