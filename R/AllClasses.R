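#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
NULL

setClassUnion("integerOrNull", c("integer", "NULL"))

#' Simulation configuration for a cfDNA methylation sequencing run
#'
#' A \code{SimConfig} holds every parameter of the generative model: the
#' tissue mixture of fragment origins, fragment-length model, the jagged-end
#' (5' overhang) model, the library preparation chemistry (single-stranded
#' \code{"ssLP"} vs double-stranded \code{"dsLP"}), the enzymatic conversion
#' channel, background CHH methylation, read length and the RNG seed.
#' Two simulations with equal configurations are bit-identical.
#'
#' @slot mixture named numeric, tissue-of-origin proportions (sum to 1).
#' @slot nFragments integer, number of cfDNA fragments to draw.
#' @slot fragMean,fragSd,fragMin numeric, truncated-normal fragment length
#'   model in bp.
#' @slot jagProb numeric, probability that a fragment end carries a 5'
#'   overhang.
#' @slot jagMean numeric, mean overhang length in bp.
#' @slot jagDist character, overhang length distribution:
#'   \code{"geometric"} (shifted geometric, support 1,2,...; the long-tailed
#'   default since real overhangs range from nearly blunt to almost fully
#'   single-stranded) or \code{"fixed"} (every overhang exactly
#'   \code{round(jagMean)} bp, useful for limit checks).
#' @slot library character, \code{"ssLP"} or \code{"dsLP"}.
#' @slot conversionRate numeric, probability an unmethylated cytosine is
#'   deaminated and read as T.
#' @slot protectionRate numeric, probability a methylated cytosine is
#'   protected and read as C.
#' @slot chhMeth numeric, background CHH methylation fraction.
#' @slot chhPerFragment integer, simulated CHH cytosines per fragment.
#' @slot readLength integer, paired-end read length in bp (must exceed the
#'   30 bp jagged-index window).
#' @slot seed integer RNG seed.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    mixture = "numeric",
    nFragments = "integer",
    fragMean = "numeric",
    fragSd = "numeric",
    fragMin = "numeric",
    jagProb = "numeric",
    jagMean = "numeric",
    jagDist = "character",
    library = "character",
    conversionRate = "numeric",
    protectionRate = "numeric",
    chhMeth = "numeric",
    chhPerFragment = "integer",
    readLength = "integer",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  mx <- object@mixture
  if (length(mx) == 0L || is.null(names(mx)) || any(!nzchar(names(mx))))
    msg <- c(msg, "mixture must be a non-empty named numeric vector")
  if (any(mx < 0)) msg <- c(msg, "mixture proportions must be >= 0")
  if (length(mx) && abs(sum(mx) - 1) > 1e-9)
    msg <- c(msg, "mixture proportions must sum to 1 (tolerance 1e-9)")
  if (anyDuplicated(names(mx))) msg <- c(msg, "duplicated mixture tissue names")
  for (p in c("jagProb", "conversionRate", "protectionRate", "chhMeth")) {
    v <- slot(object, p)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("%s must be a single probability in [0, 1]", p))
  }
  if (object@nFragments < 0L) msg <- c(msg, "nFragments must be >= 0")
  if (!object@library %in% c("ssLP", "dsLP"))
    msg <- c(msg, "library must be 'ssLP' or 'dsLP'")
  if (!object@jagDist %in% c("geometric", "fixed"))
    msg <- c(msg, "jagDist must be 'geometric' or 'fixed'")
  if (object@readLength <= 30L)
    msg <- c(msg, "readLength must be > 30 (JI-U window must fit)")
  if (object@jagMean < 1) msg <- c(msg, "jagMean must be >= 1 bp")
  if (object@fragMin < 10) msg <- c(msg, "fragMin must be >= 10 bp")
  if (object@chhPerFragment < 0L) msg <- c(msg, "chhPerFragment must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Site-based reference methylation atlas
#'
#' Extends \linkS4class{RangedSummarizedExperiment}. Rows are CpG sites
#' (width-2 ranges anchored at the forward-strand C), columns are reference
#' tissues, and the single assay \code{"beta"} holds methylation fractions
#' in [0, 1] (NA = missing). This is the design matrix of the site-based
#' tissue-of-origin deconvolution.
#'
#' @exportClass ReferenceAtlas
setClass("ReferenceAtlas", contains = "RangedSummarizedExperiment")

setValidity("ReferenceAtlas", function(object) {
  msg <- character()
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    return("assay 'beta' missing")
  b <- SummarizedExperiment::assay(object, "beta")
  if (any(b < 0 | b > 1, na.rm = TRUE))
    msg <- c(msg, "beta values must lie in [0, 1]")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "tissue (column) names must be present and unique")
  rr <- SummarizedExperiment::rowRanges(object)
  if (length(rr)) {
    key <- paste(GenomicRanges::seqnames(rr), GenomicRanges::start(rr))
    if (anyDuplicated(key)) msg <- c(msg, "duplicated CpG sites")
    if (is.unsorted(order(as.integer(GenomicRanges::seqnames(rr)),
                          GenomicRanges::start(rr))) &&
        any(key != key[order(as.integer(GenomicRanges::seqnames(rr)),
                             GenomicRanges::start(rr))]))
      msg <- c(msg, "sites must be sorted by (chrom, pos)")
  }
  if (length(msg)) msg else TRUE
})

#' Fragment-level marker-block atlas of reference U-fractions
#'
#' Extends \linkS4class{RangedSummarizedExperiment}. Rows are marker blocks
#' (genomic intervals with metadata columns \code{target_cell_type} and
#' \code{cpg_count}), columns are reference cell types, and the assay
#' \code{"u_ref"} holds the reference fraction of mostly-Unmethylated (U)
#' fragments per block and cell type. This is the design matrix of the
#' fragment-level non-negative least squares deconvolution.
#'
#' @exportClass UFractionAtlas
setClass("UFractionAtlas", contains = "RangedSummarizedExperiment")

setValidity("UFractionAtlas", function(object) {
  msg <- character()
  if (!"u_ref" %in% SummarizedExperiment::assayNames(object))
    return("assay 'u_ref' missing")
  u <- SummarizedExperiment::assay(object, "u_ref")
  if (any(u < 0 | u > 1, na.rm = TRUE))
    msg <- c(msg, "u_ref values must lie in [0, 1]")
  rr <- SummarizedExperiment::rowRanges(object)
  need <- c("target_cell_type", "cpg_count")
  if (!all(need %in% names(S4Vectors::mcols(rr))))
    msg <- c(msg, "blocks need mcols target_cell_type and cpg_count")
  else if (any(S4Vectors::mcols(rr)$cpg_count < 1))
    msg <- c(msg, "cpg_count must be >= 1")
  if (any(GenomicRanges::width(rr) < 1))
    msg <- c(msg, "blocks must have start < end")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "cell-type names must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Raw simulated cfDNA duplexes (pre library preparation)
#'
#' Intermediate container produced by [sampleFragments()] and annotated by
#' [applyJaggedEnds()] and [libraryPrep()]: double-stranded fragments with
#' latent (true) CpG methylation and, once annotated, per-end 5' overhang
#' lengths and library-preparation provenance.
#'
#' @slot fragments \code{GRanges} of fragment intervals, with metadata
#'   columns added as the pipeline proceeds (tissue, jagL/jagR, strandRead,
#'   molStart/molEnd).
#' @slot calls \code{DataFrame} in long per-CpG form: \code{frag} (fragment
#'   index), \code{siteIdx} (atlas row), \code{pos} (1-based C position),
#'   \code{meth} (latent truth), plus \code{repair}/\code{methEff} after
#'   [libraryPrep()].
#' @exportClass RawFragments
setClass("RawFragments",
  representation(fragments = "GRanges", calls = "DataFrame"))

#' Sequenced fragment methylation calls
#'
#' The central per-molecule container: one row of \code{fragments()} per
#' sequenced molecule and a long-format call table (\code{callTable()}) with
#' one row per covered CpG, holding the reported call (\code{"C"} methylated,
#' \code{"T"} unmethylated, \code{"."} no call), an end-repair provenance
#' flag (\code{TRUE} where the reported base was synthesized during dsLP
#' fill-in), and the bp offset of the CpG from each read's 5' end
#' (\code{r1pos}/\code{r2pos}, \code{NA} when the read does not cover it).
#'
#' @slot fragments \code{GRanges} with mcols \code{tissue},
#'   \code{strandRead}, \code{molStart}, \code{molEnd}, \code{chhMethCalls},
#'   \code{chhTotalCalls}.
#' @slot calls \code{DataFrame} with columns \code{frag}, \code{pos},
#'   \code{call}, \code{repair}, \code{r1pos}, \code{r2pos}.
#' @slot readLength integer bp.
#' @slot library character, \code{"ssLP"} or \code{"dsLP"}.
#' @exportClass FragmentSet
setClass("FragmentSet",
  representation(
    fragments = "GRanges",
    calls = "DataFrame",
    readLength = "integer",
    library = "character"
  )
)

setValidity("FragmentSet", function(object) {
  msg <- character()
  cl <- object@calls
  need <- c("frag", "pos", "call", "repair", "r1pos", "r2pos")
  if (!all(need %in% names(cl)))
    return(paste("calls must have columns:", paste(need, collapse = ", ")))
  if (nrow(cl)) {
    if (!all(cl$call %in% c("C", "T", ".")))
      msg <- c(msg, "calls must be 'C', 'T' or '.'")
    if (any(cl$frag < 1L | cl$frag > length(object@fragments)))
      msg <- c(msg, "call frag index out of range")
    rl <- object@readLength
    if (any(stats::na.omit(cl$r1pos) < 0L | stats::na.omit(cl$r1pos) >= rl) ||
        any(stats::na.omit(cl$r2pos) < 0L | stats::na.omit(cl$r2pos) >= rl))
      msg <- c(msg, "read positions must lie in [0, readLength)")
    if (object@library == "ssLP" && any(cl$repair))
      msg <- c(msg, "repair flags must be FALSE under ssLP (no end repair)")
  }
  if (!object@library %in% c("ssLP", "dsLP"))
    msg <- c(msg, "library must be 'ssLP' or 'dsLP'")
  if (length(msg)) msg else TRUE
})

#' Conversion-control spike-in calls
#'
#' Reported base calls for the two conversion controls: unmethylated lambda
#' DNA (every C should be deaminated and read as T) and fully methylated
#' pUC19 (every C should be protected and read as C).
#'
#' @slot lambdaCalls character vector of reported bases ("C"/"T") at
#'   unmethylated lambda cytosines.
#' @slot puc19Calls character vector of reported bases at methylated pUC19
#'   cytosines.
#' @exportClass SpikeinSet
setClass("SpikeinSet",
  representation(lambdaCalls = "character", puc19Calls = "character"))

setValidity("SpikeinSet", function(object) {
  ok <- function(x) all(x %in% c("C", "T"))
  if (!ok(object@lambdaCalls) || !ok(object@puc19Calls))
    "spike-in calls must be 'C' or 'T'" else TRUE
})

#' One simulated sample: fragments, spike-ins and generative truth
#'
#' @slot fragments \linkS4class{FragmentSet}.
#' @slot spikeins \linkS4class{SpikeinSet}.
#' @slot config the \linkS4class{SimConfig} used (the latent truth).
#' @slot realizedCounts named integer, realized fragment count per tissue.
#' @exportClass SampleDataset
setClass("SampleDataset",
  representation(
    fragments = "FragmentSet",
    spikeins = "SpikeinSet",
    config = "SimConfig",
    realizedCounts = "integer"
  )
)

setValidity("SampleDataset", function(object) {
  if (sum(object@realizedCounts) != length(object@fragments@fragments))
    "realized tissue counts must sum to the number of fragments" else TRUE
})

#' Trimming policy for methylation extraction
#'
#' Number of bp ignored from the 5' end of read 1 and read 2 when counting
#' methylation calls (the extractor-style \code{--ignore}/\code{--ignore_r2}
#' convention used to cut away end-repair artifacts).
#'
#' @slot ignoreR1,ignoreR2 integer bp, both >= 0 and < read length.
#' @exportClass TrimPolicy
setClass("TrimPolicy",
  representation(ignoreR1 = "integer", ignoreR2 = "integer"))

setValidity("TrimPolicy", function(object) {
  if (object@ignoreR1 < 0L || object@ignoreR2 < 0L)
    "trim amounts must be >= 0" else TRUE
})

#' Site-based tissue-of-origin deconvolution result
#'
#' Proportions estimated by bounded least squares over the reference atlas
#' with the simplex inequality constraint: each proportion in [0, 1], sum
#' of proportions <= 1, and \code{undetermined = 1 - sum(proportions)}.
#'
#' @slot proportions named numeric, one entry per reference tissue.
#' @slot undetermined numeric, the slack of the sum-to-one inequality.
#' @slot residualNorm numeric, value of the least-squares objective
#'   \eqn{\|Ax - b\|_2^2} at the solution.
#' @slot nSitesUsed integer, number of (non-missing) atlas sites fitted.
#' @slot method character, solver used ("nnls-slack" or "grid").
#' @exportClass DeconvolutionResult
setClass("DeconvolutionResult",
  representation(
    proportions = "numeric",
    undetermined = "numeric",
    residualNorm = "numeric",
    nSitesUsed = "integer",
    method = "character"
  )
)

setValidity("DeconvolutionResult", function(object) {
  msg <- character()
  p <- object@proportions
  if (any(p < -1e-8 | p > 1 + 1e-8))
    msg <- c(msg, "proportions must lie in [0, 1]")
  if (sum(p) > 1 + 1e-8) msg <- c(msg, "proportions must sum to <= 1")
  if (object@undetermined < -1e-8)
    msg <- c(msg, "undetermined fraction must be >= 0")
  if (abs(object@undetermined - (1 - sum(p))) > 1e-6)
    msg <- c(msg, "undetermined must equal 1 - sum(proportions)")
  if (length(msg)) msg else TRUE
})

#' Fragment-level (U/X/M) deconvolution result
#'
#' Non-negative least squares weights over the marker-block U-fraction
#' atlas; \code{proportions} are the weights renormalized to sum to 1,
#' \code{rawWeights} are the untouched NNLS solution.
#'
#' @slot proportions named numeric summing to 1.
#' @slot rawWeights named numeric, w >= 0 from the NNLS fit.
#' @slot residualNorm numeric, \eqn{\|U w - u\|_2^2} at the raw solution.
#' @slot nBlocksUsed integer.
#' @exportClass FragmentDeconvResult
setClass("FragmentDeconvResult",
  representation(
    proportions = "numeric",
    rawWeights = "numeric",
    residualNorm = "numeric",
    nBlocksUsed = "integer"
  )
)

setValidity("FragmentDeconvResult", function(object) {
  msg <- character()
  if (any(object@rawWeights < 0)) msg <- c(msg, "raw weights must be >= 0")
  if (length(object@proportions) &&
      abs(sum(object@proportions) - 1) > 1e-8 && sum(object@rawWeights) > 0)
    msg <- c(msg, "proportions must sum to 1 after normalization")
  if (length(msg)) msg else TRUE
})

#' Jagged Index-Unmethylated (JI-U) result
#'
#' \code{jiU = (M1 - M2) / M1 * 100}, where \code{M1} is the pooled CpG
#' methylation over the first \code{window} bp from the 5' end of read 1 and
#' \code{M2} the pooled methylation over the read-2 window covering the
#' fragment's 3' terminus (the first \code{window} sequenced bp of read 2).
#' \code{m2Alt}/\code{jiUAlt} report the alternative reading of the window
#' ("the last \code{window} cycles of read 2"); see the package vignette.
#'
#' @slot m1,m2,m2Alt numeric methylation fractions in [0, 1].
#' @slot jiU,jiUAlt numeric, percent.
#' @slot nCalls1,nCalls2,nCalls2Alt integer call counts per window.
#' @slot window,minCalls integer.
#' @slot defined logical; FALSE when M1 = 0 or a window has fewer than
#'   \code{minCalls} calls (then the index is NA, never silently 0).
#' @exportClass JaggedIndexResult
setClass("JaggedIndexResult",
  representation(
    m1 = "numeric", m2 = "numeric", m2Alt = "numeric",
    jiU = "numeric", jiUAlt = "numeric",
    nCalls1 = "integer", nCalls2 = "integer", nCalls2Alt = "integer",
    window = "integer", minCalls = "integer", defined = "logical"
  )
)

setValidity("JaggedIndexResult", function(object) {
  msg <- character()
  for (s in c("m1", "m2", "m2Alt")) {
    v <- slot(object, s)
    if (!is.na(v) && (v < 0 || v > 1))
      msg <- c(msg, sprintf("%s must lie in [0, 1]", s))
  }
  if (object@defined &&
      abs(object@jiU - (object@m1 - object@m2) / object@m1 * 100) > 1e-9)
    msg <- c(msg, "jiU must equal (M1 - M2)/M1 * 100")
  if (length(msg)) msg else TRUE
})

#' Two-group comparison result (t-test)
#'
#' @slot metric,groupA,groupB character labels.
#' @slot test character, "paired_t" or "unpaired_t".
#' @slot tStatistic,pRaw,pBonferroni numeric; \code{pBonferroni} is NA until
#'   [bonferroniCorrect()] is applied.
#' @slot nComparisons integer family size used for correction (NA before).
#' @exportClass ComparisonResult
setClass("ComparisonResult",
  representation(
    metric = "character", groupA = "character", groupB = "character",
    test = "character", tStatistic = "numeric", pRaw = "numeric",
    pBonferroni = "numeric", nComparisons = "integer"
  )
)

setValidity("ComparisonResult", function(object) {
  msg <- character()
  if (!object@test %in% c("paired_t", "unpaired_t"))
    msg <- c(msg, "test must be 'paired_t' or 'unpaired_t'")
  if (!is.na(object@pRaw) && (object@pRaw < 0 || object@pRaw > 1))
    msg <- c(msg, "pRaw must lie in [0, 1]")
  if (!is.na(object@pBonferroni)) {
    if (object@pBonferroni < 0 || object@pBonferroni > 1)
      msg <- c(msg, "pBonferroni must lie in [0, 1]")
    expect <- min(1, object@pRaw * object@nComparisons)
    if (abs(object@pBonferroni - expect) > 1e-12)
      msg <- c(msg, "pBonferroni must equal min(1, pRaw * nComparisons)")
  }
  if (length(msg)) msg else TRUE
})

#' Scenario-grid run report
#'
#' @slot metrics data.frame, one row per simulated run with the sample-level
#'   metrics (global/CHH methylation, conversion QC, JI-U, undetermined).
#' @slot siteProportions data.frame, long-format site-based deconvolution
#'   proportions per run.
#' @slot cellProportions data.frame, long-format fragment-level proportions
#'   per run.
#' @slot meta list: base seed, config hash per run, package version.
#' @exportClass RunReport
setClass("RunReport",
  representation(
    metrics = "data.frame",
    siteProportions = "data.frame",
    cellProportions = "data.frame",
    meta = "list"
  )
)
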