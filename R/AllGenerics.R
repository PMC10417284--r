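#' @include AllClasses.R
NULL

#' Accessors for cfMethSim containers
#'
#' Small accessor generics so downstream code never touches slots directly:
#' \code{atlasBeta()}/\code{atlasTissues()}/\code{atlasSites()} for
#' \linkS4class{ReferenceAtlas}; \code{uRef()}/\code{cellTypes()}/
#' \code{markerBlocks()} for \linkS4class{UFractionAtlas};
#' \code{fragments()}/\code{callTable()} for \linkS4class{FragmentSet};
#' \code{spikeins()}/\code{simConfig()}/\code{realizedCounts()} for
#' \linkS4class{SampleDataset}; \code{proportions()}/\code{undetermined()}/
#' \code{residualNorm()}/\code{rawWeights()} for deconvolution results;
#' \code{jiU()} for \linkS4class{JaggedIndexResult}.
#'
#' @param x an object of the matching class.
#' @return the slot contents (see each class page).
#' @name accessors
#' @aliases atlasBeta atlasTissues atlasSites uRef cellTypes markerBlocks
#'   fragments callTable spikeins simConfig realizedCounts proportions
#'   undetermined residualNorm rawWeights jiU
NULL

#' @rdname accessors
#' @export
setGeneric("atlasBeta", function(x) standardGeneric("atlasBeta"))
#' @rdname accessors
#' @export
setGeneric("atlasTissues", function(x) standardGeneric("atlasTissues"))
#' @rdname accessors
#' @export
setGeneric("atlasSites", function(x) standardGeneric("atlasSites"))
#' @rdname accessors
#' @export
setGeneric("uRef", function(x) standardGeneric("uRef"))
#' @rdname accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))
#' @rdname accessors
#' @export
setGeneric("markerBlocks", function(x) standardGeneric("markerBlocks"))
#' @rdname accessors
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))
#' @rdname accessors
#' @export
setGeneric("callTable", function(x) standardGeneric("callTable"))
#' @rdname accessors
#' @export
setGeneric("spikeins", function(x) standardGeneric("spikeins"))
#' @rdname accessors
#' @export
setGeneric("simConfig", function(x) standardGeneric("simConfig"))
#' @rdname accessors
#' @export
setGeneric("realizedCounts", function(x) standardGeneric("realizedCounts"))
#' @rdname accessors
#' @export
setGeneric("proportions", function(x) standardGeneric("proportions"))
#' @rdname accessors
#' @export
setGeneric("undetermined", function(x) standardGeneric("undetermined"))
#' @rdname accessors
#' @export
setGeneric("residualNorm", function(x) standardGeneric("residualNorm"))
#' @rdname accessors
#' @export
setGeneric("rawWeights", function(x) standardGeneric("rawWeights"))
#' @rdname accessors
#' @export
setGeneric("jiU", function(x) standardGeneric("jiU"))

#' @rdname accessors
setMethod("atlasBeta", "ReferenceAtlas", function(x)
  SummarizedExperiment::assay(x, "beta"))
#' @rdname accessors
setMethod("atlasTissues", "ReferenceAtlas", function(x) colnames(x))
#' @rdname accessors
setMethod("atlasSites", "ReferenceAtlas", function(x)
  SummarizedExperiment::rowRanges(x))
#' @rdname accessors
setMethod("uRef", "UFractionAtlas", function(x)
  SummarizedExperiment::assay(x, "u_ref"))
#' @rdname accessors
setMethod("cellTypes", "UFractionAtlas", function(x) colnames(x))
#' @rdname accessors
setMethod("markerBlocks", "UFractionAtlas", function(x)
  SummarizedExperiment::rowRanges(x))
#' @rdname accessors
setMethod("fragments", "FragmentSet", function(x) x@fragments)
#' @rdname accessors
setMethod("callTable", "FragmentSet", function(x) x@calls)
#' @rdname accessors
setMethod("fragments", "SampleDataset", function(x) x@fragments)
#' @rdname accessors
setMethod("spikeins", "SampleDataset", function(x) x@spikeins)
#' @rdname accessors
setMethod("simConfig", "SampleDataset", function(x) x@config)
#' @rdname accessors
setMethod("realizedCounts", "SampleDataset", function(x) x@realizedCounts)
#' @rdname accessors
setMethod("proportions", "DeconvolutionResult", function(x) x@proportions)
#' @rdname accessors
setMethod("undetermined", "DeconvolutionResult", function(x) x@undetermined)
#' @rdname accessors
setMethod("residualNorm", "DeconvolutionResult", function(x) x@residualNorm)
#' @rdname accessors
setMethod("proportions", "FragmentDeconvResult", function(x) x@proportions)
#' @rdname accessors
setMethod("rawWeights", "FragmentDeconvResult", function(x) x@rawWeights)
#' @rdname accessors
setMethod("residualNorm", "FragmentDeconvResult", function(x) x@residualNorm)
#' @rdname accessors
setMethod("jiU", "JaggedIndexResult", function(x) x@jiU)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@library, "|", object@nFragments, "fragments\n")
  cat("  mixture:", paste(sprintf("%s=%.3g", names(object@mixture),
                                  object@mixture), collapse = ", "), "\n")
  cat(sprintf("  fragment length ~ N(%g, %g) >= %g bp; read length %d bp\n",
              object@fragMean, object@fragSd, object@fragMin,
              object@readLength))
  cat(sprintf("  jag: prob %.3g, mean length %.3g bp\n",
              object@jagProb, object@jagMean))
  cat(sprintf("  conversion %.4g, protection %.4g, CHH meth %.4g; seed %d\n",
              object@conversionRate, object@protectionRate, object@chhMeth,
              object@seed))
})

setMethod("show", "ReferenceAtlas", function(object) {
  cat(sprintf("ReferenceAtlas: %d CpG sites x %d tissues\n",
              nrow(object), ncol(object)))
  callNextMethod()
})

setMethod("show", "UFractionAtlas", function(object) {
  cat(sprintf("UFractionAtlas: %d marker blocks x %d cell types\n",
              nrow(object), ncol(object)))
  callNextMethod()
})

setMethod("show", "FragmentSet", function(object) {
  cat(sprintf("FragmentSet (%s): %d molecules, %d CpG calls, read length %d\n",
              object@library, length(object@fragments), nrow(object@calls),
              object@readLength))
})

setMethod("show", "SampleDataset", function(object) {
  cat("SampleDataset\n")
  show(object@fragments)
  cat(sprintf("  spike-ins: %d lambda / %d pUC19 calls\n",
              length(object@spikeins@lambdaCalls),
              length(object@spikeins@puc19Calls)))
  cat("  realized tissue counts:",
      paste(sprintf("%s=%d", names(object@realizedCounts),
                    object@realizedCounts), collapse = ", "), "\n")
})

setMethod("show", "DeconvolutionResult", function(object) {
  cat(sprintf("DeconvolutionResult (%s), %d sites\n",
              object@method, object@nSitesUsed))
  p <- sort(object@proportions, decreasing = TRUE)
  p <- p[p > 1e-4]
  for (nm in names(p)) cat(sprintf("  %-20s %6.4f\n", nm, p[[nm]]))
  cat(sprintf("  %-20s %6.4f\n", "undetermined", object@undetermined))
  cat(sprintf("  residual ||Ax-b||^2 = %.4g\n", object@residualNorm))
})

setMethod("show", "FragmentDeconvResult", function(object) {
  cat(sprintf("FragmentDeconvResult, %d blocks\n", object@nBlocksUsed))
  p <- sort(object@proportions, decreasing = TRUE)
  p <- p[p > 1e-4]
  for (nm in names(p)) cat(sprintf("  %-20s %6.4f\n", nm, p[[nm]]))
})

setMethod("show", "JaggedIndexResult", function(object) {
  if (!object@defined) {
    cat("JI-U: undefined (insufficient calls or M1 = 0)\n")
  } else {
    cat(sprintf("JI-U = %.2f (M1 = %.4f, n = %d; M2 = %.4f, n = %d)\n",
                object@jiU, object@m1, object@nCalls1, object@m2,
                object@nCalls2))
    cat(sprintf("  read-2-tail window: M2 = %.4f, JI-U = %.2f (n = %d)\n",
                object@m2Alt, object@jiUAlt, object@nCalls2Alt))
  }
})

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf("%s: %s vs %s (%s) t = %.3f, p = %.3g",
              object@metric, object@groupA, object@groupB, object@test,
              object@tStatistic, object@pRaw))
  if (!is.na(object@pBonferroni))
    cat(sprintf(", p_bonf = %.3g [%s] (m = %d)",
                object@pBonferroni, significanceStars(object@pBonferroni),
                object@nComparisons))
  cat("\n")
})

setMethod("show", "RunReport", function(object) {
  cat(sprintf("RunReport: %d runs\n", nrow(object@metrics)))
  if (nrow(object@metrics)) print(utils::head(object@metrics, 12))
})
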