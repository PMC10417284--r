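#' @include AllClasses.R
NULL

#' Observed methylation vector aligned to a reference atlas
#'
#' Matches site counts to the atlas rows by (chrom, position); sites with
#' coverage below \code{minCoverage} (or absent from the counts) are marked
#' missing and later dropped row-wise by the deconvolution (pairwise
#' deletion, no imputation).
#'
#' @param counts \code{GRanges} from [extractSiteCounts()].
#' @param atlas a \linkS4class{ReferenceAtlas}.
#' @param minCoverage minimum informative calls per site (default 1).
#' @return \code{DataFrame} aligned to atlas rows with columns \code{beta}
#'   (NA = missing) and \code{coverage}.
#' @export
sampleBetaFromCounts <- function(counts, atlas, minCoverage = 1L) {
  sites <- atlasSites(atlas)
  keyA <- paste0(as.character(GenomicRanges::seqnames(sites)), ":",
                 GenomicRanges::start(sites))
  keyC <- paste0(as.character(GenomicRanges::seqnames(counts)), ":",
                 GenomicRanges::start(counts))
  idx <- match(keyA, keyC)
  if (all(is.na(idx)))
    stop("site counts share no coordinates with the atlas")
  cov <- integer(length(keyA))
  cov[!is.na(idx)] <- S4Vectors::mcols(counts)$n_total[idx[!is.na(idx)]]
  beta <- rep(NA_real_, length(keyA))
  ok <- !is.na(idx) & cov >= minCoverage
  beta[ok] <- (S4Vectors::mcols(counts)$n_meth[idx[ok]]) / cov[ok]
  S4Vectors::DataFrame(beta = beta, coverage = cov)
}

#' Site-based tissue-of-origin deconvolution (bounded least squares)
#'
#' Estimates tissue proportions \eqn{x} from the observed per-site
#' methylation vector \eqn{b} and the atlas matrix \eqn{A} by
#' \deqn{\min_x \|Ax - b\|_2^2 \quad \mbox{s.t.} \quad 0 \le x_i \le 1,\;
#'   \sum_i x_i \le 1,}
#' reporting the slack of the simplex inequality as the *undetermined*
#' fraction -- the share of the methylation signal not attributable to any
#' reference tissue. Missing sites are dropped row-wise. Optionally rows
#' are weighted by the square root of coverage.
#'
#' @param beta \code{DataFrame} from [sampleBetaFromCounts()] (columns
#'   \code{beta}, \code{coverage}), or a plain numeric vector of observed
#'   methylation fractions aligned to atlas rows (NA = missing).
#' @param atlas a \linkS4class{ReferenceAtlas}.
#' @param coverageWeight logical; weight sites by sqrt(coverage)
#'   (default FALSE -- unweighted).
#' @return a \linkS4class{DeconvolutionResult}.
#' @examples
#' atl <- makeToyAtlas(3, 10, seed = 1, calibrateN = 1000)
#' b <- atlasBeta(atl$site) %*% c(0.5, 0.3, 0)
#' deconvolveSite(drop(b), atl$site)
#' @export
deconvolveSite <- function(beta, atlas, coverageWeight = FALSE) {
  if (methods::is(beta, "DataFrame") || is.data.frame(beta)) {
    bvec <- beta$beta
    cov <- beta$coverage
  } else {
    bvec <- as.numeric(beta)
    cov <- rep(1L, length(bvec))
  }
  A <- atlasBeta(atlas)
  if (length(bvec) != nrow(A))
    stop("observed beta vector must align with atlas rows")
  use <- !is.na(bvec) & !apply(is.na(A), 1, any)
  Tn <- ncol(A)
  if (sum(use) < Tn)
    stop(sprintf("only %d usable sites for %d tissues", sum(use), Tn))
  Ause <- A[use, , drop = FALSE]
  buse <- bvec[use]
  if (coverageWeight) {
    w <- sqrt(cov[use])
    Ause <- Ause * w
    buse <- buse * w
  }
  sol <- .boundedSimplexLS(Ause, buse)
  methods::new("DeconvolutionResult",
               proportions = stats::setNames(sol$x, colnames(A)),
               undetermined = 1 - sum(sol$x),
               residualNorm = sol$residual,
               nSitesUsed = as.integer(sum(use)),
               method = "nnls-slack")
}

# grid cache: feasible simplex grids are expensive to enumerate, reuse them
.gridCache <- new.env(parent = emptyenv())

.simplexGrid <- function(Tn, step) {
  key <- sprintf("%d:%g", Tn, step)
  if (!is.null(.gridCache[[key]])) return(.gridCache[[key]])
  ax <- seq(0, 1, by = step)
  X <- as.matrix(expand.grid(rep(list(ax), Tn), KEEP.OUT.ATTRS = FALSE))
  X <- X[rowSums(X) <= 1 + 1e-9, , drop = FALSE]
  dimnames(X) <- NULL
  .gridCache[[key]] <- X
  X
}

#' Brute-force grid deconvolution (test oracle)
#'
#' Exhaustively minimizes the same objective as [deconvolveSite()] over the
#' lattice \eqn{\{x : x_i \in \{0, step, 2\,step, \dots\},\ \sum x_i \le 1\}}.
#' Exponential in the tissue count, hence restricted to atlases with at
#' most 4 tissues; exists to certify the constrained solver.
#'
#' @param beta as in [deconvolveSite()].
#' @param atlas a \linkS4class{ReferenceAtlas} with <= 4 tissues.
#' @param step grid resolution (default 0.01).
#' @return a \linkS4class{DeconvolutionResult} (method \code{"grid"}).
#' @export
bruteForceDeconv <- function(beta, atlas, step = 0.01) {
  if (methods::is(beta, "DataFrame") || is.data.frame(beta)) bvec <- beta$beta
  else bvec <- as.numeric(beta)
  A <- atlasBeta(atlas)
  Tn <- ncol(A)
  if (Tn > 4L) stop("brute-force grid limited to <= 4 tissues")
  use <- !is.na(bvec) & !apply(is.na(A), 1, any)
  Ause <- A[use, , drop = FALSE]
  b <- bvec[use]
  X <- .simplexGrid(Tn, step)
  G <- crossprod(Ause)
  cc <- drop(crossprod(Ause, b))
  obj <- rowSums((X %*% G) * X) - 2 * drop(X %*% cc) + sum(b^2)
  best <- which.min(obj)
  x <- X[best, ]
  methods::new("DeconvolutionResult",
               proportions = stats::setNames(x, colnames(A)),
               undetermined = 1 - sum(x),
               residualNorm = obj[best],
               nSitesUsed = as.integer(sum(use)),
               method = "grid")
}
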