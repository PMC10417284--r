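#' @include AllClasses.R
NULL

#' Classify fragments as U / X / M
#'
#' A fragment restricted to one marker block, with \code{k} informative CpG
#' calls of which \code{m} are methylated, is labelled \code{NA} if
#' \code{k < minCpgs}, \code{U} (mostly unmethylated) if
#' \code{m/k <= uThresh}, \code{M} (mostly methylated) if
#' \code{m/k >= mThresh}, and \code{X} (mixed) otherwise. Boundaries are
#' inclusive; \code{"."} no-calls never count.
#'
#' @param pattern character vector of per-fragment call strings over the
#'   alphabet C/T/. (e.g. \code{"CCTC"}).
#' @param uThresh,mThresh classification thresholds (defaults 0.25 / 0.75).
#' @param minCpgs minimum informative CpGs (default 3).
#' @return factor with levels U, X, M, NA_class.
#' @examples
#' classifyFragment(c("CCCC", "TTTC", "CT.."))
#' @export
classifyFragment <- function(pattern, uThresh = 0.25, mThresh = 0.75,
                             minCpgs = 3L) {
  spl <- strsplit(pattern, "", fixed = TRUE)
  k <- vapply(spl, function(x) sum(x %in% c("C", "T")), integer(1))
  m <- vapply(spl, function(x) sum(x == "C"), integer(1))
  .uxmLabel(m, k, uThresh, mThresh, minCpgs)
}

.uxmLabel <- function(m, k, uThresh, mThresh, minCpgs) {
  lab <- rep("NA_class", length(k))
  ok <- k >= minCpgs
  frac <- ifelse(k > 0, m / k, NA_real_)
  lab[ok & frac <= uThresh] <- "U"
  lab[ok & frac >= mThresh] <- "M"
  lab[ok & frac > uThresh & frac < mThresh] <- "X"
  factor(lab, levels = c("U", "X", "M", "NA_class"))
}

#' Tally U/X/M fragment classes per marker block
#'
#' Every fragment is evaluated against every marker block it overlaps with
#' at least one informative CpG (a fragment spanning two blocks contributes
#' to both); classification uses only the calls inside the block.
#'
#' @param fragset a \linkS4class{FragmentSet}.
#' @param blockAtlas a \linkS4class{UFractionAtlas}.
#' @param uThresh,mThresh,minCpgs see [classifyFragment()].
#' @return \code{DataFrame} aligned to the atlas blocks with columns
#'   \code{n_U}, \code{n_X}, \code{n_M}, \code{n_NA} and \code{u_fraction}
#'   (= n_U / (n_U + n_X + n_M); NA when no classified fragments).
#' @export
countUXM <- function(fragset, blockAtlas, uThresh = 0.25, mThresh = 0.75,
                     minCpgs = 3L) {
  blocks <- markerBlocks(blockAtlas)
  nb <- length(blocks)
  cl <- fragset@calls
  out <- S4Vectors::DataFrame(n_U = integer(nb), n_X = integer(nb),
                              n_M = integer(nb), n_NA = integer(nb),
                              u_fraction = rep(NA_real_, nb))
  if (nrow(cl) == 0L) return(out)
  inf <- cl$call %in% c("C", "T")
  chrom <- as.character(GenomicRanges::seqnames(
    fragset@fragments))[cl$frag]
  callGR <- GenomicRanges::GRanges(chrom[inf],
              IRanges::IRanges(start = cl$pos[inf], width = 1L))
  ov <- GenomicRanges::findOverlaps(callGR, blocks)
  if (length(ov) == 0L) return(out)
  qi <- S4Vectors::queryHits(ov)
  bi <- S4Vectors::subjectHits(ov)
  fragIdx <- cl$frag[inf][qi]
  methHit <- (cl$call[inf] == "C")[qi]
  grp <- paste0(fragIdx, "_", bi)
  k <- rowsum(rep.int(1L, length(grp)), grp, reorder = FALSE)
  m <- rowsum(as.integer(methHit), grp, reorder = FALSE)
  blk <- as.integer(sub("^.*_", "", rownames(k)))
  lab <- .uxmLabel(m[, 1], k[, 1], uThresh, mThresh, minCpgs)
  tab <- table(factor(blk, levels = seq_len(nb)), lab)
  out$n_U <- as.integer(tab[, "U"])
  out$n_X <- as.integer(tab[, "X"])
  out$n_M <- as.integer(tab[, "M"])
  out$n_NA <- as.integer(tab[, "NA_class"])
  denom <- out$n_U + out$n_X + out$n_M
  out$u_fraction <- ifelse(denom > 0, out$n_U / denom, NA_real_)
  out
}

#' Fragment-level deconvolution by non-negative least squares
#'
#' Solves \eqn{\min_w \|U_{ref} w - u_{obs}\|_2^2} with \eqn{w \ge 0} over
#' the marker blocks with at least \code{minFragmentsPerBlock} classified
#' fragments, then renormalizes the weights to proportions summing to 1
#' (the raw weights are kept alongside).
#'
#' @param counts \code{DataFrame} from [countUXM()].
#' @param blockAtlas a \linkS4class{UFractionAtlas}.
#' @param minFragmentsPerBlock minimum classified (U+X+M) fragments for a
#'   block to enter the system (default 1; blocks with none are always
#'   dropped, never imputed).
#' @return a \linkS4class{FragmentDeconvResult}.
#' @export
deconvolveUXM <- function(counts, blockAtlas, minFragmentsPerBlock = 1L) {
  U <- uRef(blockAtlas)
  nb <- nrow(U)
  stopifnot(nrow(counts) == nb)
  classified <- counts$n_U + counts$n_X + counts$n_M
  pass <- classified >= max(1L, minFragmentsPerBlock) &
    !is.na(counts$u_fraction)
  if (sum(pass) < ncol(U))
    stop(sprintf("only %d blocks pass (need >= %d cell types)",
                 sum(pass), ncol(U)))
  fit <- nnls(U[pass, , drop = FALSE], counts$u_fraction[pass])
  if (!fit$converged) stop("NNLS failed to converge")
  w <- stats::setNames(fit$x, colnames(U))
  tot <- sum(w)
  props <- if (tot > 0) w / tot else w
  methods::new("FragmentDeconvResult",
               proportions = props, rawWeights = w,
               residualNorm = fit$deviance,
               nBlocksUsed = as.integer(sum(pass)))
}
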