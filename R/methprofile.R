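#' @include AllClasses.R
NULL

#' Trim policy constructor
#'
#' @param ignoreR1,ignoreR2 bp ignored from the 5' end of read 1 / read 2
#'   when extracting site counts (both >= 0). The extractor-style defaults
#'   used in the scenario grid are (2, 2) for ssLP and (2, 5) for dsLP.
#' @return a \linkS4class{TrimPolicy}.
#' @export
TrimPolicy <- function(ignoreR1 = 0L, ignoreR2 = 0L) {
  obj <- methods::new("TrimPolicy", ignoreR1 = as.integer(ignoreR1),
                      ignoreR2 = as.integer(ignoreR2))
  methods::validObject(obj)
  obj
}

# long-format informative calls with per-read keep flags after trimming
.informativeCalls <- function(fragset, trim = TrimPolicy()) {
  cl <- fragset@calls
  inf <- cl$call %in% c("C", "T")
  k1 <- inf & !is.na(cl$r1pos) & cl$r1pos >= trim@ignoreR1
  k2 <- inf & !is.na(cl$r2pos) & cl$r2pos >= trim@ignoreR2
  list(calls = cl, keep1 = k1, keep2 = k2)
}

#' Extract per-CpG-site methylation counts
#'
#' Counts methylated (\code{"C"}) and total informative calls per CpG site,
#' after trimming read 5' ends per the \linkS4class{TrimPolicy}. When
#' \code{dedupOverlap} is TRUE (the \code{--no_overlap} behaviour), a CpG
#' covered by both mates of a pair counts once, the read-1 call winning;
#' otherwise it counts once per covering read.
#'
#' @param fragset a \linkS4class{FragmentSet}.
#' @param trim a \linkS4class{TrimPolicy}.
#' @param dedupOverlap logical.
#' @return a sorted \code{GRanges} of CpG sites (width 2, anchored at the
#'   forward-strand C) with mcols \code{n_meth}, \code{n_total} and
#'   \code{meth_fraction}.
#' @export
extractSiteCounts <- function(fragset, trim = TrimPolicy(),
                              dedupOverlap = TRUE) {
  ic <- .informativeCalls(fragset, trim)
  cl <- ic$calls
  w <- if (dedupOverlap) as.integer(ic$keep1 | ic$keep2)
       else as.integer(ic$keep1) + as.integer(ic$keep2)
  use <- w > 0L
  chrom <- as.character(GenomicRanges::seqnames(
    fragset@fragments))[cl$frag[use]]
  pos <- cl$pos[use]
  meth <- (cl$call[use] == "C") * w[use]
  key <- paste0(chrom, ":", pos)
  nm <- rowsum(meth, key, reorder = FALSE)
  nt <- rowsum(w[use], key, reorder = FALSE)
  first <- !duplicated(key)
  gr <- GenomicRanges::GRanges(chrom[first],
          IRanges::IRanges(start = pos[first], width = 2L))
  S4Vectors::mcols(gr)$n_meth <- as.integer(nm[match(key[first],
                                                     rownames(nm)), 1])
  S4Vectors::mcols(gr)$n_total <- as.integer(nt[match(key[first],
                                                      rownames(nt)), 1])
  gr <- GenomicRanges::sort(gr)
  S4Vectors::mcols(gr)$meth_fraction <-
    S4Vectors::mcols(gr)$n_meth / S4Vectors::mcols(gr)$n_total
  gr
}

#' Global CpG methylation
#'
#' Pooled fraction: sum of methylated calls over sum of informative calls.
#'
#' @param counts site counts from [extractSiteCounts()].
#' @return a fraction in [0, 1].
#' @export
globalMethylation <- function(counts) {
  nt <- sum(S4Vectors::mcols(counts)$n_total)
  if (nt == 0) stop("no informative CpG calls; global methylation undefined")
  sum(S4Vectors::mcols(counts)$n_meth) / nt
}

#' Global CHH methylation
#'
#' Apparent methylation in the CHH context (H = A, C or T). Near zero in
#' human DNA, so this fraction is dominated by conversion failure and is a
#' standard conversion-quality proxy.
#'
#' @param fragset a \linkS4class{FragmentSet}.
#' @return a fraction in [0, 1].
#' @export
chhMethylation <- function(fragset) {
  mc <- S4Vectors::mcols(fragset@fragments)
  tot <- sum(mc$chhTotalCalls)
  if (tot == 0) stop("no CHH calls present")
  sum(mc$chhMethCalls) / tot
}

#' Within-read M-bias profile
#'
#' Methylation fraction over all CpG calls at each bp position of read 1 or
#' read 2, computed pre-trimming (its role is diagnostic: the trim policy is
#' chosen by looking at this profile). Positions with zero calls are
#' reported as NA, never 0.
#'
#' @param fragset a \linkS4class{FragmentSet}.
#' @param readNumber 1 or 2.
#' @return a data.frame with columns \code{read}, \code{position} (0-based
#'   bp from the read's 5' end), \code{n_meth}, \code{n_total},
#'   \code{meth_fraction}.
#' @export
mbias <- function(fragset, readNumber = 1L) {
  stopifnot(readNumber %in% c(1L, 2L))
  cl <- fragset@calls
  rpos <- if (readNumber == 1L) cl$r1pos else cl$r2pos
  inf <- cl$call %in% c("C", "T") & !is.na(rpos)
  rl <- fragset@readLength
  nTot <- tabulate(rpos[inf] + 1L, nbins = rl)
  nMeth <- tabulate(rpos[inf][cl$call[inf] == "C"] + 1L, nbins = rl)
  data.frame(read = readNumber, position = 0:(rl - 1L),
             n_meth = nMeth, n_total = nTot,
             meth_fraction = ifelse(nTot > 0, nMeth / nTot, NA_real_))
}

#' M-bias flatness check
#'
#' A profile is "flat" when every defined position's methylation fraction
#' lies within \code{z} binomial standard errors of the pooled mean (the
#' expected picture for a library preparation with no positional artifact).
#'
#' @param profile output of [mbias()].
#' @param z standard-error multiplier (default 3).
#' @return list: \code{flat} (logical), \code{maxZ} (largest absolute
#'   z-score across positions), \code{mean} (pooled methylation).
#' @export
mbiasFlatness <- function(profile, z = 3) {
  ok <- profile$n_total > 0
  m <- sum(profile$n_meth[ok]) / sum(profile$n_total[ok])
  se <- sqrt(m * (1 - m) / profile$n_total[ok])
  zs <- abs(profile$meth_fraction[ok] - m) / se
  list(flat = all(zs <= z), maxZ = max(zs), mean = m)
}

#' M-bias monotone-trend check over the fill-in region
#'
#' Fits an isotonic (monotone non-decreasing) regression to the profile
#' over \code{positions} and compares its residual sum of squares with that
#' of the flat fit. A dsLP read-2 profile shaped by end-repair fill-in is
#' accepted when the isotonic fit absorbs nearly all the positional
#' variation (\code{rssIso <= rssTol * rssFlat}) and rises by at least
#' \code{minRise}.
#'
#' @param profile output of [mbias()].
#' @param positions 0-based read positions to test (default: first 25 bp).
#' @param rssTol,minRise acceptance parameters.
#' @return list: \code{monotone} (logical), \code{rssIso}, \code{rssFlat},
#'   \code{rise}.
#' @export
mbiasMonotone <- function(profile, positions = 0:24, rssTol = 0.2,
                          minRise = 0.05) {
  sub <- profile[profile$position %in% positions & profile$n_total > 0, ]
  y <- sub$meth_fraction
  w <- sub$n_total
  iso <- stats::isoreg(sub$position, y)
  rssIso <- sum(w * (y - iso$yf)^2)
  rssFlat <- sum(w * (y - stats::weighted.mean(y, w))^2)
  rise <- max(iso$yf) - min(iso$yf)
  list(monotone = rssIso <= rssTol * rssFlat && rise >= minRise,
       rssIso = rssIso, rssFlat = rssFlat, rise = rise)
}

#' Conversion QC from spike-in controls
#'
#' Conversion rate = fraction of unmethylated lambda cytosines read as T;
#' protection rate = fraction of methylated pUC19 cytosines read as C.
#'
#' @param spikes a \linkS4class{SpikeinSet}.
#' @return named numeric: \code{conversion_rate}, \code{protection_rate}.
#' @export
conversionQC <- function(spikes) {
  if (length(spikes@lambdaCalls) == 0L || length(spikes@puc19Calls) == 0L)
    stop("empty spike-in set")
  c(conversion_rate = mean(spikes@lambdaCalls == "T"),
    protection_rate = mean(spikes@puc19Calls == "C"))
}
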