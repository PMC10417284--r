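#' @include AllClasses.R
NULL

#' Jagged Index-Unmethylated (JI-U)
#'
#' \deqn{JI\mbox{-}U = (M1 - M2) / M1 \times 100}
#'
#' \code{M1} pools all CpG calls in the first \code{window} bp from the 5'
#' end of read 1; \code{M2} pools the read-2 window at the fragment's 3'
#' terminus. End repair in dsLP libraries fills jagged 5' overhangs with
#' unmethylated cytosines precisely in that second window, so JI-U grows
#' with the frequency and length of jagged ends; in ssLP libraries (no end
#' repair) it stays near 0 regardless of jaggedness.
#'
#' Both readings of the "M2" window are computed: the primary one is the
#' first \code{window} sequenced bp of read 2 (read-2 positions
#' \code{[0, window)}, covering the fragment's 3' end -- where fill-in
#' lands); \code{m2Alt}/\code{jiUAlt} use the final \code{window} sequencing
#' cycles of read 2 instead (positions \code{[readLength - window,
#' readLength)}). See the vignette for why the first is the index-defining
#' one.
#'
#' Aggregation is pooled-call (sum calls across reads, then one ratio), not
#' a mean of per-read ratios, for stability at low per-read CpG counts.
#' With \code{M1 = 0} or fewer than \code{minCalls} calls in a window the
#' result is explicitly undefined (\code{defined = FALSE}, values NA) --
#' never silently 0.
#'
#' @param fragset a \linkS4class{FragmentSet}.
#' @param window window width in bp (default 30).
#' @param minCalls minimum pooled calls per window (default 50).
#' @return a \linkS4class{JaggedIndexResult}.
#' @examples
#' atl <- makeToyAtlas(2, 10, seed = 1, calibrateN = 1000)
#' cfg <- SimConfig(c(tissue1 = 1), nFragments = 4000, library = "dsLP",
#'                  jagProb = 0.8, jagMean = 25, seed = 3)
#' jaggedIndexU(fragments(simulateSample(cfg, atl$site)))
#' @export
jaggedIndexU <- function(fragset, window = 30L, minCalls = 50L) {
  rl <- fragset@readLength
  if (window > rl) stop("window must fit within the read length")
  cl <- fragset@calls
  inf <- cl$call %in% c("C", "T")
  meth <- cl$call == "C"

  in1 <- inf & !is.na(cl$r1pos) & cl$r1pos < window
  in2 <- inf & !is.na(cl$r2pos) & cl$r2pos < window
  in2a <- inf & !is.na(cl$r2pos) & cl$r2pos >= rl - window
  n1 <- sum(in1); n2 <- sum(in2); n2a <- sum(in2a)
  m1 <- if (n1) mean(meth[in1]) else NA_real_
  m2 <- if (n2) mean(meth[in2]) else NA_real_
  m2a <- if (n2a) mean(meth[in2a]) else NA_real_

  defined <- n1 >= minCalls && n2 >= minCalls && !is.na(m1) && m1 > 0
  ji <- if (defined) (m1 - m2) / m1 * 100 else NA_real_
  jia <- if (defined && n2a >= minCalls) (m1 - m2a) / m1 * 100 else NA_real_
  methods::new("JaggedIndexResult",
               m1 = m1, m2 = m2, m2Alt = m2a, jiU = ji, jiUAlt = jia,
               nCalls1 = as.integer(n1), nCalls2 = as.integer(n2),
               nCalls2Alt = as.integer(n2a), window = as.integer(window),
               minCalls = as.integer(minCalls), defined = defined)
}
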