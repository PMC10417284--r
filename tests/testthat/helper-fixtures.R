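# shared fixtures, memoised so expensive atlases are built once per run
.fixtureEnv <- new.env()

testAtlas <- function(calibrateN = 5000L) {
  key <- paste0("atl", calibrateN)
  if (is.null(.fixtureEnv[[key]]))
    .fixtureEnv[[key]] <- makeToyAtlas(3, 30, seed = 101,
                                       calibrateN = calibrateN)
  .fixtureEnv[[key]]
}

# single-chromosome atlas with constant beta (degenerate Bernoulli checks)
constAtlas <- function(beta = 1, nSites = 40L, tissues = c("A", "B"),
                       spacing = 12L) {
  pos <- 1000L + spacing * (seq_len(nSites) - 1L)
  m <- matrix(beta, nrow = nSites, ncol = length(tissues),
              dimnames = list(NULL, tissues))
  ReferenceAtlas("chrS", pos - 1L, m)
}

# hand-build a FragmentSet from a long call table (data.frame with frag,
# pos, call, repair, r1pos, r2pos)
fsFromCalls <- function(calls, chrom = "chrS", readLength = 100L,
                        library = "ssLP") {
  calls <- as.data.frame(calls)
  if (is.null(calls$repair)) calls$repair <- FALSE
  if (is.null(calls$r1pos)) calls$r1pos <- NA_integer_
  if (is.null(calls$r2pos)) calls$r2pos <- NA_integer_
  nfrag <- if (nrow(calls)) max(calls$frag) else 0L
  rng <- vapply(seq_len(nfrag), function(i) {
    p <- calls$pos[calls$frag == i]
    if (!length(p)) c(1L, 2L) else c(min(p), max(p) + 1L)
  }, integer(2))
  gr <- if (nfrag == 0L) GenomicRanges::GRanges()
        else GenomicRanges::GRanges(chrom,
               IRanges::IRanges(start = rng[1, ], end = rng[2, ]))
  FragmentSet(gr, calls, readLength = readLength, library = library)
}

perfectConfig <- function(mixture, nFragments, library = "ssLP",
                          jagProb = 0, jagMean = 1, seed = 1L, ...) {
  SimConfig(mixture = mixture, nFragments = nFragments, library = library,
            jagProb = jagProb, jagMean = max(1, jagMean),
            conversionRate = 1, protectionRate = 1, chhMeth = 0,
            seed = seed, ...)
}

# FragmentSet with prescribed pooled window methylation: nC/nT calls in the
# read-1 5' window and the read-2 fragment-3'-end window (JI-U fixtures)
jiFixture <- function(m1C, m1T, m2C, m2T, readLength = 100L) {
  n1 <- m1C + m1T; n2 <- m2C + m2T
  cl <- data.frame(
    frag = seq_len(n1 + n2),
    pos = 100L + 2L * seq_len(n1 + n2),
    call = c(rep("C", m1C), rep("T", m1T), rep("C", m2C), rep("T", m2T)),
    repair = FALSE,
    r1pos = c(rep(0:29, length.out = n1), rep(NA_integer_, n2)),
    r2pos = c(rep(NA_integer_, n1), rep(0:29, length.out = n2)))
  fsFromCalls(cl, readLength = readLength)
}
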