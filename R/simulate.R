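#' @include AllClasses.R
NULL

#' Create a simulation configuration
#'
#' Defaults encode a plasma-like cfDNA sample sequenced 2 x 100 bp after
#' enzymatic conversion: fragment lengths ~ N(165, 20) truncated at 50 bp
#' (mononucleosomal cfDNA), conversion rate 0.994 and protection rate 0.966
#' (the spike-in performance of the single-stranded kit), background CHH
#' methylation 0.003, and a moderate jagged-end model (30% of ends carry a
#' 5' overhang of mean 8 bp). See [fluidPreset()] for the plasma-like /
#' urine-like presets used in scenario grids.
#'
#' @param mixture named numeric vector of tissue proportions (must sum to 1).
#' @param nFragments number of fragments to simulate.
#' @param fragMean,fragSd,fragMin fragment-length model (bp).
#' @param jagProb probability a fragment end carries a 5' overhang.
#' @param jagMean mean 5' overhang length in bp.
#' @param jagDist overhang length distribution, \code{"geometric"}
#'   (default) or \code{"fixed"}.
#' @param library \code{"ssLP"} (single-stranded, splint ligation, no end
#'   repair) or \code{"dsLP"} (double-stranded, end repair with unmethylated
#'   fill-in).
#' @param conversionRate P(unmethylated C read as T).
#' @param protectionRate P(methylated C read as C).
#' @param chhMeth background CHH methylation fraction.
#' @param chhPerFragment CHH cytosines simulated per fragment.
#' @param readLength read length in bp (> 30).
#' @param seed integer RNG seed; equal configs give bit-identical samples.
#' @return a validated \linkS4class{SimConfig}.
#' @examples
#' SimConfig(c(liver = 0.2, blood = 0.8), nFragments = 1000, seed = 7)
#' @export
SimConfig <- function(mixture, nFragments = 10000L,
                      fragMean = 165, fragSd = 20, fragMin = 50,
                      jagProb = 0.3, jagMean = 8,
                      jagDist = c("geometric", "fixed"),
                      library = c("ssLP", "dsLP"),
                      conversionRate = 0.994, protectionRate = 0.966,
                      chhMeth = 0.003, chhPerFragment = 10L,
                      readLength = 100L, seed = 1L) {
  library <- match.arg(library)
  jagDist <- match.arg(jagDist)
  obj <- methods::new("SimConfig",
    mixture = mixture, nFragments = as.integer(nFragments),
    fragMean = fragMean, fragSd = fragSd, fragMin = fragMin,
    jagProb = jagProb, jagMean = jagMean, jagDist = jagDist,
    library = library,
    conversionRate = conversionRate, protectionRate = protectionRate,
    chhMeth = chhMeth, chhPerFragment = as.integer(chhPerFragment),
    readLength = as.integer(readLength), seed = as.integer(seed))
  methods::validObject(obj)
  obj
}

#' Construct a FragmentSet from a call table
#'
#' Low-level constructor, mainly useful for tests and for [readPat()].
#'
#' @param fragments \code{GRanges} of molecules (see
#'   \linkS4class{FragmentSet} for required mcols; missing ones are filled
#'   with defaults).
#' @param calls \code{DataFrame}/data.frame with columns \code{frag},
#'   \code{pos}, \code{call}, \code{repair}, \code{r1pos}, \code{r2pos}.
#' @param readLength integer bp.
#' @param library \code{"ssLP"} or \code{"dsLP"}.
#' @return a validated \linkS4class{FragmentSet}.
#' @export
FragmentSet <- function(fragments, calls, readLength = 100L,
                        library = "ssLP") {
  calls <- S4Vectors::DataFrame(calls)
  mc <- S4Vectors::mcols(fragments)
  nf <- length(fragments)
  if (is.null(mc$tissue)) mc$tissue <- rep(NA_character_, nf)
  if (is.null(mc$strandRead)) mc$strandRead <- rep("top", nf)
  if (is.null(mc$molStart)) mc$molStart <- GenomicRanges::start(fragments)
  if (is.null(mc$molEnd)) mc$molEnd <- GenomicRanges::end(fragments) + 1L
  if (is.null(mc$chhMethCalls)) mc$chhMethCalls <- rep(0L, nf)
  if (is.null(mc$chhTotalCalls)) mc$chhTotalCalls <- rep(0L, nf)
  S4Vectors::mcols(fragments) <- mc
  obj <- methods::new("FragmentSet", fragments = fragments, calls = calls,
                      readLength = as.integer(readLength), library = library)
  methods::validObject(obj)
  obj
}

#' Draw cfDNA fragments with latent tissue-specific methylation
#'
#' Each fragment's tissue of origin is drawn from the mixture; its length
#' from the truncated normal length model; its position uniformly over the
#' atlas territory (so every CpG site sees the same expected coverage).
#' Every covered CpG's latent methylation state is Bernoulli with the
#' atlas methylation fraction of the fragment's tissue; both strands of the
#' duplex carry this identical truth. Uses the ambient RNG stream
#' ([simulateSample()] seeds it from the config).
#'
#' @param config a \linkS4class{SimConfig}.
#' @param atlas a \linkS4class{ReferenceAtlas}; mixture names must be a
#'   subset of its tissues.
#' @return a \linkS4class{RawFragments} object.
#' @export
sampleFragments <- function(config, atlas) {
  tissues <- names(config@mixture)
  unknown <- setdiff(tissues, atlasTissues(atlas))
  if (length(unknown))
    stop("mixture references unknown tissue(s): ",
         paste(unknown, collapse = ", "))
  n <- config@nFragments
  sites <- atlasSites(atlas)
  sitePos <- GenomicRanges::start(sites)        # 1-based C positions
  chromLev <- as.character(GenomicRanges::seqnames(sites))
  if (length(unique(chromLev)) > 1L)
    stop("the simulator expects a single-chromosome atlas")
  chrom <- chromLev[1]
  beta <- atlasBeta(atlas)

  if (n == 0L) {
    fr <- GenomicRanges::GRanges()
    S4Vectors::mcols(fr)$tissue <- character(0)
    return(methods::new("RawFragments", fragments = fr,
                        calls = S4Vectors::DataFrame(
                          frag = integer(0), siteIdx = integer(0),
                          pos = integer(0), meth = logical(0))))
  }

  tIdx <- sample.int(length(tissues), n, replace = TRUE,
                     prob = config@mixture)
  len <- pmax(as.integer(round(stats::rnorm(n, config@fragMean,
                                            config@fragSd))),
              as.integer(config@fragMin))
  gmin <- min(sitePos); gmax <- max(sitePos)
  fstart <- as.integer(floor(stats::runif(n, gmin - len + 1, gmax + 1)))
  fend <- fstart + len                          # half-open

  first <- findInterval(fstart - 0.5, sitePos) + 1L
  last <- findInterval(fend - 1.5, sitePos)     # need pos+1 <= fend-1
  k <- pmax(0L, last - first + 1L)
  frag <- rep.int(seq_len(n), k)
  siteIdx <- sequence(k, from = first)
  pos <- sitePos[siteIdx]
  p <- beta[cbind(siteIdx, match(tissues[tIdx[frag]], colnames(beta)))]
  p[is.na(p)] <- 0.5   # missing reference value: uninformative coin
  meth <- stats::runif(length(p)) < p

  fr <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(start = fstart, width = len))
  S4Vectors::mcols(fr)$tissue <- tissues[tIdx]
  methods::new("RawFragments", fragments = fr,
               calls = S4Vectors::DataFrame(frag = frag, siteIdx = siteIdx,
                                            pos = pos, meth = meth))
}

#' Annotate fragments with jagged 5' overhangs
#'
#' Each duplex end independently carries a 5' overhang with probability
#' \code{jagProb}; overhang lengths are 1 + Geometric (mean \code{jagMean};
#' or exactly \code{round(jagMean)} bp when \code{jagDist = "fixed"}),
#' truncated at fragment length - 1. The left-end overhang belongs to the
#' top strand (its 5' terminus is there) and leaves the bottom strand's 3'
#' end recessed; mirrored for the right end.
#'
#' @param raw a \linkS4class{RawFragments} from [sampleFragments()].
#' @param jagProb,jagMean,jagDist overhang model parameters.
#' @return \code{raw} with integer mcols \code{jagL}, \code{jagR} added.
#' @export
applyJaggedEnds <- function(raw, jagProb, jagMean,
                            jagDist = c("geometric", "fixed")) {
  jagDist <- match.arg(jagDist)
  fr <- raw@fragments
  n <- length(fr)
  len <- GenomicRanges::width(fr)
  if (n == 0L) {
    S4Vectors::mcols(fr)$jagL <- integer(0)
    S4Vectors::mcols(fr)$jagR <- integer(0)
    raw@fragments <- fr
    return(raw)
  }
  drawJag <- function() {
    flag <- stats::runif(n) < jagProb
    L <- if (jagDist == "fixed") rep.int(as.integer(round(jagMean)), n)
         else 1L + stats::rgeom(n, prob = 1 / jagMean)
    as.integer(ifelse(flag, pmin(L, len - 1L), 0L))
  }
  S4Vectors::mcols(fr)$jagL <- drawJag()
  S4Vectors::mcols(fr)$jagR <- drawJag()
  raw@fragments <- fr
  raw
}

#' Library preparation: end repair (dsLP) or strand-wise ligation (ssLP)
#'
#' One sequenced molecule is produced per fragment, from a uniformly chosen
#' strand. Under \code{dsLP} the recessed 3' ends are filled in across the
#' overhang region with unmethylated cytosines: the molecule spans the whole
#' fragment and every CpG whose reported base was synthesized during fill-in
#' is flagged \code{repair = TRUE} and enters conversion as unmethylated.
#' Under \code{ssLP} the duplex is denatured and the chosen strand becomes a
#' molecule of its own (possibly 3'-recessed) extent; nothing is altered and
#' no repair flags are set. 3' overhangs are never created by the jag model,
#' so dsLP 3'-overhang digestion is a no-op here (documented design choice:
#' digestion drops positions and cannot alter methylation).
#'
#' @param raw a \linkS4class{RawFragments} from [applyJaggedEnds()].
#' @param method \code{"ssLP"} or \code{"dsLP"}.
#' @return \code{raw} with molecule bounds and strand choice on the
#'   fragments, and \code{repair}/\code{methEff} columns on the calls.
#' @export
libraryPrep <- function(raw, method = c("ssLP", "dsLP")) {
  method <- match.arg(method)
  fr <- raw@fragments
  n <- length(fr)
  cl <- raw@calls
  if (n == 0L) {
    S4Vectors::mcols(fr)$strandRead <- character(0)
    S4Vectors::mcols(fr)$molStart <- integer(0)
    S4Vectors::mcols(fr)$molEnd <- integer(0)
    cl$repair <- logical(0); cl$methEff <- logical(0)
    raw@fragments <- fr; raw@calls <- cl
    return(raw)
  }
  mc <- S4Vectors::mcols(fr)
  if (is.null(mc$jagL)) stop("fragments lack overhang annotations; ",
                             "run applyJaggedEnds() first")
  fstart <- GenomicRanges::start(fr)
  fend <- fstart + GenomicRanges::width(fr)     # half-open
  strandRead <- ifelse(stats::runif(n) < 0.5, "top", "bottom")
  top <- strandRead == "top"
  if (method == "dsLP") {
    molS <- fstart
    molE <- fend
    # the sequenced strand's 3' end was filled across the opposite overhang
    fillFrom <- ifelse(top, fend - mc$jagR, fstart)          # [fillFrom,
    fillTo <- ifelse(top, fend, fstart + mc$jagL)            #  fillTo)
    repair <- cl$pos >= fillFrom[cl$frag] & cl$pos < fillTo[cl$frag]
  } else {
    molS <- as.integer(ifelse(top, fstart, fstart + mc$jagL))
    molE <- as.integer(ifelse(top, fend - mc$jagR, fend))
    repair <- rep.int(FALSE, nrow(cl))
  }
  mc$strandRead <- strandRead
  mc$molStart <- as.integer(molS)
  mc$molEnd <- as.integer(molE)
  S4Vectors::mcols(fr) <- mc
  cl$repair <- repair
  cl$methEff <- cl$meth & !repair
  raw@fragments <- fr
  raw@calls <- cl
  raw
}

#' Enzymatic conversion and paired-end readout
#'
#' Per cytosine: a methylated C is reported \code{"C"} with probability
#' \code{protectionRate} (else \code{"T"}); an unmethylated C -- including
#' every repair-synthesized one -- is reported \code{"T"} with probability
#' \code{conversionRate} (else \code{"C"}). Read 1 covers the first
#' \code{readLength} bp from the molecule's 5' end, read 2 the first
#' \code{readLength} bp from its 3' end (the mate's sequencing start);
#' positions covered by neither read are reported \code{"."}. CHH cytosines
#' are simulated per fragment with methylation probability \code{chhMeth}
#' through the same channel.
#'
#' @param raw a \linkS4class{RawFragments} from [libraryPrep()].
#' @param config the \linkS4class{SimConfig}.
#' @return a \linkS4class{FragmentSet}.
#' @export
convertAndRead <- function(raw, config) {
  fr <- raw@fragments
  cl <- raw@calls
  n <- length(fr)
  rl <- config@readLength
  if (n == 0L) {
    return(FragmentSet(fr, S4Vectors::DataFrame(
      frag = integer(0), pos = integer(0), call = character(0),
      repair = logical(0), r1pos = integer(0), r2pos = integer(0)),
      readLength = rl, library = config@library))
  }
  mc <- S4Vectors::mcols(fr)
  if (is.null(cl$methEff)) stop("run libraryPrep() first")
  molS <- mc$molStart[cl$frag]
  molE <- mc$molEnd[cl$frag]
  top <- mc$strandRead[cl$frag] == "top"
  r1 <- as.integer(ifelse(top, cl$pos - molS, (molE - 1L) - cl$pos))
  r2 <- as.integer(ifelse(top, (molE - 1L) - cl$pos, cl$pos - molS))
  onMol <- cl$pos >= molS & cl$pos <= molE - 2L
  c1 <- onMol & r1 >= 0L & r1 < rl
  c2 <- onMol & r2 >= 0L & r2 < rl
  covered <- c1 | c2

  u <- stats::runif(nrow(cl))      # one draw per cytosine, covered or not
  pC <- ifelse(cl$methEff, config@protectionRate, 1 - config@conversionRate)
  call <- ifelse(covered, ifelse(u < pC, "C", "T"), ".")

  pChh <- config@chhMeth * config@protectionRate +
    (1 - config@chhMeth) * (1 - config@conversionRate)
  mc$chhMethCalls <- stats::rbinom(n, config@chhPerFragment, pChh)
  mc$chhTotalCalls <- rep.int(config@chhPerFragment, n)
  S4Vectors::mcols(fr) <- mc

  calls <- S4Vectors::DataFrame(
    frag = cl$frag, pos = cl$pos, call = call,
    repair = cl$repair & covered,
    r1pos = ifelse(c1, r1, NA_integer_),
    r2pos = ifelse(c2, r2, NA_integer_))
  FragmentSet(fr, calls, readLength = rl, library = config@library)
}

#' Simulate conversion-control spike-ins
#'
#' Unmethylated lambda cytosines and fully methylated pUC19 cytosines pushed
#' through the conversion channel. Default counts keep the protocol's
#' 20:1 lambda:pUC19 spike-in mass ratio.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param nLambda,nPuc19 cytosine call counts (> 0).
#' @return a \linkS4class{SpikeinSet}.
#' @export
simulateSpikeins <- function(config, nLambda = 20000L, nPuc19 = 1000L) {
  if (nLambda <= 0 || nPuc19 <= 0) stop("spike-in counts must be > 0")
  lam <- ifelse(stats::runif(nLambda) < config@conversionRate, "T", "C")
  puc <- ifelse(stats::runif(nPuc19) < config@protectionRate, "C", "T")
  methods::new("SpikeinSet", lambdaCalls = lam, puc19Calls = puc)
}

#' End-to-end simulation of one sequenced cfDNA sample
#'
#' Seeds the RNG from \code{config@seed} and composes
#' [sampleFragments()] -> [applyJaggedEnds()] -> [libraryPrep()] ->
#' [convertAndRead()] -> [simulateSpikeins()]. All randomness flows from
#' this one seeded stream: equal configs give bit-identical datasets, and
#' two configs differing only in \code{library} consume the stream in the
#' same order (so with \code{jagProb = 0} their call multisets are
#' identical).
#'
#' @param config a \linkS4class{SimConfig}.
#' @param siteAtlas a \linkS4class{ReferenceAtlas}.
#' @param nLambda,nPuc19 spike-in call counts.
#' @return a \linkS4class{SampleDataset}.
#' @examples
#' atl <- makeToyAtlas(3, 10, seed = 1, calibrateN = 2000)
#' cfg <- SimConfig(c(tissue1 = 0.6, tissue2 = 0.3, tissue3 = 0.1),
#'                  nFragments = 2000, seed = 11)
#' simulateSample(cfg, atl$site)
#' @export
simulateSample <- function(config, siteAtlas, nLambda = 20000L,
                           nPuc19 = 1000L) {
  methods::validObject(config)
  set.seed(config@seed)
  raw <- sampleFragments(config, siteAtlas)
  raw <- applyJaggedEnds(raw, config@jagProb, config@jagMean,
                         config@jagDist)
  raw <- libraryPrep(raw, config@library)
  fs <- convertAndRead(raw, config)
  sp <- simulateSpikeins(config, nLambda, nPuc19)
  counts <- table(factor(S4Vectors::mcols(fs@fragments)$tissue,
                         levels = names(config@mixture)))
  methods::new("SampleDataset", fragments = fs, spikeins = sp,
               config = config,
               realizedCounts = stats::setNames(as.integer(counts),
                                                names(counts)))
}

#' Down-sample a dataset to a target fragment count
#'
#' Uniform subsample without replacement (the in-silico analogue of
#' down-sampling BAMs to equal average coverage before comparing library
#' preparations). Spike-ins and the generative config are retained.
#'
#' @param dataset a \linkS4class{SampleDataset}.
#' @param targetN fragments to keep (<= current count).
#' @param seed integer seed for the subsample.
#' @return a \linkS4class{SampleDataset} with \code{targetN} fragments.
#' @export
downsampleSample <- function(dataset, targetN, seed = 1L) {
  fs <- dataset@fragments
  n <- length(fs@fragments)
  targetN <- as.integer(targetN)
  if (targetN > n) stop("targetN exceeds current fragment count")
  if (targetN == n) return(dataset)
  set.seed(as.integer(seed))
  keep <- sort(sample.int(n, targetN))
  newIdx <- integer(n); newIdx[keep] <- seq_len(targetN)
  cl <- fs@calls[fs@calls$frag %in% keep, , drop = FALSE]
  cl$frag <- newIdx[cl$frag]
  fr <- fs@fragments[keep]
  out <- methods::new("FragmentSet", fragments = fr, calls = cl,
                      readLength = fs@readLength, library = fs@library)
  counts <- table(factor(S4Vectors::mcols(fr)$tissue,
                         levels = names(dataset@config@mixture)))
  methods::new("SampleDataset", fragments = out,
               spikeins = dataset@spikeins, config = dataset@config,
               realizedCounts = stats::setNames(as.integer(counts),
                                                names(counts)))
}
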