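#' @include AllClasses.R
NULL

#' Construct a site-based reference methylation atlas
#'
#' @param chrom character vector of chromosome labels, one per CpG site.
#' @param pos integer vector of 0-based positions of the C of each CpG
#'   dinucleotide on the forward strand (reverse-strand calls are collapsed
#'   onto this position).
#' @param beta numeric matrix, sites x tissues, methylation fractions in
#'   [0, 1]; NA marks a missing reference value.
#' @param tissues character vector of tissue names (defaults to
#'   \code{colnames(beta)}).
#' @return a validated \linkS4class{ReferenceAtlas}; rows are sorted by
#'   (chrom, pos). A warning is issued when there are fewer sites than
#'   tissues (under-determined deconvolution).
#' @examples
#' ra <- ReferenceAtlas(rep("chr1", 3), c(10L, 30L, 50L),
#'                      cbind(liver = c(0.1, 0.9, 0.9),
#'                            blood = c(0.9, 0.1, 0.9)))
#' atlasTissues(ra)
#' @export
ReferenceAtlas <- function(chrom, pos, beta, tissues = colnames(beta)) {
  beta <- as.matrix(beta)
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  stopifnot(length(chrom) == length(pos), nrow(beta) == length(pos))
  if (is.null(tissues)) stop("tissue names are required")
  colnames(beta) <- tissues
  if (any(pos < 0)) stop("positions must be >= 0")
  o <- order(chrom, pos)
  gr <- GenomicRanges::GRanges(chrom[o],
                               IRanges::IRanges(start = pos[o] + 1L,
                                                width = 2L))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = beta[o, , drop = FALSE]), rowRanges = gr)
  obj <- methods::new("ReferenceAtlas", se)
  methods::validObject(obj)
  if (nrow(obj) < ncol(obj))
    warning("fewer sites than tissues: deconvolution is under-determined")
  obj
}

#' Construct a fragment-level marker-block atlas
#'
#' @param blocks \code{GRanges} of marker blocks with metadata columns
#'   \code{target_cell_type} and \code{cpg_count}.
#' @param u_ref numeric matrix, blocks x cell types, reference U-fragment
#'   fractions in [0, 1].
#' @param cell_types character vector of cell-type names (defaults to
#'   \code{colnames(u_ref)}).
#' @return a validated \linkS4class{UFractionAtlas}.
#' @export
UFractionAtlas <- function(blocks, u_ref, cell_types = colnames(u_ref)) {
  u_ref <- as.matrix(u_ref)
  stopifnot(length(blocks) == nrow(u_ref))
  if (is.null(cell_types)) stop("cell-type names are required")
  colnames(u_ref) <- cell_types
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(u_ref = u_ref), rowRanges = blocks)
  obj <- methods::new("UFractionAtlas", se)
  methods::validObject(obj)
  obj
}

# files are 0-based half-open (BED convention); in-memory GRanges are 1-based
.openText <- function(path) if (grepl("\\.gz$", path)) gzfile(path) else file(path)

#' Read / write a site atlas as TSV
#'
#' Tab-separated with a header row: columns \code{chrom}, \code{pos}
#' (0-based C position) and one column per tissue; \code{"."} encodes a
#' missing methylation value. Gzip-compressed files (\code{*.gz}) are
#' handled transparently.
#'
#' @param path file path.
#' @return \code{readSiteAtlas()}: a \linkS4class{ReferenceAtlas};
#'   \code{writeSiteAtlas()}: \code{path}, invisibly.
#' @export
readSiteAtlas <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          na.strings = ".", check.names = FALSE,
                          colClasses = NA)
  if (ncol(df) < 3L || !identical(names(df)[1:2], c("chrom", "pos")))
    stop("site atlas must have columns chrom, pos, then one per tissue: ",
         path)
  pos <- suppressWarnings(as.integer(df$pos))
  bad <- which(is.na(pos) & !is.na(df$pos))
  if (length(bad))
    stop(sprintf("malformed pos at line %d of %s", bad[1] + 1L, path))
  beta <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(beta) <- "double"
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    bad <- which(apply(beta < 0 | beta > 1, 1, any, na.rm = TRUE))[1]
    stop(sprintf("beta outside [0, 1] at line %d of %s", bad + 1L, path))
  }
  ReferenceAtlas(as.character(df$chrom), pos, beta)
}

#' @rdname readSiteAtlas
#' @param atlas a \linkS4class{ReferenceAtlas}.
#' @export
writeSiteAtlas <- function(atlas, path) {
  gr <- atlasSites(atlas)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   pos = GenomicRanges::start(gr) - 1L,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(atlasBeta(atlas), check.names = FALSE))
  con <- .openText(path); open(con, "w"); on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a marker-block atlas (BED4 + companion U-fraction TSV)
#'
#' The BED file is 0-based half-open with columns chrom, start, end,
#' target_cell_type (no header). The companion TSV has a header row of
#' cell-type names preceded by a \code{cpg_count} column; row order must
#' match the BED file.
#'
#' @param bedPath,uRefPath file paths (gzip transparently supported).
#' @return \code{readMarkerBlocks()}: a \linkS4class{UFractionAtlas}.
#' @export
readMarkerBlocks <- function(bedPath, uRefPath) {
  bed <- utils::read.delim(bedPath, header = FALSE, sep = "\t",
                           col.names = c("chrom", "start", "end",
                                         "target_cell_type"))
  if (any(bed$start >= bed$end))
    stop("BED block with start >= end: line ",
         which(bed$start >= bed$end)[1])
  uref <- utils::read.delim(uRefPath, header = TRUE, sep = "\t",
                            check.names = FALSE)
  if (!"cpg_count" %in% names(uref))
    stop("u_ref TSV must have a cpg_count column")
  if (nrow(uref) != nrow(bed))
    stop(sprintf("block-count mismatch: %d BED blocks vs %d u_ref rows",
                 nrow(bed), nrow(uref)))
  u <- as.matrix(uref[, setdiff(names(uref), "cpg_count"), drop = FALSE])
  storage.mode(u) <- "double"
  gr <- GenomicRanges::GRanges(bed$chrom,
                               IRanges::IRanges(start = bed$start + 1L,
                                                end = bed$end))
  S4Vectors::mcols(gr)$target_cell_type <- as.character(bed$target_cell_type)
  S4Vectors::mcols(gr)$cpg_count <- as.integer(uref$cpg_count)
  UFractionAtlas(gr, u)
}

#' @rdname readMarkerBlocks
#' @param atlas a \linkS4class{UFractionAtlas}.
#' @export
writeMarkerBlocks <- function(atlas, bedPath, uRefPath) {
  gr <- markerBlocks(atlas)
  bed <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    target_cell_type = S4Vectors::mcols(gr)$target_cell_type)
  con <- .openText(bedPath); open(con, "w")
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  uref <- cbind(data.frame(cpg_count = S4Vectors::mcols(gr)$cpg_count),
                as.data.frame(uRef(atlas), check.names = FALSE))
  con <- .openText(uRefPath); open(con, "w")
  utils::write.table(uref, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(c(bedPath, uRefPath))
}

#' Build a matched pair of toy reference atlases
#'
#' Constructs a synthetic genome of \code{nTissues} marker blocks on one
#' chromosome, each block holding \code{nSitesPerTissue} CpG sites at fixed
#' spacing. Tissue specificity is encoded as hypomethylation: in its own
#' block a tissue has methylation \code{lowBeta}, everywhere else
#' \code{highBeta} (the fragment-level method counts Unmethylated fragments,
#' so hypomethylated markers keep the two atlases mutually consistent). The
#' site atlas is the beta matrix over all sites; the block atlas's reference
#' U-fractions are *calibrated* by simulating a pure sample per cell type
#' through the same fragment/conversion generative model used for samples
#' (mirroring how real fragment-level atlases are derived from deep
#' sequencing of sorted cells), so they embed the informative-CpG-count
#' distribution and the conversion error channel.
#'
#' @param nTissues number of tissues / cell types (>= 2).
#' @param nSitesPerTissue CpG sites per marker block.
#' @param highBeta,lowBeta background and marker methylation fractions,
#'   \code{0 <= lowBeta < highBeta <= 1}.
#' @param seed integer seed (drives the U-fraction calibration only; the
#'   beta matrix is deterministic).
#' @param spacing,gap bp between CpGs within a block and between blocks.
#' @param calibrateN fragments simulated per pure cell type for the U-ref
#'   calibration.
#' @param uThresh,mThresh,minCpgs U/X/M classification parameters used in
#'   calibration (keep identical to the analysis settings).
#' @param config optional \linkS4class{SimConfig} template whose fragment
#'   and conversion parameters are used for calibration.
#' @return list with elements \code{site} (\linkS4class{ReferenceAtlas}) and
#'   \code{block} (\linkS4class{UFractionAtlas}) over the same coordinates.
#' @examples
#' atl <- makeToyAtlas(3, 10, seed = 1, calibrateN = 2000)
#' dim(atlasBeta(atl$site))
#' @export
makeToyAtlas <- function(nTissues, nSitesPerTissue = 30,
                         highBeta = 0.9, lowBeta = 0.1, seed = 1L,
                         spacing = 12L, gap = 60L,
                         calibrateN = 20000L,
                         uThresh = 0.25, mThresh = 0.75, minCpgs = 3L,
                         config = NULL) {
  if (nTissues < 2) stop("nTissues must be >= 2")
  if (!(lowBeta >= 0 && lowBeta < highBeta && highBeta <= 1))
    stop("need 0 <= lowBeta < highBeta <= 1")
  tissues <- paste0("tissue", seq_len(nTissues))
  span <- spacing * (nSitesPerTissue - 1L)
  block0 <- 1000L + (seq_len(nTissues) - 1L) * (span + gap)
  pos1 <- unlist(lapply(block0, function(b) b + spacing * (0:(nSitesPerTissue - 1L))))
  blockOf <- rep(seq_len(nTissues), each = nSitesPerTissue)
  beta <- matrix(highBeta, nrow = length(pos1), ncol = nTissues,
                 dimnames = list(NULL, tissues))
  for (t in seq_len(nTissues)) beta[blockOf == t, t] <- lowBeta
  site <- ReferenceAtlas("chrS", pos1 - 1L, beta)

  blocks <- GenomicRanges::GRanges("chrS",
    IRanges::IRanges(start = block0, end = block0 + span + 1L))
  S4Vectors::mcols(blocks)$target_cell_type <- tissues
  S4Vectors::mcols(blocks)$cpg_count <- nSitesPerTissue

  # calibrate reference U-fractions from pure-cell-type simulations
  if (is.null(config))
    config <- SimConfig(mixture = stats::setNames(1, tissues[1]),
                        nFragments = as.integer(calibrateN), seed = seed)
  u <- matrix(NA_real_, nrow = nTissues, ncol = nTissues,
              dimnames = list(NULL, tissues))
  atlProto <- UFractionAtlas(blocks, u)
  for (t in seq_len(nTissues)) {
    cfg <- config
    cfg@mixture <- stats::setNames(1, tissues[t])
    cfg@nFragments <- as.integer(calibrateN)
    cfg@library <- "ssLP"
    cfg@jagProb <- 0
    cfg@seed <- as.integer((seed + 7919L * t) %% .Machine$integer.max)
    ds <- simulateSample(cfg, site)
    cnt <- countUXM(fragments(ds), atlProto, uThresh = uThresh,
                    mThresh = mThresh, minCpgs = minCpgs)
    u[, t] <- cnt$u_fraction
  }
  u[is.na(u)] <- 0
  list(site = site, block = UFractionAtlas(blocks, u))
}
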