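#' @include AllClasses.R
NULL

.fmtIntList <- function(x) {
  vapply(x, function(v) paste(ifelse(is.na(v), ".", as.character(v)),
                              collapse = ","), character(1))
}

.parseIntList <- function(s) {
  lapply(strsplit(s, ",", fixed = TRUE), function(v) {
    v[v == "."] <- NA
    as.integer(v)
  })
}

#' Write / read fragment methylation calls in a PAT-like TSV
#'
#' One row per molecule: \code{chrom}, \code{cpg_index} (1-based index of
#' the first covered CpG in the atlas site list; the pattern then runs over
#' consecutive sites), \code{pattern} (C/T/. string), \code{count} (always
#' 1 here), plus extension columns: \code{repair} (0/1 mask aligned with
#' the pattern), \code{r1pos}/\code{r2pos} (comma lists of read offsets,
#' \code{.} = not covered by that read) and \code{tissue}. Files ending in
#' \code{.gz} are compressed. Fragment metadata other than the tissue label
#' (molecule bounds, strand, CHH counts) is not serialized; [readPat()]
#' reconstructs nominal fragment intervals from the covered sites.
#'
#' @param fragset a \linkS4class{FragmentSet} whose calls lie on
#'   consecutive atlas sites (true for all simulated sets).
#' @param path output TSV path.
#' @param atlas the \linkS4class{ReferenceAtlas} supplying the CpG site
#'   indexing.
#' @return \code{writePat()}: \code{path} invisibly; \code{readPat()}: a
#'   \linkS4class{FragmentSet}.
#' @export
writePat <- function(fragset, path, atlas) {
  sites <- atlasSites(atlas)
  keyS <- paste0(as.character(GenomicRanges::seqnames(sites)), ":",
                 GenomicRanges::start(sites))
  cl <- fragset@calls
  fr <- fragset@fragments
  chromOf <- as.character(GenomicRanges::seqnames(fr))
  keyC <- paste0(chromOf[cl$frag], ":", cl$pos)
  sIdx <- match(keyC, keyS)
  if (anyNA(sIdx)) stop("calls at positions absent from the atlas")
  o <- order(cl$frag, cl$pos)
  f <- cl$frag[o]
  byFrag <- split(seq_along(o), f)
  firstIdx <- vapply(byFrag, function(i) sIdx[o[i]][1], integer(1))
  consec <- vapply(byFrag, function(i) {
    s <- sIdx[o[i]]
    all(diff(s) == 1L)
  }, logical(1))
  if (!all(consec))
    stop("fragments must cover consecutive atlas sites for PAT output")
  pat <- vapply(byFrag, function(i) paste(cl$call[o[i]], collapse = ""),
                character(1))
  rep_ <- vapply(byFrag, function(i)
    paste(as.integer(cl$repair[o[i]]), collapse = ""), character(1))
  r1 <- .fmtIntList(lapply(byFrag, function(i) cl$r1pos[o[i]]))
  r2 <- .fmtIntList(lapply(byFrag, function(i) cl$r2pos[o[i]]))
  fid <- as.integer(names(byFrag))
  df <- data.frame(chrom = chromOf[fid], cpg_index = firstIdx,
                   pattern = pat, count = 1L, repair = rep_,
                   r1pos = r1, r2pos = r2,
                   tissue = S4Vectors::mcols(fr)$tissue[fid])
  con <- .openText(path); open(con, "w"); on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePat
#' @param readLength read length of the sequencing run; when NULL it is
#'   inferred as the largest observed read offset + 1.
#' @export
readPat <- function(path, atlas, readLength = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c(pattern = "character",
                                         repair = "character"))
  sites <- atlasSites(atlas)
  sitePos <- GenomicRanges::start(sites)
  spl <- strsplit(df$pattern, "", fixed = TRUE)
  k <- lengths(spl)
  frag <- rep.int(seq_len(nrow(df)), k)
  sIdx <- sequence(k, from = df$cpg_index)
  if (any(sIdx > length(sitePos)))
    stop("cpg_index + pattern extends past the atlas site list")
  calls <- S4Vectors::DataFrame(
    frag = frag,
    pos = sitePos[sIdx],
    call = unlist(spl),
    repair = unlist(strsplit(df$repair, "", fixed = TRUE)) == "1",
    r1pos = unlist(.parseIntList(df$r1pos)),
    r2pos = unlist(.parseIntList(df$r2pos)))
  starts <- sitePos[df$cpg_index]
  ends <- sitePos[df$cpg_index + k - 1L] + 1L
  fr <- GenomicRanges::GRanges(df$chrom,
          IRanges::IRanges(start = starts, end = ends))
  S4Vectors::mcols(fr)$tissue <- as.character(df$tissue)
  lib <- if (any(calls$repair)) "dsLP" else "ssLP"
  if (is.null(readLength))
    readLength <- max(c(calls$r1pos, calls$r2pos, 0L), na.rm = TRUE) + 1L
  FragmentSet(fr, calls, readLength = as.integer(readLength), library = lib)
}
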