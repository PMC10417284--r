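test_that("site atlas TSV round-trips and validates", {
  ra <- ReferenceAtlas(rep("chr1", 3), c(10L, 30L, 50L),
                       cbind(liver = c(0.1, 0.9, NA),
                             blood = c(0.9, 0.1, 0.5)))
  expect_equal(dim(atlasBeta(ra)), c(3L, 2L))

  tmp <- tempfile(fileext = ".tsv")
  writeSiteAtlas(ra, tmp)
  ra2 <- readSiteAtlas(tmp)
  expect_equal(atlasBeta(ra2), atlasBeta(ra))
  expect_equal(GenomicRanges::start(atlasSites(ra2)),
               GenomicRanges::start(atlasSites(ra)))

  # gzip dialect
  tmpgz <- tempfile(fileext = ".tsv.gz")
  writeSiteAtlas(ra, tmpgz)
  expect_equal(atlasBeta(readSiteAtlas(tmpgz)), atlasBeta(ra))

  # invariant violations
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tliver", "chr1\t10\t1.2"), bad)
  expect_error(readSiteAtlas(bad), "outside \\[0, 1\\]")
  expect_error(ReferenceAtlas("chr1", c(5L, 5L),
                              cbind(a = c(0.1, 0.2), b = c(0.1, 0.2))),
               "duplicated")
})

test_that("marker-block atlas round-trips and validates", {
  gr <- GenomicRanges::GRanges("chr2",
          IRanges::IRanges(start = c(101, 501, 901, 1301),
                           end = c(200, 600, 1000, 1400)))
  S4Vectors::mcols(gr)$target_cell_type <- c("ct1", "ct2", "ct3", "ct1")
  S4Vectors::mcols(gr)$cpg_count <- c(5L, 4L, 6L, 3L)
  u <- matrix(runif(12), 4, 3, dimnames = list(NULL, c("ct1", "ct2", "ct3")))
  ua <- UFractionAtlas(gr, u)
  expect_equal(dim(uRef(ua)), c(4L, 3L))

  bed <- tempfile(fileext = ".bed"); uref <- tempfile(fileext = ".tsv")
  writeMarkerBlocks(ua, bed, uref)
  ua2 <- readMarkerBlocks(bed, uref)
  expect_equal(uRef(ua2), uRef(ua))
  expect_equal(GenomicRanges::start(markerBlocks(ua2)),
               GenomicRanges::start(markerBlocks(ua)))
  expect_equal(S4Vectors::mcols(markerBlocks(ua2))$target_cell_type,
               S4Vectors::mcols(markerBlocks(ua))$target_cell_type)

  # start >= end and block-count mismatch
  badBed <- tempfile(); writeLines("chr2\t100\t100\tct1", badBed)
  expect_error(readMarkerBlocks(badBed, uref), "start >= end")
  shortU <- tempfile()
  writeLines(c("cpg_count\tct1\tct2\tct3", "5\t0.1\t0.2\t0.3"), shortU)
  expect_error(readMarkerBlocks(bed, shortU), "mismatch")
})

test_that("makeToyAtlas builds matched, deterministic, full-rank atlases", {
  atl <- makeToyAtlas(3, 10, highBeta = 0.9, lowBeta = 0.1, seed = 1,
                      calibrateN = 1000)
  expect_equal(dim(atlasBeta(atl$site)), c(30L, 3L))
  expect_equal(qr(atlasBeta(atl$site))$rank, 3L)
  expect_equal(length(markerBlocks(atl$block)), 3L)

  # same seed twice -> identical (beta and calibrated u_ref)
  atl2 <- makeToyAtlas(3, 10, highBeta = 0.9, lowBeta = 0.1, seed = 1,
                       calibrateN = 1000)
  expect_identical(atlasBeta(atl$site), atlasBeta(atl2$site))
  expect_identical(uRef(atl$block), uRef(atl2$block))

  # condition number finite and stable across seeds (beta is deterministic)
  kappas <- vapply(1:4, function(s)
    kappa(atlasBeta(makeToyAtlas(3, 10, seed = s, calibrateN = 500)$site),
          exact = TRUE), numeric(1))
  expect_true(all(is.finite(kappas)))
  expect_equal(max(kappas), min(kappas))

  expect_error(makeToyAtlas(1, 10), "nTissues")
  expect_error(makeToyAtlas(3, 10, highBeta = 0.2, lowBeta = 0.5),
               "lowBeta")
})

test_that("toy atlases satisfy all invariants over random valid shapes", {
  set.seed(7)
  for (i in 1:5) {
    nt <- sample(2:4, 1)
    ns <- sample(5:15, 1)
    hb <- runif(1, 0.6, 1)
    lb <- runif(1, 0, 0.3)
    atl <- makeToyAtlas(nt, ns, highBeta = hb, lowBeta = lb, seed = i,
                        calibrateN = 500)
    expect_s4_class(atl$site, "ReferenceAtlas")
    expect_s4_class(atl$block, "UFractionAtlas")
    expect_true(all(atlasBeta(atl$site) >= 0 & atlasBeta(atl$site) <= 1))
    expect_true(all(uRef(atl$block) >= 0 & uRef(atl$block) <= 1))
    expect_true(validObject(atl$site))
    expect_true(validObject(atl$block))
  }
})
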