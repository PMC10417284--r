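test_that("site counts: patterns, overlap dedup and call conservation", {
  # one fragment, pattern "CCT" at three sites
  cl <- data.frame(frag = 1L, pos = c(100L, 112L, 124L),
                   call = c("C", "C", "T"), repair = FALSE,
                   r1pos = c(0L, 12L, 24L), r2pos = NA_integer_)
  fs <- fsFromCalls(cl)
  cnt <- extractSiteCounts(fs)
  expect_equal(S4Vectors::mcols(cnt)$n_meth, c(1L, 1L, 0L))
  expect_equal(S4Vectors::mcols(cnt)$n_total, c(1L, 1L, 1L))

  # site covered by both mates: counts once with dedup, twice without
  cl2 <- cl; cl2$r2pos <- c(40L, NA_integer_, NA_integer_)
  fs2 <- fsFromCalls(cl2)
  expect_equal(S4Vectors::mcols(extractSiteCounts(fs2))$n_total[1], 1L)
  expect_equal(S4Vectors::mcols(extractSiteCounts(
    fs2, dedupOverlap = FALSE))$n_total[1], 2L)

  # trimming drops read positions below the ignore threshold
  cntT <- extractSiteCounts(fs, TrimPolicy(2L, 0L))
  expect_equal(length(cntT), 2L)   # the r1pos = 0 call is gone

  # with (0,0) trim and no overlaps every call is conserved
  atl <- testAtlas()
  cfg <- SimConfig(c(tissue1 = 1), nFragments = 2000, seed = 6)
  fss <- fragments(simulateSample(cfg, atl$site))
  cls <- callTable(fss)
  inf <- cls$call %in% c("C", "T")
  cntS <- extractSiteCounts(fss, TrimPolicy(0L, 0L), dedupOverlap = TRUE)
  expect_equal(sum(S4Vectors::mcols(cntS)$n_total), sum(inf))
})

test_that("pooled site fraction recovers the simulated beta", {
  atl <- constAtlas(beta = 0.8, tissues = "A")
  cfg <- perfectConfig(c(A = 1), 10000, seed = 17)
  cnt <- extractSiteCounts(fragments(simulateSample(cfg, atl)))
  n <- sum(S4Vectors::mcols(cnt)$n_total)
  expect_gt(n, 1e5)
  expect_lt(abs(globalMethylation(cnt) - 0.8), 3 * sqrt(0.8 * 0.2 / n))
})

test_that("global methylation is a pooled ratio with an explicit zero guard", {
  gr <- GenomicRanges::GRanges("chrS", IRanges::IRanges(1:2, width = 2))
  S4Vectors::mcols(gr)$n_meth <- c(50L, 25L)
  S4Vectors::mcols(gr)$n_total <- c(60L, 40L)
  expect_equal(globalMethylation(gr), 0.75)
  S4Vectors::mcols(gr)$n_meth <- c(60L, 40L)
  expect_equal(globalMethylation(gr), 1.0)
  S4Vectors::mcols(gr)$n_total <- c(0L, 0L)
  S4Vectors::mcols(gr)$n_meth <- c(0L, 0L)
  expect_error(globalMethylation(gr), "no informative")
})

test_that("CHH methylation tracks its simulated rate and the conversion floor", {
  atl <- constAtlas()
  # zero CHH methylation, perfect conversion -> exactly 0
  cfg0 <- perfectConfig(c(A = 1), 2000, seed = 3)
  expect_equal(chhMethylation(fragments(simulateSample(cfg0, atl))), 0)

  # rate recovery at chhMeth = 0.005
  cfg1 <- SimConfig(c(A = 1), 10000, chhMeth = 0.005, conversionRate = 1,
                    protectionRate = 1, jagProb = 0, seed = 9)
  v <- chhMethylation(fragments(simulateSample(cfg1, atl)))
  expect_lt(abs(v - 0.005), 3 * sqrt(0.005 * 0.995 / 1e5))

  # conversion-failure floor at chhMeth = 0
  cfg2 <- SimConfig(c(A = 1), 10000, chhMeth = 0, conversionRate = 0.99,
                    protectionRate = 1, jagProb = 0, seed = 9)
  v2 <- chhMethylation(fragments(simulateSample(cfg2, atl)))
  expect_lt(abs(v2 - 0.01), 3 * sqrt(0.01 * 0.99 / 1e5))

  cfgN <- SimConfig(c(A = 1), 100, chhPerFragment = 0L, seed = 1)
  expect_error(chhMethylation(fragments(simulateSample(cfgN, atl))),
               "no CHH")
})

test_that("M-bias profiles: single-call anatomy and call accounting", {
  cl <- data.frame(frag = 1L, pos = 100L, call = "C", repair = FALSE,
                   r1pos = 7L, r2pos = NA_integer_)
  pr <- mbias(fsFromCalls(cl), 1L)
  expect_equal(pr$meth_fraction[pr$position == 7], 1.0)
  expect_true(all(is.na(pr$meth_fraction[pr$position != 7])))

  atl <- testAtlas()
  cfg <- SimConfig(c(tissue1 = 1), nFragments = 3000, library = "dsLP",
                   jagProb = 0.5, jagMean = 10, seed = 31)
  fs <- fragments(simulateSample(cfg, atl$site))
  cl2 <- callTable(fs)
  inf <- cl2$call %in% c("C", "T")
  p1 <- mbias(fs, 1L); p2 <- mbias(fs, 2L)
  expect_equal(sum(p1$n_total) + sum(p2$n_total),
               sum(inf & !is.na(cl2$r1pos)) + sum(inf & !is.na(cl2$r2pos)))
})

test_that("conversion QC estimates the channel rates", {
  cfg <- SimConfig(c(A = 1), 10, conversionRate = 0.995,
                   protectionRate = 0.95, seed = 1)
  set.seed(100)
  sp <- simulateSpikeins(cfg, 1e5, 1e5)
  qc <- conversionQC(sp)
  expect_lt(abs(qc[["conversion_rate"]] - 0.995),
            3 * sqrt(0.995 * 0.005 / 1e5))
  expect_lt(abs(qc[["protection_rate"]] - 0.95),
            3 * sqrt(0.95 * 0.05 / 1e5))

  perfect <- methods::new("SpikeinSet", lambdaCalls = rep("T", 10),
                          puc19Calls = rep("C", 10))
  expect_equal(unname(conversionQC(perfect)), c(1, 1))
  empty <- methods::new("SpikeinSet", lambdaCalls = character(0),
                        puc19Calls = rep("C", 10))
  expect_error(conversionQC(empty), "empty")
})

test_that("global methylation is invariant to fragment order and stable under downsampling", {
  atl <- testAtlas()
  cfg <- SimConfig(c(tissue1 = 0.5, tissue2 = 0.5), nFragments = 6000,
                   seed = 41)
  ds <- simulateSample(cfg, atl$site)
  fs <- fragments(ds)
  gm <- globalMethylation(extractSiteCounts(fs))

  # permute fragments (and remap call indices accordingly)
  n <- length(fs@fragments)
  set.seed(1); perm <- sample.int(n)
  inv <- integer(n); inv[perm] <- seq_len(n)
  cl <- callTable(fs); cl$frag <- inv[cl$frag]
  fsP <- FragmentSet(fs@fragments[perm], cl, fs@readLength, fs@library)
  expect_equal(globalMethylation(extractSiteCounts(fsP)), gm)

  # downsampling changes it only within sampling noise
  gmHalf <- globalMethylation(extractSiteCounts(
    fragments(downsampleSample(ds, 3000, seed = 2))))
  expect_lt(abs(gmHalf - gm), 0.02)
})
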