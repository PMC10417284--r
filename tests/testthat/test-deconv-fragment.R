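test_that("U/X/M classification follows the threshold rule with inclusive bounds", {
  lab <- classifyFragment(c("CCCC", "TTTC", "CT..", "CTTC", "TTTT", "..."))
  expect_equal(as.character(lab),
               c("M", "U", "NA_class", "X", "U", "NA_class"))
  # "TTTC": 1/4 = 0.25, boundary inclusive -> U
  expect_equal(as.character(classifyFragment("TTTC")), "U")
  # 3/4 = 0.75 boundary -> M
  expect_equal(as.character(classifyFragment("CCCT")), "M")
  # '.' positions never count
  expect_identical(classifyFragment("C.T.C.T."),
                   classifyFragment("CTCT"))
})

test_that("countUXM tallies per block and handles empty input", {
  atl <- testAtlas()
  empty <- fsFromCalls(data.frame(frag = integer(0), pos = integer(0),
                                  call = character(0), repair = logical(0),
                                  r1pos = integer(0), r2pos = integer(0)))
  cnt0 <- countUXM(empty, atl$block)
  expect_true(all(cnt0$n_U + cnt0$n_X + cnt0$n_M + cnt0$n_NA == 0L))

  # one fully unmethylated fragment inside block 1
  b1 <- markerBlocks(atl$block)[1]
  pos <- GenomicRanges::start(b1) + c(0L, 12L, 24L)
  cl <- data.frame(frag = 1L, pos = pos, call = "T", repair = FALSE,
                   r1pos = c(0L, 12L, 24L), r2pos = NA_integer_)
  cnt1 <- countUXM(fsFromCalls(cl), atl$block)
  expect_equal(cnt1$n_U[1], 1L)
  expect_equal(sum(cnt1$n_U), 1L)
})

test_that("pure-tissue samples give a near-unit U-fraction at their own markers", {
  atl <- testAtlas()
  cfg <- SimConfig(c(tissue2 = 1), nFragments = 8000, seed = 61)
  cnt <- countUXM(fragments(simulateSample(cfg, atl$site)), atl$block)
  expect_gt(cnt$u_fraction[2], 0.85)       # own marker block: mostly U
  expect_lt(max(cnt$u_fraction[c(1, 3)]), 0.02)
})

test_that("NNLS fragment deconvolution inverts exact and noisy mixtures", {
  atl <- testAtlas()
  U <- uRef(atl$block)
  mkCounts <- function(u) S4Vectors::DataFrame(
    n_U = as.integer(round(u * 1000)), n_X = 0L,
    n_M = as.integer(round((1 - u) * 1000)), n_NA = 0L, u_fraction = u)

  # u_obs = U e_k -> e_k
  r <- deconvolveUXM(mkCounts(drop(U %*% c(0, 1, 0))), atl$block)
  expect_equal(unname(proportions(r)), c(0, 1, 0), tolerance = 1e-6)

  # two-component mixture, consistent system -> exact within 1e-3
  r2 <- deconvolveUXM(mkCounts(drop(U %*% c(0.7, 0, 0.3))), atl$block)
  expect_equal(unname(proportions(r2)), c(0.7, 0, 0.3), tolerance = 1e-3)
  expect_equal(sum(proportions(r2)), 1.0)

  # fewer passing blocks than cell types -> error
  short <- mkCounts(drop(U %*% c(1, 0, 0)))
  short$n_U[1:2] <- 0L; short$n_M[1:2] <- 0L
  short$u_fraction[1:2] <- NA_real_
  expect_error(deconvolveUXM(short, atl$block), "pass")
})

test_that("end-to-end fragment-level recovery of a three-tissue mixture", {
  atl <- testAtlas()
  cfg <- SimConfig(c(tissue1 = 0.6, tissue2 = 0.3, tissue3 = 0.1),
                   nFragments = 20000, seed = 67)
  fs <- fragments(simulateSample(cfg, atl$site))
  r <- deconvolveUXM(countUXM(fs, atl$block), atl$block)
  expect_lt(max(abs(proportions(r) -
                      c(tissue1 = 0.6, tissue2 = 0.3, tissue3 = 0.1))),
            0.05)
})

test_that("dsLP jag shifts fragment-level proportions toward spurious cell types", {
  atl <- testAtlas()
  shifts <- vapply(1:10, function(s) {
    mix <- c(tissue1 = 0.7, tissue2 = 0.3, tissue3 = 0)
    cfgS <- SimConfig(mix, nFragments = 6000, library = "ssLP",
                      jagProb = 0.8, jagMean = 25, seed = 300 + s)
    cfgD <- cfgS; cfgD@library <- "dsLP"
    pS <- proportions(deconvolveUXM(countUXM(fragments(
      simulateSample(cfgS, atl$site)), atl$block), atl$block))
    pD <- proportions(deconvolveUXM(countUXM(fragments(
      simulateSample(cfgD, atl$site)), atl$block), atl$block))
    # end-repair inflates U fractions everywhere; the absent tissue3 should
    # gain weight under dsLP relative to the matched ssLP run
    pD[["tissue3"]] - pS[["tissue3"]]
  }, numeric(1))
  expect_gte(sum(shifts > 0), 9)
})
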