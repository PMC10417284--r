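test_that("SimConfig validates its parameters", {
  expect_error(SimConfig(c(a = 0.5, b = 0.6)), "sum to 1")
  expect_error(SimConfig(c(a = 1), conversionRate = 1.2), "probability")
  expect_error(SimConfig(c(a = 1), readLength = 30), "readLength")
  expect_s4_class(SimConfig(c(a = 0.4, b = 0.6)), "SimConfig")
})

test_that("fragment origins and methylation follow mixture and atlas", {
  atl <- constAtlas(beta = 1, tissues = c("A", "B"))
  cfg <- perfectConfig(c(A = 1), 500, seed = 3)
  set.seed(cfg@seed)
  raw <- sampleFragments(cfg, atl)
  # degenerate Bernoulli: beta = 1 everywhere -> every latent state methylated
  expect_true(all(raw@calls$meth))
  expect_true(all(S4Vectors::mcols(raw@fragments)$tissue == "A"))

  # unknown tissue in the mixture
  expect_error(sampleFragments(perfectConfig(c(zzz = 1), 10), atl),
               "unknown tissue")

  # realized counts within 3 binomial SDs of the mixture expectation
  cfg2 <- perfectConfig(c(A = 0.5, B = 0.5), 10000, seed = 11)
  ds <- simulateSample(cfg2, atl)
  expect_lt(abs(realizedCounts(ds)[["A"]] - 5000), 3 * sqrt(10000 * 0.25))

  # determinism: same config -> bit-identical sample
  ds2 <- simulateSample(cfg2, atl)
  expect_identical(callTable(fragments(ds)), callTable(fragments(ds2)))
})

test_that("jagged-end model: prevalence, truncation and mean length", {
  atl <- constAtlas()
  cfg <- perfectConfig(c(A = 1), 5000, seed = 5)
  set.seed(1)
  raw <- sampleFragments(cfg, atl)

  set.seed(2)
  r0 <- applyJaggedEnds(raw, 0, 10)
  expect_true(all(S4Vectors::mcols(r0@fragments)$jagL == 0L))
  expect_true(all(S4Vectors::mcols(r0@fragments)$jagR == 0L))

  # constant-length overhangs: every end exactly 20 bp
  set.seed(2)
  rC <- applyJaggedEnds(raw, 1, 20, jagDist = "fixed")
  expect_true(all(S4Vectors::mcols(rC@fragments)$jagL == 20L))
  expect_true(all(S4Vectors::mcols(rC@fragments)$jagR == 20L))

  set.seed(2)
  r1 <- applyJaggedEnds(raw, 1, 10)
  jl <- S4Vectors::mcols(r1@fragments)$jagL
  expect_true(all(jl >= 1L))
  expect_true(all(jl < GenomicRanges::width(r1@fragments)))
  # mean realized overhang ~ distribution mean (truncation negligible here)
  expect_lt(abs(mean(jl) - 10), 3 * sqrt(10 * 9 / length(jl)) + 0.2)
})

test_that("library prep: fill-in flips exactly the overhang CpGs (dsLP), touches nothing (ssLP)", {
  atl <- constAtlas(beta = 1, tissues = "A")
  cfg <- perfectConfig(c(A = 1), 2000, library = "dsLP", jagProb = 1,
                       jagMean = 30, seed = 8)
  ds <- simulateSample(cfg, atl)
  cl <- callTable(fragments(ds))
  inf <- cl$call %in% c("C", "T")
  # truth is fully methylated and conversion is perfect, so a T call can
  # only arise from end-repair fill-in, and every filled CpG must read T
  expect_identical(cl$call[inf] == "T", cl$repair[inf])
  expect_gt(sum(cl$repair), 0)

  # no jag -> no repair
  cfg0 <- perfectConfig(c(A = 1), 500, library = "dsLP", jagProb = 0,
                        seed = 8)
  expect_false(any(callTable(fragments(simulateSample(cfg0, atl)))$repair))

  # ssLP: never any repair, patterns equal latent truth
  cfgS <- perfectConfig(c(A = 1), 2000, library = "ssLP", jagProb = 1,
                        jagMean = 30, seed = 8)
  clS <- callTable(fragments(simulateSample(cfgS, atl)))
  expect_false(any(clS$repair))
  expect_true(all(clS$call[clS$call != "."] == "C"))
})

test_that("conversion channel hits its rates", {
  atl <- constAtlas(beta = 0, tissues = "A")   # all unmethylated
  # inversion limit: conversionRate = 0 reports every unmethylated C as C
  cfg0 <- SimConfig(c(A = 1), 300, conversionRate = 0, protectionRate = 1,
                    jagProb = 0, chhMeth = 0, seed = 2)
  cl <- callTable(fragments(simulateSample(cfg0, atl)))
  expect_true(all(cl$call[cl$call != "."] == "C"))

  # conversion failure floor ~ 1 - conversionRate
  cfg <- SimConfig(c(A = 1), 10000, conversionRate = 0.99,
                   protectionRate = 1, jagProb = 0, chhMeth = 0, seed = 4)
  cl <- callTable(fragments(simulateSample(cfg, atl)))
  inf <- cl$call %in% c("C", "T")
  n <- sum(inf)
  expect_gt(n, 1e5)
  pC <- mean(cl$call[inf] == "C")
  expect_lt(abs(pC - 0.01), 3 * sqrt(0.01 * 0.99 / n))
})

test_that("ssLP and dsLP are identical in the no-jag limit (matched seed)", {
  atl <- testAtlas()
  base <- SimConfig(c(tissue1 = 0.5, tissue2 = 0.3, tissue3 = 0.2),
                    nFragments = 3000, jagProb = 0, seed = 77)
  dsS <- simulateSample(base, atl$site)
  cfgD <- base; cfgD@library <- "dsLP"
  dsD <- simulateSample(cfgD, atl$site)
  expect_identical(callTable(fragments(dsS))$call,
                   callTable(fragments(dsD))$call)
  expect_identical(callTable(fragments(dsS))$pos,
                   callTable(fragments(dsD))$pos)
})

test_that("global methylation decreases with jag load under dsLP", {
  atl <- testAtlas()
  gm <- vapply(c(1, 10, 25), function(jm) {
    cfg <- SimConfig(c(tissue1 = 0.5, tissue2 = 0.3, tissue3 = 0.2),
                     nFragments = 20000, library = "dsLP",
                     jagProb = if (jm == 1) 0 else 0.8, jagMean = jm,
                     seed = 55)
    globalMethylation(extractSiteCounts(fragments(simulateSample(cfg,
                                                                atl$site))))
  }, numeric(1))
  expect_true(all(diff(gm) < 0))
})

test_that("repair density concentrates at read-2 5' ends (dsLP geometry)", {
  atl <- testAtlas()
  cfg <- SimConfig(c(tissue1 = 1), nFragments = 10000, library = "dsLP",
                   jagProb = 0.8, jagMean = 25, seed = 21)
  cl <- callTable(fragments(simulateSample(cfg, atl$site)))
  w <- 30L
  r1win <- !is.na(cl$r1pos) & cl$r1pos < w
  r2win <- !is.na(cl$r2pos) & cl$r2pos < w
  expect_gt(mean(cl$repair[r2win]), 5 * mean(cl$repair[r1win]))
})

test_that("empty simulation and downsampling behave", {
  atl <- testAtlas()
  cfg <- SimConfig(c(tissue1 = 1), nFragments = 0, seed = 1)
  ds <- simulateSample(cfg, atl$site)
  expect_equal(length(fragments(ds)@fragments), 0L)

  cfg <- SimConfig(c(tissue1 = 0.5, tissue2 = 0.5), nFragments = 4000,
                   seed = 13)
  ds <- simulateSample(cfg, atl$site)
  expect_identical(downsampleSample(ds, 4000), ds)
  half <- downsampleSample(ds, 2000, seed = 3)
  expect_equal(length(fragments(half)@fragments), 2000L)
  expect_error(downsampleSample(ds, 5000), "exceeds")

  # hypergeometric composition bound
  p <- realizedCounts(ds)[["tissue1"]] / 4000
  sdHyper <- sqrt(2000 * p * (1 - p) * (4000 - 2000) / (4000 - 1))
  expect_lt(abs(realizedCounts(half)[["tissue1"]] - 2000 * p),
            3 * sdHyper + 1)

  # call table consistent after subsetting
  expect_true(validObject(fragments(half)))
})

test_that("spike-in channel is exact in the noiseless limits", {
  cfg <- perfectConfig(c(A = 1), 10)
  set.seed(1)
  sp <- simulateSpikeins(cfg, 500, 500)
  expect_true(all(sp@lambdaCalls == "T"))
  expect_true(all(sp@puc19Calls == "C"))
  expect_error(simulateSpikeins(cfg, 0, 10), "> 0")
})
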