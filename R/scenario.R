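#' @include AllClasses.R
NULL

#' Body-fluid simulation presets
#'
#' Illustrative jagged-end and fragment-length settings for the two fluids:
#' \code{plasma_like} (jag probability 0.3, mean overhang 8 bp, fragment
#' lengths N(165, 20)) and \code{urine_like} (jag probability 0.8, mean
#' overhang 25 bp, shorter and wider fragments N(140, 25)). Chosen so that
#' simulated JI-U and global-methylation contrasts have the ordering and
#' rough magnitudes seen in real plasma vs urine cfDNA; they are stated
#' model inputs, not estimates from data.
#'
#' @param fluid \code{"plasma_like"} or \code{"urine_like"}.
#' @return named list: jagProb, jagMean, fragMean, fragSd, fragMin.
#' @export
fluidPreset <- function(fluid = c("plasma_like", "urine_like")) {
  fluid <- match.arg(fluid)
  switch(fluid,
    plasma_like = list(jagProb = 0.3, jagMean = 8,
                       fragMean = 165, fragSd = 20, fragMin = 50),
    urine_like = list(jagProb = 0.8, jagMean = 25,
                      fragMean = 140, fragSd = 25, fragMin = 50))
}

#' Build the SimConfig for one scenario cell
#'
#' @param fluid,library scenario axes.
#' @param mixture,nFragments,seed forwarded to [SimConfig()].
#' @return a \linkS4class{SimConfig}.
#' @export
scenarioConfig <- function(fluid, library, mixture, nFragments = 20000L,
                           seed = 1L) {
  p <- fluidPreset(fluid)
  SimConfig(mixture = mixture, nFragments = nFragments,
            fragMean = p$fragMean, fragSd = p$fragSd, fragMin = p$fragMin,
            jagProb = p$jagProb, jagMean = p$jagMean, library = library,
            seed = seed)
}

.trimFor <- function(library) {
  if (library == "dsLP") TrimPolicy(2L, 5L) else TrimPolicy(2L, 2L)
}

# all sample-level metrics for one simulated dataset
.runMetrics <- function(ds, siteAtlas, blockAtlas, minCoverage = 1L) {
  fs <- fragments(ds)
  trim <- .trimFor(fs@library)
  counts <- extractSiteCounts(fs, trim = trim)
  qc <- conversionQC(spikeins(ds))
  ji <- jaggedIndexU(fs)
  sb <- sampleBetaFromCounts(counts, siteAtlas, minCoverage = minCoverage)
  site <- deconvolveSite(sb, siteAtlas)
  frag <- NULL
  if (!is.null(blockAtlas)) {
    ux <- countUXM(fs, blockAtlas)
    frag <- tryCatch(deconvolveUXM(ux, blockAtlas), error = function(e) NULL)
  }
  list(globalMeth = globalMethylation(counts),
       chhMeth = chhMethylation(fs),
       conversion = qc[["conversion_rate"]],
       protection = qc[["protection_rate"]],
       jiU = ji, site = site, frag = frag)
}

#' Run the fluid x library scenario grid
#'
#' Reproduces the study design in silico: every combination of fluid preset
#' and library preparation, \code{nReplicates} times. Seeds are matched
#' across libraries within a (fluid, replicate) cell, so ssLP and dsLP see
#' identical fragments and jag draws and differ only in chemistry. All runs
#' use the same fragment count, which is the in-silico form of comparing
#' libraries at equal average coverage (see [downsampleSample()] for
#' unequal inputs). Site counts are extracted with trim (2, 2) for ssLP and
#' (2, 5) for dsLP.
#'
#' @param siteAtlas,blockAtlas the reference atlases (block atlas may be
#'   NULL to skip fragment-level deconvolution).
#' @param mixture named tissue mixture simulated in every run.
#' @param nReplicates replicates per scenario cell.
#' @param nFragments fragments per run.
#' @param baseSeed integer; run seeds are derived deterministically.
#' @param fluids,libraries scenario axes (defaults: full 2 x 2 grid).
#' @return a \linkS4class{RunReport}.
#' @export
runScenarioGrid <- function(siteAtlas, blockAtlas = NULL, mixture,
                            nReplicates = 3L, nFragments = 20000L,
                            baseSeed = 1L,
                            fluids = c("plasma_like", "urine_like"),
                            libraries = c("ssLP", "dsLP")) {
  metrics <- list()
  siteP <- list()
  cellP <- list()
  hashes <- character(0)
  for (fl in fluids) {
    for (rep_ in seq_len(nReplicates)) {
      seed <- as.integer((baseSeed + 7817L * match(fl, fluids) +
                            131L * rep_) %% .Machine$integer.max)
      for (lib in libraries) {
        cfg <- scenarioConfig(fl, lib, mixture, nFragments, seed)
        ds <- simulateSample(cfg, siteAtlas)
        met <- .runMetrics(ds, siteAtlas, blockAtlas)
        id <- sprintf("%s.%s.r%d", fl, lib, rep_)
        hashes[id] <- rlang::hash(cfg)
        metrics[[id]] <- data.frame(
          scenario = id, fluid = fl, library = lib, replicate = rep_,
          seed = seed, n_fragments = nFragments,
          global_meth = met$globalMeth, chh_meth = met$chhMeth,
          conversion_rate = met$conversion,
          protection_rate = met$protection,
          m1 = met$jiU@m1, m2 = met$jiU@m2, ji_u = met$jiU@jiU,
          undetermined = undetermined(met$site),
          site_residual = residualNorm(met$site))
        sp <- proportions(met$site)
        siteP[[id]] <- data.frame(scenario = id, fluid = fl, library = lib,
                                  replicate = rep_, tissue = names(sp),
                                  proportion = unname(sp))
        if (!is.null(met$frag)) {
          cp <- proportions(met$frag)
          cellP[[id]] <- data.frame(scenario = id, fluid = fl,
                                    library = lib, replicate = rep_,
                                    cell_type = names(cp),
                                    proportion = unname(cp),
                                    raw_weight = unname(rawWeights(met$frag)))
        }
      }
    }
  }
  bindDF <- function(x) if (length(x))
    do.call(rbind, c(x, list(make.row.names = FALSE))) else data.frame()
  methods::new("RunReport",
    metrics = bindDF(metrics),
    siteProportions = bindDF(siteP),
    cellProportions = bindDF(cellP),
    meta = list(baseSeed = baseSeed, nReplicates = nReplicates,
                nFragments = nFragments, configHash = as.list(hashes),
                package = as.character(utils::packageVersion("cfMethSim"))))
}

#' Write / read a run report
#'
#' Writes the metric and proportion tables as TSV, a JSON summary that
#' round-trips through [readReport()], and (optionally) diagnostic plots
#' (global methylation and JI-U by scenario) as a PDF.
#'
#' @param report a \linkS4class{RunReport}.
#' @param dir output directory (created if needed).
#' @param plots logical; emit \code{report_plots.pdf} only when TRUE.
#' @return \code{writeReport()}: the directory, invisibly;
#'   \code{readReport()}: a \linkS4class{RunReport} rebuilt from the JSON
#'   summary.
#' @export
writeReport <- function(report, dir, plots = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report@metrics, file.path(dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report@siteProportions,
                     file.path(dir, "site_proportions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report@cellProportions,
                     file.path(dir, "cell_proportions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(metrics = report@metrics, siteProportions = report@siteProportions,
         cellProportions = report@cellProportions, meta = report@meta),
    file.path(dir, "summary.json"), digits = NA, auto_unbox = TRUE)
  if (plots && nrow(report@metrics)) {
    grDevices::pdf(file.path(dir, "report_plots.pdf"), width = 7, height = 5)
    on.exit(grDevices::dev.off())
    m <- report@metrics
    graphics::boxplot(global_meth ~ paste(fluid, library), data = m,
                      ylab = "global CpG methylation", las = 2,
                      main = "Global methylation by scenario")
    if (any(!is.na(m$ji_u)))
      graphics::boxplot(ji_u ~ paste(fluid, library), data = m,
                        ylab = "JI-U (%)", las = 2,
                        main = "Jagged Index-Unmethylated")
  }
  invisible(dir)
}

#' @rdname writeReport
#' @export
readReport <- function(dir) {
  js <- jsonlite::read_json(file.path(dir, "summary.json"),
                            simplifyVector = TRUE)
  toDF <- function(x) if (is.null(x) || length(x) == 0) data.frame()
                      else as.data.frame(x)
  methods::new("RunReport", metrics = toDF(js$metrics),
               siteProportions = toDF(js$siteProportions),
               cellProportions = toDF(js$cellProportions),
               meta = as.list(js$meta))
}
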