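#' @include AllClasses.R
NULL

#' Two-sided t-test between two metric vectors
#'
#' Paired or unpaired (classical equal-variance) two-sided t-test, the
#' between-method / between-fluid comparison used throughout the scenario
#' analyses. Degenerate inputs follow an explicit contract: identical
#' paired vectors (all differences zero) return p = 1 by convention, while
#' paired differences that are constant but non-zero raise an error (the t
#' statistic is infinite; reporting p = 0 would be a false certainty).
#'
#' @param valuesA,valuesB numeric vectors; equal lengths (>= 2) when
#'   \code{paired}, each of length >= 2 otherwise.
#' @param paired logical.
#' @param metric,groupA,groupB labels carried into the result.
#' @return a \linkS4class{ComparisonResult} (uncorrected: apply
#'   [bonferroniCorrect()] to a family of these).
#' @examples
#' compareMetric(c(1, 2, 3, 4, 6), c(2, 3, 4, 5, 8), paired = TRUE)
#' @export
compareMetric <- function(valuesA, valuesB, paired = FALSE,
                          metric = "metric", groupA = "A", groupB = "B") {
  a <- as.numeric(valuesA); b <- as.numeric(valuesB)
  if (paired) {
    if (length(a) != length(b)) stop("paired vectors must have equal length")
    if (length(a) < 2L) stop("need n >= 2 per group")
    d <- a - b
    if (stats::sd(d) == 0) {
      if (all(d == 0)) {
        tt <- list(statistic = 0, p.value = 1)
      } else {
        stop("degenerate paired input: constant non-zero differences ",
             "(zero variance); t-test undefined")
      }
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
    }
    test <- "paired_t"
  } else {
    if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 per group")
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) tt <- list(statistic = 0, p.value = 1)
      else stop("degenerate unpaired input: both groups constant")
    } else {
      tt <- stats::t.test(a, b, var.equal = TRUE)
    }
    test <- "unpaired_t"
  }
  methods::new("ComparisonResult", metric = metric, groupA = groupA,
               groupB = groupB, test = test,
               tStatistic = unname(as.numeric(tt$statistic)),
               pRaw = as.numeric(tt$p.value),
               pBonferroni = NA_real_, nComparisons = NA_integer_)
}

#' Bonferroni correction across a family of comparisons
#'
#' Each raw p-value is multiplied by the family size and capped at 1; the
#' family size is recorded on every result. The family is whatever list the
#' caller assembles (typically all tissues compared within one analysis) --
#' always log it, since significance depends on it.
#'
#' @param results list of \linkS4class{ComparisonResult}.
#' @return the list with \code{pBonferroni}/\code{nComparisons} filled in.
#' @export
bonferroniCorrect <- function(results) {
  if (length(results) == 0L) stop("empty comparison family")
  if (methods::is(results, "ComparisonResult")) results <- list(results)
  m <- length(results)
  lapply(results, function(r) {
    r@pBonferroni <- min(1, r@pRaw * m)
    r@nComparisons <- as.integer(m)
    methods::validObject(r)
    r
  })
}

#' Significance stars
#'
#' Figure-legend binning: \code{ns} for p > 0.05, \code{*} for
#' 0.01 < p <= 0.05, \code{**} for 0.001 < p <= 0.01, \code{***} for
#' 0.0001 < p <= 0.001, \code{****} for p <= 0.0001.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return character vector of labels.
#' @examples
#' significanceStars(c(0.2, 0.03, 0.005, 5e-4, 1e-5))
#' @export
significanceStars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"),
      right = TRUE) |> as.character()
}

#' Comparison results as a long-format data frame
#'
#' @param results list of \linkS4class{ComparisonResult}.
#' @return data.frame with one row per comparison (metric, groups, test,
#'   t, p_raw, p_bonf, stars).
#' @export
comparisonTable <- function(results) {
  if (methods::is(results, "ComparisonResult")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(metric = r@metric, group_a = r@groupA, group_b = r@groupB,
               test = r@test, t = r@tStatistic, p_raw = r@pRaw,
               p_bonf = r@pBonferroni,
               stars = if (is.na(r@pBonferroni)) NA_character_
                       else significanceStars(r@pBonferroni))
  }))
}
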