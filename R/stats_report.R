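# Statistical comparisons following the study recipe: Shapiro-Wilk per
# group and Levene across groups as recorded diagnostics, then a two-sided
# two-sample t-test (Welch variant when Levene rejects variance
# homogeneity); significance stars at p < 0.05 / 0.01 / 0.001.

#' Significance stars for a p-value
#'
#' Strict thresholds: *** for p < 0.001, ** for p < 0.01, * for p < 0.05,
#' otherwise "ns". Monotone: a smaller p never yields fewer stars.
#'
#' @param p p-value in [0, 1].
#' @return One of "ns", "*", "**", "***".
#' @export
starsForP <- function(p) {
  if (is.na(p)) return("ns")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "ns"
}

.safeShapiro <- function(x) {
  if (length(unique(x)) < 3) return(NA)
  p <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
  if (is.na(p)) NA else p > 0.05
}

#' Compare two groups
#'
#' Runs Shapiro-Wilk normality per group and Levene's test for homogeneity
#' of variances (both recorded as diagnostics), then a two-sided two-sample
#' t-test: pooled-variance when Levene does not reject, Welch otherwise.
#' Both samples identical gives t = 0, p = 1.
#'
#' @param a,b numeric vectors, each of length >= 3.
#' @return A \code{StatResult}.
#' @examples
#' compareGroups(rnorm(10), rnorm(10, 2))
#' @export
compareGroups <- function(a, b) {
  if (length(a) < 3 || length(b) < 3)
    stop("insufficient data: each group needs n >= 3")
  normA <- .safeShapiro(a)
  normB <- .safeShapiro(b)
  lev <- tryCatch({
    g <- factor(rep(c("a", "b"), c(length(a), length(b))))
    p <- car::leveneTest(c(a, b) ~ g)[["Pr(>F)"]][1]
    if (is.na(p)) NA else p > 0.05
  }, error = function(e) NA)
  varEqual <- !isFALSE(lev)   # Welch only when Levene actually rejects
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    stat <- if (mean(a) == mean(b)) 0 else Inf
    p <- if (mean(a) == mean(b)) 1 else 0
    testName <- "two-sample t-test (degenerate: zero variance)"
  } else {
    tt <- stats::t.test(a, b, var.equal = varEqual)
    stat <- unname(tt$statistic)
    p <- tt$p.value
    testName <- if (varEqual) "two-sample t-test (pooled)"
                else "Welch two-sample t-test"
  }
  new("StatResult", testName = testName, statistic = stat, pValue = p,
      nPerGroup = c(length(a), length(b)),
      groupMeans = c(mean(a), mean(b)),
      groupSds = c(stats::sd(a), stats::sd(b)),
      normalityOk = c(isTRUE(normA), isTRUE(normB)),
      varianceHomogeneous = isTRUE(lev) || is.na(lev),
      stars = starsForP(p))
}

.statRow <- function(s) {
  data.frame(test = s@testName, statistic = s@statistic, p_value = s@pValue,
             stars = s@stars, n_a = s@nPerGroup[1], n_b = s@nPerGroup[2],
             mean_a = s@groupMeans[1], sd_a = s@groupSds[1],
             mean_b = s@groupMeans[2], sd_b = s@groupSds[2],
             normality_a = s@normalityOk[1], normality_b = s@normalityOk[2],
             variance_homogeneous = s@varianceHomogeneous)
}

#' Bundle module outputs into a report set
#'
#' Assembles the standard report tables: a thickness table (one row per
#' site), an intensity summary with the dorsal/ventral fold-change and
#' stars, an orientation summary (percent perpendicular / parallel, with the
#' perpendicular-vs-parallel comparison when per-ROI values are available),
#' and a crossing-density summary. All values are reported as mean plus or
#' minus standard deviation. No multiple-testing correction is applied; the
#' number of comparisons performed is recorded.
#'
#' @param thickness list of \code{ThicknessProfile} (optional).
#' @param intensity list with elements \code{a} and \code{b}
#'   (\code{IntensityResult}) to contrast, or a single result (optional).
#' @param orientation output of \code{\link{roiOrientationAnalysis}}
#'   (optional).
#' @param crossings output of \code{\link{crossingDensityRois}} or a
#'   \code{CrossingResult} (optional).
#' @return A \code{ReportSet}: a named list of data.frames with a
#'   \code{comparisons} attribute counting the tests performed.
#' @export
reportBundle <- function(thickness = NULL, intensity = NULL,
                         orientation = NULL, crossings = NULL) {
  if (is.null(thickness) && is.null(intensity) && is.null(orientation) &&
      is.null(crossings))
    stop("at least one upstream result is required")
  out <- list()
  ncomp <- 0L
  if (!is.null(thickness))
    out$thickness <- thicknessTable(thickness)
  if (!is.null(intensity)) {
    if (is.list(intensity) && !is.null(intensity$a)) {
      ct <- intensityContrast(intensity$a, intensity$b)
      out$intensity <- cbind(
        data.frame(surface_a = intensity$a@meta@surface,
                   surface_b = intensity$b@meta@surface,
                   fold_change = ct$fold),
        .statRow(ct$test))
      ncomp <- ncomp + 1L
    } else {
      out$intensity <- data.frame(surface = intensity@meta@surface,
                                  grand_mean = intensity@grandMean,
                                  grand_sd = intensity@grandSd)
    }
  }
  if (!is.null(orientation)) {
    pool <- orientation$pooled
    pp <- vapply(orientation$perRoi, function(o) o@pctPerpendicular, 1.0)
    pl <- vapply(orientation$perRoi, function(o) o@pctParallel, 1.0)
    tab <- data.frame(metric = pool$metric, mean_pct = pool$mean,
                      sd_pct = pool$sd)
    if (sum(stats::complete.cases(cbind(pp, pl))) >= 3) {
      cmp <- compareGroups(pp[!is.na(pp)], pl[!is.na(pl)])
      attr(tab, "perp_vs_parallel") <- .statRow(cmp)
      tab$comparison_stars <- cmp@stars
      ncomp <- ncomp + 1L
    }
    out$orientation <- tab
  }
  if (!is.null(crossings)) {
    if (is(crossings, "CrossingResult")) {
      out$crossings <- data.frame(crossing_count = crossings@crossingCount,
                                  roi_volume_um3 = crossings@roiVolumeUm3,
                                  density_per_um3 = crossings@densityPerUm3)
    } else {
      out$crossings <- data.frame(
        n_rois = length(crossings$perRoi),
        density_mean_per_um3 = crossings$densityMean,
        density_sd_per_um3 = crossings$densitySd)
    }
  }
  attr(out, "comparisons") <- ncomp
  class(out) <- c("ReportSet", "list")
  out
}

#' Write a report set to disk
#'
#' One CSV per section plus a machine-readable JSON summary. Output is
#' deterministic: no timestamps, fixed column order.
#'
#' @param report a \code{ReportSet}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeTables <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(report)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(report[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(lapply(report, function(d) as.list(d)), jp,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, jp)
  invisible(paths)
}
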