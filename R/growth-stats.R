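# Derived growth statistics: relative growth rate, linear-phase onset and
# Tukey-fence outlier screening.

#' Relative growth rate between two days
#'
#' `RGR = (mean(ln W2) - mean(ln W1)) / (t2 - t1)`: the difference of the
#' replicate means of log biomass at the two days, per day. Note the
#' order of operations — logs are taken per replicate, then averaged.
#'
#' @param series `data.frame` with columns `das` and a value column
#'   (replicate rows allowed).
#' @param t1,t2 the two days, `t1 < t2`, both present in the series.
#' @param value_col name of the biomass column.
#' @return the relative growth rate (per day).
#' @export
rgr <- function(series, t1, t2, value_col = "eb_kpix") {
  if (!(t1 < t2)) stop_bad_arg("t1", "must be smaller than t2")
  w1 <- series[[value_col]][series$das == t1]
  w2 <- series[[value_col]][series$das == t2]
  if (!length(w1) || !length(w2))
    stop_bad_arg("t1", "both days must be present in the series")
  if (any(c(w1, w2) <= 0))
    stop_bad_arg(value_col, "biomass must be positive for the log transform")
  (mean(log(w2)) - mean(log(w1))) / (t2 - t1)
}

#' Onset day of the linear growth phase
#'
#' The common comparison day for vigour ranking: the smallest integer day
#' strictly greater than the largest fitted breakpoint across genotypes,
#' so every genotype is past its lag phase from that day onward.
#'
#' @param fits fitted breakpoints: a numeric vector of `X` values, a
#'   `data.frame` with an `X` column ([fit_genotypes()] output), or a
#'   list of `broken_stick` fits.
#' @return integer day (DAS).
#' @export
linear_phase_onset <- function(fits) {
  x <- if (is.numeric(fits)) fits
  else if (is.data.frame(fits)) fits$X
  else vapply(fits, function(f) f$X, numeric(1))
  x <- x[!is.na(x)]
  if (!length(x)) stop_bad_arg("fits", "no breakpoints supplied")
  as.integer(floor(max(x)) + 1L)
}

#' Flag outliers by Tukey's boxplot fences
#'
#' Flags values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles by
#' the linear-interpolation convention (`stats::quantile()` type 7), the
#' screen applied to trait replicates before genotype means are taken.
#'
#' @param values numeric vector, at least 4 values.
#' @return logical vector; `TRUE` marks outliers (`NA` values are never
#'   flagged).
#' @export
detect_outliers <- function(values) {
  if (sum(is.finite(values)) < 4L)
    stop_bad_arg("values", "at least 4 finite values are required")
  q <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE, type = 7)
  iqr <- q[2] - q[1]
  out <- values < q[1] - 1.5 * iqr | values > q[2] + 1.5 * iqr
  out & !is.na(out)
}
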