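# Split-line ("broken-stick") regression with a single breakpoint,
# estimated by profiling the breakpoint on a dense grid.

profile_sse <- function(X, t, y) {
  b <- cbind(1, t - X, pmax(t - X, 0))
  f <- stats::.lm.fit(b, y)
  list(sse = sum(f$residuals^2), coef = f$coefficients)
}

#' Fit the continuous two-phase growth model
#'
#' Fits `y(t) = Y + slope1 * (t - X)` for `t <= X` and
#' `y(t) = Y + slope2 * (t - X)` for `t > X` by least squares, with the
#' two lines constrained to meet at the breakpoint `(X, Y)`. For each
#' candidate breakpoint the model is linear in `(Y, slope1, slope2)` via
#' the basis `{1, t - X, max(t - X, 0)}`, so the breakpoint is profiled:
#' a dense grid (default 0.01 day) between the 2nd and (n-1)th observed
#' days, ties broken toward the smallest `X`, followed by a local
#' golden-section refinement around the best grid point. This keeps the
#' estimator reproducible and directly checkable against a brute-force
#' scan.
#'
#' Perfectly collinear data (a single straight line) are not an error:
#' the fit is returned with `degenerate = TRUE`, both slopes equal to the
#' single-line slope, `X` at the first grid point attaining the minimum
#' SSE, and a warning.
#'
#' @param days numeric vector of observation days (DAS), at least 6,
#'   strictly increasing once sorted.
#' @param values biomass observations (kilopixels), same length.
#' @param grid_step breakpoint grid resolution in days.
#' @param refine logical; refine the grid minimum with [stats::optimize()].
#' @return an object of class `broken_stick`: list with `X`, `Y`,
#'   `slope1`, `slope2`, `adj_r2` (adjusted R-squared with p = 4
#'   parameters), `sse`, `degenerate`, `n`.
#' @export
fit_broken_stick <- function(days, values, grid_step = 0.01, refine = TRUE) {
  if (length(days) != length(values))
    stop_bad_arg("values", "must match 'days' in length")
  ok <- is.finite(days) & is.finite(values)
  days <- days[ok]; values <- values[ok]
  n <- length(days)
  if (n < 6L)
    stop_bad_arg("days", "at least 6 observations are required")
  o <- order(days)
  t <- as.numeric(days[o]); y <- as.numeric(values[o])
  if (any(diff(t) <= 0)) stop_bad_arg("days", "must be strictly increasing")
  # candidate breakpoints keep >= 2 observations on each side
  lo <- t[2]; hi <- t[n - 1L]
  xs <- seq(lo, hi, by = grid_step)
  if (xs[length(xs)] < hi - 1e-12) xs <- c(xs, hi)
  sses <- vapply(xs, function(X) profile_sse(X, t, y)$sse, numeric(1))
  best_sse <- min(sses)
  sst <- sum((y - mean(y))^2)
  tol0 <- max(1e-10 * sst, 1e-12)
  # first grid point attaining the minimum (within numerical tolerance),
  # so ties break toward the smallest breakpoint
  grid_x <- best_x <- xs[which(sses <= best_sse + tol0)[1]]
  best_sse <- sses[which(sses <= best_sse + tol0)[1]]
  # single-line nested model: collinear data flagged as degenerate
  line <- stats::.lm.fit(cbind(1, t), y)
  sse_line <- sum(line$residuals^2)
  degenerate <- sse_line <= best_sse + tol0
  if (!degenerate && refine) {
    opt <- stats::optimize(function(X) profile_sse(X, t, y)$sse,
                           lower = max(lo, grid_x - grid_step),
                           upper = min(hi, grid_x + grid_step), tol = 1e-10)
    if (opt$objective <= best_sse) { best_x <- opt$minimum; best_sse <- opt$objective }
  }
  if (degenerate) {
    warning("data are collinear: single-line fit, breakpoint not identified",
            call. = FALSE)
    sl <- line$coefficients[2]
    fit <- list(X = grid_x, Y = line$coefficients[1] + sl * grid_x,
                slope1 = sl, slope2 = sl, sse = sse_line)
  } else {
    cf <- profile_sse(best_x, t, y)$coef
    fit <- list(X = best_x, Y = cf[1], slope1 = cf[2], slope2 = cf[2] + cf[3],
                sse = best_sse)
  }
  p <- 4L
  r2 <- if (sst > 0) 1 - fit$sse / sst else NA_real_
  adj <- if (is.na(r2) || n - p - 1L <= 0L) NA_real_ else
    1 - (1 - r2) * (n - 1) / (n - p - 1)
  structure(c(lapply(fit, unname),
              list(adj_r2 = adj, degenerate = degenerate, n = n)),
            class = "broken_stick")
}

#' @export
print.broken_stick <- function(x, ...) {
  cat(sprintf(
    "Two-phase linear fit (n = %d)%s\n  breakpoint X = %.2f DAS, Y = %.2f kPix\n  slope1 = %.3f, slope2 = %.3f kPix/day\n  adj R-squared = %.4f, SSE = %.4g\n",
    x$n, if (x$degenerate) " [degenerate: single line]" else "",
    x$X, x$Y, x$slope1, x$slope2, x$adj_r2, x$sse))
  invisible(x)
}

#' Fit the two-phase model per genotype
#'
#' Fits [fit_broken_stick()] to each genotype of a long-format series
#' table, using per-day means over replicates (genotype-level growth
#' trajectories). Genotypes whose series cannot be fitted (for example
#' too few days) are reported as `NA` rows with a warning rather than
#' aborting the batch.
#'
#' @param series `data.frame` with columns `genotype`, `das` and the
#'   value column (replicate column optional).
#' @param value_col name of the value column (default `"eb_kpix"`).
#' @param grid_step breakpoint grid resolution in days.
#' @return a `data.frame` with one row per genotype: `genotype`, `X`,
#'   `Y`, `slope1`, `slope2`, `adj_r2`, `sse`, `degenerate`.
#' @export
fit_genotypes <- function(series, value_col = "eb_kpix", grid_step = 0.01) {
  need <- c("genotype", "das", value_col)
  if (!all(need %in% names(series)))
    stop_bad_arg("series", paste("needs columns", paste(need, collapse = ", ")))
  gts <- unique(series$genotype)
  rows <- lapply(gts, function(g) {
    sub <- series[series$genotype == g & !is.na(series[[value_col]]), ]
    means <- tapply(sub[[value_col]], sub$das, mean)
    days <- as.numeric(names(means))
    fit <- tryCatch(
      suppressWarnings(fit_broken_stick(days, as.numeric(means),
                                        grid_step = grid_step)),
      error = function(e) {
        warning(sprintf("genotype '%s' not fitted: %s", g, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(fit))
      data.frame(genotype = g, X = NA_real_, Y = NA_real_, slope1 = NA_real_,
                 slope2 = NA_real_, adj_r2 = NA_real_, sse = NA_real_,
                 degenerate = NA, stringsAsFactors = FALSE)
    else
      data.frame(genotype = g, X = fit$X, Y = fit$Y, slope1 = fit$slope1,
                 slope2 = fit$slope2, adj_r2 = fit$adj_r2, sse = fit$sse,
                 degenerate = fit$degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
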