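# Generative side of the growth analysis: the continuous two-phase model,
# replicate-level noisy trajectories, and linked field reflectance.

#' Parameters of the continuous two-phase growth model
#'
#' The "broken-stick" model describes seedling biomass accumulation as two
#' straight lines meeting at a breakpoint: a lag phase of slope `s1` up to
#' day `X`, then a linear growth phase of slope `s2`. `Y` is the biomass
#' (kilopixels) at the breakpoint, so the model value is
#' `Y + s1 * (t - X)` for `t <= X` and `Y + s2 * (t - X)` after.
#'
#' @param X breakpoint day (days after sowing, DAS).
#' @param Y biomass at the breakpoint, kilopixels.
#' @param s1,s2 pre-/post-breakpoint slopes, kilopixels per day.
#' @param day_start,day_end integer DAS limits of the observation window;
#'   must bracket `X` strictly.
#' @param cv coefficient of variation of the multiplicative replicate
#'   noise (biomass noise scales with plant size).
#' @param n_reps number of replicate plants.
#' @param seed integer seed for the replicate noise.
#' @param genotype genotype label carried into the simulated series.
#' @return an object of class `growth_params`.
#' @export
growth_params <- function(X, Y, s1, s2, day_start = 11L, day_end = 39L,
                          cv = 0, n_reps = 8L, seed = 1L,
                          genotype = "genotype") {
  if (!(day_start < X && X < day_end))
    stop_bad_arg("X", "breakpoint must lie strictly inside [day_start, day_end]")
  if (s1 <= 0) stop_bad_arg("s1", "pre-breakpoint slope must be positive")
  if (cv < 0) stop_bad_arg("cv", "must be non-negative")
  if (!is_count(n_reps)) stop_bad_arg("n_reps", "must be a positive integer")
  # the model must be positive from the breakpoint onward; a lag line that
  # extrapolates below zero near the window start is tolerated (published
  # split-line fits do this) and truncated at the simulation floor
  days <- seq.int(day_start, day_end)
  m <- broken_stick_value(days, X, Y, s1, s2)
  if (any(m[days >= X] <= 0))
    stop_bad_arg("Y", "model value must stay positive from the breakpoint on")
  structure(list(X = X, Y = Y, s1 = s1, s2 = s2,
                 day_start = as.integer(day_start),
                 day_end = as.integer(day_end), cv = cv,
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 genotype = genotype), class = "growth_params")
}

#' Evaluate the two-phase growth model
#'
#' @param t day (DAS), vectorized.
#' @param X,Y,s1,s2 model parameters, see [growth_params()].
#' @return model biomass at `t`, kilopixels.
#' @export
broken_stick_value <- function(t, X, Y, s1, s2) {
  ifelse(t <= X, Y + s1 * (t - X), Y + s2 * (t - X))
}

#' Simulate replicate growth series from the two-phase model
#'
#' Each replicate observes `m(t) * (1 + cv * e)` at every integer day of
#' the window, with `e` standard normal, truncated at a small positive
#' floor so log-traits stay defined. With `cv = 0` the model curve is
#' reproduced exactly wherever it is positive; lag-phase days on which
#' the model line extrapolates below zero are emitted at the floor.
#'
#' @param params a [growth_params()].
#' @return a `data.frame` with columns `genotype`, `replicate`, `das`,
#'   `eb_kpix`.
#' @export
simulate_growth <- function(params) {
  stopifnot(inherits(params, "growth_params"))
  days <- seq.int(params$day_start, params$day_end)
  m <- broken_stick_value(days, params$X, params$Y, params$s1, params$s2)
  with_seed(params$seed, {
    out <- lapply(seq_len(params$n_reps), function(r) {
      eps <- if (params$cv > 0) stats::rnorm(length(days)) else numeric(length(days))
      data.frame(genotype = params$genotype, replicate = r, das = days,
                 eb_kpix = pmax(m * (1 + params$cv * eps), 1e-6),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Simulate a cohort of genotypes from a parameter table
#'
#' Convenience wrapper running [simulate_growth()] for each row of a
#' parameter table shaped like [pea_reference_params()]; genotype `i` uses
#' seed `seed + i` so the cohort is reproducible yet replicates are
#' independent across genotypes.
#'
#' @param params_table `data.frame` with columns `genotype`, `X`, `Y`,
#'   `slope1`, `slope2`.
#' @param day_start,day_end,cv,n_reps see [growth_params()].
#' @param seed base integer seed.
#' @return row-bound `data.frame` of all simulated series.
#' @export
simulate_cohort <- function(params_table, day_start = 11L, day_end = 39L,
                            cv = 0, n_reps = 8L, seed = 1L) {
  need <- c("genotype", "X", "Y", "slope1", "slope2")
  if (!all(need %in% names(params_table)))
    stop_bad_arg("params_table", paste("needs columns", paste(need, collapse = ", ")))
  out <- lapply(seq_len(nrow(params_table)), function(i) {
    p <- params_table[i, ]
    simulate_growth(growth_params(p$X, p$Y, p$slope1, p$slope2,
                                  day_start = day_start, day_end = day_end,
                                  cv = cv, n_reps = n_reps,
                                  seed = seed + i, genotype = p$genotype))
  })
  do.call(rbind, out)
}

#' Affine link from biomass to a target NDVI range
#'
#' @param eb_range range of the biomass values to be mapped.
#' @param ndvi_range target NDVI interval, strictly inside (-1, 1).
#' @return list with `intercept` and `slope`.
#' @export
ndvi_link <- function(eb_range, ndvi_range = c(0.3, 0.8)) {
  eb_range <- range(eb_range)
  if (diff(eb_range) <= 0) stop_bad_arg("eb_range", "must have positive width")
  slope <- diff(ndvi_range) / diff(eb_range)
  list(intercept = ndvi_range[1] - slope * eb_range[1], slope = slope)
}

#' Simulate field reflectance records linked to biomass
#'
#' Emulates a two-band canopy reflectance sensor run over field plots of
#' the same genotypes: each plot's NDVI is an affine function of the
#' genotype's biomass plus Gaussian noise, and the emitted (R670, R760)
#' pair is chosen with a fixed band sum so that the Rouse index
#' `(R760 - R670) / (R760 + R670)` reproduces that NDVI exactly.
#'
#' @param genotype_means named numeric vector of per-genotype biomass
#'   (kilopixels); names become genotype labels.
#' @param link list with `intercept` and `slope` ([ndvi_link()]), or
#'   `NULL` to map the observed biomass range onto NDVI 0.3-0.8.
#' @param noise_sd standard deviation of the additive NDVI noise.
#' @param total_reflectance the fixed band sum R670 + R760 (in (0, 1\]
#'   reflectance units).
#' @param seed integer seed.
#' @return a `data.frame` with columns `plot_id`, `genotype`, `R670`,
#'   `R760`.
#' @export
simulate_field_ndvi <- function(genotype_means, link = NULL, noise_sd = 0.02,
                                total_reflectance = 0.8, seed = 1L) {
  if (is.null(names(genotype_means)))
    names(genotype_means) <- paste0("G", seq_along(genotype_means))
  if (is.null(link)) link <- ndvi_link(range(genotype_means))
  target <- link$intercept + link$slope * genotype_means
  if (any(target <= -1 | target >= 1))
    stop_bad_arg("link", "maps biomass outside the NDVI interval (-1, 1)")
  with_seed(seed, {
    nd <- target + if (noise_sd > 0) stats::rnorm(length(target), 0, noise_sd) else 0
    nd <- pmin(pmax(nd, -1 + 1e-6), 1 - 1e-6)
    r760 <- total_reflectance * (1 + nd) / 2
    r670 <- total_reflectance * (1 - nd) / 2
    data.frame(plot_id = paste0("plot", seq_along(nd)),
               genotype = names(genotype_means),
               R670 = r670, R760 = r760, row.names = NULL,
               stringsAsFactors = FALSE)
  })
}

#' Packaged reference growth parameters for 44 field pea genotypes
#'
#' Published split-line regression parameters (breakpoint day `X`,
#' breakpoint biomass `Y` in kilopixels, and the two phase slopes) for a
#' panel of 44 genetically diverse field pea genotypes grown on an
#' automated imaging platform. Used as the default cohort of the
#' simulator and as the round-trip reference for the fitter.
#'
#' @return a `data.frame` with columns `genotype`, `X`, `Y`, `slope1`,
#'   `slope2` (44 rows).
#' @export
pea_reference_params <- function() {
  path <- system.file("extdata", "pea_growth_params.csv",
                      package = "peavigour", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
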