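# Pipeline configuration: defaults, YAML loading, strict validation.

#' Default pipeline configuration
#'
#' Nested list of every knob the pipeline stages read, with defaults
#' mirroring the reference experiment scale: the packaged 44-genotype
#' cohort, 8 replicates, daily imaging from 11 to 39 DAS. Unknown keys
#' are rejected by [validate_config()], so typos fail loudly.
#'
#' Sections: `cohort` (genotype subset, replicates, day window), `growth`
#' (replicate noise CV), `scene` (image size, palette, noise, pixels per
#' kilopixel scale, whether images are written), `segmentation` (colour
#' windows and the component denoising size), `fit` (breakpoint grid
#' resolution, input choice), `ndvi` (reference day, noise, target NDVI
#' range), `water` (base supply and spread), `paths` (output directory)
#' and `seed`.
#'
#' @return the configuration list.
#' @export
default_config <- function() {
  list(
    cohort = list(genotypes = NULL, n_genotypes = NULL, n_reps = 8L,
                  day_start = 11L, day_end = 39L),
    growth = list(cv = 0.03),
    scene = list(width = 200L, height = 200L, pixels_per_kpix = 40,
                 noise_sd = 5, write_images = TRUE,
                 plant_colour = c(50, 180, 60), cage_colour = c(40, 60, 200),
                 background_colour = c(245, 245, 245),
                 top_share = 0.20),
    segmentation = list(plant_hue = c(0.18, 0.45), plant_sat = 0.20,
                        plant_val = 0.10, cage_hue = c(0.52, 0.80),
                        cage_sat = 0.20, min_size = 50L),
    fit = list(grid_step = 0.01, input = "auto"),
    ndvi = list(reference_day = 27L, noise_sd = 0.02,
                ndvi_range = c(0.3, 0.8), total_reflectance = 0.8),
    water = list(base_kg = 1.5, kg_per_kpix = 0.002, cv = 0.05),
    paths = list(out_dir = "peavigour_run"),
    seed = 1L)
}

config_schema <- function() {
  num <- function(min = -Inf, max = Inf, len = 1L)
    list(kind = "numeric", min = min, max = max, len = len)
  list(
    cohort = list(genotypes = list(kind = "character_or_null"),
                  n_genotypes = list(kind = "count_or_null"),
                  n_reps = num(1), day_start = num(0), day_end = num(1)),
    growth = list(cv = num(0, 10)),
    scene = list(width = num(16), height = num(16),
                 pixels_per_kpix = num(1e-6), noise_sd = num(0, 127),
                 write_images = list(kind = "logical"),
                 plant_colour = num(0, 255, 3), cage_colour = num(0, 255, 3),
                 background_colour = num(0, 255, 3), top_share = num(0.01, 0.9)),
    segmentation = list(plant_hue = num(0, 1, 2), plant_sat = num(0, 1),
                        plant_val = num(0, 1), cage_hue = num(0, 1, 2),
                        cage_sat = num(0, 1), min_size = num(1)),
    fit = list(grid_step = num(1e-4, 1),
               input = list(kind = "choice", choices = c("auto", "traits", "growth"))),
    ndvi = list(reference_day = num(0), noise_sd = num(0, 1),
                ndvi_range = num(-1, 1, 2), total_reflectance = num(1e-6, 1)),
    water = list(base_kg = num(1e-6), kg_per_kpix = num(0), cv = num(0, 10)),
    paths = list(out_dir = list(kind = "character")),
    seed = num(-2^31 + 1, 2^31 - 1))
}

check_leaf <- function(value, rule, path) {
  fail <- function(msg) stop(sprintf("config field '%s' %s", path, msg),
                             call. = FALSE)
  switch(rule$kind,
    numeric = {
      if (!is.numeric(value) || length(value) != rule$len || any(!is.finite(value)))
        fail(sprintf("must be numeric of length %d", rule$len))
      if (any(value < rule$min) || any(value > rule$max))
        fail(sprintf("must lie in [%g, %g]", rule$min, rule$max))
    },
    logical = if (!is.logical(value) || length(value) != 1L || is.na(value))
      fail("must be TRUE or FALSE"),
    character = if (!is.character(value) || length(value) != 1L)
      fail("must be a single string"),
    character_or_null = if (!is.null(value) && !is.character(value))
      fail("must be a character vector or null"),
    count_or_null = if (!is.null(value) && !is_count(value))
      fail("must be a positive integer or null"),
    choice = if (!is.character(value) || length(value) != 1L ||
                 !value %in% rule$choices)
      fail(paste("must be one of", paste(rule$choices, collapse = ", "))))
  invisible(NULL)
}

#' Validate a pipeline configuration
#'
#' Checks the nested config against the schema: unknown keys are
#' rejected (named in the error), every numeric field must be inside its
#' documented range, and cross-field constraints (day window, colour
#' separation) are enforced.
#'
#' @param config a configuration list (see [default_config()]).
#' @return the validated config, invisibly.
#' @export
validate_config <- function(config) {
  schema <- config_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (sec in names(config)) {
    rule <- schema[[sec]]
    if (!is.null(rule$kind)) { check_leaf(config[[sec]], rule, sec); next }
    unknown <- setdiff(names(config[[sec]]), names(rule))
    if (length(unknown))
      stop("unknown config key(s): ",
           paste(paste0(sec, ".", unknown), collapse = ", "), call. = FALSE)
    for (key in names(config[[sec]]))
      check_leaf(config[[sec]][[key]], rule[[key]], paste0(sec, ".", key))
  }
  if (config$cohort$day_start >= config$cohort$day_end)
    stop("config field 'cohort.day_start' must be smaller than 'cohort.day_end'",
         call. = FALSE)
  if (config$ndvi$ndvi_range[1] >= config$ndvi$ndvi_range[2])
    stop("config field 'ndvi.ndvi_range' must be increasing", call. = FALSE)
  # colour-separation feasibility under the scene noise
  sep <- function(a, b) max(abs(a - b))
  s <- config$scene
  if (min(sep(s$plant_colour, s$cage_colour),
          sep(s$plant_colour, s$background_colour),
          sep(s$cage_colour, s$background_colour)) <= 2 * s$noise_sd)
    stop("config field 'scene.noise_sd' too large for the palette separation",
         call. = FALSE)
  invisible(config)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[nm] <- override[nm]   # [ ] keeps explicit NULLs
  }
  base
}

#' Read a YAML pipeline configuration
#'
#' Loads a YAML file, overlays it on [default_config()] (missing keys
#' keep their defaults) and validates the result.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return validated configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    # reject unknown keys before merging so they are not silently dropped
    validate_tree_keys(user, config_schema())
    cfg <- merge_config(cfg, user)
  }
  validate_config(cfg)
  cfg
}

validate_tree_keys <- function(user, schema, prefix = "") {
  unknown <- setdiff(names(user), names(schema))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste(paste0(prefix, unknown), collapse = ", "), call. = FALSE)
  for (nm in names(user))
    if (is.list(schema[[nm]]) && is.null(schema[[nm]]$kind) && is.list(user[[nm]]))
      validate_tree_keys(user[[nm]], schema[[nm]], paste0(prefix, nm, "."))
  invisible(NULL)
}
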