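# Pipeline orchestration: the four stages communicate only through CSV
# files (and PNG images) under one output directory, so each stage can be
# re-run independently and every run is reproducible from config + seed.

log_line <- function(out_dir, stage, ...) {
  dir.create(file.path(out_dir, "logs"), showWarnings = FALSE, recursive = TRUE)
  msg <- sprintf("ts=%s stage=%s %s",
                 format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage,
                 paste(..., sep = " "))
  cat(msg, "\n", file = file.path(out_dir, "logs", paste0(stage, ".log")),
      append = TRUE, sep = "")
  pv_log(msg)
  invisible(NULL)
}

write_stage_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  path
}

# Reader with schema checking; errors name the file, offending line and
# column so batch failures are diagnosable.
read_stage_csv <- function(path, numeric_cols = character(),
                           required = character()) {
  if (!file.exists(path))
    stop(sprintf("missing input file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("schema mismatch in %s: missing column(s) %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  for (cc in intersect(numeric_cols, names(df))) {
    v <- df[[cc]]
    if (is.character(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & v != "" & v != "NA")
      if (length(bad))
        stop(sprintf("schema mismatch in %s: line %d, column '%s' is not numeric",
                     path, bad[1] + 1L, cc), call. = FALSE)
      df[[cc]] <- vn
    }
  }
  df
}

cohort_params <- function(config) {
  params <- pea_reference_params()
  if (!is.null(config$cohort$genotypes)) {
    miss <- setdiff(config$cohort$genotypes, params$genotype)
    if (length(miss))
      stop("unknown genotype(s) in config: ", paste(miss, collapse = ", "),
           call. = FALSE)
    params <- params[params$genotype %in% config$cohort$genotypes, ]
  }
  if (!is.null(config$cohort$n_genotypes))
    params <- utils::head(params, config$cohort$n_genotypes)
  params
}

plant_table <- function(params, n_reps) {
  g <- rep(params$genotype, each = n_reps)
  data.frame(plant_id = sprintf("P%03d", seq_along(g)), genotype = g,
             replicate = rep(seq_len(n_reps), times = nrow(params)),
             stringsAsFactors = FALSE)
}

#' Simulate a full synthetic experiment
#'
#' Generates the cohort defined by the config: replicate growth series
#' from the two-phase model, per-plant water logs, field reflectance
#' records linked to biomass, and (optionally) the multi-view scene
#' images for every plant-day, with the plant silhouette sized so that
#' the summed plant pixels track the simulated biomass
#' (`scene.pixels_per_kpix` pixels per kilopixel of model biomass, the
#' top view taking `scene.top_share` of them). A manifest lists every
#' artifact written.
#'
#' @param config validated configuration ([default_config()]).
#' @param out_dir output directory; default `config$paths$out_dir`.
#' @param seed integer override of `config$seed`.
#' @return (invisibly) the manifest `data.frame` (columns `file`, `kind`).
#' @export
run_simulate <- function(config = default_config(),
                         out_dir = config$paths$out_dir, seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0)
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  params <- cohort_params(config)
  co <- config$cohort
  series <- simulate_cohort(params, day_start = co$day_start,
                            day_end = co$day_end, cv = config$growth$cv,
                            n_reps = co$n_reps, seed = config$seed)
  plants <- plant_table(params, co$n_reps)
  key <- paste(series$genotype, series$replicate)
  series$plant_id <- plants$plant_id[match(key, paste(plants$genotype,
                                                      plants$replicate))]
  series <- series[c("plant_id", "genotype", "replicate", "das", "eb_kpix")]
  manifest <- list()
  # manifest paths are relative to out_dir so runs are relocatable
  add <- function(path, kind) manifest[[length(manifest) + 1L]] <<-
    data.frame(file = path, kind = kind, stringsAsFactors = FALSE)
  write_stage_csv(plants, file.path(out_dir, "plants.csv"))
  add("plants.csv", "plants")
  write_stage_csv(series, file.path(out_dir, "growth.csv"))
  add("growth.csv", "growth_series")

  # water supplied scales with final plant size plus a log-normal spread
  final_eb <- series$eb_kpix[series$das == co$day_end]
  final_eb <- final_eb[match(plants$plant_id,
                             series$plant_id[series$das == co$day_end])]
  wcfg <- config$water
  water_kg <- with_seed(config$seed + 700001L,
    (wcfg$base_kg + wcfg$kg_per_kpix * final_eb) *
      exp(stats::rnorm(nrow(plants), 0, wcfg$cv)))
  water <- data.frame(plant_id = plants$plant_id,
                      total_water_kg = water_kg, stringsAsFactors = FALSE)
  write_stage_csv(water, file.path(out_dir, "water.csv"))
  add("water.csv", "water_log")

  nd_day <- min(max(config$ndvi$reference_day, co$day_start), co$day_end)
  eb_ref <- tapply(series$eb_kpix[series$das == nd_day],
                   series$genotype[series$das == nd_day], mean)
  refl <- simulate_field_ndvi(eb_ref,
                              link = ndvi_link(range(eb_ref),
                                               config$ndvi$ndvi_range),
                              noise_sd = config$ndvi$noise_sd,
                              total_reflectance = config$ndvi$total_reflectance,
                              seed = config$seed + 700002L)
  write_stage_csv(refl, file.path(out_dir, "reflectance.csv"))
  add("reflectance.csv", "reflectance")

  if (isTRUE(config$scene$write_images)) {
    img_dir <- file.path(out_dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    sc <- config$scene
    for (i in seq_len(nrow(series))) {
      row <- series[i, ]
      total <- max(8L, round(row$eb_kpix * sc$pixels_per_kpix))
      top_px <- max(2L, round(total * sc$top_share))
      side_px <- max(2L, round((total - top_px) / 3))
      spec <- scene_spec(width = sc$width, height = sc$height,
                         target_px = c(top_px, side_px, side_px, side_px),
                         plant_colour = sc$plant_colour,
                         cage_colour = sc$cage_colour,
                         background_colour = sc$background_colour,
                         noise_sd = sc$noise_sd,
                         seed = (config$seed + 101L * i) %% .Machine$integer.max)
      scene <- make_scene(spec)
      for (v in view_names()) {
        fname <- sprintf("%s_%d_%s.png", row$plant_id, row$das, v)
        png::writePNG(scene$images[[v]] / 255, file.path(img_dir, fname))
        add(file.path("images", fname), "image")
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  write_stage_csv(manifest, file.path(out_dir, "manifest.csv"))
  log_line(out_dir, "simulate", sprintf(
    "genotypes=%d reps=%d days=%d-%d cv=%g images=%s artifacts=%d",
    nrow(params), co$n_reps, co$day_start, co$day_end, config$growth$cv,
    isTRUE(config$scene$write_images), nrow(manifest)))
  invisible(manifest)
}

#' Extract traits from the simulated (or supplied) images
#'
#' Reads every `<plant_id>_<das>_<view>.png` under `out_dir/images`,
#' segments the four views and writes the per-plant-day trait records to
#' `traits.csv`. A plant-day with missing view images is flagged (traits
#' `NA`, `flags` names the views) and logged, never dropped silently.
#'
#' @inheritParams run_simulate
#' @return (invisibly) the trait `data.frame`.
#' @export
run_extract <- function(config = default_config(),
                        out_dir = config$paths$out_dir) {
  validate_config(config)
  plants <- read_stage_csv(file.path(out_dir, "plants.csv"),
                           required = c("plant_id", "genotype"))
  img_dir <- file.path(out_dir, "images")
  files <- list.files(img_dir, pattern = "\\.png$")
  if (!length(files))
    stop("no images found under ", img_dir, call. = FALSE)
  parts <- strsplit(sub("\\.png$", "", files), "_")
  ok <- lengths(parts) == 3L
  info <- data.frame(file = files[ok],
                     plant_id = vapply(parts[ok], `[`, "", 1L),
                     das = as.integer(vapply(parts[ok], `[`, "", 2L)),
                     view = vapply(parts[ok], `[`, "", 3L),
                     stringsAsFactors = FALSE)
  th <- config$segmentation
  thresholds <- list(plant_hue = th$plant_hue, plant_sat = th$plant_sat,
                     plant_val = th$plant_val, cage_hue = th$cage_hue,
                     cage_sat = th$cage_sat)
  keys <- unique(info[c("plant_id", "das")])
  keys <- keys[order(keys$plant_id, keys$das), ]
  n_flagged <- 0L
  recs <- lapply(seq_len(nrow(keys)), function(i) {
    pid <- keys$plant_id[i]; das <- keys$das[i]
    gt <- plants$genotype[match(pid, plants$plant_id)]
    sub <- info[info$plant_id == pid & info$das == das, ]
    have <- stats::setNames(sub$file, sub$view)
    missing <- setdiff(view_names(), names(have))
    if (length(missing)) {
      n_flagged <<- n_flagged + 1L
      log_line(out_dir, "extract", sprintf(
        "flag plant=%s das=%d missing=%s", pid, das,
        paste(missing, collapse = "+")))
      return(data.frame(plant_id = pid, genotype = gt, das = das,
                        eb_kpix = NA_real_, tva_kpix = NA_real_,
                        tvch_kpix = NA_real_, tvcom = NA_real_,
                        eh_px = NA_real_,
                        flags = paste("missing", paste(missing, collapse = "+")),
                        stringsAsFactors = FALSE))
    }
    imgs <- lapply(have[view_names()], function(f)
      png::readPNG(file.path(img_dir, f)) * 255)
    set <- multi_view_set(imgs$top, imgs[c("side0", "side120", "side240")],
                          plant_id = pid, genotype = gt, das = das)
    extract_traits(set, thresholds = thresholds, min_size = th$min_size)
  })
  traits <- do.call(rbind, recs)
  write_stage_csv(traits, file.path(out_dir, "traits.csv"))
  log_line(out_dir, "extract", sprintf("records=%d flagged=%d",
                                       nrow(traits), n_flagged))
  invisible(traits)
}

#' Fit the two-phase growth model per genotype
#'
#' Fits [fit_genotypes()] on per-day replicate means and writes
#' `fits.csv` (genotype, X, Y, slope1, slope2, adj_r2, sse, degenerate).
#' With `fit.input = "auto"` the image-derived `traits.csv` is used when
#' present, else the simulated `growth.csv`; note image-derived biomass
#' is on the scene pixel scale (`scene.pixels_per_kpix / 1000` times the
#' model scale), which leaves breakpoints and ranking unchanged.
#'
#' @inheritParams run_simulate
#' @return (invisibly) the fits `data.frame`.
#' @export
run_fit <- function(config = default_config(),
                    out_dir = config$paths$out_dir) {
  validate_config(config)
  src <- config$fit$input
  traits_path <- file.path(out_dir, "traits.csv")
  use_traits <- switch(src, traits = TRUE, growth = FALSE,
                       auto = file.exists(traits_path))
  path <- if (use_traits) traits_path else file.path(out_dir, "growth.csv")
  series <- read_stage_csv(path, numeric_cols = c("das", "eb_kpix"),
                           required = c("genotype", "das", "eb_kpix"))
  fits <- fit_genotypes(series, grid_step = config$fit$grid_step)
  write_stage_csv(fits, file.path(out_dir, "fits.csv"))
  log_line(out_dir, "fit", sprintf(
    "source=%s genotypes=%d fitted=%d degenerate=%d",
    basename(path), nrow(fits), sum(!is.na(fits$X)),
    sum(fits$degenerate %in% TRUE)))
  invisible(fits)
}

#' Rank genotypes at the linear-phase onset day
#'
#' Determines the onset of the linear growth phase from the fitted
#' breakpoints ([linear_phase_onset()]), takes the traits observed at
#' that day (clamped into the observed day range with a warning if the
#' fits place it outside), adds per-plant relative growth rate between
#' the onset day and the last observed day and, when water/reflectance
#' records exist, eWUE and field NDVI correlations; then writes the
#' vigour table (`vigour.csv`), the per-trait ANOVA (`anova.csv`) and
#' the correlation report (`correlations.csv`).
#'
#' @inheritParams run_simulate
#' @return (invisibly) the [rank_genotypes()] result with the onset day
#'   attached as attribute `onset_day`.
#' @export
run_analyze <- function(config = default_config(),
                        out_dir = config$paths$out_dir) {
  validate_config(config)
  fits <- read_stage_csv(file.path(out_dir, "fits.csv"),
                         numeric_cols = c("X", "Y", "slope1", "slope2"),
                         required = c("genotype", "X"))
  traits <- read_stage_csv(file.path(out_dir, "traits.csv"),
                           numeric_cols = c("das", "eb_kpix", "tva_kpix",
                                            "tvch_kpix", "tvcom", "eh_px"),
                           required = c("plant_id", "genotype", "das",
                                        "eb_kpix"))
  if (!"flags" %in% names(traits)) traits$flags <- ""
  onset <- linear_phase_onset(fits)
  days <- sort(unique(traits$das))
  onset_used <- onset
  if (onset > max(days) || onset < min(days)) {
    onset_used <- days[which.min(abs(days - onset))]
    warning(sprintf("onset day %d outside observed days; using %d",
                    onset, onset_used), call. = FALSE)
  }
  flagged <- traits$flags != "" & !is.na(traits$flags)
  if (any(flagged))
    log_line(out_dir, "analyze", sprintf("excluded_flagged_records=%d",
                                         sum(flagged)))
  tr_on <- traits[traits$das == onset_used & !flagged, ]
  last_day <- max(days)
  tr_on$rgr <- vapply(seq_len(nrow(tr_on)), function(i) {
    sub <- traits[traits$plant_id == tr_on$plant_id[i] & !flagged, ]
    if (onset_used < last_day &&
        all(c(onset_used, last_day) %in% sub$das) &&
        all(sub$eb_kpix[sub$das %in% c(onset_used, last_day)] > 0, na.rm = TRUE))
      tryCatch(rgr(sub, onset_used, last_day), error = function(e) NA_real_)
    else NA_real_
  }, numeric(1))
  missing_g <- setdiff(unique(traits$genotype), unique(tr_on$genotype))
  if (length(missing_g)) {
    warning("genotype(s) missing at the onset day, dropped: ",
            paste(missing_g, collapse = ", "), call. = FALSE)
    log_line(out_dir, "analyze", sprintf("dropped_genotypes=%s",
                                         paste(missing_g, collapse = "+")))
  }
  wpath <- file.path(out_dir, "water.csv")
  water <- if (file.exists(wpath))
    read_stage_csv(wpath, numeric_cols = "total_water_kg",
                   required = c("plant_id", "total_water_kg")) else NULL
  rpath <- file.path(out_dir, "reflectance.csv")
  refl <- if (file.exists(rpath))
    read_stage_csv(rpath, numeric_cols = c("R670", "R760"),
                   required = c("genotype", "R670", "R760")) else NULL
  vt <- rank_genotypes(tr_on[setdiff(names(tr_on), c("das", "flags"))],
                       water = water, reflectance = refl)
  attr(vt, "onset_day") <- onset_used
  write_stage_csv(vt$table, file.path(out_dir, "vigour.csv"))
  write_stage_csv(vt$anova, file.path(out_dir, "anova.csv"))
  num <- vt$table[setdiff(names(vt$table), c("rank", "genotype"))]
  num <- num[vapply(num, function(v) sum(is.finite(v)) >= 3, logical(1))]
  corr <- data.frame(trait1 = character(0), trait2 = character(0),
                     r = numeric(0), p = numeric(0), stars = character(0),
                     stringsAsFactors = FALSE)
  if (ncol(num) >= 2 && nrow(num) >= 3) {
    pm <- suppressWarnings(pearson_matrix(num))
    pairs <- which(upper.tri(pm$r), arr.ind = TRUE)
    corr <- data.frame(trait1 = rownames(pm$r)[pairs[, 1]],
                       trait2 = colnames(pm$r)[pairs[, 2]],
                       r = pm$r[pairs], p = pm$p[pairs],
                       stars = pm$stars[pairs], stringsAsFactors = FALSE)
  }
  if (!is.null(vt$ndvi_cor))
    corr <- rbind(corr, data.frame(trait1 = "ndvi", trait2 = vt$ndvi_cor$trait,
                                   r = vt$ndvi_cor$r, p = vt$ndvi_cor$p,
                                   stars = p_stars(vt$ndvi_cor$p),
                                   stringsAsFactors = FALSE))
  write_stage_csv(corr, file.path(out_dir, "correlations.csv"))
  log_line(out_dir, "analyze", sprintf(
    "onset_day=%d genotypes=%d records_used=%d", onset_used,
    nrow(vt$table), nrow(tr_on)))
  invisible(vt)
}
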