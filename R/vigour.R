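# Physiological indices and genotype-level vigour statistics: eWUE, NDVI,
# Pearson correlation matrices, one-way ANOVA with s.e.d./LSD, ranking.

#' Estimated water-use efficiency
#'
#' Biomass produced per unit of water supplied over the experiment:
#' `eb / water`, in kilopixels per kilogram.
#'
#' @param eb estimated shoot biomass, kilopixels (vectorized).
#' @param water total water supplied, kilograms (> 0).
#' @return eWUE, kPix per kg.
#' @export
ewue <- function(eb, water) {
  if (any(!is.finite(water) | water <= 0))
    stop_bad_arg("water", "total supplied water must be positive")
  eb / water
}

#' Normalized difference vegetation index
#'
#' The Rouse index `(R760 - R670) / (R760 + R670)` from red (670 nm) and
#' near-infrared (760 nm) reflectance fractions; always in \[-1, 1\] and
#' antisymmetric under swapping the two bands.
#'
#' @param r670,r760 reflectance fractions in \[0, 1\] (vectorized).
#' @return NDVI values.
#' @export
ndvi <- function(r670, r760) {
  if (any(r670 < 0 | r670 > 1 | r760 < 0 | r760 > 1, na.rm = TRUE))
    stop_bad_arg("r670", "reflectances must be fractions in [0, 1]")
  s <- r670 + r760
  if (any(s <= 0, na.rm = TRUE))
    stop_bad_arg("r670", "R670 + R760 must be positive")
  (r760 - r670) / s
}

p_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                       ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Pearson correlation matrix with tests
#'
#' Product-moment correlations between all numeric column pairs, with
#' two-sided p-values from the t transform on `n - 2` degrees of freedom
#' and significance stars at the 0.05 / 0.01 / 0.001 levels. Incomplete
#' rows are handled pairwise-complete; the handling is recorded in the
#' result. Zero-variance columns yield `NA` correlations with a warning.
#'
#' @param data `data.frame` (or matrix) of aligned trait columns; at
#'   least 3 complete rows per pair.
#' @return an object of class `pearson_matrix`: list with matrices `r`,
#'   `p`, `n`, `stars` and the string `use`.
#' @export
pearson_matrix <- function(data) {
  x <- as.matrix(as.data.frame(data)[vapply(as.data.frame(data), is.numeric,
                                            logical(1))])
  k <- ncol(x)
  if (k < 2L) stop_bad_arg("data", "at least two numeric columns are required")
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  if (any(!is.na(sds) & sds == 0))
    warning("zero-variance column(s): ",
            paste(colnames(x)[which(sds == 0)], collapse = ", "),
            "; correlations reported as NA", call. = FALSE)
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  n <- crossprod(!is.na(x))
  if (any(n[upper.tri(n)] < 3L))
    stop_bad_arg("data", "fewer than 3 complete rows for some column pair")
  df <- n - 2
  tt <- r * sqrt(df / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tt), df)
  p[!is.finite(tt)] <- 0          # |r| = 1 exactly
  p[is.na(r)] <- NA_real_
  diag(p) <- NA_real_
  structure(list(r = r, p = p, n = n, stars = matrix(p_stars(p), k, k,
                                                     dimnames = dimnames(r)),
                 use = "pairwise.complete.obs"),
            class = "pearson_matrix")
}

#' @export
print.pearson_matrix <- function(x, digits = 2, ...) {
  cat("Pearson correlations (", x$use, ")\n", sep = "")
  m <- matrix(paste0(format(round(x$r, digits)), x$stars),
              nrow(x$r), ncol(x$r), dimnames = dimnames(x$r))
  print(m, quote = FALSE)
  invisible(x)
}

#' One-way ANOVA with s.e.d. and LSD
#'
#' Standard one-way decomposition of a trait across genotype groups,
#' reporting the F statistic, its p-value, the standard error of a
#' difference between two group means `sqrt(2 * MSE / n)` and the least
#' significant difference `t(0.975, df_error) * s.e.d.`. For unbalanced
#' groups the harmonic mean group size is used for s.e.d./LSD, with a
#' warning. If the within-group mean square is zero the F ratio is
#' degenerate: reported as `Inf` with `p = 0` when group means differ,
#' and as `NA` when all values are identical.
#'
#' @param values numeric trait values.
#' @param groups group labels, coerced to factor; at least 2 groups with
#'   at least 2 observations each.
#' @return list with `F`, `p`, `df_between`, `df_error`, `mse`, `sed`,
#'   `lsd`, `n_per_group`, `balanced`.
#' @export
one_way_anova <- function(values, groups) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(as.factor(groups[keep]))
  sizes <- table(groups)
  if (length(sizes) < 2L) stop_bad_arg("groups", "at least 2 groups are required")
  if (any(sizes < 2L))
    stop_bad_arg("groups", "each group needs at least 2 observations")
  fit <- stats::aov(values ~ groups)
  # anova.lm warns on its own for near-perfect fits; the degenerate case
  # is re-diagnosed (and warned about) explicitly below
  tab <- suppressWarnings(stats::anova(fit))
  ssb <- tab$`Sum Sq`[1]; sse <- tab$`Sum Sq`[2]
  df1 <- tab$Df[1]; df2 <- tab$Df[2]
  if (sse <= 1e-12 * max(ssb + sse, 1)) sse <- 0   # numerically zero
  mse <- sse / df2
  if (mse == 0) {
    if (ssb > 0) { Fv <- Inf; p <- 0 } else { Fv <- NA_real_; p <- NA_real_ }
    warning("zero within-group variance: degenerate F ratio", call. = FALSE)
  } else {
    Fv <- tab$`F value`[1]; p <- tab$`Pr(>F)`[1]
  }
  balanced <- length(unique(sizes)) == 1L
  nh <- if (balanced) sizes[[1]] else {
    warning("unbalanced groups: s.e.d./LSD use the harmonic mean group size",
            call. = FALSE)
    length(sizes) / sum(1 / as.numeric(sizes))
  }
  sed <- sqrt(2 * mse / nh)
  lsd <- stats::qt(0.975, df2) * sed
  list(F = Fv, p = p, df_between = df1, df_error = df2, mse = mse,
       sed = sed, lsd = lsd, n_per_group = nh, balanced = balanced)
}

screen_means <- function(values, groups) {
  # per-group Tukey screen, then group means; groups too small to screen
  # are averaged as-is
  vapply(split(values, groups), function(v) {
    v <- v[is.finite(v)]
    if (length(v) >= 4L) v <- v[!detect_outliers(v)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
}

#' Genotype vigour table: means, ANOVA and ranks
#'
#' Builds the genotype-comparison table from a per-plant trait table at
#' the common comparison day: replicate values are screened with
#' [detect_outliers()] per genotype and trait, averaged, tested with
#' [one_way_anova()] per trait, and the genotypes ranked (descending) by
#' measured biomass `mb` when present, else by estimated biomass
#' `eb_kpix`; ties break by `eb_kpix` and then genotype name. When a
#' water log is supplied, per-plant eWUE joins the trait set; when field
#' reflectance records are supplied, the NDVI-biomass and NDVI-top-view
#' area correlations across genotypes are reported.
#'
#' @param traits `data.frame`, one row per plant, with columns `plant_id`
#'   and `genotype` plus numeric trait columns (e.g. `eb_kpix`,
#'   `tva_kpix`, `tvch_kpix`, `tvcom`, `eh_px`, `rgr`, optionally `mb`).
#' @param water optional `data.frame` with `plant_id`, `total_water_kg`.
#' @param reflectance optional `data.frame` with `genotype`, `R670`,
#'   `R760` (e.g. from [simulate_field_ndvi()]).
#' @return an object of class `vigour_table`: list with `table` (one row
#'   per genotype: `rank`, `genotype`, trait means), `anova` (per-trait
#'   `F`, `p`, `sed`, `lsd`), and `ndvi_cor` (`NULL` unless reflectance
#'   given: per-trait `r`, `p`).
#' @export
rank_genotypes <- function(traits, water = NULL, reflectance = NULL) {
  if (!all(c("genotype") %in% names(traits)))
    stop_bad_arg("traits", "needs a 'genotype' column")
  traits <- as.data.frame(traits)
  if (!is.null(water)) {
    if (!all(c("plant_id", "total_water_kg") %in% names(water)))
      stop_bad_arg("water", "needs columns plant_id, total_water_kg")
    i <- match(traits$plant_id, water$plant_id)
    traits$ewue <- ewue(traits$eb_kpix, water$total_water_kg[i])
  }
  trait_cols <- setdiff(names(traits)[vapply(traits, is.numeric, logical(1))],
                        c("das", "replicate"))
  if (!length(trait_cols)) stop_bad_arg("traits", "no numeric trait columns")
  g <- factor(traits$genotype)
  tab <- data.frame(genotype = levels(g), stringsAsFactors = FALSE)
  anova_rows <- list()
  for (tc in trait_cols) {
    tab[[tc]] <- unname(screen_means(traits[[tc]], g))
    a <- tryCatch(suppressWarnings(one_way_anova(traits[[tc]], g)),
                  error = function(e) NULL)
    anova_rows[[tc]] <- data.frame(
      trait = tc, F = a$F %||% NA_real_, p = a$p %||% NA_real_,
      sed = a$sed %||% NA_real_, lsd = a$lsd %||% NA_real_,
      stringsAsFactors = FALSE)
  }
  key <- if ("mb" %in% trait_cols) "mb" else "eb_kpix"
  if (!key %in% names(tab))
    stop_bad_arg("traits", "ranking needs an 'mb' or 'eb_kpix' column")
  tie <- if ("eb_kpix" %in% names(tab)) tab$eb_kpix else tab[[key]]
  ord <- order(-tab[[key]], -tie, tab$genotype)
  tab <- tab[ord, , drop = FALSE]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  ndvi_cor <- NULL
  if (!is.null(reflectance)) {
    nd <- ndvi(reflectance$R670, reflectance$R760)
    nd_mean <- tapply(nd, reflectance$genotype, mean)
    rows <- list()
    for (tc in intersect(c("eb_kpix", "tva_kpix"), names(tab))) {
      v <- tab[[tc]][match(names(nd_mean), tab$genotype)]
      ok <- is.finite(v) & is.finite(nd_mean)
      if (sum(ok) >= 3) {
        ct <- stats::cor.test(v[ok], nd_mean[ok])
        rows[[tc]] <- data.frame(trait = tc, r = unname(ct$estimate),
                                 p = ct$p.value, n = sum(ok),
                                 stringsAsFactors = FALSE)
      } else {
        rows[[tc]] <- data.frame(trait = tc, r = NA_real_, p = NA_real_,
                                 n = sum(ok), stringsAsFactors = FALSE)
      }
    }
    ndvi_cor <- do.call(rbind, rows)
    rownames(ndvi_cor) <- NULL
  }
  an <- do.call(rbind, anova_rows)
  rownames(an) <- NULL
  structure(list(table = tab, anova = an, ndvi_cor = ndvi_cor),
            class = "vigour_table")
}

#' @export
print.vigour_table <- function(x, ...) {
  cat("Genotype vigour ranking (", nrow(x$table), " genotypes)\n", sep = "")
  print(utils::head(x$table, 10))
  if (nrow(x$table) > 10) cat("...\n")
  cat("\nPer-trait one-way ANOVA:\n")
  print(x$anova)
  if (!is.null(x$ndvi_cor)) {
    cat("\nField NDVI correlations:\n")
    print(x$ndvi_cor)
  }
  invisible(x)
}
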