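# Angle-sensitivity statistics: nadir-relative amplitudes, one-way ANOVA
# across VZAs, per-angle Pearson correlation with LAI, and the DR
# angular-stability statistic.

AMP_TOL <- 1e-12

#' Percent change of an index value relative to nadir
#'
#' `100 * (vi_theta - vi_nadir) / vi_nadir`, the amplitude used to screen
#' indices for angle sensitivity. Vectorized over `vi_theta`.
#'
#' @param vi_theta index value(s) at an off-nadir VZA.
#' @param vi_nadir index value at nadir (must not be ~0).
#' @return percent change(s).
#' @export
amplitude_vs_nadir <- function(vi_theta, vi_nadir) {
  if (length(vi_nadir) != 1L || !is.finite(vi_nadir) ||
      abs(vi_nadir) < AMP_TOL) {
    opivi_error("amplitude undefined: nadir value is zero (within tolerance) or not a finite scalar.",
                "opivi_undefined_amplitude")
  }
  100 * (vi_theta - vi_nadir) / vi_nadir
}

#' One-way ANOVA F statistic
#'
#' Standard fixed-effects one-way analysis of variance,
#' F = MS_between / MS_within with (k - 1, N - k) degrees of freedom,
#' used to test whether an index differs across view zenith angles.
#' When the within-group variance is zero, F is defined as 0 if all group
#' means are equal and +Inf otherwise.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return list with `f`, `df_between`, `df_within`, `p_value`.
#' @export
oneway_f <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    opivi_error("need at least two groups.", "opivi_bad_groups")
  }
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    opivi_error("every group needs at least two values.", "opivi_bad_groups")
  }
  y <- unlist(groups, use.names = FALSE)
  finite_or_error(y, "ANOVA input")
  g <- factor(rep(seq_along(groups), sizes))
  k <- length(groups); n <- length(y)
  fit <- stats::lm(y ~ g)
  a <- stats::anova(fit)
  ss_b <- a[["Sum Sq"]][1]; ss_w <- a[["Sum Sq"]][2]
  df_b <- k - 1L; df_w <- n - k
  if (ss_w <= AMP_TOL * max(ss_b, 1)) {
    f <- if (ss_b <= AMP_TOL) 0 else Inf
  } else {
    f <- (ss_b / df_b) / (ss_w / df_w)
  }
  list(f = f, df_between = df_b, df_within = df_w,
       p_value = stats::pf(f, df_b, df_w, lower.tail = FALSE))
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Pearson correlation between an index and LAI, per view zenith angle
#'
#' @param vitable a `vi_table` from [compute_index_table()].
#' @param metadata per-sample metadata with `sample_id` and `lai`.
#' @param index index code.
#' @param subset optional filter on metadata: a logical vector over metadata
#'   rows, or a function `metadata -> logical`.
#' @return data.frame `vza_deg, r, n`.
#' @export
correlation_by_angle <- function(vitable, metadata, index, subset = NULL) {
  metadata <- as.data.frame(metadata)
  keep <- rep(TRUE, nrow(metadata))
  if (is.function(subset)) keep <- subset(metadata)
  else if (!is.null(subset)) keep <- as.logical(subset)
  ids <- metadata$sample_id[keep]
  lai <- stats::setNames(metadata$lai[keep], ids)
  vt <- vitable[vitable$index == index & vitable$sample_id %in% ids, ]
  if (nrow(vt) == 0L) {
    opivi_error(sprintf("no values for index %s in the selected subset.", index),
                "opivi_empty_subset")
  }
  vzas <- sort(unique(vt$vza_deg))
  out <- lapply(vzas, function(a) {
    block <- vt[vt$vza_deg == a & !is.na(vt$value), ]
    if (nrow(block) < 3L) {
      opivi_error(sprintf("fewer than 3 samples at VZA %s for index %s.",
                          a, index), "opivi_too_few_samples")
    }
    x <- block$value
    y <- unname(lai[block$sample_id])
    if (stats::sd(x) < AMP_TOL || stats::sd(y) < AMP_TOL) {
      opivi_error(sprintf("zero variance at VZA %s: correlation undefined.", a),
                  "opivi_undefined_r")
    }
    data.frame(vza_deg = a, r = stats::cor(x, y), n = nrow(block))
  })
  do.call(rbind, out)
}

#' DR angular-stability statistic
#'
#' `DR = (max(r) - min(r)) / mean(r)` over a set of correlation coefficients
#' (typically the per-VZA correlations of one index with LAI within one
#' sub-dataset). A smaller DR means the index-LAI relationship is more
#' stable across view zenith angles. DR is scale-invariant (`DR(c r) = DR(r)`
#' for `c > 0`) and zero iff all values are equal.
#'
#' @param r_values numeric vector of correlation coefficients (or any values
#'   whose relative spread is wanted); mean must not be ~0.
#' @return the DR value (>= 0 when the mean is positive).
#' @examples
#' dr_statistic(c(0.74, 0.78, 0.81, 0.82, 0.81, 0.81, 0.78, 0.75, 0.74))
#' @export
dr_statistic <- function(r_values) {
  if (length(r_values) == 0L) {
    opivi_error("empty value list.", "opivi_bad_groups")
  }
  finite_or_error(r_values, "DR input")
  m <- mean(r_values)
  if (abs(m) < AMP_TOL) {
    opivi_error("DR undefined: mean of the values is zero (within tolerance).",
                "opivi_undefined_dr")
  }
  (max(r_values) - min(r_values)) / m
}

default_sub_datasets <- function(metadata) {
  subs <- list()
  for (st in intersect(valid_stages, unique(metadata$stage))) {
    subs[[st]] <- metadata$stage == st
  }
  # "n_rates": nitrogen is the varied factor -> hold coverage at its mode;
  # "overlay_mode": coverage varied -> hold nitrogen at its mode.
  if (length(unique(metadata$coverage)) > 1L &&
      length(unique(metadata$nitrogen)) > 1L) {
    mode_of <- function(x) names(which.max(table(x)))
    subs[["n_rates"]] <- metadata$coverage == mode_of(metadata$coverage)
    subs[["overlay_mode"]] <- metadata$nitrogen == mode_of(metadata$nitrogen)
  }
  subs
}

#' Full angle-stability report
#'
#' Assembles, for each index: the mean-profile percent change versus nadir at
#' every VZA (with the -60 deg and +60 deg extremes reported as amplitudes),
#' one-way ANOVA F over all VZAs and over the forward-scatter subset
#' {+30, +45, +60}, per-angle Pearson correlations with LAI within each
#' sub-dataset, and the DR statistic of each (index, sub-dataset) correlation
#' profile. Indices are ranked by ascending mean DR, ties broken by
#' descending mean |r|.
#'
#' @param vitable a `vi_table`.
#' @param metadata per-sample metadata.
#' @param sub_datasets named list of metadata filters (logical vectors or
#'   functions); by default one per growth stage plus nitrogen-rate and
#'   coverage ("overlay mode") strata.
#' @return An object of class `"stability_report"`: list with data.frames
#'   `amplitudes`, `profile`, `anova`, `r_by_angle`, `dr`, `ranking`.
#' @export
stability_report <- function(vitable, metadata,
                             sub_datasets = default_sub_datasets(metadata)) {
  stopifnot(is.data.frame(vitable))
  metadata <- as.data.frame(metadata)
  vzas <- sort(unique(vitable$vza_deg))
  if (!0 %in% vzas) {
    opivi_error("stability report requires nadir (VZA 0) observations.",
                "opivi_missing_nadir")
  }
  if (length(vzas) < 2L) {
    opivi_error("stability report requires at least one non-nadir VZA.",
                "opivi_missing_obs")
  }
  idx <- sort(unique(vitable$index))  # stable order: permutation-invariant
  fwd <- intersect(c(30, 45, 60), vzas)

  profile <- list(); amps <- list(); anov <- list()
  for (nm in idx) {
    vt <- vitable[vitable$index == nm & !is.na(vitable$value), ]
    mean_by_vza <- tapply(vt$value, vt$vza_deg, mean)
    nadir_mean <- unname(mean_by_vza[as.character(0)])
    prof <- amplitude_vs_nadir(unname(mean_by_vza), nadir_mean)
    profile[[nm]] <- data.frame(index = nm,
                                vza_deg = as.numeric(names(mean_by_vza)),
                                pct_change = prof)
    amps[[nm]] <- data.frame(
      index = nm,
      amplitude_minus60 = if ("-60" %in% names(mean_by_vza))
        amplitude_vs_nadir(mean_by_vza[["-60"]], nadir_mean) else NA_real_,
      amplitude_plus60 = if ("60" %in% names(mean_by_vza))
        amplitude_vs_nadir(mean_by_vza[["60"]], nadir_mean) else NA_real_)
    g_full <- split(vt$value, vt$vza_deg)
    a_full <- oneway_f(g_full)
    if (length(fwd) >= 2L) {
      a_fwd <- oneway_f(split(vt$value[vt$vza_deg %in% fwd],
                              vt$vza_deg[vt$vza_deg %in% fwd]))
    } else {
      a_fwd <- list(f = NA_real_, df_between = NA, df_within = NA,
                    p_value = NA_real_)
    }
    anov[[nm]] <- data.frame(
      index = nm,
      f_full = a_full$f, df1_full = a_full$df_between,
      df2_full = a_full$df_within, p_full = a_full$p_value,
      stars_full = significance_stars(a_full$p_value),
      f_forward = a_fwd$f, df1_forward = a_fwd$df_between,
      df2_forward = a_fwd$df_within, p_forward = a_fwd$p_value,
      stars_forward = significance_stars(a_fwd$p_value))
  }

  r_rows <- list(); dr_rows <- list()
  for (sub_name in names(sub_datasets)) {
    for (nm in idx) {
      rba <- correlation_by_angle(vitable, metadata, nm,
                                  subset = sub_datasets[[sub_name]])
      r_rows[[paste(sub_name, nm)]] <-
        cbind(data.frame(subset = sub_name, index = nm), rba)
      dr_rows[[paste(sub_name, nm)]] <- data.frame(
        subset = sub_name, index = nm, dr = dr_statistic(rba$r),
        mean_abs_r = mean(abs(rba$r)))
    }
  }
  dr_df <- do.call(rbind, dr_rows)
  # rank on mean |DR|: a negative DR (negative mean correlation) means less
  # stability, not more, and signed DRs must not cancel across sub-datasets
  rank_df <- stats::aggregate(cbind(dr, mean_abs_r) ~ index,
                              transform(dr_df, dr = abs(dr)), mean)
  names(rank_df)[names(rank_df) == "dr"] <- "mean_abs_dr"
  rank_df <- rank_df[order(rank_df$mean_abs_dr, -rank_df$mean_abs_r), ]
  rank_df$rank <- seq_len(nrow(rank_df))
  rownames(rank_df) <- NULL

  structure(list(amplitudes = do.call(rbind, amps),
                 profile = do.call(rbind, profile),
                 anova = do.call(rbind, anov),
                 r_by_angle = do.call(rbind, r_rows),
                 dr = dr_df,
                 ranking = rank_df),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>\n")
  cat(sprintf("  %d indices, %d VZAs, %d sub-datasets\n",
              nrow(x$amplitudes), length(unique(x$profile$vza_deg)),
              length(unique(x$dr$subset))))
  cat("  ranking (ascending mean DR):",
      paste(utils::head(x$ranking$index, 5), collapse = " > "), "...\n")
  invisible(x)
}

#' Write a stability report as CSV blocks plus a JSON summary
#'
#' @param report a `stability_report`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_stability_report <- function(report, dir) {
  stopifnot(inherits(report, "stability_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    amplitudes = file.path(dir, "amplitudes.csv"),
    anova = file.path(dir, "anova.csv"),
    r_by_angle = file.path(dir, "r_by_angle.csv"),
    dr = file.path(dir, "dr.csv"),
    profile = file.path(dir, "profile.csv"),
    summary = file.path(dir, "summary.json"))
  utils::write.csv(report$amplitudes, paths["amplitudes"], row.names = FALSE)
  utils::write.csv(report$anova, paths["anova"], row.names = FALSE)
  utils::write.csv(report$r_by_angle, paths["r_by_angle"], row.names = FALSE)
  utils::write.csv(report$dr, paths["dr"], row.names = FALSE)
  utils::write.csv(report$profile, paths["profile"], row.names = FALSE)
  jsonlite::write_json(list(ranking = report$ranking,
                            dr = report$dr),
                       paths["summary"], dataframe = "rows", digits = NA)
  invisible(paths)
}
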