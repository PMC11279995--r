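# End-to-end study orchestration: simulate/load -> smooth -> indices ->
# stability -> per-angle linear fits -> multi-angle models -> report bundle.

#' Run configuration
#'
#' A fully serializable description of one pipeline run; a run is a pure
#' function of its config (and the input files it points at).
#'
#' @param spectra_path,metadata_path long-format input CSVs, or `NULL` to
#'   simulate.
#' @param simulate list of [simulate_dataset()] arguments (used when no input
#'   paths are given): `reps`, `stages`, `noise_sd`.
#' @param sg_window,sg_order Savitzky-Golay settings.
#' @param indices index codes to compute.
#' @param vzas view zenith angle set.
#' @param index_for_models index fed to the LAI models.
#' @param model_angles VZAs supplying the multi-angle features.
#' @param models multi-angle model kinds to fit.
#' @param train_fraction,split_seed sample partition settings.
#' @param seed master seed (simulation and stochastic models).
#' @param out_dir output directory, or `NULL` to keep results in memory.
#' @return object of class `"run_config"`.
#' @export
run_config <- function(spectra_path = NULL, metadata_path = NULL,
                       simulate = list(reps = 3L,
                                       stages = c("budding", "flowering"),
                                       noise_sd = 0.02),
                       sg_window = 15L, sg_order = 2L,
                       indices = vi_names(), vzas = default_vzas(),
                       index_for_models = "OPIVI",
                       model_angles = c(-30, -15, 0),
                       models = c("rf", "gbt", "svr_rbf"),
                       train_fraction = 0.7, split_seed = 1L,
                       seed = 1L, out_dir = NULL) {
  if (xor(is.null(spectra_path), is.null(metadata_path))) {
    opivi_error("provide both spectra_path and metadata_path, or neither.",
                "opivi_bad_config")
  }
  structure(list(spectra_path = spectra_path, metadata_path = metadata_path,
                 simulate = simulate, sg_window = sg_window,
                 sg_order = sg_order, indices = indices, vzas = vzas,
                 index_for_models = index_for_models,
                 model_angles = model_angles, models = models,
                 train_fraction = train_fraction, split_seed = split_seed,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

log_line <- function(log, fmt, ...) {
  line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
  message(line)
  c(log, line)
}

#' Run the full multi-angle study
#'
#' Executes every stage on real (CSV) or simulated data and returns (and
#' optionally writes) the report bundle: the smoothed dataset summary, the
#' index table, the stability report (skipped with a notice when fewer than
#' two VZAs are present), per-angle linear fits of the model index, and the
#' multi-angle machine-learning fits. All defaults are recorded in the run
#' log.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `config`, `dataset`, `vitable`,
#'   `stability`, `linear_fits`, `ml_fits`, `log`.
#' @export
run_study <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log <- character()
  log <- log_line(log, "run_study start; config: %s",
                  jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                   null = "null"))

  stage <- "load"
  bundle <- tryCatch({
    if (!is.null(config$spectra_path)) {
      ds <- read_dataset(config$spectra_path, config$metadata_path,
                         vza_set = config$vzas)
      log <- log_line(log, "load: %d observations, %d samples from %s",
                      nrow(ds$obs), nrow(ds$metadata), config$spectra_path)
    } else {
      sim <- config$simulate
      brdf <- brdf_params(noise_sd = sim$noise_sd %||% 0.02)
      ds <- simulate_dataset(reps = sim$reps %||% 3L,
                             stages = sim$stages %||% valid_stages,
                             vzas = config$vzas, brdf = brdf,
                             seed = config$seed)
      log <- log_line(log, "simulate: %d observations, %d samples (seed %d)",
                      nrow(ds$obs), nrow(ds$metadata), config$seed)
    }

    stage <- "smooth"
    ds <- smooth_dataset(ds, config$sg_window, config$sg_order)
    log <- log_line(log, "smooth: SG window %d, order %d",
                    config$sg_window, config$sg_order)

    stage <- "indices"
    vitable <- compute_index_table(ds, config$indices)
    log <- log_line(log, "indices: %d cells (%d indices)",
                    nrow(vitable), length(config$indices))

    stage <- "stability"
    stability <- NULL
    if (length(unique(vitable$vza_deg)) < 2L) {
      log <- log_line(log,
                      "stability: skipped (fewer than two VZAs in the data)")
    } else {
      stability <- stability_report(vitable, ds$metadata)
      log <- log_line(log, "stability: ranking head %s",
                      paste(utils::head(stability$ranking$index, 3),
                            collapse = " < "))
    }

    stage <- "linear_fits"
    split <- split_spec(config$train_fraction, config$split_seed)
    linear_fits <- lapply(sort(unique(vitable$vza_deg)), function(a) {
      fit_linear_per_angle(vitable, ds$metadata, config$index_for_models,
                           a, split)
    })
    names(linear_fits) <- sort(unique(vitable$vza_deg))
    best <- which.max(vapply(linear_fits, `[[`, 0, "r2_test"))
    log <- log_line(log,
                    "linear fits: %s at %d VZAs; best test R^2 = %.3f at %s deg",
                    config$index_for_models, length(linear_fits),
                    linear_fits[[best]]$r2_test, names(linear_fits)[best])

    stage <- "ml_fits"
    ml_fits <- list()
    if (all(config$model_angles %in% unique(vitable$vza_deg))) {
      for (mk in config$models) {
        ml_fits[[mk]] <- fit_multiangle(vitable, ds$metadata,
                                        config$index_for_models,
                                        config$model_angles, mk, split,
                                        seed = config$seed)
        log <- log_line(log, "ml fit %s: test R^2 = %.3f, RMSE = %.3f",
                        mk, ml_fits[[mk]]$r2_test, ml_fits[[mk]]$rmse_test)
      }
    } else {
      log <- log_line(log, "ml fits: skipped (model angles not all present)")
    }

    list(config = config, dataset = ds, vitable = vitable,
         stability = stability, linear_fits = linear_fits,
         ml_fits = ml_fits, log = log)
  }, opivi_error = function(e) {
    opivi_error(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
                "opivi_stage_failure")
  })

  if (!is.null(config$out_dir)) {
    bundle$log <- write_bundle(bundle, config$out_dir)
  }
  invisible(bundle)
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  log <- bundle$log
  utils::write.csv(bundle$vitable, file.path(dir, "vitable.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$stability)) {
    write_stability_report(bundle$stability, file.path(dir, "stability"))
  }
  lin <- do.call(rbind, lapply(names(bundle$linear_fits), function(a) {
    f <- bundle$linear_fits[[a]]
    data.frame(vza_deg = as.numeric(a), index = f$index,
               intercept = f$parameters[["intercept"]],
               slope = f$parameters[["slope"]],
               r2_train = f$r2_train, rmse_train = f$rmse_train,
               r2_test = f$r2_test, rmse_test = f$rmse_test)
  }))
  utils::write.csv(lin, file.path(dir, "linear_fits.csv"), row.names = FALSE)
  for (mk in names(bundle$ml_fits)) {
    write_fit_result(bundle$ml_fits[[mk]],
                     file.path(dir, paste0("fit_", mk, ".json")))
  }
  log <- log_line(log, "bundle written to %s", dir)
  writeLines(log, file.path(dir, "run.log"))
  log
}
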