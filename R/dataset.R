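#' Default view zenith angle set
#'
#' Signed VZAs in the solar principal plane: negative = back-scatter
#' (towards the hotspot), positive = forward-scatter, 0 = nadir.
#'
#' @return integer vector of degrees.
#' @export
default_vzas <- function() c(-60, -45, -30, -15, 0, 15, 30, 45, 60)

valid_stages <- c("budding", "flowering")
valid_nitrogen <- paste0("N", 0:4)
valid_coverage <- c("SM", "FM", "NM")

#' Nitrogen application rates
#'
#' Rates (kg/hm^2) behind the N0..N4 treatment codes.
#' @return named numeric vector.
#' @export
nitrogen_rates <- function() {
  stats::setNames(c(0, 70, 140, 210, 280), valid_nitrogen)
}

validate_metadata <- function(metadata) {
  metadata <- as.data.frame(metadata)
  need <- c("sample_id", "stage", "nitrogen", "coverage", "lai")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) {
    opivi_error(paste0("metadata is missing columns: ",
                       paste(miss, collapse = ", ")), "opivi_bad_metadata")
  }
  metadata$sample_id <- as.character(metadata$sample_id)
  if (anyDuplicated(metadata$sample_id)) {
    opivi_error("duplicate sample_id in metadata.", "opivi_bad_metadata")
  }
  bad <- setdiff(unique(metadata$stage), valid_stages)
  if (length(bad)) {
    opivi_error(paste0("unknown stage value(s): ", paste(bad, collapse = ", ")),
                "opivi_bad_metadata")
  }
  bad <- setdiff(unique(metadata$nitrogen), valid_nitrogen)
  if (length(bad)) {
    opivi_error(paste0("unknown nitrogen level(s): ", paste(bad, collapse = ", ")),
                "opivi_bad_metadata")
  }
  bad <- setdiff(unique(metadata$coverage), valid_coverage)
  if (length(bad)) {
    opivi_error(paste0("unknown coverage value(s): ", paste(bad, collapse = ", ")),
                "opivi_bad_metadata")
  }
  if (any(!is.finite(metadata$lai)) || any(metadata$lai <= 0)) {
    opivi_error("lai must be finite and > 0 (cm^2 per cm^2).",
                "opivi_bad_metadata")
  }
  metadata
}

new_multiangle_dataset <- function(wavelength_nm, reflectance, obs, metadata) {
  stopifnot(is.matrix(reflectance),
            nrow(reflectance) == nrow(obs),
            ncol(reflectance) == length(wavelength_nm))
  structure(list(wavelength_nm = wavelength_nm,
                 reflectance = reflectance,
                 obs = obs,
                 metadata = metadata),
            class = "multiangle_dataset")
}

#' @export
print.multiangle_dataset <- function(x, ...) {
  cat(sprintf(
    "<multiangle_dataset> %d samples, %d VZAs (%s), %d bands %.0f-%.0f nm\n",
    length(unique(x$obs$sample_id)), length(unique(x$obs$vza_deg)),
    paste(sort(unique(x$obs$vza_deg)), collapse = ", "),
    length(x$wavelength_nm), min(x$wavelength_nm), max(x$wavelength_nm)))
  invisible(x)
}

#' Assemble a multi-angle dataset from long-format tables
#'
#' `spectra` is a long table (or CSV path) with columns
#' `sample_id, vza_deg, wavelength_nm, reflectance`; `metadata` has columns
#' `sample_id, stage, nitrogen, coverage, lai`. On read, reflectance given in
#' percent is auto-detected (maximum > 1.5) and rescaled to fractions with a
#' warning; replicate scans of the same (sample, VZA, wavelength) are
#' averaged by default; and every spectrum is resampled to the uniform
#' working grid.
#'
#' @param spectra data.frame or CSV path, long format.
#' @param metadata data.frame or CSV path of per-sample records.
#' @param grid target uniform wavelength grid (nm).
#' @param vza_set allowed VZAs; observations outside it are an error.
#' @param replicates `"average"` (default) averages duplicated
#'   (sample, vza, wavelength) rows as replicate scans; `"error"` rejects them.
#' @return A `multiangle_dataset`.
#' @export
read_dataset <- function(spectra, metadata, grid = working_grid(),
                         vza_set = default_vzas(),
                         replicates = c("average", "error")) {
  replicates <- match.arg(replicates)
  if (is.character(spectra)) spectra <- data.table::fread(spectra)
  if (is.character(metadata)) metadata <- data.table::fread(metadata)
  spectra <- data.table::as.data.table(spectra)
  need <- c("sample_id", "vza_deg", "wavelength_nm", "reflectance")
  miss <- setdiff(need, names(spectra))
  if (length(miss)) {
    opivi_error(paste0("spectra table is missing columns: ",
                       paste(miss, collapse = ", ")), "opivi_bad_table")
  }
  metadata <- validate_metadata(metadata)
  spectra[, sample_id := as.character(sample_id)]

  orphans <- setdiff(unique(spectra$sample_id), metadata$sample_id)
  if (length(orphans)) {
    opivi_error(paste0("observations without a metadata record: ",
                       paste(orphans, collapse = ", ")), "opivi_orphan_samples")
  }
  bad_vza <- setdiff(unique(spectra$vza_deg), vza_set)
  if (length(bad_vza)) {
    opivi_error(paste0("VZAs outside the configured set: ",
                       paste(bad_vza, collapse = ", ")), "opivi_bad_vza")
  }
  if (max(spectra$reflectance) > 1.5) {
    warning("reflectance maximum > 1.5: interpreting input as percent and dividing by 100.")
    spectra[, reflectance := reflectance / 100]
  }
  if (anyDuplicated(spectra, by = c("sample_id", "vza_deg", "wavelength_nm"))) {
    if (replicates == "error") {
      opivi_error("duplicate (sample_id, vza_deg, wavelength_nm) rows.",
                  "opivi_duplicate_rows")
    }
    spectra <- spectra[, list(reflectance = mean(reflectance)),
                       by = c("sample_id", "vza_deg", "wavelength_nm")]
  }

  data.table::setkeyv(spectra, c("sample_id", "vza_deg", "wavelength_nm"))
  obs <- unique(spectra[, c("sample_id", "vza_deg")])
  obs <- as.data.frame(obs)
  mat <- matrix(NA_real_, nrow(obs), length(grid))
  parts <- split(spectra, by = c("sample_id", "vza_deg"), sorted = TRUE)
  stopifnot(length(parts) == nrow(obs))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    sp <- spectrum(p$wavelength_nm, p$reflectance)
    mat[i, ] <- resample_spectrum(sp, grid)$reflectance
  }
  new_multiangle_dataset(grid, mat, obs, metadata)
}

#' Serialize a multi-angle dataset back to long-format tables
#'
#' The inverse of [read_dataset()]: values written and re-read round-trip
#' exactly (the dataset already lives on the working grid).
#'
#' @param dataset a `multiangle_dataset`.
#' @param spectra_path,metadata_path optional CSV output paths; when omitted
#'   the tables are returned instead of written.
#' @return Invisibly, a list with `spectra` and `metadata` data.frames.
#' @export
write_dataset <- function(dataset, spectra_path = NULL, metadata_path = NULL) {
  stopifnot(inherits(dataset, "multiangle_dataset"))
  nw <- length(dataset$wavelength_nm)
  long <- data.table::data.table(
    sample_id = rep(dataset$obs$sample_id, each = nw),
    vza_deg = rep(dataset$obs$vza_deg, each = nw),
    wavelength_nm = rep(dataset$wavelength_nm, times = nrow(dataset$obs)),
    reflectance = as.vector(t(dataset$reflectance))
  )
  if (!is.null(spectra_path)) data.table::fwrite(long, spectra_path)
  if (!is.null(metadata_path)) data.table::fwrite(dataset$metadata, metadata_path)
  invisible(list(spectra = as.data.frame(long), metadata = dataset$metadata))
}

#' Extract one observation's spectrum
#'
#' @param dataset a `multiangle_dataset`.
#' @param sample_id sample identifier.
#' @param vza_deg signed view zenith angle.
#' @return A [spectrum()].
#' @export
get_spectrum <- function(dataset, sample_id, vza_deg) {
  stopifnot(inherits(dataset, "multiangle_dataset"))
  i <- which(dataset$obs$sample_id == sample_id &
               dataset$obs$vza_deg == vza_deg)
  if (length(i) != 1L) {
    opivi_error(sprintf("no observation for sample %s at VZA %s.",
                        sample_id, vza_deg), "opivi_missing_obs")
  }
  spectrum(dataset$wavelength_nm, dataset$reflectance[i, ])
}

#' Savitzky-Golay smoothing of every observation in a dataset
#'
#' Applies [sg_smooth()] to all spectra at once (a single matrix product with
#' the smoothing operator), as the preprocessing step before index
#' computation.
#'
#' @inheritParams sg_smooth
#' @param dataset a `multiangle_dataset`.
#' @return The smoothed `multiangle_dataset`.
#' @export
smooth_dataset <- function(dataset, window_length = 15L, poly_order = 2L) {
  stopifnot(inherits(dataset, "multiangle_dataset"))
  if (!is_uniform_grid(dataset$wavelength_nm)) {
    opivi_error("Savitzky-Golay smoothing requires a uniform wavelength grid.",
                "opivi_nonuniform_grid")
  }
  S <- sg_matrix(length(dataset$wavelength_nm), as.integer(window_length),
                 as.integer(poly_order))
  sm <- dataset$reflectance %*% t(S)
  sm[sm < 0] <- 0
  new_multiangle_dataset(dataset$wavelength_nm, sm, dataset$obs,
                         dataset$metadata)
}
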