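# Registry of the 16 vegetation indices: 15 established formulas plus OPIVI.
#
# Each definition evaluates from named band reflectances; evaluators are
# vectorized so whole datasets can be scored at once. `denom` returns the
# quantities that must stay away from zero for the index to be defined.

vi_def <- function(name, band_class, bands, fun, denom = NULL) {
  list(name = name, band_class = band_class, bands = sort(unique(bands)),
       fun = fun, denom = denom %||% function(R) list())
}

# band accessor: R is a named list mapping "650" -> reflectance vector
b <- function(R, wl) R[[as.character(wl)]]

# Literature-standard components for CCII (not defined in-source by the index
# table; see the methods vignette for the external-assumption note).
tcari <- function(R) {
  3 * ((b(R, 700) - b(R, 670)) - 0.2 * (b(R, 700) - b(R, 550)) *
         (b(R, 700) / b(R, 670)))
}
osavi <- function(R) {
  1.16 * (b(R, 800) - b(R, 670)) / (b(R, 800) + b(R, 670) + 0.16)
}

build_registry <- function(vlopt_variant = c("printed", "r800_linear")) {
  vlopt_variant <- match.arg(vlopt_variant)
  defs <- list(
    # two bands ---------------------------------------------------------
    vi_def("PRI", "two", c(570, 531),
           function(R) (b(R, 570) - b(R, 531)) / (b(R, 570) + b(R, 531)),
           function(R) list(b(R, 570) + b(R, 531))),
    vi_def("RI-dB", "two", c(735, 720),
           function(R) b(R, 735) / b(R, 720),
           function(R) list(b(R, 720))),
    vi_def("SAVI", "two", c(870, 680),
           function(R) 1.5 * (b(R, 870) - b(R, 680)) /
             (b(R, 870) + b(R, 680) + 0.5),
           function(R) list(b(R, 870) + b(R, 680) + 0.5)),
    vi_def("NDRE", "two", c(790, 720),
           function(R) (b(R, 790) - b(R, 720)) / (b(R, 790) + b(R, 720)),
           function(R) list(b(R, 790) + b(R, 720))),
    vi_def("DVI", "two", c(860, 560),
           function(R) b(R, 860) - b(R, 560)),
    vi_def("Vlopt", "two", c(800, 670),
           if (vlopt_variant == "printed") {
             function(R) (1 + 0.45) * (b(R, 800)^2 + 1) / (b(R, 670) + 0.45)
           } else {
             function(R) (1 + 0.45) * (b(R, 800) + 1) / (b(R, 670) + 0.45)
           },
           function(R) list(b(R, 670) + 0.45)),
    # three bands -------------------------------------------------------
    vi_def("mND705", "three", c(750, 705, 445),
           function(R) (b(R, 750) - b(R, 705)) /
             (b(R, 750) + b(R, 705) - 2 * b(R, 445)),
           function(R) list(b(R, 750) + b(R, 705) - 2 * b(R, 445))),
    vi_def("NDDA", "three", c(680, 756, 718),
           function(R) (b(R, 680) + b(R, 756) - 2 * b(R, 718)) /
             (b(R, 756) - b(R, 680)),
           function(R) list(b(R, 756) - b(R, 680))),
    vi_def("MTCI", "three", c(754, 709, 681),
           function(R) (b(R, 754) - b(R, 709)) / (b(R, 709) - b(R, 681)),
           function(R) list(b(R, 709) - b(R, 681))),
    vi_def("EVI-1", "three", c(860, 645, 470),
           function(R) 2.5 * (b(R, 860) - b(R, 645)) /
             (1 + b(R, 860) + 6 * b(R, 645) - 7.5 * b(R, 470)),
           function(R) list(1 + b(R, 860) + 6 * b(R, 645) - 7.5 * b(R, 470))),
    vi_def("DDn", "three", c(710, 660, 760),
           function(R) 2.5 * b(R, 710) - b(R, 660) - b(R, 760)),
    vi_def("OPIVI", "three", c(720, 660, 450),
           function(R) (b(R, 720) - b(R, 450)) / (b(R, 660) - b(R, 450)),
           function(R) list(b(R, 660) - b(R, 450))),
    # four bands --------------------------------------------------------
    vi_def("VOG-2", "four", c(734, 747, 715, 726),
           function(R) (b(R, 734) - b(R, 747)) / (b(R, 715) - b(R, 726)),
           function(R) list(b(R, 715) - b(R, 726))),
    vi_def("DD", "four", c(749, 720, 701, 672),
           function(R) (b(R, 749) - b(R, 720)) - (b(R, 701) - b(R, 672))),
    vi_def("REP", "four", c(700, 670, 780, 740),
           function(R) b(R, 700) + 40 *
             ((b(R, 670) + b(R, 780)) / 2 - b(R, 700)) /
             (b(R, 740) - b(R, 700)),
           function(R) list(b(R, 740) - b(R, 700))),
    vi_def("CCII", "four", c(700, 670, 550, 800),
           function(R) tcari(R) / osavi(R),
           function(R) list(osavi(R), b(R, 670)))
  )
  names(defs) <- vapply(defs, `[[`, "", "name")
  stopifnot(!anyDuplicated(names(defs)),
            all(vapply(defs, function(d)
      all(d$bands >= 350 & d$bands <= 1300), TRUE)))
  defs
}

the_registry <- local({
  cache <- list()
  function(vlopt_variant = "printed") {
    if (is.null(cache[[vlopt_variant]])) {
      cache[[vlopt_variant]] <<- build_registry(vlopt_variant)
    }
    cache[[vlopt_variant]]
  }
})

#' Vegetation index registry
#'
#' The 16 validated index definitions: 15 established indices plus OPIVI,
#' the observation perspective insensitivity vegetation index
#' `(R720 - R450)/(R660 - R450)`.
#'
#' @param vlopt_variant `"printed"` (default) evaluates Vlopt exactly as
#'   published, `(1 + 0.45)(R800^2 + 1)/(R670 + 0.45)`; `"r800_linear"`
#'   replaces the squared term by R800 (the squared term is a suspected
#'   typo in the source formula; see the methods vignette).
#' @return Named list of index definitions, each with elements `name`,
#'   `band_class` (`"two"`, `"three"`, `"four"`), `bands` (wavelengths, nm)
#'   and the vectorized evaluator `fun`.
#' @export
vi_registry <- function(vlopt_variant = c("printed", "r800_linear")) {
  the_registry(match.arg(vlopt_variant))
}

#' @rdname vi_registry
#' @export
vi_names <- function() names(the_registry())

DENOM_TOL <- 1e-12

eval_index_def <- function(def, R) {
  dens <- def$denom(R)
  undef <- FALSE
  for (d in dens) undef <- undef | (abs(d) < DENOM_TOL)
  v <- def$fun(R)
  v[undef] <- NA_real_
  list(value = v, undefined = undef)
}

band_list <- function(spectrum_obj, bands) {
  vals <- band_reflectance(spectrum_obj, bands)
  stats::setNames(as.list(vals), as.character(bands))
}

#' Compute a single vegetation index from a spectrum
#'
#' Bands are sampled by linear interpolation ([band_reflectance()]); a
#' denominator within `1e-12` of zero raises an undefined-index error rather
#' than propagating NaN.
#'
#' @param name registered index code (see [vi_names()]).
#' @param spectrum_obj a [spectrum()].
#' @param registry index registry, by default [vi_registry()].
#' @return numeric index value (REP is in formula units of nm-like position;
#'   all others are unitless).
#' @examples
#' sp <- spectrum(400:900, seq(0.05, 0.5, length.out = 501))
#' compute_index("NDRE", sp)
#' @export
compute_index <- function(name, spectrum_obj, registry = vi_registry()) {
  if (!name %in% names(registry)) {
    opivi_error(paste0("unknown index '", name, "'; registered indices: ",
                       paste(names(registry), collapse = ", ")),
                "opivi_unknown_index")
  }
  def <- registry[[name]]
  R <- band_list(spectrum_obj, def$bands)
  out <- eval_index_def(def, R)
  if (out$undefined || !is.finite(out$value)) {
    opivi_error(sprintf("index %s undefined: denominator within %g of zero.",
                        name, DENOM_TOL), "opivi_undefined_index")
  }
  out$value
}

#' @describeIn compute_index OPIVI, `(R720 - R450)/(R660 - R450)`. Invariant
#'   under any affine transform of the whole spectrum (R -> aR + b, a != 0).
#' @export
opivi <- function(spectrum_obj) compute_index("OPIVI", spectrum_obj)

#' Compute an index table over a whole dataset
#'
#' Evaluates each requested index for every (sample, VZA) observation.
#' Undefined cells (near-zero denominators) are stored as `NA` and counted in
#' a message rather than raising.
#'
#' @param dataset a `multiangle_dataset`.
#' @param names index codes, default all 16.
#' @param registry index registry.
#' @return A tidy data.frame `sample_id, vza_deg, index, value` of class
#'   `"vi_table"`, one row per (sample, VZA, index).
#' @export
compute_index_table <- function(dataset, names = vi_names(),
                                registry = vi_registry()) {
  stopifnot(inherits(dataset, "multiangle_dataset"))
  if (nrow(dataset$obs) == 0L) {
    opivi_error("dataset has no observations.", "opivi_empty_dataset")
  }
  bad <- setdiff(names, base::names(registry))
  if (length(bad)) {
    opivi_error(paste0("unknown index name(s): ", paste(bad, collapse = ", ")),
                "opivi_unknown_index")
  }
  grid <- dataset$wavelength_nm
  all_bands <- sort(unique(unlist(lapply(registry[names], `[[`, "bands"))))
  rng <- range(grid)
  if (any(all_bands < rng[1] | all_bands > rng[2])) {
    opivi_error("dataset grid does not cover all required bands.",
                "opivi_out_of_range")
  }
  # interpolate each needed band across all observations at once
  lo <- findInterval(all_bands, grid)
  lo <- pmin(lo, length(grid) - 1L)
  fr <- (all_bands - grid[lo]) / (grid[lo + 1L] - grid[lo])
  Rb <- lapply(seq_along(all_bands), function(k) {
    (1 - fr[k]) * dataset$reflectance[, lo[k]] +
      fr[k] * dataset$reflectance[, lo[k] + 1L]
  })
  base::names(Rb) <- as.character(all_bands)

  n_obs <- nrow(dataset$obs)
  n_undef <- 0L
  cols <- lapply(names, function(nm) {
    out <- eval_index_def(registry[[nm]], Rb)
    v <- out$value
    v[!is.finite(v)] <- NA_real_
    n_undef <<- n_undef + sum(is.na(v))
    v
  })
  if (n_undef > 0L) {
    message(sprintf("compute_index_table: %d undefined index cells stored as NA.",
                    n_undef))
  }
  res <- data.frame(
    sample_id = rep(dataset$obs$sample_id, times = length(names)),
    vza_deg = rep(dataset$obs$vza_deg, times = length(names)),
    index = rep(names, each = n_obs),
    value = unlist(cols),
    stringsAsFactors = FALSE
  )
  class(res) <- c("vi_table", "data.frame")
  res
}
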