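# Fixtures are built in code; no stored data.

# piecewise-linear spectrum passing exactly through the named band values
spectrum_from_bands <- function(bands, grid = working_grid()) {
  wl <- as.numeric(names(bands))
  o <- order(wl)
  wl <- wl[o]; v <- unname(bands[o])
  x <- c(min(grid), wl, max(grid))
  y <- c(v[1], v, v[length(v)])
  keep <- !duplicated(x)
  spectrum(grid, approx(x[keep], y[keep], xout = grid)$y)
}

# smooth positive random spectrum (sum of random Gaussian bumps on a base)
random_smooth_spectrum <- function(grid = working_grid()) {
  # global tilt keeps any two distinct bands from being exactly equal
  y <- runif(1, 0.05, 0.25) + runif(1, -0.05, 0.08) * (grid - 350) / 950
  for (k in seq_len(5)) {
    y <- y + runif(1, -0.1, 0.25) *
      exp(-(grid - runif(1, 350, 1300))^2 / (2 * runif(1, 30, 200)^2))
  }
  # clamp to positive, then break exact ties a flat clamp would create
  spectrum(grid, pmax(y, 0.001) + 1e-5 * (grid - 350) / 950)
}

# tiny long-format tables for I/O tests
tiny_tables <- function(n_samples = 2, vzas = default_vzas(),
                        grid = seq(350, 1300, by = 1)) {
  ids <- sprintf("P%02d", seq_len(n_samples))
  spectra <- do.call(rbind, lapply(ids, function(id) {
    do.call(rbind, lapply(vzas, function(a) {
      data.frame(sample_id = id, vza_deg = a, wavelength_nm = grid,
                 reflectance = 0.1 + 0.2 * (grid - 350) / 950 +
                   0.01 * match(id, ids) + 0.001 * a / 60)
    }))
  }))
  metadata <- data.frame(sample_id = ids, stage = "budding",
                         nitrogen = "N2", coverage = "SM",
                         lai = seq(1, 3, length.out = n_samples))
  list(spectra = spectra, metadata = metadata)
}

# deterministic vi_table for model-layer tests: one index, value linear in a
# latent per-sample score, slightly angle-shifted
toy_vitable <- function(n = 30, vzas = c(-30, -15, 0), index = "VI",
                        seed = 42) {
  set.seed(seed)
  ids <- sprintf("T%03d", seq_len(n))
  score <- runif(n, 0.2, 2)
  vt <- expand.grid(sample_id = ids, vza_deg = vzas,
                    stringsAsFactors = FALSE)
  vt$index <- index
  vt$value <- score[match(vt$sample_id, ids)] * (1 + 0.02 * vt$vza_deg / 60)
  meta <- data.frame(sample_id = ids, stage = "budding", nitrogen = "N2",
                     coverage = "SM", lai = 2 * score + 1)
  list(vitable = vt, metadata = meta, score = score)
}
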