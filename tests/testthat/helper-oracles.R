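# Independent oracles: direct transliterations and brute-force statistics,
# kept deliberately separate from the package implementation paths.

# direct re-typing of the published index formulas, sampling bands with
# band_reflectance only
oracle_index <- function(name, sp) {
  R <- function(wl) band_reflectance(sp, wl)
  switch(name,
    "PRI"    = (R(570) - R(531)) / (R(570) + R(531)),
    "RI-dB"  = R(735) / R(720),
    "SAVI"   = 1.5 * (R(870) - R(680)) / (R(870) + R(680) + 0.5),
    "NDRE"   = (R(790) - R(720)) / (R(790) + R(720)),
    "DVI"    = R(860) - R(560),
    "Vlopt"  = (1 + 0.45) * (R(800)^2 + 1) / (R(670) + 0.45),
    "mND705" = (R(750) - R(705)) / (R(750) + R(705) - 2 * R(445)),
    "NDDA"   = (R(680) + R(756) - 2 * R(718)) / (R(756) - R(680)),
    "MTCI"   = (R(754) - R(709)) / (R(709) - R(681)),
    "EVI-1"  = 2.5 * (R(860) - R(645)) /
      (1 + R(860) + 6 * R(645) - 7.5 * R(470)),
    "DDn"    = 2.5 * R(710) - R(660) - R(760),
    "OPIVI"  = (R(720) - R(450)) / (R(660) - R(450)),
    "VOG-2"  = (R(734) - R(747)) / (R(715) - R(726)),
    "DD"     = (R(749) - R(720)) - (R(701) - R(672)),
    "REP"    = R(700) + 40 * ((R(670) + R(780)) / 2 - R(700)) /
      (R(740) - R(700)),
    "CCII"   = {
      tcari <- 3 * ((R(700) - R(670)) -
                      0.2 * (R(700) - R(550)) * (R(700) / R(670)))
      osavi <- (1 + 0.16) * (R(800) - R(670)) / (R(800) + R(670) + 0.16)
      tcari / osavi
    },
    stop("oracle has no formula for ", name)
  )
}

# explicit sums-of-squares one-way ANOVA
oracle_oneway_f <- function(groups) {
  y <- unlist(groups)
  grand <- mean(y)
  ss_b <- 0; ss_w <- 0
  for (g in groups) {
    m <- mean(g)
    ss_b <- ss_b + length(g) * (m - grand)^2
    for (v in g) ss_w <- ss_w + (v - m)^2
  }
  k <- length(groups); n <- length(y)
  (ss_b / (k - 1)) / (ss_w / (n - k))
}

# closed-form least squares for lai ~ vi
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  as.numeric(solve(t(X) %*% X) %*% t(X) %*% y)
}
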