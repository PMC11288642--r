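test_that("adaptive KDE normalizes and matches the kernel-sum oracle", {
  set.seed(21)
  ang <- gen_torsion_mixture(
    data.frame(mean = c(60, -60), kappa = c(8, 8), weight = c(0.7, 0.3)), 1000)
  kde <- fit_adaptive_kde(ang)
  grid <- seq(-180, 179.5, by = 0.5)
  integral <- sum(kde_density(kde, grid)) * 0.5 * pi / 180
  expect_equal(integral, 1, tolerance = 1e-3)
  # brute-force kernel sum oracle at random angles
  oracle <- function(theta) {
    mean(exp(kde$kappa * (cos((theta - kde$mu) * pi / 180) - 1)) /
         (2 * pi * besselI(kde$kappa, 0, expon.scaled = TRUE)))
  }
  set.seed(22)
  th <- stats::runif(100, -180, 180)
  expect_equal(kde_density(kde, th), vapply(th, oracle, numeric(1)),
               tolerance = 1e-6)
  # periodicity
  expect_equal(kde_density(kde, -180), kde_density(kde, 180), tolerance = 1e-12)
  expect_equal(kde_density(kde, 37), kde_density(kde, 37 + 360), tolerance = 1e-12)
})

test_that("single observation gives a symmetric unimodal density", {
  kde <- fit_adaptive_kde(0, pilot_kappa = 10)
  expect_equal(kde$grid[which.max(kde$fgrid)], 0)
  expect_equal(kde_density(kde, 25), kde_density(kde, -25), tolerance = 1e-12)
  expect_error(fit_adaptive_kde(numeric()), "empty")
})

test_that("uniform observations fit a nearly flat density", {
  set.seed(23)
  kde <- fit_adaptive_kde(stats::runif(1e5, -180, 180))
  expect_lt(max(kde$fgrid) / min(kde$fgrid), 1.2)
  expect_equal(mean(kde$fgrid), 1 / (2 * pi), tolerance = 0.01)
})

test_that("alpha = 0 reduces to the fixed-bandwidth estimate", {
  set.seed(24)
  ang <- stats::rnorm(80, 50, 20)
  kde <- fit_adaptive_kde(ang, pilot_kappa = 15, alpha = 0)
  expect_true(all(abs(kde$kappa - 15) < 1e-12))
  # and differs when adaptive
  kde2 <- fit_adaptive_kde(ang, pilot_kappa = 15, alpha = 0.5)
  expect_gt(stats::sd(kde2$kappa), 0)
})

test_that("KDE sampling is seeded, exact and KS-close to the density", {
  set.seed(25)
  ang <- gen_torsion_mixture(
    data.frame(mean = c(60, -60), kappa = c(8, 8), weight = c(0.7, 0.3)), 1000)
  kde <- fit_adaptive_kde(ang)
  set.seed(26); a <- kde_sample(kde, 50)
  set.seed(26); b <- kde_sample(kde, 50)
  expect_identical(a, b)
  expect_length(kde_sample(kde, 0), 0)
  set.seed(27)
  s <- kde_sample(kde, 1e5)
  thg <- seq(-179.99, 179.99, length.out = 1000)
  cdf <- cumsum(kde_density(kde, thg)) * diff(thg)[1] * pi / 180
  ks <- max(abs(stats::ecdf(s)(thg) - cdf))
  expect_lt(ks, 0.01)
  # tight kernel: circular mean of draws sits at the mode
  tight <- fit_adaptive_kde(rep(75, 5), pilot_kappa = 400, alpha = 0)
  set.seed(28)
  sm <- kde_sample(tight, 5000)
  cm <- atan2(mean(sin(sm * pi / 180)), mean(cos(sm * pi / 180))) * 180 / pi
  expect_lt(abs(cm - 75), 2)
})

test_that("mixture modes and masses are recovered from 5000 draws", {
  ang <- gen_torsion_mixture(
    data.frame(mean = c(60, -60), kappa = c(8, 8), weight = c(0.7, 0.3)),
    5000, seed = 29)
  kde <- fit_adaptive_kde(ang)
  modes <- glycantree:::kde_modes(kde)
  top2 <- modes[1:2, ]
  expect_lt(abs(top2$mode[1] - 60), 5)
  expect_lt(abs(top2$mode[2] - (-60)), 5)
  expect_lt(abs(top2$mass[1] - 0.7), 0.05)
  expect_lt(abs(top2$mass[2] - 0.3), 0.05)
})

test_that("mode recovery holds across separations and concentrations", {
  # the reference is the true mixture density: at small separation and low
  # concentration (e.g. 60 degrees at kappa 4) the mixture itself is
  # unimodal, so the KDE must track the density's modes, not the component
  # means
  cases <- expand.grid(sep = c(60, 120, 180), kappa = c(4, 8, 16))
  grid <- seq(-180, 179)
  for (i in seq_len(nrow(cases))) {
    m1 <- -cases$sep[i] / 2; m2 <- cases$sep[i] / 2
    kap <- cases$kappa[i]
    truth <- 0.5 * glycantree:::vm_density(grid, m1, kap) +
      0.5 * glycantree:::vm_density(grid, m2, kap)
    left <- truth[c(360, 1:359)]; right <- truth[c(2:360, 1)]
    true_modes <- grid[truth > left & truth >= right]
    ang <- gen_torsion_mixture(
      data.frame(mean = c(m1, m2), kappa = kap, weight = c(0.5, 0.5)),
      5000, seed = 30 + i)
    kde <- fit_adaptive_kde(ang)
    modes <- glycantree:::kde_modes(kde)
    modes <- modes[modes$mass > 0.1, , drop = FALSE]
    expect_equal(nrow(modes), length(true_modes),
                 info = paste("sep", cases$sep[i], "kappa", kap))
    for (tm in true_modes)
      expect_lt(min(abs(wrap_angle(modes$mode - tm))), 5)
    if (length(true_modes) == 2)
      expect_true(all(abs(modes$mass - 0.5) < 0.05))
  }
})

test_that("conformer extraction crosses per-torsion modes with product masses", {
  phi <- fit_adaptive_kde(gen_torsion_mixture(
    data.frame(mean = c(60, -60), kappa = c(8, 8), weight = c(0.7, 0.3)),
    5000, seed = 41))
  psi <- fit_adaptive_kde(gen_torsion_mixture(
    data.frame(mean = 120, kappa = 25, weight = 1), 3000, seed = 42))
  cf <- extract_conformers(list(phi = phi, psi = psi))
  expect_equal(nrow(cf), 2)
  expect_lt(abs(cf$mass[1] - 0.7), 0.05)
  expect_lt(abs(cf$mass[2] - 0.3), 0.05)
  expect_lt(abs(cf$phi[1] - 60), 5)
  expect_lt(abs(cf$psi[1] - 120), 5)
  expect_true(all(diff(cf$mass) <= 0))
  expect_lte(sum(cf$mass), 1 + 1e-9)
  # unimodal x unimodal: single conformer with mass ~ 1
  cf1 <- extract_conformers(list(phi = psi, psi = psi))
  expect_equal(nrow(cf1), 1)
  expect_gt(cf1$mass, 0.95)
  # impossible mass threshold empties the list
  expect_equal(nrow(extract_conformers(list(phi = phi, psi = psi),
                                       min_mass = 1.1)), 0)
})

test_that("kde_energy is zero at the mode, floored, and arithmetic-correct", {
  set.seed(43)
  kde <- fit_adaptive_kde(gen_torsion_mixture(
    data.frame(mean = 10, kappa = 12, weight = 1), 2000))
  mode <- kde$grid[which.max(kde$fgrid)]
  expect_equal(kde_energy(kde, mode), 0, tolerance = 1e-9)
  expect_true(all(kde_energy(kde, seq(-180, 179)) >= 0))
  # floored far tail: finite cap at -log(1e-8 / fmax)
  far <- wrap_angle(mode + 180)
  if (kde_density(kde, far) < 1e-8)
    expect_equal(kde_energy(kde, far), -log(1e-8 / kde$fmax), tolerance = 1e-9)
  # half-max density -> ln 2
  fhalf <- kde$fmax / 2
  idx <- which(abs(kde$fgrid - fhalf) == min(abs(kde$fgrid - fhalf)))[1]
  expect_equal(kde_energy(kde, kde$grid[idx]),
               -log(kde$fgrid[idx] / kde$fmax), tolerance = 1e-9)
})
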