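# Adaptive circular kernel density estimation for glycosidic torsions.
#
# Each torsion of each linkage type gets a von Mises kernel density estimate
# with Abramson-style adaptive concentrations: a pilot fixed-bandwidth
# estimate f~ at concentration kappa0 is evaluated at every observation,
# lambda_i = (f~(mu_i)/g)^(-alpha) with g the geometric mean of the pilot
# values, and the per-observation concentration is kappa_i = kappa0 /
# lambda_i^2 (concentration is the circular analog of inverse squared
# bandwidth).  alpha = 0 recovers the fixed-bandwidth estimate exactly.

.KDE_GRID_P <- 360L
.KDE_FLOOR <- 1e-8  # density floor (per radian) for the energy transform

# von Mises density per radian; works for kappa = 0 (uniform) and large
# kappa via the exponentially scaled Bessel function
vm_density <- function(theta_deg, mu_deg, kappa) {
  d <- (theta_deg - mu_deg) * .deg2rad
  exp(kappa * (cos(d) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

# Best & Fisher (1979) von Mises sampler, degrees; uses R's global RNG
rvonmises <- function(n, mu_deg, kappa) {
  if (n == 0) return(numeric())
  if (kappa < 1e-8) return(stats::runif(n, -180, 180))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    if (any(ok)) {
      th <- sign(u3[ok] - 0.5) * acos(pmax(-1, pmin(1, f[ok])))
      k <- sum(ok)
      out[(got + 1):(got + k)] <- th
      got <- got + k
    }
  }
  wrap_angle(mu_deg + out * .rad2deg)
}

#' Fit an adaptive von Mises kernel density estimate
#'
#' @param angles observed torsion angles in degrees.
#' @param pilot_kappa pilot concentration \eqn{\kappa_0}; default 50 when
#'   \eqn{n \ge 100}, else 20.
#' @param alpha adaptive sensitivity in \code{[0, 1]}; 0 gives a
#'   fixed-bandwidth estimate, default 0.5.
#' @return object of class \code{torsion_kde}: observations, per-observation
#'   concentrations, and a cached 1-degree evaluation grid of densities and
#'   statistical energies.
#' @export
fit_adaptive_kde <- function(angles, pilot_kappa = NULL, alpha = 0.5) {
  angles <- wrap_angle(as.numeric(angles))
  n <- length(angles)
  if (n < 1) stop("empty observation list")
  if (is.null(pilot_kappa)) pilot_kappa <- if (n >= 100) 50 else 20
  stopifnot(pilot_kappa > 0, alpha >= 0, alpha <= 1)

  # pilot estimate, evaluated on the 1-degree grid and interpolated at the
  # observations (keeps the fit O(n * grid) for large harvests)
  pgrid <- seq(-180, 179, length.out = .KDE_GRID_P)
  pilot_grid <- vapply(pgrid, function(t)
    mean(vm_density(t, angles, pilot_kappa)), numeric(1))
  f_tilde <- .grid_interp(pgrid, pilot_grid, angles)
  g <- exp(mean(log(pmax(f_tilde, 1e-300))))
  lambda <- (f_tilde / g)^(-alpha)
  kappa_i <- pilot_kappa / lambda^2

  kde <- structure(list(mu = angles, kappa0 = pilot_kappa, alpha = alpha,
                        kappa = kappa_i, n = n),
                   class = "torsion_kde")
  .kde_refresh_grid(kde)
}

# (re)compute the cached grid, mode density and energy grid
.kde_refresh_grid <- function(kde) {
  grid <- seq(-180, 179, length.out = .KDE_GRID_P)
  kde$grid <- grid
  kde$fgrid <- kde_density(kde, grid, use_grid = FALSE)
  kde$fmax <- max(kde$fgrid)
  kde$egrid <- -log(pmax(kde$fgrid, .KDE_FLOOR) / kde$fmax)
  kde
}

#' Evaluate a circular KDE
#'
#' Exact O(n) kernel sum (per radian); periodic in 360 degrees.
#'
#' @param kde a \code{torsion_kde}.
#' @param theta_deg angles in degrees (vectorized).
#' @param use_grid if TRUE, linear interpolation on the cached 1-degree grid
#'   (used by the sampler's energy path); default FALSE, the exact sum.
#' @return densities per radian.
#' @export
kde_density <- function(kde, theta_deg, use_grid = FALSE) {
  if (use_grid || is.null(kde$mu)) {
    return(.grid_interp(kde$grid, kde$fgrid, theta_deg))
  }
  vapply(theta_deg, function(t) {
    d <- (t - kde$mu) * .deg2rad
    mean(exp(kde$kappa * (cos(d) - 1)) /
         (2 * pi * besselI(kde$kappa, 0, expon.scaled = TRUE)))
  }, numeric(1))
}

# periodic linear interpolation on the 1-degree grid
.grid_interp <- function(grid, values, theta) {
  th <- wrap_angle(theta)
  p <- length(grid)
  step <- 360 / p
  pos <- (th - grid[1]) / step
  i0 <- floor(pos)
  fr <- pos - i0
  i0 <- (as.integer(i0) %% p) + 1L
  i1 <- (i0 %% p) + 1L
  values[i0] * (1 - fr) + values[i1] * fr
}

#' Sample angles from a fitted KDE
#'
#' When the observation set is available the draw is exact (pick a kernel,
#' then a von Mises variate); a table-loaded KDE without observations falls
#' back to inverse-CDF sampling on the cached grid.
#'
#' @param kde a \code{torsion_kde}.
#' @param n number of draws.
#' @return angles in degrees, \code{[-180, 180)}.
#' @export
kde_sample <- function(kde, n) {
  if (n == 0) return(numeric())
  if (!is.null(kde$mu)) {
    idx <- sample.int(kde$n, n, replace = TRUE)
    out <- numeric(n)
    for (i in unique(idx)) {
      w <- idx == i
      out[w] <- rvonmises(sum(w), kde$mu[i], kde$kappa[i])
    }
    return(out)
  }
  # grid inverse-CDF fallback
  p <- kde$fgrid / sum(kde$fgrid)
  cdf <- cumsum(p)
  u <- stats::runif(n)
  i <- findInterval(u, cdf) + 1L
  step <- 360 / length(kde$grid)
  wrap_angle(kde$grid[pmin(i, length(kde$grid))] + stats::runif(n, 0, step))
}

#' Torsional statistical energy from a KDE
#'
#' \eqn{E(\theta) = -\ln(f(\theta)/f_{max})}, zero exactly at the global
#' mode and capped by the density floor of 1e-8 per radian, so it is finite
#' everywhere.
#'
#' @inheritParams kde_density
#' @return non-negative energies (unitless, thermal units).
#' @export
kde_energy <- function(kde, theta_deg, use_grid = FALSE) {
  if (use_grid) return(.grid_interp(kde$grid, kde$egrid, theta_deg))
  f <- kde_density(kde, theta_deg)
  -log(pmax(f, .KDE_FLOOR) / kde$fmax)
}

# local maxima/minima bookkeeping on the circular grid -----------------------

.circular_modes <- function(fgrid) {
  p <- length(fgrid)
  left <- fgrid[c(p, 1:(p - 1))]
  right <- fgrid[c(2:p, 1)]
  which(fgrid > left & fgrid >= right)
}

# watershed partition of the circular grid: every point is assigned to the
# local maximum reached by steepest ascent (robust to flat tails)
.basin_assignment <- function(fgrid, modes) {
  p <- length(fgrid)
  nxt <- function(i) if (i == p) 1L else i + 1L
  prv <- function(i) if (i == 1L) p else i - 1L
  is_mode <- logical(p); is_mode[modes] <- TRUE
  gmax <- which.max(fgrid)
  assign <- integer(p)
  for (i in seq_len(p)) {
    cur <- i
    steps <- 0L
    while (!is_mode[cur] && steps <= p) {
      l <- prv(cur); r <- nxt(cur)
      cur <- if (fgrid[l] > fgrid[r]) l else r
      steps <- steps + 1L
    }
    assign[i] <- if (is_mode[cur]) cur else gmax
  }
  assign
}

# per-torsion modes with basin probability mass and circular sd (degrees)
kde_modes <- function(kde) {
  fg <- kde$fgrid
  grid <- kde$grid
  p <- length(grid)
  step_rad <- (360 / p) * .deg2rad
  modes <- .circular_modes(fg)
  if (!length(modes)) modes <- which.max(fg)
  assign <- .basin_assignment(fg, modes)
  out <- lapply(modes, function(m) {
    idx <- which(assign == m)
    w <- fg[idx] * step_rad
    mass <- sum(w)
    # circular moments about the mode (angles re-centered to avoid wrap bias)
    th <- (grid[idx] - grid[m]) * .deg2rad
    C <- sum(w * cos(th)); S <- sum(w * sin(th))
    Rbar <- sqrt(C^2 + S^2) / max(sum(w), 1e-300)
    sd <- sqrt(max(0, -2 * log(max(min(Rbar, 1), 1e-12)))) * .rad2deg
    list(mode = grid[m], mass = mass, sd = sd)
  })
  df <- data.frame(mode = vapply(out, `[[`, numeric(1), "mode"),
                   mass = vapply(out, `[[`, numeric(1), "mass"),
                   sd = vapply(out, `[[`, numeric(1), "sd"))
  df[order(-df$mass, df$mode), , drop = FALSE]
}

#' Extract conformers from the torsion KDEs of one linkage
#'
#' Per-torsion modes are the local maxima of each KDE on the grid; the mass
#' of a mode is the integrated density between its flanking minima, and its
#' spread the circular standard deviation within that basin.  Conformers are
#' the cross-product of per-torsion modes with mass equal to the product of
#' basin masses, filtered by \code{min_mass} and sorted by mass descending.
#'
#' @param kdes named list of \code{torsion_kde} objects (\code{phi},
#'   \code{psi} and optionally \code{omega}).
#' @param min_mass drop conformers below this probability mass.
#' @return data.frame with one row per conformer: columns \code{<t>},
#'   \code{<t>_sd} for each torsion, and \code{mass}.
#' @export
extract_conformers <- function(kdes, min_mass = 0.01) {
  stopifnot(all(c("phi", "psi") %in% names(kdes)))
  tnames <- intersect(c("phi", "psi", "omega"), names(kdes))
  per <- lapply(kdes[tnames], kde_modes)
  combos <- expand.grid(lapply(per, function(df) seq_len(nrow(df))))
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    vals <- lapply(tnames, function(t) {
      df <- per[[t]][combos[i, t], ]
      c(df$mode, df$sd, df$mass)
    })
    ang <- vapply(vals, `[`, numeric(1), 1)
    sds <- vapply(vals, `[`, numeric(1), 2)
    mass <- prod(vapply(vals, `[`, numeric(1), 3))
    out <- as.list(c(ang, sds, mass))
    names(out) <- c(tnames, paste0(tnames, "_sd"), "mass")
    as.data.frame(out)
  })
  df <- do.call(rbind, rows)
  df <- df[df$mass >= min_mass, , drop = FALSE]
  ord <- do.call(order, c(list(-df$mass), as.list(df[tnames])))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}
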