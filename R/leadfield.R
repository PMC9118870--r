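#' Age-dependent skull conductivity
#'
#' `3.958 + 62.77 exp(-0.2404 age)` mS/m: skull conductivity decreases with
#' age towards an adult asymptote of 3.958 mS/m.
#'
#' @param age age in years (non-negative).
#' @return conductivity in mS/m.
#' @export
skull_conductivity <- function(age) {
  if (any(age < 0)) stop("age must be non-negative")
  3.958 + 62.77 * exp(-0.2404 * age)
}

# internal: mirror-symmetric diamond-style grid inside a head-shaped
# ellipsoid. Two interleaved cubic lattices (the second offset by half the
# spacing in all axes, which places some points on the x = 0 midline), points
# sorted by ellipsoidal radius.
diamond_grid <- function(n_sources, spacing = 15) {
  radii <- c(65, 80, 60)   # mm, brain-sized ellipsoid
  h <- spacing
  k <- ceiling(max(radii) / h) + 1
  base <- expand.grid(x = (seq(-k, k) + 0.5) * h, y = (seq(-k, k) + 0.5) * h,
                      z = (seq(-k, k) + 0.5) * h)
  sub <- base + h / 2
  pts <- rbind(as.matrix(base), as.matrix(sub))
  r2 <- (pts[, 1] / radii[1])^2 + (pts[, 2] / radii[2])^2 + (pts[, 3] / radii[3])^2
  pts <- pts[r2 <= 1, , drop = FALSE]
  pts <- round(pts, 6)
  # unique representatives with x >= 0; midline points are their own mirror
  rep_pts <- pts[pts[, 1] >= 0, , drop = FALSE]
  rep_pts <- rep_pts[order((rep_pts[, 1] / radii[1])^2 +
                           (rep_pts[, 2] / radii[2])^2 +
                           (rep_pts[, 3] / radii[3])^2), , drop = FALSE]
  # when fewer sources than grid points are requested, spread the selection
  # over the whole volume (all depths) instead of filling from the center out
  n_rep <- nrow(rep_pts)
  walk <- unique(round(seq(1, n_rep,
                           length.out = min(n_rep, ceiling(n_sources / 2) + 2L))))
  sel <- matrix(numeric(0), 0, 3)
  for (i in c(walk, setdiff(seq_len(n_rep), walk))) {
    if (nrow(sel) >= n_sources) break
    p <- rep_pts[i, ]
    if (abs(p[1]) < 1e-9) {
      sel <- rbind(sel, p)
    } else if (n_sources - nrow(sel) >= 2) {
      sel <- rbind(sel, p, c(-p[1], p[2], p[3]))
    }
  }
  if (nrow(sel) < n_sources)
    stop("grid too small for the requested number of sources")
  unname(sel)
}

#' Generate a synthetic leadfield
#'
#' Sensors are placed on the upper hemisphere of a 95 mm sphere (with a small
#' seeded position jitter); sources sit on a mirror-symmetric diamond-style
#' grid with 1.5 cm spacing inside a brain-shaped ellipsoid. Gains follow the
#' homogeneous-conductor dipole potential, giving a sensors x sources x 3
#' array of full column rank per source triple. This synthetic forward model
#' stands where a subject-specific FEM-derived gain matrix would be supplied.
#'
#' @param n_sensors number of sensors (at least 3).
#' @param n_sources number of source positions (at least 1).
#' @param seed integer seed (controls only the sensor jitter).
#' @param spacing grid spacing in mm (default 15).
#' @return list of class `leadfield` with `gain` (sensors x sources x 3),
#'   `positions` (sources x 3, mm), `sensors` (sensors x 3, mm), `spacing`.
#' @export
generate_leadfield <- function(n_sensors, n_sources, seed = 1, spacing = 15) {
  stopifnot(n_sensors >= 3, n_sources >= 1)
  set.seed(substream_seed(seed, 0L))
  pos <- diamond_grid(n_sources, spacing)
  # Fibonacci spiral on the upper hemisphere
  i <- seq_len(n_sensors)
  z <- seq(0.12, 0.98, length.out = n_sensors)
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  sens <- 95 * cbind(r * cos(phi), r * sin(phi), z)
  sens <- sens + matrix(stats::rnorm(3 * n_sensors, 0, 2), n_sensors, 3)
  gain <- array(0, c(n_sensors, n_sources, 3))
  sigma <- 0.33  # S/m, homogeneous volume
  for (q in seq_len(n_sources)) {
    dvec <- sweep(sens, 2, pos[q, ])
    d3 <- (rowSums(dvec^2))^(3 / 2)
    gain[, q, ] <- dvec / (4 * pi * sigma * d3)
  }
  for (q in seq_len(n_sources)) {
    if (qr(gain[, q, ])$rank < 3)
      stop(sprintf("rank-deficient gain at source %d", q))
  }
  structure(list(gain = gain, positions = pos, sensors = sens,
                 spacing = spacing), class = "leadfield")
}

#' Collapse a leadfield to fixed (radial) orientations
#'
#' @param lf a [generate_leadfield()] result.
#' @param orientations optional sources x 3 matrix of unit orientation
#'   vectors; defaults to the radial direction of each source position.
#' @return sensors x sources gain matrix.
#' @export
leadfield_fixed_gain <- function(lf, orientations = NULL) {
  stopifnot(inherits(lf, "leadfield"))
  if (is.null(orientations)) {
    orientations <- lf$positions + matrix(rep(c(0, 0, 1e-6), each = nrow(lf$positions)),
                                          ncol = 3)
    orientations <- orientations / sqrt(rowSums(orientations^2))
  }
  out <- matrix(0, dim(lf$gain)[1], dim(lf$gain)[2])
  for (q in seq_len(dim(lf$gain)[2]))
    out[, q] <- lf$gain[, q, ] %*% orientations[q, ]
  out
}
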