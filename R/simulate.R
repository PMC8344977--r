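# Seeded synthetic-data generators: tumor masks with boundary-parallel
# fiber fields (tissue mode), globally aligned matrices (in-vitro mode),
# T-cell masks with region-dependent density, and persistent-random-walk
# migration tracks. These stand in for the SHG/immunofluorescence raw data;
# the contract is statistical structure, not visual realism.

# ---- axial von Mises machinery ---------------------------------------------

# von Mises sampler (Best & Fisher 1979 rejection scheme), mu/kappa in rad.
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi) + mu)
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
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    k <- sum(ok)
    if (k) {
      out[(got + 1L):(got + k)] <- sign(u3[ok] - 0.5) * acos(f[ok])
      got <- got + k
    }
  }
  th <- out + mu
  ((th + pi) %% (2 * pi)) - pi
}

#' Sample axial orientations from a von Mises model
#'
#' Standard axial-data construction by angle doubling: draw phi from a von
#' Mises distribution about `2 * axis` with concentration `kappa` and return
#' `phi / 2`, folded into `[0, 180)` degrees. `kappa = 0` gives isotropic
#' orientations; the population alignment coefficient of the sample
#' converges to `besselI(kappa, 1) / besselI(kappa, 0)`.
#'
#' @param n Number of orientations.
#' @param axis_deg Axial mean direction, degrees.
#' @param kappa Concentration (>= 0) of the doubled-angle von Mises.
#' @return Axial orientations in degrees, `[0, 180)`.
#' @export
rvonmises_axial <- function(n, axis_deg = 90, kappa = 1) {
  phi <- rvonmises(n, 0, kappa)
  fold_axial(axis_deg + phi * 90 / pi)
}

#' Expected parallel fraction under an axial von Mises model
#'
#' Probability that the axial deviation from the mean axis is at most
#' `range_deg` degrees when orientations follow the doubled-angle von Mises
#' with concentration `kappa`.
#'
#' @param kappa Concentration (>= 0).
#' @param range_deg Half-width of the parallel window, degrees.
#' @return Probability in `(range_deg/90, 1)`.
#' @export
parallel_fraction_vonmises <- function(kappa, range_deg = 15) {
  a <- 2 * range_deg * pi / 180
  if (kappa < 1e-10) return(a / pi / 2 * 2)    # uniform: a / pi
  dens <- function(phi) exp(kappa * (cos(phi) - 1))
  num <- stats::integrate(dens, -a, a, rel.tol = 1e-10)$value
  den <- stats::integrate(dens, -pi, pi, rel.tol = 1e-10)$value
  num / den
}

#' Concentration achieving a target parallel fraction
#'
#' Inverse of [parallel_fraction_vonmises()] in `kappa`.
#'
#' @param target Desired parallel fraction, in `(range_deg/90, 1)`.
#' @param range_deg Half-width of the parallel window, degrees.
#' @return Concentration `kappa`.
#' @export
kappa_for_parallel_fraction <- function(target, range_deg = 15) {
  lo <- range_deg / 90
  stopifnot(target > lo, target < 1)
  stats::uniroot(function(k) parallel_fraction_vonmises(k, range_deg) - target,
                 c(1e-8, 500), tol = 1e-9)$root
}

#' Concentration achieving a target alignment coefficient
#'
#' Inverts the closed-form mean resultant length `I1(kappa)/I0(kappa)` of
#' the doubled-angle von Mises.
#'
#' @param target Desired alignment coefficient, in `(0, 1)`.
#' @return Concentration `kappa`.
#' @export
kappa_for_alignment <- function(target) {
  stopifnot(target > 0, target < 1)
  A <- function(k) besselI(k, 1, expon.scaled = TRUE) /
                   besselI(k, 0, expon.scaled = TRUE)
  stats::uniroot(function(k) A(k) - target, c(1e-8, 1e4), tol = 1e-9)$root
}

# ---- preset ----------------------------------------------------------------

#' Canonical PDAC parameter preset
#'
#' The named configuration used throughout the synthetic generators:
#' log-normal fiber lengths with mean 22.4 um (the dataset-level mean fiber
#' length that also sets the band width), fiber width about 3 um,
#' straightness about 0.9, tissue calibration 0.39 um/px and the default
#' 11-band analysis configuration. A parameter bundle, not a claim about any
#' real tissue.
#'
#' @return Named list of preset values.
#' @export
pdac_preset <- function() {
  list(mean_fiber_length_um = 22.4,
       length_sdlog = 0.35,
       width_mean_um = 3, width_sd_um = 0.5,
       straightness_mean = 0.9, straightness_sd = 0.04,
       calibration = calibration(0.39, 0.5),
       config = analysis_config())
}

# Log-normal meanlog for a desired arithmetic mean.
lnorm_meanlog <- function(mean, sdlog) log(mean) - sdlog^2 / 2

# ---- tissue simulation -----------------------------------------------------

#' Specification of a synthetic tumor/stroma tissue field
#'
#' Describes a raster with one or more smooth tumor-cluster blobs and a
#' surrounding collagen fiber field whose orientations follow a
#' boundary-parallel axial von Mises model: concentration `kappa_near` in
#' the `true_extension_bands` innermost distance bands and `kappa_far`
#' beyond, so the parallel-fiber fraction deviates from the distant plateau
#' in exactly the inner bands. `orientation_mode = "isotropic"` disables the
#' boundary coupling entirely (null model).
#'
#' Concentrations default to parallel fractions of 0.825 (near) and 0.75
#' (plateau): a contrast strong enough to detect each deviating band yet
#' small enough that, when the deviation reaches into the plateau window
#' (7-band extensions), the contaminated plateau mean still leaves distant
#' bands below the 5% ratio threshold.
#'
#' @param raster_px Raster side, px.
#' @param calibration A [calibration()]; synthetic tissue defaults to
#'   0.78 um/px (band geometry lives on the um scale; 28.7 px per band is
#'   ample resolution).
#' @param n_clusters Number of tumor clusters.
#' @param cluster_radius_um Mean blob radius, um.
#' @param cluster_irregularity Relative amplitude of the blob boundary
#'   harmonics (0 = circle).
#' @param mean_fiber_length_um,length_sdlog Log-normal fiber length model
#'   (arithmetic mean, um; sdlog).
#' @param width_mean_um,width_sd_um Normal fiber width model, um.
#' @param straightness_mean,straightness_sd Normal straightness model,
#'   truncated to `[0.5, 1]`.
#' @param orientation_mode `"boundary"` or `"isotropic"`.
#' @param R_near,R_far Target parallel fractions in the deviating bands and
#'   on the plateau (converted to `kappa_near`/`kappa_far`).
#' @param true_extension_bands Number of innermost deviating bands (ground
#'   truth).
#' @param fibers_per_band Fibers placed per distance band.
#' @param cfg An [analysis_config()] (band width, number of bands, parallel
#'   window).
#' @param seed Integer seed.
#' @return An object of class `tissue_sim_spec`.
#' @export
tissue_sim_spec <- function(raster_px = 896,
                            calibration = peristroma::calibration(0.78, 0.5),
                            n_clusters = 1L,
                            cluster_radius_um = 60,
                            cluster_irregularity = 0.12,
                            mean_fiber_length_um = 22.4,
                            length_sdlog = 0.35,
                            width_mean_um = 3, width_sd_um = 0.5,
                            straightness_mean = 0.9, straightness_sd = 0.04,
                            orientation_mode = c("boundary", "isotropic"),
                            R_near = 0.825, R_far = 0.75,
                            true_extension_bands = 3L,
                            fibers_per_band = 3000L,
                            cfg = analysis_config(),
                            seed = 1L) {
  orientation_mode <- match.arg(orientation_mode)
  stopifnot(true_extension_bands < cfg$n_bands, fibers_per_band > 0,
            n_clusters >= 1L, cluster_radius_um > 0)
  spec <- list(raster_px = as.integer(raster_px), calibration = calibration,
               n_clusters = as.integer(n_clusters),
               cluster_radius_um = cluster_radius_um,
               cluster_irregularity = cluster_irregularity,
               mean_fiber_length_um = mean_fiber_length_um,
               length_sdlog = length_sdlog,
               width_mean_um = width_mean_um, width_sd_um = width_sd_um,
               straightness_mean = straightness_mean,
               straightness_sd = straightness_sd,
               orientation_mode = orientation_mode,
               R_near = R_near, R_far = R_far,
               kappa_near = if (orientation_mode == "boundary")
                 kappa_for_parallel_fraction(R_near, cfg$parallel_range_deg) else 0,
               kappa_far = if (orientation_mode == "boundary")
                 kappa_for_parallel_fraction(R_far, cfg$parallel_range_deg) else 0,
               true_extension_bands = as.integer(true_extension_bands),
               fibers_per_band = as.integer(fibers_per_band),
               cfg = cfg, seed = seed)
  class(spec) <- "tissue_sim_spec"
  spec
}

# Star-shaped smooth blob mask; center/radius in px. Harmonics 2..5.
render_blob <- function(nx, ny, cx, cy, radius_px, irregularity) {
  amps <- stats::rnorm(4, 0, irregularity / (2:5))
  phs <- stats::runif(4, 0, 2 * pi)
  rmax <- radius_px * (1 + sum(abs(amps))) + 2
  xr <- max(1L, floor(cx - rmax)):min(nx, ceiling(cx + rmax))
  yr <- max(1L, floor(cy - rmax)):min(ny, ceiling(cy + rmax))
  dx <- outer(xr - 1 - cx, rep(1, length(yr)))
  dy <- outer(rep(1, length(xr)), yr - 1 - cy)
  phi <- atan2(dy, dx)
  r <- radius_px * (1 + Reduce(`+`, lapply(1:4, function(i)
    amps[i] * cos((i + 1) * phi + phs[i]))))
  m <- matrix(0L, nx, ny)
  m[xr, yr] <- (sqrt(dx^2 + dy^2) <= r) * 1L
  m
}

#' Simulate a tumor/stroma tissue field
#'
#' Renders the tumor clusters, builds the distance-band geometry, and places
#' fibers band by band: arc-length midpoints uniformly over the band's
#' non-excluded pixels and axial orientations about the local boundary
#' tangent with band-dependent concentration (or isotropic). Each fiber is a
#' three-vertex polyline realising the drawn length, straightness and
#' orientation exactly, with its arc midpoint at the sampled pixel.
#'
#' @param spec A [tissue_sim_spec()].
#' @return List with elements `tumor` ([region_mask()]), `fibers`
#'   ([fiber_field()]), `bands` (precomputed [distance_bands()] with
#'   exclusions), `geometry` (precomputed [boundary_geometry()]) and `truth`
#'   (ground-truth record: `true_extension_bands`, `extension_um`, per-band
#'   `kappa` and expected parallel fraction `expected_R`).
#' @export
simulate_tissue <- function(spec) {
  stopifnot(inherits(spec, "tissue_sim_spec"))
  cfg <- spec$cfg
  cal <- spec$calibration
  um <- cal$microns_per_pixel
  nx <- spec$raster_px; ny <- spec$raster_px
  with_seed(spec$seed, {
    rad_px <- spec$cluster_radius_um / um
    margin <- rad_px * (1 + 4 * spec$cluster_irregularity) + 4
    centers <- if (spec$n_clusters == 1L) {
      cbind((nx - 1) / 2, (ny - 1) / 2)
    } else {
      pts <- matrix(NA_real_, 0, 2)
      tries <- 0L
      while (nrow(pts) < spec$n_clusters && tries < 2000L) {
        cand <- c(stats::runif(1, margin, nx - 1 - margin),
                  stats::runif(1, margin, ny - 1 - margin))
        if (!nrow(pts) || all(sqrt(rowSums(sweep(pts, 2, cand)^2)) > 2.4 * rad_px))
          pts <- rbind(pts, cand)
        tries <- tries + 1L
      }
      if (nrow(pts) < spec$n_clusters) stop("could not place tumor clusters")
      pts
    }
    tum <- matrix(0L, nx, ny)
    for (i in seq_len(nrow(centers)))
      tum <- pmax(tum, render_blob(nx, ny, centers[i, 1], centers[i, 2],
                                   rad_px, spec$cluster_irregularity))
    tumor <- region_mask(tum, role = "tumor", calibration = cal)
    bands <- distance_bands(tumor, cfg)
    if (spec$n_clusters > 1L) bands <- mark_exclusions(bands, cfg)
    geom <- boundary_geometry(tumor, cfg)

    nb <- cfg$n_bands
    kappa_band <- if (spec$orientation_mode == "boundary") {
      ifelse(seq_len(nb) <= spec$true_extension_bands,
             spec$kappa_near, spec$kappa_far)
    } else rep(0, nb)
    nfib <- spec$fibers_per_band * nb
    mid <- matrix(NA_real_, nfib, 2)
    theta <- numeric(nfib)
    open_band <- bands$band >= 1L & bands$band <= nb & !bands$excluded
    for (k in seq_len(nb)) {
      idx <- which(open_band & bands$band == k)
      if (!length(idx)) stop("band ", k, " has no available pixels")
      rows <- (k - 1L) * spec$fibers_per_band + seq_len(spec$fibers_per_band)
      pick <- idx[sample.int(length(idx), spec$fibers_per_band, replace = TRUE)]
      mid[rows, 1] <- (pick - 1L) %% nx
      mid[rows, 2] <- (pick - 1L) %/% nx
      if (spec$orientation_mode == "boundary") {
        tang <- tangent_at_points(geom, mid[rows, , drop = FALSE])
        theta[rows] <- fold_axial(tang +
          rvonmises_axial(spec$fibers_per_band, 0, kappa_band[k]))
      } else {
        theta[rows] <- stats::runif(spec$fibers_per_band, 0, 180)
      }
    }
    L_um <- stats::rlnorm(nfib, lnorm_meanlog(spec$mean_fiber_length_um,
                                              spec$length_sdlog),
                          spec$length_sdlog)
    s <- pmin(pmax(stats::rnorm(nfib, spec$straightness_mean,
                                spec$straightness_sd), 0.5), 1)
    w_um <- pmax(stats::rnorm(nfib, spec$width_mean_um, spec$width_sd_um), 0.3)
    verts <- fiber_polylines(mid, theta, L_um / um, s, nx, ny, bands, nb)
    field <- fiber_field(vertices = verts, dim = c(nx, ny), calibration = cal,
                         width_um = w_um)
    truth <- list(true_extension_bands = spec$true_extension_bands,
                  extension_um = if (spec$orientation_mode == "boundary")
                    spec$true_extension_bands * cfg$band_width_um else 0,
                  kappa = kappa_band,
                  expected_R = vapply(kappa_band, parallel_fraction_vonmises,
                                      numeric(1),
                                      range_deg = cfg$parallel_range_deg),
                  orientation_mode = spec$orientation_mode,
                  spec = spec)
    list(tumor = tumor, fibers = field, bands = bands, geometry = geom,
         truth = truth)
  })
}

# Build three-vertex polylines (apex = arc midpoint at `mid`), resampling
# positions whose endpoints leave the raster or the fiber's band.
fiber_polylines <- function(mid, theta_deg, L_px, s, nx, ny, bands, nb) {
  n <- nrow(mid)
  th <- theta_deg * pi / 180
  ux <- cos(th); uy <- sin(th)
  half_chord <- s * L_px / 2
  h <- sqrt(pmax((L_px / 2)^2 - half_chord^2, 0))
  # normal side chosen at random
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  e1x <- mid[, 1] - sgn * h * (-uy) - half_chord * ux
  e1y <- mid[, 2] - sgn * h * (ux) - half_chord * uy
  e2x <- e1x + 2 * half_chord * ux
  e2y <- e1y + 2 * half_chord * uy
  bad <- e1x < 0 | e1x > nx - 1 | e1y < 0 | e1y > ny - 1 |
         e2x < 0 | e2x > nx - 1 | e2y < 0 | e2y > ny - 1
  it <- 0L
  open_band <- bands$band >= 1L & bands$band <= nb & !bands$excluded
  band_of <- rep(seq_len(nb), each = n / nb)
  while (any(bad) && it < 60L) {
    for (k in unique(band_of[bad])) {
      rows <- which(bad & band_of == k)
      idx <- which(open_band & bands$band == k)
      pick <- idx[sample.int(length(idx), length(rows), replace = TRUE)]
      mid[rows, 1] <- (pick - 1L) %% nx
      mid[rows, 2] <- (pick - 1L) %/% nx
      e1x[rows] <- mid[rows, 1] - sgn[rows] * h[rows] * (-uy[rows]) -
        half_chord[rows] * ux[rows]
      e1y[rows] <- mid[rows, 2] - sgn[rows] * h[rows] * ux[rows] -
        half_chord[rows] * uy[rows]
      e2x[rows] <- e1x[rows] + 2 * half_chord[rows] * ux[rows]
      e2y[rows] <- e1y[rows] + 2 * half_chord[rows] * uy[rows]
    }
    bad <- e1x < 0 | e1x > nx - 1 | e1y < 0 | e1y > ny - 1 |
           e2x < 0 | e2x > nx - 1 | e2y < 0 | e2y > ny - 1
    it <- it + 1L
  }
  if (any(bad)) {             # last resort: clamp (affects a handful of fibers)
    e1x <- pmin(pmax(e1x, 0), nx - 1); e1y <- pmin(pmax(e1y, 0), ny - 1)
    e2x <- pmin(pmax(e2x, 0), nx - 1); e2y <- pmin(pmax(e2y, 0), ny - 1)
  }
  apexx <- (e1x + e2x) / 2 + sgn * h * (-uy)
  apexy <- (e1y + e2y) / 2 + sgn * h * ux
  data.frame(fiber_id = rep(seq_len(n), each = 3L),
             vertex_index = rep(0:2, n),
             x_px = as.vector(rbind(e1x, apexx, e2x)),
             y_px = as.vector(rbind(e1y, apexy, e2y)))
}

# ---- T-cell mask simulation ------------------------------------------------

#' Specification of a synthetic T-cell mask
#'
#' @param density_peritumoral_pct,density_distant_pct Target T-cell area
#'   densities per region, percent.
#' @param mean_area_px Mean cell-blob area, px^2 (log-normal, floored at the
#'   particle-filter threshold so generated cells survive filtering).
#' @param area_sdlog Log-normal sdlog of blob areas.
#' @param min_area_px Blob area floor, px^2.
#' @param seed Integer seed.
#' @return An object of class `tcell_sim_spec`.
#' @export
tcell_sim_spec <- function(density_peritumoral_pct = 5,
                           density_distant_pct = 2,
                           mean_area_px = 60, area_sdlog = 0.4,
                           min_area_px = 25, seed = 1L) {
  stopifnot(density_peritumoral_pct >= 0, density_peritumoral_pct <= 100,
            density_distant_pct >= 0, density_distant_pct <= 100,
            mean_area_px >= min_area_px)
  structure(list(density_peritumoral_pct = density_peritumoral_pct,
                 density_distant_pct = density_distant_pct,
                 mean_area_px = mean_area_px, area_sdlog = area_sdlog,
                 min_area_px = min_area_px, seed = seed),
            class = "tcell_sim_spec")
}

#' Simulate a T-cell mask over a stroma partition
#'
#' Places non-overlapping elliptical cell blobs with centers in each region
#' until the region's pixel density reaches its target (up to placement
#' granularity); blobs may bleed marginally across region borders. The
#' realised densities are recorded as ground truth.
#'
#' @param partition A `stroma_partition` with labels.
#' @param spec A [tcell_sim_spec()].
#' @return List with `mask` (a T-cell [region_mask()]) and `truth` (targets,
#'   realised densities per region, flags).
#' @export
simulate_tcells <- function(partition, spec) {
  stopifnot(inherits(partition, "stroma_partition"),
            inherits(spec, "tcell_sim_spec"))
  if (is.null(partition$labels)) stop("partition carries no labels")
  labels <- partition$labels
  nx <- nrow(labels); ny <- ncol(labels)
  cell <- matrix(0L, nx, ny)
  flags <- character(0)
  with_seed(spec$seed, {
    for (tag in c("peritumoral", "distant")) {
      code <- if (tag == "peritumoral") 1L else 2L
      target_pct <- if (code == 1L) spec$density_peritumoral_pct else
        spec$density_distant_pct
      region_idx <- which(labels == code)
      region_px <- length(region_idx)
      if (region_px == 0L) {
        if (target_pct > 0) flags <- c(flags, paste0("no ", tag, " region"))
        next
      }
      target_px <- round(target_pct / 100 * region_px)
      placed <- 0L
      fails <- 0L
      while (placed < target_px && fails < 4000L) {
        ctr <- region_idx[sample.int(region_px, 1L)]
        cx <- (ctr - 1L) %% nx + 1L; cy <- (ctr - 1L) %/% nx + 1L
        area <- max(spec$min_area_px,
                    stats::rlnorm(1, lnorm_meanlog(spec$mean_area_px,
                                                   spec$area_sdlog),
                                  spec$area_sdlog))
        ar <- stats::runif(1, 1, 2.5)
        a <- sqrt(area * ar / pi); b <- a / ar
        ang <- stats::runif(1, 0, pi)
        ext <- ceiling(a) + 1L
        xr <- max(1L, cx - ext):min(nx, cx + ext)
        yr <- max(1L, cy - ext):min(ny, cy + ext)
        dx <- outer(xr - cx, rep(1, length(yr)))
        dy <- outer(rep(1, length(xr)), yr - cy)
        u <- dx * cos(ang) + dy * sin(ang)
        v <- -dx * sin(ang) + dy * cos(ang)
        inside <- (u / a)^2 + (v / b)^2 <= 1
        if (sum(inside) < spec$min_area_px) { fails <- fails + 1L; next }
        sub <- cell[xr, yr]
        if (any(sub[inside] != 0L)) { fails <- fails + 1L; next }
        sub[inside] <- 1L
        cell[xr, yr] <- sub
        placed <- placed + sum(inside & matrix(labels[xr, yr] == code,
                                               length(xr), length(yr)))
      }
      if (placed < target_px)
        flags <- c(flags, paste0(tag, " density target unreachable (",
                                 placed, "/", target_px, " px)"))
    }
  })
  mask <- region_mask(cell, role = "tcell", calibration = partition$calibration)
  realised <- c(
    peritumoral = 100 * sum(cell == 1L & labels == 1L) / max(sum(labels == 1L), 1L),
    distant = 100 * sum(cell == 1L & labels == 2L) / max(sum(labels == 2L), 1L))
  list(mask = mask,
       truth = list(target_pct = c(peritumoral = spec$density_peritumoral_pct,
                                   distant = spec$density_distant_pct),
                    realised_pct = realised, flags = flags, spec = spec))
}

# ---- migration track simulation --------------------------------------------

#' Specification of synthetic T-cell migration tracks
#'
#' A persistent random walk with optional axial bias: successive headings
#' receive Gaussian turning noise plus a restoring drift
#' `bias * sin(2 * (axis - heading))` toward the matrix alignment axis
#' (axial: both directions along the axis are equivalent). `bias = 0` gives
#' an isotropic persistent random walk.
#'
#' @param n_tracks Number of tracks.
#' @param frames Frames per track (>= 2).
#' @param calibration A [calibration()] (frame interval; pixel pitch used
#'   when exporting to pixel CSV).
#' @param speed_mean_um_min,speed_sdlog Log-normal per-track speed model.
#' @param turn_sd_deg Per-step Gaussian turning noise, degrees (persistence:
#'   smaller = straighter).
#' @param bias Axial bias strength (>= 0, drift coefficient per step).
#' @param axis_deg Alignment axis, degrees (default 90: the y axis).
#' @param field_um Side of the field in which start positions are drawn.
#' @param seed Integer seed.
#' @return An object of class `track_sim_spec`.
#' @export
track_sim_spec <- function(n_tracks = 100L, frames = 60L,
                           calibration = peristroma::calibration(0.65, 0.5),
                           speed_mean_um_min = 5, speed_sdlog = 0.3,
                           turn_sd_deg = 35, bias = 0, axis_deg = 90,
                           field_um = 600, seed = 1L) {
  stopifnot(frames >= 2L, n_tracks >= 1L, bias >= 0)
  structure(list(n_tracks = as.integer(n_tracks), frames = as.integer(frames),
                 calibration = calibration,
                 speed_mean_um_min = speed_mean_um_min,
                 speed_sdlog = speed_sdlog, turn_sd_deg = turn_sd_deg,
                 bias = bias, axis_deg = axis_deg, field_um = field_um,
                 seed = seed),
            class = "track_sim_spec")
}

#' Simulate T-cell migration tracks
#'
#' @param spec A [track_sim_spec()].
#' @return A `tcell_tracks` data frame (columns `track_id`, `frame`,
#'   `time_min`, `x_um`, `y_um`, `usable`) with the calibration attached.
#' @export
simulate_tracks <- function(spec) {
  stopifnot(inherits(spec, "track_sim_spec"))
  n <- spec$n_tracks; fr <- spec$frames
  dt <- spec$calibration$frame_interval_min
  with_seed(spec$seed, {
    speed <- stats::rlnorm(n, lnorm_meanlog(spec$speed_mean_um_min,
                                            spec$speed_sdlog),
                           spec$speed_sdlog)
    step <- speed * dt
    sdr <- spec$turn_sd_deg * pi / 180
    axis <- spec$axis_deg * pi / 180
    x <- matrix(0, fr, n); y <- matrix(0, fr, n)
    x[1, ] <- stats::runif(n, 0, spec$field_um)
    y[1, ] <- stats::runif(n, 0, spec$field_um)
    a <- stats::runif(n, 0, 2 * pi)
    for (t in 2:fr) {
      x[t, ] <- x[t - 1, ] + step * cos(a)
      y[t, ] <- y[t - 1, ] + step * sin(a)
      a <- a + stats::rnorm(n, 0, sdr) + spec$bias * sin(2 * (axis - a))
    }
    out <- data.frame(track_id = rep(seq_len(n), each = fr),
                      frame = rep(seq_len(fr) - 1L, n),
                      time_min = rep((seq_len(fr) - 1L) * dt, n),
                      x_um = as.vector(x), y_um = as.vector(y),
                      usable = fr >= 2L)
    attr(out, "calibration") <- spec$calibration
    class(out) <- c("tcell_tracks", class(out))
    out
  })
}

# ---- in-vitro matrix simulation --------------------------------------------

#' Specification of a synthetic collagen matrix
#'
#' Straight fibers with axial von Mises orientations about a global axis;
#' the concentration is set directly or from a target alignment coefficient
#' via [kappa_for_alignment()], so matrices in all three alignment groups
#' (< 0.40, 0.40--0.60, > 0.60) are reachable.
#'
#' @param n_fibers Number of fibers.
#' @param kappa Concentration of the doubled-angle von Mises (0 = isotropic).
#' @param alignment_target If given, overrides `kappa`.
#' @param axis_deg Alignment axis, degrees.
#' @param raster_px Raster side, px.
#' @param calibration A [calibration()].
#' @param mean_fiber_length_um,length_sdlog Log-normal length model.
#' @param width_mean_um,width_sd_um Normal width model.
#' @param seed Integer seed.
#' @return An object of class `matrix_sim_spec`.
#' @export
matrix_sim_spec <- function(n_fibers = 500L, kappa = 0,
                            alignment_target = NULL, axis_deg = 90,
                            raster_px = 2048L,
                            calibration = peristroma::calibration(0.39, 0.5),
                            mean_fiber_length_um = 22.4, length_sdlog = 0.35,
                            width_mean_um = 3, width_sd_um = 0.5,
                            seed = 1L) {
  if (!is.null(alignment_target)) kappa <- kappa_for_alignment(alignment_target)
  stopifnot(n_fibers >= 1L, kappa >= 0)
  structure(list(n_fibers = as.integer(n_fibers), kappa = kappa,
                 axis_deg = axis_deg, raster_px = as.integer(raster_px),
                 calibration = calibration,
                 mean_fiber_length_um = mean_fiber_length_um,
                 length_sdlog = length_sdlog,
                 width_mean_um = width_mean_um, width_sd_um = width_sd_um,
                 seed = seed),
            class = "matrix_sim_spec")
}

#' Simulate an in-vitro collagen matrix
#'
#' @param spec A [matrix_sim_spec()].
#' @return List with `fibers` (a [fiber_field()] of straight two-vertex
#'   fibers) and `truth` (`kappa`, expected and realised alignment
#'   coefficient).
#' @export
simulate_matrix <- function(spec) {
  stopifnot(inherits(spec, "matrix_sim_spec"))
  n <- spec$n_fibers; nx <- spec$raster_px; ny <- spec$raster_px
  um <- spec$calibration$microns_per_pixel
  with_seed(spec$seed, {
    theta <- rvonmises_axial(n, spec$axis_deg, spec$kappa)
    L_px <- stats::rlnorm(n, lnorm_meanlog(spec$mean_fiber_length_um,
                                           spec$length_sdlog),
                          spec$length_sdlog) / um
    w_um <- pmax(stats::rnorm(n, spec$width_mean_um, spec$width_sd_um), 0.3)
    th <- theta * pi / 180
    hx <- L_px / 2 * cos(th); hy <- L_px / 2 * sin(th)
    mx <- stats::runif(n, 0, nx - 1); my <- stats::runif(n, 0, ny - 1)
    bad <- mx - abs(hx) < 0 | mx + abs(hx) > nx - 1 |
           my - abs(hy) < 0 | my + abs(hy) > ny - 1
    it <- 0L
    while (any(bad) && it < 100L) {
      mx[bad] <- stats::runif(sum(bad), 0, nx - 1)
      my[bad] <- stats::runif(sum(bad), 0, ny - 1)
      bad <- mx - abs(hx) < 0 | mx + abs(hx) > nx - 1 |
             my - abs(hy) < 0 | my + abs(hy) > ny - 1
      it <- it + 1L
    }
    verts <- data.frame(fiber_id = rep(seq_len(n), each = 2L),
                        vertex_index = rep(0:1, n),
                        x_px = as.vector(rbind(mx - hx, mx + hx)),
                        y_px = as.vector(rbind(my - hy, my + hy)))
    field <- fiber_field(vertices = verts, dim = c(nx, ny),
                         calibration = spec$calibration, width_um = w_um)
    expected_A <- if (spec$kappa < 1e-12) 0 else
      besselI(spec$kappa, 1, expon.scaled = TRUE) /
      besselI(spec$kappa, 0, expon.scaled = TRUE)
    list(fibers = field,
         truth = list(kappa = spec$kappa, expected_alignment = expected_A,
                      realised_alignment =
                        alignment_coefficient(field$fibers$orientation_deg),
                      spec = spec))
  })
}
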