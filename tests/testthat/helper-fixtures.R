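# Fixtures built in code: small masks, hand-placed fiber fields, and a
# manually assembled stroma partition with strip-shaped regions.

cal1 <- calibration(microns_per_pixel = 1, frame_interval_min = 0.5)

# Tumor occupying the strip x < x_edge (straight vertical boundary).
strip_tumor <- function(n = 160L, x_edge = 20L, cal = cal1) {
  m <- matrix(0L, n, n)
  m[seq_len(x_edge), ] <- 1L
  region_mask(m, role = "tumor", calibration = cal)
}

circle_tumor <- function(n = 101L, r = 20, cal = cal1) {
  c0 <- (n - 1) / 2
  d <- sqrt(outer((0:(n - 1) - c0)^2, (0:(n - 1) - c0)^2, `+`))
  region_mask((d <= r) * 1L, role = "tumor", calibration = cal)
}

# Two-vertex fiber of half-length `half` centered at (x, y) with axial
# orientation theta (degrees).
fiber_rows <- function(id, x, y, theta_deg, half = 3) {
  th <- theta_deg * pi / 180
  data.frame(fiber_id = id, vertex_index = 0:1,
             x_px = c(x - half * cos(th), x + half * cos(th)),
             y_px = c(y - half * sin(th), y + half * sin(th)))
}

field_from_fibers <- function(rows, dim, cal = cal1) {
  fiber_field(vertices = do.call(rbind, rows), dim = dim, calibration = cal)
}

# Stroma partition with vertical strip regions (tumor | peritumoral |
# distant), built by hand for ROI and T-cell tests.
strip_partition <- function(n = 300L, tumor_w = 20L, peri_w = 86L,
                            cal = cal1) {
  labels <- matrix(2L, n, n)
  labels[seq_len(tumor_w), ] <- 0L
  labels[tumor_w + seq_len(peri_w), ] <- 1L
  dist_um <- outer(seq_len(n) - tumor_w, rep(1, n)) * cal$microns_per_pixel
  dist_um[dist_um < 0] <- 0
  structure(list(extension_um = peri_w * cal$microns_per_pixel,
                 extension_bands = 1L, labels = labels,
                 profile = list(bands = list(dist_um = dist_um), R_bar = 0.5),
                 calibration = cal, flagged = character(0)),
            class = "stroma_partition")
}

# Run the delineation on a freshly simulated tissue field; returns the
# recovered extension in um.
recover_extension <- function(k, seed, ...) {
  spec <- tissue_sim_spec(true_extension_bands = k, seed = seed, ...)
  sim <- simulate_tissue(spec)
  prof <- parallel_fraction_profile(sim$fibers, sim$bands, sim$geometry,
                                    spec$cfg)
  define_peritumoral_extension(prof)$extension_um
}
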