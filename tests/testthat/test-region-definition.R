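# Distance bands, boundary tangents, exclusions, the parallel-fraction
# profile, the extension rule and ROI generation.

test_that("distance bands follow the half-open interval convention", {
  cfg <- analysis_config(band_width_um = 22.4, n_bands = 11)
  tum <- strip_tumor(n = 300L, x_edge = 20L)       # 1 um/px
  b <- distance_bands(tum, cfg)
  # pixel 11 um from the boundary -> band 1; 30 um -> band 2
  expect_equal(b$band[20L + 11L, 150], 1L)
  expect_equal(b$band[20L + 30L, 150], 2L)
  expect_equal(b$band[5, 150], 0L)                 # inside tumor
  expect_equal(b$band[300, 150], 255L)             # beyond 246.4 um
  # a distance of exactly k*w belongs to band k
  cfg4 <- analysis_config(band_width_um = 4, n_bands = 11)
  b4 <- distance_bands(tum, cfg4)
  expect_equal(b4$band[20L + 4L, 150], 1L)
  expect_equal(b4$band[20L + 5L, 150], 2L)
  expect_error(distance_bands(region_mask(matrix(0L, 5, 5)), cfg),
               "empty tumor mask")
})

test_that("boundary tangents are parallel to flat edges and perpendicular to circle radii", {
  tum <- strip_tumor(n = 120L, x_edge = 20L)       # edge runs along y
  tf <- boundary_tangent_field(tum, max_dist_um = 40)
  expect_lt(max(abs(90 - tf[25:50, 40:80])), 2)
  circ <- circle_tumor(n = 231L, r = 80)
  geom <- boundary_geometry(circ)
  set.seed(5)
  ang <- runif(200, 0, 2 * pi)
  rr <- runif(200, 84, 110)
  pts <- cbind(115 + rr * cos(ang), 115 + rr * sin(ang))
  tang <- peristroma:::tangent_at_points(geom, pts)
  radial <- (atan2(pts[, 2] - 115, pts[, 1] - 115) * 180 / pi) %% 180
  mism <- abs(peristroma:::axial_diff(tang, (radial + 90) %% 180))
  expect_lt(max(mism), 5)
  expect_error(boundary_geometry(region_mask(matrix(1L, 5, 5))), "whole raster")
})

test_that("stroma between close clusters is excluded; distant or single clusters are not", {
  cfg <- analysis_config(band_width_um = 10, n_bands = 5,   # 50 um range
                         plateau_band_count = 2)
  n <- 300L
  two <- function(gap_px) {
    m <- matrix(0L, n, n)
    m[40:60, 140:160] <- 1L
    m[(60 + gap_px):(80 + gap_px), 140:160] <- 1L
    region_mask(m, calibration = cal1)
  }
  far <- mark_exclusions(distance_bands(two(150L), cfg), cfg)
  expect_equal(sum(far$excluded), 0L)
  near <- mark_exclusions(distance_bands(two(40L), cfg), cfg)
  expect_gt(sum(near$excluded), 0L)
  # the corridor midline between the clusters is excluded
  expect_true(all(near$excluded[90, 145:155]))
  one <- mark_exclusions(distance_bands(strip_tumor(n = 80L), cfg), cfg)
  expect_equal(sum(one$excluded), 0L)
})

test_that("parallel fractions, plateau mean and deviation ratios follow the band profile arithmetic", {
  cfg <- analysis_config(band_width_um = 10, n_bands = 11, parallel_range_deg = 15)
  tum <- strip_tumor(n = 160L, x_edge = 20L)       # tangent 90 everywhere east
  bands <- distance_bands(tum, cfg)
  geom <- boundary_geometry(tum, cfg)
  rows <- list()
  # band 1 (x = 25, distance 6): 10 fibers, 3 parallel -> R = 0.3
  for (i in 1:10) rows[[i]] <- fiber_rows(i, 25, 20 + 12 * i,
                                          if (i <= 3) 90 else 45)
  # plateau bands 7..11 (distances 61..70 etc.): 4 fibers each, 1 parallel -> R = 0.25
  id <- 10L
  for (b in 7:11) for (j in 1:4) {
    id <- id + 1L
    rows[[id]] <- fiber_rows(id, 20 + (b - 1) * 10 + 5, 15 + 30 * j,
                             if (j == 1) 85 else 30)
  }
  f <- field_from_fibers(rows, dim = c(160, 160))
  prof <- parallel_fraction_profile(f, bands, geom, cfg)
  p <- prof$profile
  expect_equal(p$n[1], 10L)
  expect_equal(p$R[1], 0.3)
  expect_equal(prof$R_bar, 0.25)
  expect_equal(p$ratio[1], 0.2)                    # |0.30 - 0.25| / 0.25
  expect_equal(p$ratio[7], 0.0)                    # R = Rbar on the plateau
  expect_true(all(is.na(p$R[2:6])))                # empty bands carry no R
  part <- define_peritumoral_extension(prof, cfg)
  expect_equal(part$extension_bands, 1L)           # run stops at empty band 2
  expect_equal(part$extension_um, 10)
})

test_that("boundary-relative angle windows count inclusively at the 15-degree edge", {
  cfg <- analysis_config(band_width_um = 10, n_bands = 11)
  tum <- strip_tumor(n = 160L, x_edge = 20L)
  bands <- distance_bands(tum, cfg)
  geom <- boundary_geometry(tum, cfg)
  rows <- list(fiber_rows(1, 25, 60, 80),          # delta 10 -> parallel
               fiber_rows(2, 25, 90, 70))          # delta 20 -> not
  for (b in 7:11) for (j in 1:2)
    rows[[length(rows) + 1L]] <- fiber_rows(10 * b + j, 20 + (b - 1) * 10 + 5,
                                            30 + 40 * j, 90)
  f <- field_from_fibers(rows, dim = c(160, 160))
  p <- parallel_fraction_profile(f, bands, geom, cfg)$profile
  expect_equal(p$R[1], 0.5)
  expect_equal(p$R[7], 1.0)
})

test_that("the extension rule takes the leading super-threshold run, with an inverse switch", {
  cfg <- analysis_config()
  tum <- strip_tumor(n = 300L, x_edge = 20L)
  bands <- distance_bands(tum, cfg)
  ratios <- c(0.20, 0.15, 0.08, 0.03, 0.02, 0.01, 0.02, 0.01, 0.03, 0.02, 0.01)
  prof <- structure(list(profile = data.frame(band = 1:11, n = 100,
                                              R = 0.5, ratio = ratios),
                         R_bar = 0.5, band_width_um = 22.4, n_bands = 11L,
                         plateau_bands = 7:11, bands = bands, cfg = cfg,
                         flagged = character(0)),
                    class = "band_profile")
  part <- define_peritumoral_extension(prof, cfg)
  expect_equal(part$extension_um, 67.2)            # 3 bands of 22.4 um
  # all ratios below threshold: extension 0, flagged
  prof0 <- prof; prof0$profile$ratio <- rep(0.01, 11)
  part0 <- define_peritumoral_extension(prof0, cfg)
  expect_equal(part0$extension_um, 0)
  expect_match(paste(part0$flagged, collapse = " "), "no detectable")
  # literal label direction: leading sub-threshold run
  cfg_inv <- analysis_config(invert_region_rule = TRUE)
  prof_inv <- prof; prof_inv$cfg <- cfg_inv
  part_inv <- define_peritumoral_extension(prof_inv, cfg_inv)
  expect_equal(part_inv$extension_bands, 0L)       # band 1 deviates -> run empty
  expect_equal(define_peritumoral_extension(prof0, cfg_inv)$extension_bands, 11L)
  # labels partition the raster: every pixel gets exactly one role
  counts <- table(factor(part$labels, levels = 0:4))
  expect_equal(sum(counts), length(part$labels))
})

test_that("an undefined plateau leaves the partition flagged without labels", {
  cfg <- analysis_config(band_width_um = 10, n_bands = 11)
  tum <- strip_tumor(n = 160L, x_edge = 20L)
  bands <- distance_bands(tum, cfg)
  # fibers only in band 1; plateau bands empty
  f <- field_from_fibers(list(fiber_rows(1, 25, 80, 90)), dim = c(160, 160))
  prof <- parallel_fraction_profile(f, bands, boundary_geometry(tum, cfg), cfg)
  expect_true(is.na(prof$R_bar))
  part <- define_peritumoral_extension(prof, cfg)
  expect_true(is.na(part$extension_um))
  expect_match(paste(part$flagged, collapse = " "), "not computable")
})

test_that("dilating the tumor never increases a pixel's band index", {
  cfg <- analysis_config(band_width_um = 8, n_bands = 6)
  tum <- circle_tumor(n = 141L, r = 18)
  b1 <- distance_bands(tum, cfg)$band
  big <- region_mask(EBImage::imageData(EBImage::dilate(tum$raster,
                       EBImage::makeBrush(7, "disc"))),
                     calibration = cal1)
  b2 <- distance_bands(big, cfg)$band
  to_ord <- function(b) { o <- b; o[o == 255L] <- 7L; o }
  expect_true(all(to_ord(b2) <= to_ord(b1)))
})

test_that("ROI generation is deterministic, non-overlapping and region-confined", {
  part <- strip_partition(n = 300L, tumor_w = 20L, peri_w = 86L)
  cfg <- analysis_config()
  r1 <- generate_rois(part, cfg, seed = 9)
  r2 <- generate_rois(part, cfg, seed = 9)
  expect_identical(r1, r2)
  expect_gte(sum(r1$tag == "peritumoral"), 2L)
  expect_gte(sum(r1$tag == "distant"), 2L)
  expect_true(all(r1$side_px == 86L))
  expect_lte(nrow(r1), 24L)
  # containment: every ROI pixel carries its tag's label
  for (i in seq_len(nrow(r1))) {
    code <- if (r1$tag[i] == "peritumoral") 1L else 2L
    block <- part$labels[r1$x[i] + 1:86, r1$y[i] + 1:86]
    expect_true(all(block == code))
  }
  # pairwise non-overlap
  if (nrow(r1) > 1L) {
    for (i in 1:(nrow(r1) - 1L)) for (j in (i + 1L):nrow(r1)) {
      expect_false(abs(r1$x[i] - r1$x[j]) < 86 & abs(r1$y[i] - r1$y[j]) < 86)
    }
  }
  # a cramped region yields fewer (possibly zero) ROIs, flagged
  tight <- strip_partition(n = 120L, tumor_w = 20L, peri_w = 86L)
  rt <- generate_rois(tight, cfg, seed = 1)
  expect_lte(sum(rt$tag == "peritumoral"), 1L)
  expect_match(paste(attr(rt, "flagged"), collapse = " "), "peritumoral")
})

test_that("synthetic tissue recovery: the delineation recovers the built-in extension", {
  for (k in c(3L, 5L)) {
    ext <- vapply(1:30, function(s) recover_extension(k, seed = 7000L + 31L * k + s),
                  numeric(1))
    exact <- mean(ext == k * 22.4)
    expect_gte(exact, 0.9)
    expect_true(all(abs(ext - k * 22.4) <= 22.4))
  }
})

test_that("isotropic fiber fields mostly yield a zero extension with fluctuating ratios", {
  ext <- vapply(1:20, function(s)
    recover_extension(2L, seed = 900L + s, orientation_mode = "isotropic"),
    numeric(1))
  expect_gt(mean(ext == 0), 0.5)
})
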