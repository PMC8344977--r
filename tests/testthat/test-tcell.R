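# Particle filtering and region-wise T-cell quantification.

square_blob <- function(m, x, y, s) { m[x + 0:(s - 1), y + 0:(s - 1)] <- 1L; m }

test_that("the particle filter removes exactly the components below the area threshold", {
  m <- matrix(0L, 80, 80)
  m <- square_blob(m, 2, 2, 3)     #  9 px -> removed
  m <- square_blob(m, 20, 2, 5)    # 25 px -> kept (boundary)
  m <- square_blob(m, 40, 2, 10)   # 100 px -> kept
  m[60, 2:25] <- 1L                # 24 px line -> removed
  msk <- region_mask(m, role = "tcell", calibration = cal1)
  filt <- particle_filter(msk, analysis_config(min_particle_area_px = 25))
  expect_equal(sum(filt$raster), 125L)
  expect_equal(filt$raster[20:24, 2:6], matrix(1L, 5, 5))
  # idempotent, and empty masks pass through
  expect_identical(particle_filter(filt)$raster, filt$raster)
  empty <- region_mask(matrix(0L, 10, 10), role = "tcell", calibration = cal1)
  expect_equal(sum(particle_filter(empty)$raster), 0L)
})

test_that("particle connectivity is 8-connected and filtering is monotone in the threshold", {
  # two diagonally-touching 13 px blocks: one 26 px component under
  # 8-connectivity, two sub-threshold pieces under 4-connectivity
  m <- matrix(0L, 40, 40)
  m[5:8, 5:7] <- 1L; m[4, 5] <- 1L              # 13 px
  m[9:12, 8:10] <- 1L; m[13, 10] <- 1L          # 13 px, touches (8,7) diagonally
  msk <- region_mask(m, role = "tcell", calibration = cal1)
  kept <- particle_filter(msk, analysis_config(min_particle_area_px = 25))
  expect_equal(sum(kept$raster), sum(m))
  # raising the threshold never adds pixels
  a25 <- particle_filter(msk, analysis_config(min_particle_area_px = 25))$raster
  a30 <- particle_filter(msk, analysis_config(min_particle_area_px = 30))$raster
  expect_true(all(a30 <= a25))
})

test_that("region areas, densities and coefficients follow the defining formulas", {
  expect_equal(tcell_density(0.05, 1.0), 5.0)
  expect_equal(tcell_density(0.3, 0.3), 100.0)
  expect_equal(tcell_density(0, 2), 0.0)
  expect_true(is.na(tcell_density(0.1, 0)))
  expect_equal(tcell_coefficient(0.05, 0.2, 1.0), 0.25)
  expect_equal(tcell_coefficient(0.2, 0.2, 0.5), 1 / 0.5)  # all T-cells in region
  expect_equal(tcell_coefficient(0, 0.2, 1.0), 0.0)
  expect_true(is.na(tcell_coefficient(0.1, 0, 1)))
  # 1,000,000 px at 1 um/px = 1 mm^2; halving the pitch quarters the area
  part <- strip_partition(n = 1000L, tumor_w = 0L, peri_w = 500L)
  a <- region_areas(part)
  expect_equal(sum(a), 1.0)
  part$calibration <- calibration(0.5, 0.5)
  expect_equal(sum(region_areas(part)), 0.25)
})

test_that("the coefficient identity holds and saturates when all T-cells are in-region", {
  part <- strip_partition(n = 200L, tumor_w = 20L, peri_w = 60L)
  m <- matrix(0L, 200, 200)
  m <- square_blob(m, 30, 30, 10)    # peritumoral
  m <- square_blob(m, 120, 80, 12)   # distant
  st <- quantify_tcells(region_mask(m, "tcell", cal1), part)
  lhs <- st$coeff_peritumoral_per_mm2 * st$peritumoral_area_mm2 +
    st$coeff_distant_per_mm2 * st$distant_area_mm2
  expect_equal(lhs, 1.0)             # every T-cell pixel is in a region
  # a blob on tumor counts toward the total but neither region
  m2 <- square_blob(m, 2, 2, 10)
  st2 <- quantify_tcells(region_mask(m2, "tcell", cal1), part)
  lhs2 <- st2$coeff_peritumoral_per_mm2 * st2$peritumoral_area_mm2 +
    st2$coeff_distant_per_mm2 * st2$distant_area_mm2
  expect_equal(lhs2, (st2$peritumoral_tcell_area_mm2 +
                      st2$distant_tcell_area_mm2) / st2$total_tcell_area_mm2)
  expect_lt(lhs2, 1.0)
  expect_gt(st2$total_tcell_area_mm2, st$total_tcell_area_mm2)
})

test_that("synthetic T-cell masks recover their target densities", {
  part <- strip_partition(n = 400L, tumor_w = 40L, peri_w = 120L)
  sim <- simulate_tcells(part, tcell_sim_spec(density_peritumoral_pct = 5,
                                              density_distant_pct = 2,
                                              seed = 21))
  st <- quantify_tcells(sim$mask, part)
  expect_equal(st$density_peritumoral_pct, 5, tolerance = 0.2)
  expect_equal(st$density_distant_pct, 2, tolerance = 0.2)
  expect_equal(st$density_peritumoral_pct, sim$truth$realised_pct[["peritumoral"]],
               tolerance = 1e-10)
  # zero target leaves the region empty
  sim0 <- simulate_tcells(part, tcell_sim_spec(density_peritumoral_pct = 0,
                                               density_distant_pct = 3,
                                               seed = 4))
  expect_equal(quantify_tcells(sim0$mask, part)$density_peritumoral_pct, 0,
               tolerance = 0.05)
})
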