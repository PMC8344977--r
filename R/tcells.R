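# Region-wise T-cell quantification: particle filtering, areas, densities
# and distribution coefficients.

#' Remove sub-cellular particles from a binary mask
#'
#' Deletes 8-connected components whose pixel area is strictly below the
#' threshold (default 25 px^2, the virtual particle filter applied to
#' segmented T-cell masks); all retained components are preserved bit-exactly.
#' Idempotent and monotone in the threshold.
#'
#' @param mask A [region_mask()].
#' @param cfg An [analysis_config()] (uses `min_particle_area_px`).
#' @return The filtered [region_mask()].
#' @export
particle_filter <- function(mask, cfg = analysis_config()) {
  stopifnot(inherits(mask, "region_mask"))
  if (sum(mask$raster) == 0L || cfg$min_particle_area_px <= 1) return(mask)
  lab <- label8(mask$raster)
  areas <- component_areas(lab)
  drop <- which(areas < cfg$min_particle_area_px)
  if (length(drop)) {
    r <- mask$raster
    r[lab %in% drop] <- 0L
    mask$raster <- r
  }
  mask
}

#' Areas of the peritumoral and tumor-cell-distant regions
#'
#' @param partition A `stroma_partition` with labels.
#' @return Named numeric vector `c(peritumoral =, distant =)` in mm^2.
#' @export
region_areas <- function(partition) {
  stopifnot(inherits(partition, "stroma_partition"))
  if (is.null(partition$labels)) stop("partition carries no labels")
  cal <- partition$calibration
  c(peritumoral = px_to_mm2(sum(partition$labels == 1L), cal),
    distant = px_to_mm2(sum(partition$labels == 2L), cal))
}

#' T-cell density of a stroma region
#'
#' `100 * tcell_area / region_area`, in percent of the region covered by
#' T-cells.
#'
#' @param tcell_area_mm2 T-cell area inside the region, mm^2.
#' @param region_area_mm2 Region area, mm^2 (> 0).
#' @return Density in percent; `NA` when the region area is zero.
#' @export
tcell_density <- function(tcell_area_mm2, region_area_mm2) {
  ifelse(region_area_mm2 > 0, 100 * tcell_area_mm2 / region_area_mm2, NA_real_)
}

#' T-cell distribution coefficient of a stroma region
#'
#' The region's share of the image's total T-cell area, normalised by the
#' region area: `(tcell_area / total_tcell_area) / region_area`, in 1/mm^2.
#'
#' @param tcell_area_mm2 T-cell area inside the region, mm^2.
#' @param total_tcell_area_mm2 Total T-cell area of the image, mm^2 (> 0).
#' @param region_area_mm2 Region area, mm^2 (> 0).
#' @return Coefficient in 1/mm^2; `NA` when either denominator is zero.
#' @export
tcell_coefficient <- function(tcell_area_mm2, total_tcell_area_mm2,
                              region_area_mm2) {
  ifelse(total_tcell_area_mm2 > 0 & region_area_mm2 > 0,
         (tcell_area_mm2 / total_tcell_area_mm2) / region_area_mm2, NA_real_)
}

#' Quantify a T-cell mask over a stroma partition
#'
#' Applies the particle filter, measures the T-cell area overall and inside
#' the peritumoral and tumor-cell-distant regions, and computes the two
#' densities and two distribution coefficients. T-cell pixels on excluded or
#' beyond-range stroma (or on tumor) count toward the total T-cell area but
#' toward neither region, which makes the identity
#' `coeff_p * area_p + coeff_d * area_d <= 1` exact.
#'
#' @param tcells A T-cell [region_mask()] with the same dimensions as the
#'   partition.
#' @param partition A `stroma_partition` with labels.
#' @param cfg An [analysis_config()].
#' @return An object of class `tcell_stats` (one-row data frame): areas
#'   (mm^2), densities (%) and coefficients (1/mm^2) per region.
#' @export
quantify_tcells <- function(tcells, partition, cfg = analysis_config()) {
  stopifnot(inherits(tcells, "region_mask"),
            inherits(partition, "stroma_partition"))
  if (is.null(partition$labels)) stop("partition carries no labels")
  stopifnot(all(dim(tcells$raster) == dim(partition$labels)))
  filt <- particle_filter(tcells, cfg)
  cal <- tcells$calibration
  fg <- filt$raster != 0L
  areas <- region_areas(partition)
  total <- px_to_mm2(sum(fg), cal)
  peri_t <- px_to_mm2(sum(fg & partition$labels == 1L), cal)
  dist_t <- px_to_mm2(sum(fg & partition$labels == 2L), cal)
  out <- data.frame(
    total_tcell_area_mm2 = total,
    peritumoral_tcell_area_mm2 = peri_t,
    distant_tcell_area_mm2 = dist_t,
    peritumoral_area_mm2 = areas[["peritumoral"]],
    distant_area_mm2 = areas[["distant"]],
    density_peritumoral_pct = tcell_density(peri_t, areas[["peritumoral"]]),
    density_distant_pct = tcell_density(dist_t, areas[["distant"]]),
    coeff_peritumoral_per_mm2 = tcell_coefficient(peri_t, total, areas[["peritumoral"]]),
    coeff_distant_per_mm2 = tcell_coefficient(dist_t, total, areas[["distant"]]))
  class(out) <- c("tcell_stats", class(out))
  out
}

#' @export
print.tcell_stats <- function(x, ...) {
  cat("T-cell quantification\n")
  cat(sprintf("  areas (mm^2): total %.4g, peritumoral %.4g, distant %.4g\n",
              x$total_tcell_area_mm2, x$peritumoral_tcell_area_mm2,
              x$distant_tcell_area_mm2))
  cat(sprintf("  density: peritumoral %.4g%%, distant %.4g%%\n",
              x$density_peritumoral_pct, x$density_distant_pct))
  cat(sprintf("  coefficient (1/mm^2): peritumoral %.4g, distant %.4g\n",
              x$coeff_peritumoral_per_mm2, x$coeff_distant_per_mm2))
  invisible(x)
}
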