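# Delineation of individual peritumoral stroma regions from the
# distance-resolved angular distribution of collagen fibers around
# tumor-cell clusters.

#' Boundary geometry of a tumor mask
#'
#' Traces the contour of every 8-connected tumor cluster, smooths it with a
#' circular moving average and attaches an axial tangent direction to every
#' contour sample. Unsmoothed discrete tangents alias badly on raster
#' contours, hence the smoothing window (default 11 samples).
#'
#' @param tumor A tumor [region_mask()].
#' @param cfg An [analysis_config()] (uses `tangent_smooth_window`).
#' @return An object of class `boundary_geometry`: `samples` (n x 2 matrix,
#'   0-based pixel coordinates), `tangent_deg` (axial, `[0, 180)`),
#'   `cluster_id`.
#' @export
boundary_geometry <- function(tumor, cfg = analysis_config()) {
  stopifnot(inherits(tumor, "region_mask"), tumor$role == "tumor")
  if (sum(tumor$raster) == 0L) stop("empty tumor mask")
  if (all(tumor$raster != 0L)) stop("tumor mask covers the whole raster")
  lab <- label8(tumor$raster)
  ctrs <- EBImage::ocontour(lab)
  samples <- list(); tangents <- list(); ids <- list()
  for (i in seq_along(ctrs)) {
    p <- ctrs[[i]]
    if (nrow(p) < 3L) {               # tiny cluster: isotropic tangent undefined; use 0
      samples[[i]] <- p
      tangents[[i]] <- rep(0, nrow(p))
      ids[[i]] <- rep(i, nrow(p))
      next
    }
    ps <- smooth_closed(p, cfg$tangent_smooth_window)
    n <- nrow(ps)
    st <- min(3L, (n - 1L) %/% 2L)      # wider stencil damps raster aliasing
    nxt <- ((seq_len(n) - 1L + st) %% n) + 1L
    prv <- ((seq_len(n) - 1L - st) %% n) + 1L
    tan_deg <- fold_axial(atan2(ps[nxt, 2] - ps[prv, 2],
                                ps[nxt, 1] - ps[prv, 1]) * 180 / pi)
    samples[[i]] <- p                 # query positions stay on the raw contour
    tangents[[i]] <- tan_deg
    ids[[i]] <- rep(i, n)
  }
  structure(list(samples = do.call(rbind, samples),
                 tangent_deg = unlist(tangents),
                 cluster_id = unlist(ids),
                 n_clusters = length(ctrs)),
            class = "boundary_geometry")
}

# Nearest-contour-sample tangent for query points (m x 2, 0-based px).
# Exact nearest neighbour via class::knn1; contours are O(10^3) samples.
tangent_at_points <- function(geom, pts) {
  stopifnot(inherits(geom, "boundary_geometry"))
  pts <- matrix(as.numeric(pts), ncol = 2)
  if (nrow(pts) == 0L) return(numeric(0))
  S <- geom$samples
  if (nrow(S) == 1L) return(rep(geom$tangent_deg, nrow(pts)))
  idx <- as.integer(class::knn1(S, pts, factor(seq_len(nrow(S)))))
  geom$tangent_deg[idx]
}

#' Per-pixel nearest-boundary tangent field
#'
#' For every stromal pixel (optionally limited to a maximal distance from
#' the tumor), the axial tangent direction of the tumor contour at its
#' nearest boundary sample. Pixels belonging to the nearer of two clusters
#' take that cluster's tangent.
#'
#' @param tumor A tumor [region_mask()].
#' @param cfg An [analysis_config()].
#' @param max_dist_um Restrict the field to pixels within this distance of
#'   the tumor (default: the full analysis range `n_bands * band_width_um`;
#'   `Inf` for the whole raster).
#' @return Numeric matrix in `[x, y]` layout of axial tangent angles
#'   (degrees); `NA` inside the tumor and beyond `max_dist_um`.
#' @export
boundary_tangent_field <- function(tumor, cfg = analysis_config(),
                                   max_dist_um = cfg$n_bands * cfg$band_width_um) {
  geom <- boundary_geometry(tumor, cfg)
  r <- tumor$raster
  dist_um <- as.matrix(EBImage::distmap(1 - r)) * tumor$calibration$microns_per_pixel
  sel <- which(r == 0L & dist_um <= max_dist_um)
  pts <- cbind((sel - 1L) %% nrow(r), (sel - 1L) %/% nrow(r))
  out <- matrix(NA_real_, nrow(r), ncol(r))
  out[sel] <- tangent_at_points(geom, pts)
  out
}

#' Distance bands around tumor clusters
#'
#' Euclidean distance transform of the stroma to the nearest tumor pixel,
#' banded at multiples of the band width: band k covers distances in
#' `((k-1) w, k w]` (a distance of exactly `k w` belongs to band k), band 0
#' is the tumor itself, and pixels beyond `n_bands * w` are labelled beyond
#' range (255).
#'
#' @param tumor A tumor [region_mask()].
#' @param cfg An [analysis_config()].
#' @return An object of class `band_field`: integer `band` matrix, `dist_um`
#'   matrix, logical `excluded` matrix (all `FALSE` until
#'   [mark_exclusions()]), band width, number of bands, calibration, and the
#'   tumor raster.
#' @export
distance_bands <- function(tumor, cfg = analysis_config()) {
  stopifnot(inherits(tumor, "region_mask"))
  if (sum(tumor$raster) == 0L) stop("empty tumor mask")
  cal <- tumor$calibration
  dist_um <- as.matrix(EBImage::distmap(1 - tumor$raster)) * cal$microns_per_pixel
  band <- ceiling(dist_um / cfg$band_width_um)
  band[tumor$raster != 0L] <- 0L
  band[band > cfg$n_bands] <- 255L
  storage.mode(band) <- "integer"
  structure(list(band = band, dist_um = dist_um,
                 excluded = matrix(FALSE, nrow(band), ncol(band)),
                 band_width_um = cfg$band_width_um, n_bands = cfg$n_bands,
                 calibration = cal, tumor = tumor),
            class = "band_field")
}

#' Flag stroma contested between nearby tumor clusters
#'
#' Stromal pixels lying within the analysis range of two or more distinct
#' tumor clusters cannot be attributed to a single cluster's stroma region
#' and are excluded from the band analysis (the narrow corridors between
#' close clusters).
#'
#' @param bands A [distance_bands()] result.
#' @param cfg An [analysis_config()].
#' @return The `band_field` with its `excluded` matrix filled in.
#' @export
mark_exclusions <- function(bands, cfg = analysis_config()) {
  stopifnot(inherits(bands, "band_field"))
  tumor <- bands$tumor
  lab <- label8(tumor$raster)
  k <- max(lab)
  if (k >= 2L) {
    range_um <- bands$n_bands * bands$band_width_um
    um <- bands$calibration$microns_per_pixel
    count <- matrix(0L, nrow(lab), ncol(lab))
    for (c in seq_len(k)) {
      dc <- as.matrix(EBImage::distmap(1 - (lab == c))) * um
      count <- count + (dc <= range_um & lab != c)
    }
    bands$excluded <- count >= 2L & tumor$raster == 0L
  }
  bands
}

#' Distance-resolved parallel-fiber fraction profile
#'
#' For each distance band, the fraction R of fibers whose axial orientation
#' lies within `parallel_range_deg` of the local tumor-boundary tangent,
#' the plateau mean Rbar over the outermost `plateau_band_count` bands (only
#' bands containing fibers contribute), and the per-band deviation ratio
#' `|R - Rbar| / Rbar`. Each fiber is assigned to the band of its arc-length
#' midpoint; fibers on excluded stroma, inside the tumor, beyond range, or
#' without a defined orientation are left out.
#'
#' @param field A [fiber_field()] with polylines.
#' @param bands A [distance_bands()] result (after [mark_exclusions()] if
#'   the mask has several clusters).
#' @param geom Optional precomputed [boundary_geometry()].
#' @param cfg An [analysis_config()].
#' @return An object of class `band_profile`: data frame `profile` with
#'   columns `band`, `n`, `R`, `ratio`; plus `R_bar`, `band_width_um`,
#'   `n_bands`, `flagged`.
#' @export
parallel_fraction_profile <- function(field, bands, geom = NULL,
                                      cfg = analysis_config()) {
  stopifnot(inherits(field, "fiber_field"), inherits(bands, "band_field"))
  if (!field$has_polylines)
    stop("summary-only fiber field: band assignment needs polylines")
  if (is.null(geom)) geom <- boundary_geometry(bands$tumor, cfg)
  fib <- field$fibers
  nb <- bands$n_bands
  ix <- pmin(pmax(round(fib$mid_x_px) + 1L, 1L), nrow(bands$band))
  iy <- pmin(pmax(round(fib$mid_y_px) + 1L, 1L), ncol(bands$band))
  band_at <- bands$band[cbind(ix, iy)]
  excl_at <- bands$excluded[cbind(ix, iy)]
  keep <- band_at >= 1L & band_at <= nb & !excl_at & !is.na(fib$orientation_deg)
  delta <- rep(NA_real_, nrow(fib))
  if (any(keep)) {
    tang <- tangent_at_points(geom, cbind(fib$mid_x_px[keep], fib$mid_y_px[keep]))
    delta[keep] <- axial_diff(fib$orientation_deg[keep], tang)
  }
  n <- tabulate(band_at[keep], nbins = nb)
  par_count <- tabulate(band_at[keep & delta <= cfg$parallel_range_deg],
                        nbins = nb)
  R <- ifelse(n > 0, par_count / n, NA_real_)
  plateau <- (nb - cfg$plateau_band_count + 1L):nb
  plat_ok <- plateau[n[plateau] > 0]
  R_bar <- if (length(plat_ok)) mean(R[plat_ok]) else NA_real_
  flagged <- character(0)
  if (!length(plat_ok)) flagged <- c(flagged, "no fibers in plateau bands")
  else if (R_bar == 0) flagged <- c(flagged, "plateau parallel fraction is zero; ratios undefined")
  ratio <- if (!is.na(R_bar) && R_bar > 0) abs(R - R_bar) / R_bar else rep(NA_real_, nb)
  structure(list(profile = data.frame(band = seq_len(nb), n = n, R = R,
                                      ratio = ratio),
                 R_bar = R_bar, band_width_um = bands$band_width_um,
                 n_bands = nb, plateau_bands = plateau,
                 bands = bands, cfg = cfg, flagged = flagged),
            class = "band_profile")
}

#' Define the peritumoral extension and partition the stroma
#'
#' The peritumoral stroma region is the contiguous run of bands, starting at
#' the tumor boundary, whose deviation ratio `|R - Rbar|/Rbar` exceeds the
#' threshold (default 5%), i.e. whose collagen orientation still deviates
#' from the distant plateau; its extension is that run length times the band
#' width. Bands at and beyond the first sub-threshold band form the
#' tumor-cell-distant region. Setting `invert_region_rule` in the config
#' applies the opposite label direction.
#'
#' @param profile A [parallel_fraction_profile()] result.
#' @param cfg An [analysis_config()] (defaults to the one used for the
#'   profile).
#' @return An object of class `stroma_partition`: `extension_um`,
#'   `extension_bands`, label matrix `labels` (0 tumor, 1 peritumoral,
#'   2 distant, 3 excluded, 4 beyond range), the profile, and `flagged`.
#' @export
define_peritumoral_extension <- function(profile, cfg = profile$cfg) {
  stopifnot(inherits(profile, "band_profile"))
  flagged <- profile$flagged
  if (is.na(profile$R_bar) || profile$R_bar == 0) {
    return(structure(list(extension_um = NA_real_, extension_bands = NA_integer_,
                          labels = NULL, profile = profile,
                          calibration = profile$bands$calibration,
                          flagged = c(flagged, "extension not computable")),
                     class = "stroma_partition"))
  }
  r <- profile$profile$ratio
  dev <- if (cfg$invert_region_rule) r < cfg$ratio_threshold
         else r > cfg$ratio_threshold
  dev[is.na(dev)] <- FALSE
  k <- if (dev[1]) which.min(c(dev, FALSE)) - 1L else 0L
  if (k == 0L) flagged <- c(flagged, "no detectable peritumoral region")
  bands <- profile$bands
  b <- bands$band
  labels <- matrix(2L, nrow(b), ncol(b))
  labels[b == 0L] <- 0L
  if (k > 0L) labels[b >= 1L & b <= k] <- 1L
  labels[b == 255L] <- 4L
  labels[bands$excluded & b != 0L] <- 3L
  structure(list(extension_um = k * profile$band_width_um,
                 extension_bands = k, labels = labels, profile = profile,
                 calibration = bands$calibration, flagged = flagged),
            class = "stroma_partition")
}

#' Delineate stroma regions around tumor clusters
#'
#' Convenience wrapper running the whole delineation: distance bands,
#' between-cluster exclusions, boundary tangents, the parallel-fraction
#' profile and the extension rule.
#'
#' @param tumor A tumor [region_mask()].
#' @param fibers A [fiber_field()] with polylines.
#' @param cfg An [analysis_config()].
#' @return A `stroma_partition` (see [define_peritumoral_extension()]).
#' @examples
#' sim <- simulate_tissue(tissue_sim_spec(seed = 1, fibers_per_band = 300))
#' part <- delineate_regions(sim$tumor, sim$fibers)
#' part$extension_um
#' @export
delineate_regions <- function(tumor, fibers, cfg = analysis_config()) {
  bands <- distance_bands(tumor, cfg)
  bands <- mark_exclusions(bands, cfg)
  geom <- boundary_geometry(tumor, cfg)
  prof <- parallel_fraction_profile(fibers, bands, geom, cfg)
  define_peritumoral_extension(prof, cfg)
}

#' Generate square analysis ROIs inside the partitioned stroma
#'
#' Places axis-aligned square ROIs with side equal to the peritumoral
#' extension: peritumoral ROIs abut the tumor boundary (candidates are
#' ranked by distance to the tumor), tumor-cell-distant ROIs lie beyond the
#' extension. ROIs never overlap, lie wholly inside their region, and avoid
#' excluded pixels; between 2 and 12 are placed per region (as many as fit),
#' with seeded, reproducible placement.
#'
#' @param partition A `stroma_partition` with a positive extension.
#' @param cfg An [analysis_config()].
#' @param seed Integer seed for the placement order.
#' @param max_rois Maximum ROIs per region (default 12).
#' @return Data frame with columns `tag` ("peritumoral"/"distant"), `x`,
#'   `y` (0-based top-left corner, px), `side_px`. Regions where fewer than
#'   2 ROIs fit are flagged via the `attr(, "flagged")` character vector.
#' @export
generate_rois <- function(partition, cfg = analysis_config(), seed = 1L,
                          max_rois = 12L) {
  stopifnot(inherits(partition, "stroma_partition"))
  if (is.na(partition$extension_bands) || partition$extension_bands == 0L)
    stop("no peritumoral extension: cannot size ROIs")
  um <- partition$calibration$microns_per_pixel
  side <- max(1L, round(partition$extension_um / um))
  labels <- partition$labels
  dist_um <- partition$profile$bands$dist_um
  flagged <- character(0)
  out <- list()
  with_seed(seed, {
    for (tag in c("peritumoral", "distant")) {
      code <- if (tag == "peritumoral") 1L else 2L
      feas <- feasible_squares(labels == code, side)
      if (!nrow(feas)) {
        flagged <- c(flagged, paste0("no ", tag, " ROI fits"))
        next
      }
      ord <- if (tag == "peritumoral") {
        ctr_d <- dist_um[cbind(feas[, 1] + side %/% 2L, feas[, 2] + side %/% 2L)]
        order(ctr_d + stats::runif(nrow(feas), 0, 1e-3))
      } else sample.int(nrow(feas))
      chosen <- matrix(integer(0), ncol = 2)
      for (i in ord) {
        cand <- feas[i, ]
        if (nrow(chosen) &&
            any(abs(cand[1] - chosen[, 1]) < side & abs(cand[2] - chosen[, 2]) < side))
          next
        chosen <- rbind(chosen, cand)
        if (nrow(chosen) >= max_rois) break
      }
      if (nrow(chosen) < 2L)
        flagged <- c(flagged, paste0("fewer than 2 ", tag, " ROIs fit"))
      if (nrow(chosen))
        out[[tag]] <- data.frame(tag = tag, x = chosen[, 1] - 1L,
                                 y = chosen[, 2] - 1L, side_px = side)
    }
  })
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(tag = character(0), x = integer(0), y = integer(0),
               side_px = integer(0))
  row.names(res) <- NULL
  attr(res, "flagged") <- flagged
  res
}

# Top-left corners (1-based) of side x side squares fully inside `ind`.
feasible_squares <- function(ind, side) {
  nx <- nrow(ind); ny <- ncol(ind)
  if (nx < side || ny < side)
    return(matrix(integer(0), ncol = 2))
  S <- matrix(0, nx + 1L, ny + 1L)
  S[-1, -1] <- apply(apply(ind * 1, 2, cumsum), 1, cumsum) |> t()
  xs <- 1:(nx - side + 1L); ys <- 1:(ny - side + 1L)
  box <- S[xs + side, ys + side, drop = FALSE] -
         S[xs, ys + side, drop = FALSE] -
         S[xs + side, ys, drop = FALSE] + S[xs, ys, drop = FALSE]
  hit <- which(box == side * side, arr.ind = TRUE)
  cbind(xs[hit[, 1]], ys[hit[, 2]])
}

#' Write the band/exclusion label raster to TIFF
#'
#' Encoding: 0 tumor, 1..n_bands distance bands, 254 excluded, 255 beyond
#' range.
#'
#' @param bands A [distance_bands()] result.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_band_labels <- function(bands, path) {
  stopifnot(inherits(bands, "band_field"))
  lab <- bands$band
  lab[bands$excluded & lab != 0L] <- 254L
  tiff::writeTIFF(t(lab) / 255, path, bits.per.sample = 8L)
  invisible(path)
}
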