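#' Collagen fiber field
#'
#' A collection of collagen fibers with per-fiber metrics, covering one
#' raster. Fibers either carry full polylines (vertex table, from which
#' length, straightness, axial orientation and the arc-length midpoint are
#' derived) or only precomputed summary metrics (e.g. imported from external
#' fiber-extraction software), in which case geometry-requiring operations
#' refuse the field.
#'
#' @param vertices `NULL`, or a data frame with columns `fiber_id`,
#'   `vertex_index`, `x_px`, `y_px` (0-based pixel coordinates).
#' @param summary `NULL`, or a data frame with columns `fiber_id`,
#'   `length_um`, `width_um`, `straightness`, `angle_deg` (exactly one of
#'   `vertices`/`summary` must be given).
#' @param dim Raster dimensions `c(width_px, height_px)` (may be `NA`).
#' @param calibration A [calibration()].
#' @param width_um Optional per-fiber widths (um) carried alongside a vertex
#'   table, recycled to the number of fibers.
#' @return An object of class `fiber_field` with elements `fibers` (one row
#'   per fiber: `id`, `length_um`, `width_um`, `straightness`,
#'   `orientation_deg`, `mid_x_px`, `mid_y_px`), `vertices`, `dim`,
#'   `calibration`, `has_polylines`.
#' @export
fiber_field <- function(vertices = NULL, summary = NULL,
                        dim = c(NA_real_, NA_real_),
                        calibration = peristroma::calibration(),
                        width_um = NA_real_) {
  stopifnot(xor(is.null(vertices), is.null(summary)),
            inherits(calibration, "calibration"))
  if (!is.null(vertices)) {
    need <- c("fiber_id", "vertex_index", "x_px", "y_px")
    stopifnot(all(need %in% names(vertices)))
    vertices <- vertices[order(vertices$fiber_id, vertices$vertex_index), , drop = FALSE]
    row.names(vertices) <- NULL
    nv <- tabulate(factor(vertices$fiber_id))
    if (nrow(vertices) && any(nv < 2L))
      stop("fiber(s) with fewer than 2 vertices: ",
           paste(levels(factor(vertices$fiber_id))[nv < 2L], collapse = ", "))
    fib <- polyline_metrics(vertices, calibration)
    fib$width_um <- rep_len(width_um, nrow(fib))
    has_poly <- TRUE
  } else {
    need <- c("fiber_id", "length_um", "width_um", "straightness", "angle_deg")
    stopifnot(all(need %in% names(summary)))
    fib <- data.frame(id = summary$fiber_id,
                      length_um = summary$length_um,
                      width_um = summary$width_um,
                      straightness = summary$straightness,
                      orientation_deg = fold_axial(summary$angle_deg),
                      mid_x_px = NA_real_, mid_y_px = NA_real_)
    has_poly <- FALSE
  }
  structure(list(fibers = fib, vertices = vertices, dim = dim,
                 calibration = calibration, has_polylines = has_poly),
            class = "fiber_field")
}

# Vectorised per-fiber metrics from an ordered vertex table.
polyline_metrics <- function(v, cal) {
  if (nrow(v) == 0L) {
    return(data.frame(id = integer(0), length_um = numeric(0),
                      width_um = numeric(0), straightness = numeric(0),
                      orientation_deg = numeric(0),
                      mid_x_px = numeric(0), mid_y_px = numeric(0)))
  }
  f <- v$fiber_id
  first <- !duplicated(f)
  last <- !duplicated(f, fromLast = TRUE)
  ids <- f[first]
  n <- length(ids)
  dx <- diff(v$x_px); dy <- diff(v$y_px)
  segok <- !first[-1]                       # segment rows: vertex i-1 -> i within a fiber
  seglen <- sqrt(dx^2 + dy^2) * segok
  seg_fiber <- factor(f[-1], levels = ids)
  arc_px <- as.numeric(rowsum(seglen, seg_fiber, reorder = FALSE))
  cx <- v$x_px[first]; cy <- v$y_px[first]
  ex <- v$x_px[last];  ey <- v$y_px[last]
  chord_px <- sqrt((ex - cx)^2 + (ey - cy)^2)
  straight <- ifelse(arc_px > 0, chord_px / arc_px, NA_real_)
  orient <- ifelse(chord_px > 0,
                   fold_axial(atan2(ey - cy, ex - cx) * 180 / pi),
                   NA_real_)
  # arc-length midpoint: first segment whose cumulative length reaches arc/2
  cum <- cumsum(c(0, seglen))               # cum[i] = arc length up to vertex i
  start_cum <- cum[which(first)]
  rel_cum <- cum - start_cum[as.integer(factor(f, levels = ids))]
  target <- arc_px / 2
  tgt_row <- target[as.integer(factor(f, levels = ids))]
  prev_rel <- c(0, rel_cum[-length(rel_cum)])
  hit <- which(rel_cum >= tgt_row & prev_rel < tgt_row & c(FALSE, segok))
  mid_x <- cx; mid_y <- cy                  # degenerate fibers: first vertex
  if (length(hit)) {
    fi <- as.integer(factor(f[hit], levels = ids))
    slen <- rel_cum[hit] - prev_rel[hit]
    tfrac <- ifelse(slen > 0, (tgt_row[hit] - prev_rel[hit]) / slen, 0)
    mid_x[fi] <- v$x_px[hit - 1L] + tfrac * (v$x_px[hit] - v$x_px[hit - 1L])
    mid_y[fi] <- v$y_px[hit - 1L] + tfrac * (v$y_px[hit] - v$y_px[hit - 1L])
  }
  data.frame(id = ids,
             length_um = arc_px * cal$microns_per_pixel,
             width_um = NA_real_,
             straightness = straight,
             orientation_deg = orient,
             mid_x_px = mid_x, mid_y_px = mid_y)
}

#' @export
print.fiber_field <- function(x, ...) {
  cat(sprintf("fiber_field: %d fibers%s, %.4g um/px\n",
              nrow(x$fibers),
              if (x$has_polylines) " (with polylines)" else " (summary only)",
              x$calibration$microns_per_pixel))
  if (nrow(x$fibers)) {
    cat(sprintf("  mean length %.3g um, mean straightness %.3g, alignment %.3g\n",
                mean(x$fibers$length_um, na.rm = TRUE),
                mean(x$fibers$straightness, na.rm = TRUE),
                alignment_coefficient(x$fibers$orientation_deg)))
  }
  invisible(x)
}

# ---- per-fiber metric operations -------------------------------------------

#' Arc length of a fiber polyline
#'
#' @param vertices Numeric matrix (n >= 2 rows) of pixel coordinates, or a
#'   two-column data frame.
#' @param cal A [calibration()].
#' @return Length in micrometres (polyline arc length times pixel pitch).
#' @export
fiber_length <- function(vertices, cal = calibration()) {
  v <- as.matrix(vertices)
  if (nrow(v) < 2L) stop("a fiber needs at least 2 vertices")
  sum(sqrt(rowSums(diff(v)^2))) * cal$microns_per_pixel
}

#' Straightness of a fiber polyline
#'
#' Chord length (first to last vertex) divided by arc length; 1 for a
#' perfectly straight fiber, 0 for a closed one.
#'
#' @inheritParams fiber_length
#' @return Straightness in `[0, 1]`; `NA` (undefined) for zero arc length.
#' @export
fiber_straightness <- function(vertices) {
  v <- as.matrix(vertices)
  if (nrow(v) < 2L) stop("a fiber needs at least 2 vertices")
  arc <- sum(sqrt(rowSums(diff(v)^2)))
  if (arc == 0) return(NA_real_)
  chord <- sqrt(sum((v[nrow(v), ] - v[1, ])^2))
  chord / arc
}

#' Axial orientation of a fiber polyline
#'
#' Angle of the endpoint-to-endpoint chord, folded into the axial range
#' `[0, 180)` degrees (a fiber has no head or tail). 0 degrees points along
#' +x, 90 along +y.
#'
#' @inheritParams fiber_length
#' @return Orientation in degrees, or `NA` for a closed fiber (zero chord).
#' @export
fiber_orientation <- function(vertices) {
  v <- as.matrix(vertices)
  if (nrow(v) < 2L) stop("a fiber needs at least 2 vertices")
  d <- v[nrow(v), ] - v[1, ]
  if (all(d == 0)) return(NA_real_)
  fold_axial(atan2(d[2], d[1]) * 180 / pi)
}

#' Alignment coefficient of an axial orientation sample
#'
#' The mean resultant length of the doubled angles: with phi_i = 2 theta_i
#' (radians), `A = || (mean cos phi, mean sin phi) ||`. A is 1 for a
#' perfectly parallel population and 0 for an isotropic one; it is the
#' standard axial-data alignment measure and the quantity thresholded at
#' 0.40/0.60 when grouping collagen matrices.
#'
#' @param orientations_deg Axial orientations in degrees; `NA`s (undefined
#'   orientations, e.g. closed fibers) are dropped.
#' @return Alignment coefficient in `[0, 1]`; `NA` if no usable orientation.
#' @examples
#' alignment_coefficient(rep(37, 10))       # 1
#' alignment_coefficient(c(0, 90, 0, 90))   # 0
#' @export
alignment_coefficient <- function(orientations_deg) {
  th <- orientations_deg[!is.na(orientations_deg)]
  if (!length(th)) return(NA_real_)
  phi <- 2 * th * pi / 180
  sqrt(mean(cos(phi))^2 + mean(sin(phi))^2)
}

# ---- population summary ----------------------------------------------------

#' Summarise the five collagen parameters over a region of interest
#'
#' Computes mean fiber length, width and straightness, the alignment
#' coefficient, and fiber density (fibers per mm^2) over the fibers whose
#' arc-length midpoint falls inside the ROI. Fibers are assigned to an ROI by
#' their midpoint so that a fiber crossing an ROI border is counted exactly
#' once.
#'
#' @param field A [fiber_field()] with polylines (or with summary metrics
#'   when `roi = NULL`, in which case density requires `field$dim`).
#' @param roi `NULL` for the whole raster; a numeric `c(x, y, side_px)` or
#'   `c(x, y, w_px, h_px)` axis-aligned rectangle (0-based top-left corner);
#'   or a binary matrix in `[x, y]` layout.
#' @return An object of class `collagen_summary` (also a one-row data frame)
#'   with columns `n_fibers`, `mean_length_um`, `mean_width_um`,
#'   `mean_straightness`, `alignment_coefficient`, `density_per_mm2`,
#'   `area_mm2`.
#' @export
summarize_collagen <- function(field, roi = NULL) {
  stopifnot(inherits(field, "fiber_field"))
  cal <- field$calibration
  fib <- field$fibers
  if (is.null(roi)) {
    if (any(is.na(field$dim))) stop("field has no raster dimensions; supply an roi")
    sel <- rep(TRUE, nrow(fib))
    area_mm2 <- px_to_mm2(prod(field$dim), cal)
  } else {
    if (!field$has_polylines)
      stop("summary-only fiber field: ROI selection needs polylines")
    if (is.matrix(roi)) {
      area_mm2 <- px_to_mm2(sum(roi != 0), cal)
      ix <- round(fib$mid_x_px) + 1L; iy <- round(fib$mid_y_px) + 1L
      inside <- ix >= 1L & ix <= nrow(roi) & iy >= 1L & iy <= ncol(roi)
      sel <- inside
      sel[inside] <- roi[cbind(ix[inside], iy[inside])] != 0
    } else {
      roi <- as.numeric(roi)
      w <- roi[3]; h <- if (length(roi) >= 4L) roi[4] else roi[3]
      stopifnot(w > 0, h > 0)
      area_mm2 <- px_to_mm2(w * h, cal)
      sel <- fib$mid_x_px >= roi[1] & fib$mid_x_px < roi[1] + w &
             fib$mid_y_px >= roi[2] & fib$mid_y_px < roi[2] + h
    }
  }
  n <- sum(sel)
  out <- data.frame(
    n_fibers = n,
    mean_length_um = if (n) mean(fib$length_um[sel]) else NA_real_,
    mean_width_um = if (n) mean(fib$width_um[sel]) else NA_real_,
    mean_straightness = if (n) mean(fib$straightness[sel], na.rm = TRUE) else NA_real_,
    alignment_coefficient = if (n) alignment_coefficient(fib$orientation_deg[sel]) else NA_real_,
    density_per_mm2 = n / area_mm2,
    area_mm2 = area_mm2)
  class(out) <- c("collagen_summary", class(out))
  out
}

#' @export
print.collagen_summary <- function(x, ...) {
  cat(sprintf(paste0("collagen summary: %d fibers in %.4g mm^2 ",
                     "(%.4g /mm^2)\n"), x$n_fibers, x$area_mm2, x$density_per_mm2))
  cat(sprintf("  length %.4g um, width %.4g um, straightness %.4g, alignment %.4g\n",
              x$mean_length_um, x$mean_width_um, x$mean_straightness,
              x$alignment_coefficient))
  invisible(x)
}
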