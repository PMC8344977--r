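#' Read a fiber table (vertex or summary dialect)
#'
#' Two CSV dialects are supported, distinguished by their header (never
#' per-row): the vertex dialect (`fiber_id, vertex_index, x_px, y_px`), from
#' which all per-fiber metrics are recomputed, and the summary dialect
#' (`fiber_id, length_um, width_um, straightness, angle_deg`) for
#' interoperability with exported fiber-extraction statistics, which carries
#' no polylines. A file mixing both header sets is rejected.
#'
#' @param path CSV path.
#' @param calibration A [calibration()].
#' @param dim Optional raster dimensions `c(width_px, height_px)`.
#' @return A [fiber_field()].
#' @export
read_fiber_table <- function(path, calibration = peristroma::calibration(),
                             dim = c(NA_real_, NA_real_)) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  vcols <- c("vertex_index", "x_px", "y_px")
  scols <- c("length_um", "width_um", "straightness", "angle_deg")
  has_v <- all(vcols %in% names(d))
  has_s <- all(scols %in% names(d))
  if (has_v && has_s) stop("mixed fiber-table dialects in one file")
  if (!has_v && !has_s)
    stop("unrecognised fiber-table header: need vertex columns (",
         paste(vcols, collapse = ", "), ") or summary columns (",
         paste(scols, collapse = ", "), ")")
  if (!"fiber_id" %in% names(d)) stop("fiber table lacks fiber_id")
  if (has_v) {
    width <- if ("width_um" %in% names(d) && nrow(d))
      tapply(d$width_um, d$fiber_id, `[`, 1)[as.character(sort(unique(d$fiber_id)))]
    else NA_real_
    fiber_field(vertices = d[, c("fiber_id", vcols)], dim = dim,
                calibration = calibration, width_um = as.numeric(width))
  } else {
    fiber_field(summary = d, dim = dim, calibration = calibration)
  }
}

#' Write a fiber field to CSV
#'
#' Uses the vertex dialect when polylines are present, the summary dialect
#' otherwise.
#'
#' @param field A [fiber_field()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fiber_table <- function(field, path) {
  stopifnot(inherits(field, "fiber_field"))
  if (field$has_polylines) {
    v <- field$vertices[, c("fiber_id", "vertex_index", "x_px", "y_px")]
    w <- field$fibers$width_um[match(v$fiber_id, field$fibers$id)]
    if (!all(is.na(w))) v$width_um <- w
    utils::write.csv(v, path, row.names = FALSE)
  } else {
    s <- data.frame(fiber_id = field$fibers$id,
                    length_um = field$fibers$length_um,
                    width_um = field$fibers$width_um,
                    straightness = field$fibers$straightness,
                    angle_deg = field$fibers$orientation_deg)
    utils::write.csv(s, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a migration track table
#'
#' CSV with columns `track_id, frame, x_px, y_px` (manual-tracking style).
#' Points are sorted by frame and converted to micrometres and minutes.
#'
#' @param path CSV path.
#' @param calibration A [calibration()] (pixel pitch and frame interval).
#' @return A data frame of class `tcell_tracks` with columns `track_id`,
#'   `frame`, `time_min`, `x_um`, `y_um` and attribute `calibration`.
#'   Single-point tracks are kept but flagged via the `usable` column.
#' @export
read_track_table <- function(path, calibration = peristroma::calibration()) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "x_px", "y_px")
  stopifnot(all(need %in% names(d)))
  if (anyDuplicated(d[, c("track_id", "frame")]))
    stop("duplicate (track_id, frame) rows")
  d <- d[order(d$track_id, d$frame), , drop = FALSE]
  out <- data.frame(track_id = d$track_id,
                    frame = d$frame,
                    time_min = d$frame * calibration$frame_interval_min,
                    x_um = d$x_px * calibration$microns_per_pixel,
                    y_um = d$y_px * calibration$microns_per_pixel)
  npts <- table(out$track_id)
  out$usable <- as.vector(npts[as.character(out$track_id)] >= 2L)
  row.names(out) <- NULL
  attr(out, "calibration") <- calibration
  class(out) <- c("tcell_tracks", class(out))
  out
}

#' Write a track table to CSV (pixel coordinates)
#'
#' @param tracks A `tcell_tracks` data frame (from [read_track_table()] or
#'   [simulate_tracks()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_track_table <- function(tracks, path) {
  cal <- attr(tracks, "calibration")
  stopifnot(inherits(cal, "calibration"))
  d <- data.frame(track_id = tracks$track_id,
                  frame = tracks$frame,
                  x_px = tracks$x_um / cal$microns_per_pixel,
                  y_px = tracks$y_um / cal$microns_per_pixel)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
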