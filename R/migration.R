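# In-vitro arm: per-track velocity and axial directionality, collagen
# alignment grouping, and the alignment-vs-directionality association.

# Split a tcell_tracks frame into per-track data frames (ordered by time).
split_tracks <- function(tracks) {
  split(tracks[order(tracks$track_id, tracks$time_min), ], tracks$track_id)
}

#' Track velocity
#'
#' Total path length (sum of per-step Euclidean displacements) divided by
#' elapsed time: a back-and-forth cell is as fast as a straight-moving one.
#'
#' @param track Data frame with columns `time_min`, `x_um`, `y_um`
#'   (>= 2 points, strictly increasing time).
#' @return Velocity in um/min.
#' @export
track_velocity <- function(track) {
  stopifnot(nrow(track) >= 2L)
  dt <- diff(track$time_min)
  if (any(dt <= 0)) stop("track time must be strictly increasing")
  path <- sum(sqrt(diff(track$x_um)^2 + diff(track$y_um)^2))
  path / (track$time_min[nrow(track)] - track$time_min[1])
}

#' Axial orientation of a migration track
#'
#' Integrates directionality over the single steps of a trajectory as the
#' ratio of summed absolute y-displacements to summed absolute
#' x-displacements, `sum(|dy|) / sum(|dx|)`. With the matrix alignment axis
#' at 90 degrees, a value of 1 indicates no axial preference and values > 1
#' a bias along the alignment axis.
#'
#' @param track Data frame with columns `x_um`, `y_um` (>= 2 points).
#' @return Unitless ratio >= 0; `NA` (undefined) when `sum(|dx|) = 0`.
#' @export
axial_orientation <- function(track) {
  stopifnot(nrow(track) >= 2L)
  sx <- sum(abs(diff(track$x_um)))
  sy <- sum(abs(diff(track$y_um)))
  if (sx == 0) return(NA_real_)
  sy / sx
}

#' Classify a collagen matrix by its alignment coefficient
#'
#' Groups: non-aligned (< 0.40), partially aligned (0.40--0.60, bounds
#' included), aligned (> 0.60).
#'
#' @param coefficient Alignment coefficient(s) in `[0, 1]`.
#' @param cfg An [analysis_config()] (uses `alignment_group_bounds`).
#' @return Factor with levels `non-aligned`, `partially aligned`, `aligned`.
#' @export
classify_alignment <- function(coefficient, cfg = analysis_config()) {
  if (any(coefficient < 0 | coefficient > 1, na.rm = TRUE))
    stop("alignment coefficient must lie in [0, 1]")
  b <- cfg$alignment_group_bounds
  lv <- c("non-aligned", "partially aligned", "aligned")
  factor(ifelse(coefficient < b[1], lv[1],
                ifelse(coefficient <= b[2], lv[2], lv[3])), levels = lv)
}

#' Per-track migration statistics
#'
#' Velocity, axial orientation and step count per track; tracks with fewer
#' than `min_track_frames` points are excluded (tracking noise).
#'
#' @param tracks A `tcell_tracks` data frame.
#' @param cfg An [analysis_config()].
#' @return Data frame with columns `track_id`, `n_steps`, `velocity_um_min`,
#'   `axial_orientation` (`NA` where undefined).
#' @export
summarize_tracks <- function(tracks, cfg = analysis_config()) {
  pieces <- split_tracks(tracks)
  keep <- vapply(pieces, nrow, integer(1)) >= cfg$min_track_frames
  pieces <- pieces[keep]
  if (!length(pieces)) {
    return(data.frame(track_id = integer(0), n_steps = integer(0),
                      velocity_um_min = numeric(0),
                      axial_orientation = numeric(0)))
  }
  data.frame(
    track_id = unlist(lapply(pieces, function(p) p$track_id[1]), use.names = FALSE),
    n_steps = vapply(pieces, nrow, integer(1)) - 1L,
    velocity_um_min = vapply(pieces, track_velocity, numeric(1)),
    axial_orientation = vapply(pieces, axial_orientation, numeric(1)),
    row.names = NULL)
}

#' Association between matrix alignment and T-cell directionality
#'
#' Pearson correlation (with two-sided p and least-squares line) between
#' per-channel collagen alignment coefficients and the per-channel median
#' axial orientation of T-cell migration.
#'
#' @param alignment Numeric vector of per-channel alignment coefficients.
#' @param median_orientation Numeric vector of per-channel median axial
#'   orientations (same length, >= 3 pairs).
#' @return An object of class `migration_association`: `r`, `p`,
#'   `intercept`, `slope`, `n`, and the input pairs.
#' @export
alignment_orientation_association <- function(alignment, median_orientation) {
  stopifnot(length(alignment) == length(median_orientation))
  ok <- is.finite(alignment) & is.finite(median_orientation)
  x <- alignment[ok]; y <- median_orientation[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  pa <- pearson_association(x, y)
  fit <- stats::lm(y ~ x)
  structure(list(r = pa$r, p = pa$p,
                 intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 n = length(x), alignment = x, median_orientation = y),
            class = "migration_association")
}

#' @export
print.migration_association <- function(x, ...) {
  cat(sprintf("alignment vs axial orientation: n = %d, r = %.3f, p = %.3g\n",
              x$n, x$r, x$p))
  invisible(x)
}

#' @export
plot.migration_association <- function(x, ...) {
  graphics::plot(x$alignment, x$median_orientation,
                 xlab = "collagen alignment coefficient",
                 ylab = "median axial orientation of T-cell migration",
                 pch = 19, ...)
  graphics::abline(x$intercept, x$slope, lty = 2)
  graphics::mtext(sprintf("r = %.3f, p = %.3g", x$r, x$p), side = 3, adj = 1,
                  cex = 0.9)
  invisible(x)
}
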