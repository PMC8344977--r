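#' Spatial and temporal calibration of an imaging dataset
#'
#' Bundles the pixel pitch of the raster data and the frame interval of
#' time-lapse recordings. Defaults correspond to a 16x SHG acquisition
#' (625 um over 1611 px) and a 2-frames-per-minute confocal time lapse.
#'
#' @param microns_per_pixel Pixel pitch in micrometres per pixel (> 0).
#' @param frame_interval_min Minutes between consecutive time-lapse frames
#'   (> 0).
#' @return An object of class `calibration`.
#' @examples
#' calibration()                      # 0.39 um/px, 0.5 min/frame
#' calibration(microns_per_pixel = 1)
#' @export
calibration <- function(microns_per_pixel = 0.39, frame_interval_min = 0.5) {
  stopifnot(is.numeric(microns_per_pixel), length(microns_per_pixel) == 1L,
            is.finite(microns_per_pixel), microns_per_pixel > 0,
            is.numeric(frame_interval_min), length(frame_interval_min) == 1L,
            is.finite(frame_interval_min), frame_interval_min > 0)
  structure(list(microns_per_pixel = microns_per_pixel,
                 frame_interval_min = frame_interval_min),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("calibration: %.6g um/px, %.6g min/frame\n",
              x$microns_per_pixel, x$frame_interval_min))
  invisible(x)
}

#' Pixel pitch from a field of view
#'
#' Convenience helper computing microns-per-pixel from the physical width of
#' the field and its width in pixels (e.g. 625 um over 1611 px gives the
#' default tissue calibration of ~0.39 um/px).
#'
#' @param field_width_um Physical field width in micrometres.
#' @param width_px Field width in pixels.
#' @return Micrometres per pixel.
#' @export
microns_per_pixel <- function(field_width_um, width_px) {
  stopifnot(field_width_um > 0, width_px > 0)
  field_width_um / width_px
}

#' Analysis configuration
#'
#' All tunable parameters of the stroma-region and T-cell analysis, with the
#' defaults used throughout: distance bands of width equal to the dataset's
#' mean fiber length (22.4 um), eleven bands (246.4 um total range), a
#' 0--15 degree window counting a fiber as boundary-parallel, the 5% rule on
#' the ratio |R - Rbar|/Rbar, a plateau estimated from the five outermost
#' bands, and a 25 px^2 particle filter for T-cell masks.
#'
#' @param band_width_um Width of one distance band, um. Conventionally the
#'   dataset's mean collagen fiber length.
#' @param n_bands Number of distance bands analysed around each tumor
#'   cluster; must exceed `plateau_band_count`.
#' @param parallel_range_deg Maximum axial deviation (degrees, in (0, 90])
#'   from the local boundary tangent for a fiber to count as parallel.
#' @param ratio_threshold Threshold on the Formula-style ratio
#'   |R - Rbar|/Rbar above which a band is considered deviating (in (0,1)).
#' @param plateau_band_count Number of outermost bands whose mean R defines
#'   the distant plateau Rbar.
#' @param min_particle_area_px Connected components strictly smaller than
#'   this (px^2) are removed from T-cell masks.
#' @param alignment_group_bounds Two cut points on the alignment coefficient
#'   separating non-aligned / partially aligned / aligned collagen.
#' @param change_threshold Relative-change threshold for paired
#'   peritumoral-vs-distant classification (fraction, in (0,1)).
#' @param min_track_frames Tracks with fewer frames are excluded from
#'   migration statistics.
#' @param tangent_smooth_window Contour samples averaged when estimating the
#'   boundary tangent (odd integer >= 3).
#' @param invert_region_rule If `TRUE`, apply the threshold rule with the
#'   opposite label direction (deviating bands become "tumor-cell-distant"),
#'   i.e. the literal reading of the published sentence; the default follows
#'   the construction that yields finite tumor-adjacent extensions.
#' @param rng_seed Optional integer seed recorded for provenance.
#' @return An object of class `analysis_config`.
#' @examples
#' cfg <- analysis_config()
#' cfg$band_width_um * cfg$n_bands   # 246.4 um analysis range
#' @export
analysis_config <- function(band_width_um = 22.4,
                            n_bands = 11L,
                            parallel_range_deg = 15,
                            ratio_threshold = 0.05,
                            plateau_band_count = 5L,
                            min_particle_area_px = 25,
                            alignment_group_bounds = c(0.40, 0.60),
                            change_threshold = 0.05,
                            min_track_frames = 3L,
                            tangent_smooth_window = 11L,
                            invert_region_rule = FALSE,
                            rng_seed = NULL) {
  n_bands <- as.integer(n_bands)
  plateau_band_count <- as.integer(plateau_band_count)
  stopifnot(band_width_um > 0,
            n_bands > plateau_band_count, plateau_band_count >= 1L,
            parallel_range_deg > 0, parallel_range_deg <= 90,
            ratio_threshold > 0, ratio_threshold < 1,
            min_particle_area_px >= 0,
            length(alignment_group_bounds) == 2L,
            alignment_group_bounds[1] < alignment_group_bounds[2],
            change_threshold > 0, change_threshold < 1,
            min_track_frames >= 2L,
            tangent_smooth_window >= 3L,
            is.logical(invert_region_rule))
  structure(list(band_width_um = band_width_um,
                 n_bands = n_bands,
                 parallel_range_deg = parallel_range_deg,
                 ratio_threshold = ratio_threshold,
                 plateau_band_count = plateau_band_count,
                 min_particle_area_px = min_particle_area_px,
                 alignment_group_bounds = alignment_group_bounds,
                 change_threshold = change_threshold,
                 min_track_frames = as.integer(min_track_frames),
                 tangent_smooth_window = as.integer(tangent_smooth_window),
                 invert_region_rule = invert_region_rule,
                 rng_seed = rng_seed),
            class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config\n")
  cat(sprintf("  bands: %d x %.6g um (range %.6g um), parallel window %g deg\n",
              x$n_bands, x$band_width_um, x$n_bands * x$band_width_um,
              x$parallel_range_deg))
  cat(sprintf("  ratio threshold %g, plateau from %d outermost bands%s\n",
              x$ratio_threshold, x$plateau_band_count,
              if (x$invert_region_rule) " (inverted rule)" else ""))
  cat(sprintf("  particle filter < %g px^2, alignment bounds (%g, %g)\n",
              x$min_particle_area_px, x$alignment_group_bounds[1],
              x$alignment_group_bounds[2]))
  invisible(x)
}

#' Read an analysis configuration from a key-value text file
#'
#' Lines of the form `key = value` (or `key: value`); blank lines and lines
#' starting with `#` are ignored. Keys mirror the arguments of
#' [analysis_config()]; unknown keys are an error.
#'
#' @param path Path to the configuration file.
#' @param ... Overrides applied after the file is read (a CLI flag beats the
#'   file).
#' @return An `analysis_config`.
#' @export
read_config <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[=:]\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L) stop("malformed config line: ", ln)
    key <- m[2]; val <- trimws(m[3])
    parsed <- if (tolower(val) %in% c("true", "false")) {
      as.logical(toupper(val))
    } else {
      v <- suppressWarnings(as.numeric(strsplit(val, "[,;]\\s*")[[1]]))
      if (anyNA(v)) stop("non-numeric value for key '", key, "': ", val)
      v
    }
    kv[[key]] <- parsed
  }
  allowed <- names(formals(analysis_config))
  bad <- setdiff(names(kv), allowed)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  overrides <- list(...)
  kv[names(overrides)] <- overrides
  do.call(analysis_config, kv)
}
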