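# print / summary / plot methods for the delineation result objects.

#' @export
print.band_profile <- function(x, ...) {
  cat(sprintf("band_profile: %d bands x %.4g um, Rbar = %.4g (bands %d-%d)\n",
              x$n_bands, x$band_width_um, x$R_bar,
              min(x$plateau_bands), max(x$plateau_bands)))
  print(format(x$profile, digits = 4), row.names = FALSE)
  if (length(x$flagged)) cat("flagged:", paste(x$flagged, collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.band_profile <- function(x, ...) x$profile

#' @export
plot.band_profile <- function(x, ...) {
  p <- x$profile
  d <- (p$band - 0.5) * x$band_width_um
  graphics::plot(d, p$R, type = "b", pch = 19, ylim = c(0, 1),
                 xlab = "distance to tumor borderline (um)",
                 ylab = "parallel-fiber fraction R", ...)
  graphics::abline(h = x$R_bar, lty = 2)
  graphics::abline(h = x$R_bar * c(1 - 0.05, 1 + 0.05), lty = 3, col = "grey40")
  graphics::legend("topright", bty = "n", lty = c(2, 3),
                   legend = c("plateau mean", "5% band"))
  invisible(x)
}

#' @export
print.stroma_partition <- function(x, ...) {
  if (is.na(x$extension_um)) {
    cat("stroma_partition: extension not computable\n")
  } else {
    cat(sprintf("stroma_partition: peritumoral extension %.4g um (%d bands)\n",
                x$extension_um, x$extension_bands))
  }
  if (!is.null(x$labels)) {
    px <- table(factor(x$labels, levels = 0:4,
                       labels = c("tumor", "peritumoral", "distant",
                                  "excluded", "beyond")))
    cat("  pixels:", paste(names(px), px, sep = " = ", collapse = ", "), "\n")
  }
  if (length(x$flagged)) cat("  flagged:", paste(x$flagged, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.stroma_partition <- function(object, ...) {
  areas <- if (!is.null(object$labels)) region_areas(object) else
    c(peritumoral = NA_real_, distant = NA_real_)
  out <- data.frame(extension_um = object$extension_um,
                    extension_bands = object$extension_bands,
                    peritumoral_area_mm2 = areas[["peritumoral"]],
                    distant_area_mm2 = areas[["distant"]],
                    R_bar = object$profile$R_bar)
  row.names(out) <- NULL
  out
}

#' @export
plot.stroma_partition <- function(x, ...) {
  if (is.null(x$labels)) stop("partition carries no labels")
  cols <- c("black", "firebrick", "steelblue", "grey70", "white")
  graphics::image(seq_len(nrow(x$labels)) - 1L, seq_len(ncol(x$labels)) - 1L,
                  x$labels[, ncol(x$labels):1], col = cols, breaks = -0.5 + 0:5,
                  asp = 1, xlab = "x (px)", ylab = "y (px)", useRaster = TRUE, ...)
  graphics::legend("topright", fill = cols[1:4], bg = "white", cex = 0.8,
                   legend = c("tumor", "peritumoral", "distant", "excluded"))
  invisible(x)
}
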