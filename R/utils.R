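# Shared internal helpers: angle arithmetic, labeling, RNG scoping.

# Fold an angle in degrees into the axial range [0, 180).
fold_axial <- function(theta_deg) {
  th <- theta_deg %% 180
  th[th < 0] <- th[th < 0] + 180
  # 180 can appear through floating error after %%
  th[th >= 180] <- th[th >= 180] - 180
  th
}

# Axial (orientation) difference in degrees, range [0, 90].
axial_diff <- function(a_deg, b_deg) {
  d <- abs(a_deg - b_deg) %% 180
  pmin(d, 180 - d)
}

# 8-connected labeling of a binary matrix. EBImage::bwlabel is 4-connected;
# diagonal-touching components are merged with a union-find pass over the
# two diagonal adjacency directions.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- EBImage::imageData(lab)
  n <- max(lab)
  if (n <= 1L) return(lab)
  nx <- nrow(lab); ny <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nx, -ny]), as.vector(lab[-1, -1])),   # \ diagonal
    cbind(as.vector(lab[-nx, -1]), as.vector(lab[-1, -ny])))   # / diagonal
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# Areas (pixel counts) of 8-connected components; returns named integer
# vector indexed by label.
component_areas <- function(lab) {
  tab <- tabulate(lab[lab > 0])
  tab
}

# Evaluate an expression with a locally seeded RNG, restoring global state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

# Circular moving average of the rows of a closed polyline (n x 2 matrix).
smooth_closed <- function(pts, window) {
  n <- nrow(pts)
  if (n < 3L || window < 3L) return(pts)
  w <- min(window, if (n %% 2L == 1L) n else n - 1L)
  half <- (w - 1L) %/% 2L
  idx <- outer(seq_len(n), -half:half, `+`)
  idx <- ((idx - 1L) %% n) + 1L
  cbind(rowMeans(matrix(pts[idx, 1], nrow = n)),
        rowMeans(matrix(pts[idx, 2], nrow = n)))
}
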