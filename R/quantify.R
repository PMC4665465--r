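# Quantitative readouts of reconstructed volumes: total power, peak
# detection with sub-voxel refinement, separations, and projections.

as_volume <- function(volume) {
  if (inherits(volume, c("source_estimate", "fluence_field"))) {
    list(vol = volume$volume, grid = volume$grid,
         units = volume$units %||% "fluence")
  } else {
    stop("need a source_estimate or fluence_field")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total power of a reconstructed volume
#'
#' Sum over voxels in absolute units. Whole-volume by default; an optional
#' mask restricts the aggregation region.
#'
#' @param volume A `source_estimate` (units photons/s) or `fluence_field`.
#' @param mask Optional logical array of grid shape.
#' @return Total, photons/s for a source estimate.
#' @export
total_power <- function(volume, mask = NULL) {
  v <- as_volume(volume)
  if (is.null(v$units) || is.na(v$units)) stop("volume has no units flag")
  if (any(v$vol < 0)) stop("volume must be non-negative")
  if (is.null(mask)) sum(v$vol) else sum(v$vol[mask])
}

#' Detect intensity peaks in a volume
#'
#' Local maxima over the 26-neighborhood above `threshold * global max`,
#' greedily suppressed within `min_separation` (strongest first; ties broken
#' by lowest lexicographic voxel index). Positions are refined to sub-voxel
#' accuracy by per-axis 3-point parabolic interpolation unless
#' `refine = FALSE`.
#'
#' @param volume A `source_estimate` or `fluence_field`.
#' @param min_separation Minimum distance between reported peaks (mm).
#' @param threshold Fraction of the global maximum below which maxima are
#'   ignored.
#' @param refine Sub-voxel parabolic refinement.
#' @return An object of class `peak_set`: data frame with columns `x_mm`,
#'   `y_mm`, `z_mm`, `intensity`, `prominence`, sorted by intensity
#'   descending; attributes `threshold` and `grid`.
#' @export
find_peaks <- function(volume, min_separation = 5, threshold = 0.5,
                       refine = TRUE) {
  v <- as_volume(volume)
  vol <- v$vol
  grid <- v$grid
  stopifnot(all(is.finite(vol)))
  n <- dim(vol)
  gmax <- max(vol)
  if (gmax <= 0) {
    return(empty_peak_set(threshold, grid))
  }
  lev <- threshold * gmax
  is_max <- vol >= lev
  # compare against all 26 shifted copies (zero-padded shifts)
  shift3 <- function(a, s) {
    out <- array(-Inf, dim = dim(a))
    src <- lapply(1:3, function(k) {
      i <- seq_len(n[k]) + s[k]
      i[i >= 1 & i <= n[k]]
    })
    dst <- lapply(1:3, function(k) {
      i <- seq_len(n[k])
      i[i + s[k] >= 1 & i + s[k] <= n[k]]
    })
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (!any(is_max)) break
    is_max <- is_max & (vol >= shift3(vol, c(dx, dy, dz)))
  }
  cand <- which(is_max)
  if (!length(cand)) return(empty_peak_set(threshold, grid))
  idx <- arrayInd(cand, n)
  val <- vol[cand]
  # strongest first; lexicographic (linear index) tie-break
  o <- order(-val, cand)
  idx <- idx[o, , drop = FALSE]
  val <- val[o]
  pos <- index_to_world(grid, idx)
  keep <- logical(length(val))
  for (i in seq_along(val)) {
    if (!any(keep)) {
      keep[i] <- TRUE
      next
    }
    dd <- sqrt(rowSums(sweep(pos[keep, , drop = FALSE], 2, pos[i, ])^2))
    if (all(dd >= min_separation)) keep[i] <- TRUE
  }
  idx <- idx[keep, , drop = FALSE]
  val <- val[keep]
  pos <- pos[keep, , drop = FALSE]
  if (refine) {
    h <- grid$voxel_size
    for (i in seq_len(nrow(idx))) {
      for (a in 1:3) {
        c0 <- idx[i, ]
        if (c0[a] <= 1 || c0[a] >= n[a]) next
        cm <- c0; cm[a] <- cm[a] - 1L
        cp <- c0; cp[a] <- cp[a] + 1L
        fm <- vol[matrix(cm, 1)]
        f0 <- vol[matrix(c0, 1)]
        fp <- vol[matrix(cp, 1)]
        den <- fm - 2 * f0 + fp
        if (den < 0) {
          delta <- 0.5 * (fm - fp) / den
          pos[i, a] <- pos[i, a] + max(min(delta, 0.5), -0.5) * h
        }
      }
    }
  }
  ps <- data.frame(x_mm = pos[, 1], y_mm = pos[, 2], z_mm = pos[, 3],
                   intensity = val, prominence = val - lev)
  structure(ps, class = c("peak_set", "data.frame"),
            threshold = threshold, grid = grid)
}

empty_peak_set <- function(threshold, grid) {
  structure(data.frame(x_mm = numeric(0), y_mm = numeric(0),
                       z_mm = numeric(0), intensity = numeric(0),
                       prominence = numeric(0)),
            class = c("peak_set", "data.frame"),
            threshold = threshold, grid = grid)
}

#' Distance between the two strongest peaks
#'
#' @param peaks A `peak_set` with at least two peaks.
#' @return Euclidean separation in mm.
#' @export
peak_separation <- function(peaks) {
  if (nrow(peaks) < 2) stop("need at least two peaks")
  a <- as.numeric(peaks[1, c("x_mm", "y_mm", "z_mm")])
  b <- as.numeric(peaks[2, c("x_mm", "y_mm", "z_mm")])
  sqrt(sum((a - b)^2))
}

#' Radial displacement of a position from an axis
#'
#' Perpendicular distance from a point to a line through `origin` with
#' direction `axis` (default: the gantry rotation axis, +z through the world
#' origin).
#'
#' @param position Length-3 position (mm) or a `peak_set` (first peak used).
#' @param axis Axis direction.
#' @param origin A point on the axis.
#' @return Distance in mm.
#' @export
radial_displacement <- function(position, axis = c(0, 0, 1),
                                origin = c(0, 0, 0)) {
  if (inherits(position, "peak_set")) {
    stopifnot(nrow(position) >= 1)
    position <- as.numeric(position[1, c("x_mm", "y_mm", "z_mm")])
  }
  a <- axis / sqrt(sum(axis^2))
  w <- as.numeric(position) - origin
  perp <- w - sum(w * a) * a
  sqrt(sum(perp^2))
}

# Anatomical axis names mapped onto the grid: the gantry/long axis is z, so a
# transverse section is a z-slice, coronal projects along y, sagittal along x.
axis_index <- function(axis) {
  if (is.numeric(axis)) {
    stopifnot(axis %in% 1:3)
    return(as.integer(axis))
  }
  switch(tolower(axis),
         x = 1L, sagittal = 1L,
         y = 2L, coronal = 2L,
         z = 3L, transverse = 3L, axial = 3L,
         stop("unknown axis label: ", axis))
}

#' Maximum intensity projection
#'
#' Per-line maximum of a volume along a grid axis; anatomical labels
#' (`"coronal"` = along y, `"sagittal"` = along x, `"transverse"` = along z)
#' are accepted.
#'
#' @param volume A `source_estimate` or `fluence_field`.
#' @param axis Axis index (1-3) or label.
#' @return 2-D matrix of per-line maxima.
#' @export
max_intensity_projection <- function(volume, axis = "coronal") {
  v <- as_volume(volume)
  a <- axis_index(axis)
  apply(v$vol, setdiff(1:3, a), max)
}

#' Extract a single section of a volume
#'
#' @param volume A `source_estimate` or `fluence_field`.
#' @param axis Axis index or label (see [max_intensity_projection()]).
#' @param coordinate World coordinate of the slice along the axis (mm);
#'   defaults to the grid middle.
#' @return 2-D matrix.
#' @export
volume_section <- function(volume, axis = "transverse", coordinate = NULL) {
  v <- as_volume(volume)
  a <- axis_index(axis)
  grid <- v$grid
  if (is.null(coordinate)) {
    k <- (grid$shape[a] + 1L) %/% 2L
  } else {
    k <- floor((coordinate - grid$origin[a]) / grid$voxel_size) + 1L
    k <- min(max(k, 1L), grid$shape[a])
  }
  idx <- list(quote(expr =), quote(expr =), quote(expr =))
  idx[[a]] <- k
  do.call(`[`, c(list(v$vol), idx))
}
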