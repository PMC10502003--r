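# Low-level grid operations shared by the metrics and simulator code:
# exact anisotropic Euclidean distance transform, connected components and
# basic binary morphology.

#' Euclidean distance transform to a voxel set
#'
#' For every voxel of the grid, the exact Euclidean distance in mm to the
#' nearest `TRUE` (site) voxel, honouring anisotropic spacing.  Computed by
#' the separable lower-envelope algorithm, exact for squared distances.
#'
#' @param sites 3-D logical/0-1 array of site voxels.
#' @param spacing numeric length-3 spacing in mm.
#' @return 3-D numeric array of distances (all `Inf` when no site exists).
#' @export
distance_transform <- function(sites, spacing = c(1, 1, 1)) {
  if (inherits(sites, "seg_volume")) {
    spacing <- sites$spacing
    sites <- sites$voxels
  }
  sites <- check_voxels(sites != 0)
  spacing <- check_spacing(spacing)
  d <- .edt3d_cpp(as.logical(sites), dim(sites), spacing)
  array(d, dim(sites))
}

#' Connected components (6-connectivity)
#'
#' @param mask 3-D logical/0-1 array or [binary_mask()].
#' @return integer array of component labels, background 0, labels in
#'   column-major first-encounter order.
#' @export
connected_components <- function(mask) {
  if (inherits(mask, "seg_volume")) mask <- mask$voxels
  mask <- check_voxels(mask != 0)
  array(.label6_cpp(as.logical(mask), dim(mask)), dim(mask))
}

#' Number of 6-connected foreground components
#' @param mask 3-D array or [binary_mask()].
#' @return integer count.
#' @export
n_components <- function(mask) {
  max(connected_components(mask))
}

# shift a logical array by (dx, dy, dz), padding with FALSE
shift_logical <- function(v, dx, dy, dz) {
  d <- dim(v)
  out <- array(FALSE, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- v[sx - dx, sy - dy, sz - dz]
  out
}

neighbor_offsets <- function(connectivity = 6L) {
  if (connectivity == 6L) {
    rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  }
}

# bounding box of TRUE voxels expanded by `pad`, clipped to the grid
bbox_ranges <- function(v, pad = 1L) {
  fg <- which(v, arr.ind = TRUE)
  if (nrow(fg) == 0) return(NULL)
  d <- dim(v)
  lapply(1:3, function(a) max(1L, min(fg[, a]) - pad):min(d[a], max(fg[, a]) + pad))
}

# binary dilation/erosion with a 6- or 26-neighbourhood structuring element;
# out-of-grid counts as background.  The work is confined to the mask's
# padded bounding box, which is exact because both operations only change
# voxels within one structuring element of the foreground.
dilate_mask <- function(v, connectivity = 6L) {
  bb <- bbox_ranges(v, pad = 1L)
  if (is.null(bb)) return(v)
  sub <- v[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  out <- sub
  off <- neighbor_offsets(connectivity)
  for (r in seq_len(nrow(off))) out <- out | shift_logical(sub, off[r, 1], off[r, 2], off[r, 3])
  v[bb[[1]], bb[[2]], bb[[3]]] <- out
  v
}

erode_mask <- function(v, connectivity = 6L) {
  bb <- bbox_ranges(v, pad = 1L)
  if (is.null(bb)) return(v)
  sub <- v[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  out <- sub
  off <- neighbor_offsets(connectivity)
  for (r in seq_len(nrow(off))) out <- out & shift_logical(sub, off[r, 1], off[r, 2], off[r, 3])
  v[bb[[1]], bb[[2]], bb[[3]]] <- out
  v
}
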