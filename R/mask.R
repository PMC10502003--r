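#' Binary segmentation mask
#'
#' The universal currency of the pipeline: a 3-D voxel grid of \{0, 1\}
#' labels together with the physical voxel spacing in millimetres along
#' each axis.  Masks of one image are assumed co-registered on a common
#' grid; all pairwise operations check that geometry and refuse to guess.
#'
#' @param voxels 3-D array (logical or numeric) of voxel labels; any value
#'   not exactly 0/FALSE is rejected unless it is exactly 1/TRUE.
#' @param spacing numeric length-3, voxel edge length in mm per axis; all
#'   components must be positive.
#' @param label free-text tag (organ name, model id, fusion scheme).
#' @return An object of class `binary_mask` with fields `voxels`
#'   (integer array), `spacing` and `label`.
#' @seealso [probability_map()], [load_mask()], [dice()]
#' @examples
#' m <- binary_mask(array(0L, c(4, 4, 4)))
#' mask_volume(m)
#' @export
binary_mask <- function(voxels, spacing = c(1, 1, 1), label = "") {
  voxels <- check_voxels(voxels, n_dim = 3)
  bad <- !(voxels == 0 | voxels == 1)
  if (any(bad)) {
    stop("binary_mask: voxel values must all be in {0, 1}; found ",
         format(voxels[which(bad)[1]]), call. = FALSE)
  }
  storage.mode(voxels) <- "integer"
  structure(
    list(voxels = voxels, spacing = check_spacing(spacing), label = as.character(label)[1]),
    class = c("binary_mask", "seg_volume")
  )
}

#' Voxel-wise probability map
#'
#' Same geometry contract as [binary_mask()] but with values in \[0, 1\]:
#' the voxel-wise mean of ensemble masks before thresholding, or the
#' consensus weight field estimated by [staple()].
#'
#' @param voxels 3-D numeric array with all values in \[0, 1\].
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param provenance character vector naming the sources (model ids,
#'   scheme) that produced the map.
#' @return An object of class `probability_map`.
#' @export
probability_map <- function(voxels, spacing = c(1, 1, 1), provenance = character()) {
  voxels <- check_voxels(voxels, n_dim = 3)
  storage.mode(voxels) <- "double"
  if (any(voxels < 0 | voxels > 1)) {
    stop("probability_map: voxel values must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(voxels = voxels, spacing = check_spacing(spacing),
         provenance = as.character(provenance)),
    class = c("probability_map", "seg_volume")
  )
}

check_voxels <- function(voxels, n_dim = 3) {
  if (is.logical(voxels)) storage.mode(voxels) <- "integer"
  if (!is.array(voxels) || length(dim(voxels)) != n_dim) {
    stop("voxel grid must be a ", n_dim, "-D array; got dimensionality ",
         if (is.array(voxels)) length(dim(voxels)) else 1L, call. = FALSE)
  }
  if (any(dim(voxels) < 1L)) stop("voxel grid has a zero-length dimension", call. = FALSE)
  if (any(!is.finite(voxels))) stop("voxel values must be finite", call. = FALSE)
  voxels
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 positive mm values", call. = FALSE)
  }
  spacing
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask%s> %s, spacing %s mm, %d foreground voxels\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              sum(x$voxels)))
  invisible(x)
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> %s, spacing %s mm, values in [%.3f, %.3f]%s\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$voxels), max(x$voxels),
              if (length(x$provenance)) paste0(", from ", length(x$provenance), " sources") else ""))
  invisible(x)
}

#' @export
as.array.binary_mask <- function(x, ...) x$voxels

#' @export
as.array.probability_map <- function(x, ...) x$voxels

#' @export
dim.binary_mask <- function(x) dim(x$voxels)

#' @export
dim.probability_map <- function(x) dim(x$voxels)

#' Foreground volume of a mask
#'
#' @param mask a [binary_mask()].
#' @param physical if `TRUE`, return mm^3 (voxel count times voxel volume);
#'   otherwise the voxel count.
#' @return scalar volume.
#' @export
mask_volume <- function(mask, physical = FALSE) {
  n <- sum(mask$voxels)
  if (physical) n * prod(mask$spacing) else n
}

#' Physical diagonal of a volume's grid in mm
#'
#' Used as the finite worst-case cap for surface distances when one mask is
#' empty: catastrophic failures stay rankable instead of producing Inf/NaN.
#'
#' @param x a `binary_mask` or `probability_map`.
#' @return scalar mm.
#' @export
grid_diagonal <- function(x) {
  sqrt(sum((dim(x$voxels) * x$spacing)^2))
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    all(abs(a$spacing - b$spacing) <= tol * pmax(a$spacing, b$spacing))
}

check_same_geometry <- function(a, b, what = "masks") {
  if (!identical(dim(a$voxels), dim(b$voxels))) {
    stop("geometry mismatch between ", what, ": shapes ",
         paste(dim(a$voxels), collapse = "x"), " vs ",
         paste(dim(b$voxels), collapse = "x"), call. = FALSE)
  }
  if (!all(abs(a$spacing - b$spacing) <= 1e-6 * pmax(a$spacing, b$spacing))) {
    stop("geometry mismatch between ", what, ": spacings ",
         paste(format(a$spacing), collapse = "x"), " vs ",
         paste(format(b$spacing), collapse = "x"), call. = FALSE)
  }
  invisible(TRUE)
}

check_mask_list <- function(masks, min_n = 1L) {
  if (!is.list(masks) || length(masks) < min_n) {
    stop("need a list of at least ", min_n, " mask(s)", call. = FALSE)
  }
  for (m in masks) {
    if (!inherits(m, "seg_volume")) stop("inputs must be binary_mask/probability_map objects", call. = FALSE)
  }
  if (length(masks) > 1) {
    for (i in seq_along(masks)[-1]) check_same_geometry(masks[[1]], masks[[i]])
  }
  invisible(TRUE)
}
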