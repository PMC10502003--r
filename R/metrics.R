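# Segmentation-quality metrics: overlap (Dice), volume agreement (RVD) and
# spacing-aware symmetric surface distances (ASSD, MSSD).  Degenerate masks
# never crash the pipeline: they take documented fallback values and are
# flagged, so catastrophic failures remain rankable as outliers.

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`: relative overlap between two masks, in \[0, 1\].
#' By convention two empty masks agree perfectly (returns 1).
#'
#' @param a,b [binary_mask()] objects on the same grid.
#' @return scalar in \[0, 1\].
#' @export
dice <- function(a, b) {
  check_same_geometry(a, b)
  na <- sum(a$voxels)
  nb <- sum(b$voxels)
  if (na + nb == 0L) return(1)
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

#' Relative volume difference
#'
#' Volume discrepancy between prediction and reference ignoring overlap:
#' `| |pred| - |ref| | / |ref|` (absolute by default; `signed = TRUE`
#' returns `(|pred| - |ref|) / |ref|`).  Undefined for an empty reference
#' (returns `NA`).
#'
#' @param pred,ref [binary_mask()] objects on the same grid.
#' @param signed return the signed variant.
#' @return scalar (>= 0 unless `signed`), or `NA` if `ref` is empty.
#' @export
rvd <- function(pred, ref, signed = FALSE) {
  check_same_geometry(pred, ref)
  np <- sum(pred$voxels)
  nr <- sum(ref$voxels)
  if (nr == 0L) {
    if (np == 0L) return(0)
    return(NA_real_)
  }
  r <- (np - nr) / nr
  if (signed) r else abs(r)
}

#' Boundary voxels of a mask
#'
#' Exactly the foreground voxels having at least one background 6-neighbour;
#' a voxel on the grid border is boundary (out-of-grid counts as background).
#'
#' @param mask a [binary_mask()].
#' @return integer matrix with one row per boundary voxel and columns
#'   `i, j, k` (1-based grid coordinates); zero rows for an empty mask.
#' @export
boundary_voxels <- function(mask) {
  b <- boundary_array(mask$voxels)
  which(b, arr.ind = TRUE)
}

boundary_array <- function(vox) {
  v <- vox != 0
  interior <- erode_mask(v, connectivity = 6L)
  v & !interior
}

# directed nearest-boundary distances in both directions, in mm.
# ref_edt may be precomputed (distance transform of ref's boundary) so one
# reference can be scored against many predictions cheaply.
surface_distance_sets <- function(pred, ref, ref_edt = NULL) {
  bp <- boundary_array(pred$voxels)
  br <- boundary_array(ref$voxels)
  if (!any(bp) || !any(br)) return(NULL)
  if (is.null(ref_edt)) ref_edt <- distance_transform(br, pred$spacing)
  pred_edt <- distance_transform(bp, pred$spacing)
  list(pred_to_ref = ref_edt[bp], ref_to_pred = pred_edt[br])
}

#' Average symmetric surface distance (mm)
#'
#' Mean over the union of both directed nearest-distance multisets: every
#' boundary voxel of the prediction contributes its distance to the nearest
#' reference boundary voxel, and vice versa.  Distances use per-axis voxel
#' spacing.  If either mask is empty the grid's physical diagonal is
#' returned as a finite worst-case cap (0 when both are empty).
#'
#' @param pred,ref [binary_mask()] objects on the same grid.
#' @return scalar mm.
#' @seealso [mssd()], [evaluate()]
#' @export
assd <- function(pred, ref) {
  check_same_geometry(pred, ref)
  s <- surface_distance_sets(pred, ref)
  if (is.null(s)) return(degenerate_surface_distance(pred, ref))
  mean(c(s$pred_to_ref, s$ref_to_pred))
}

#' Maximum symmetric surface distance (mm)
#'
#' The Hausdorff distance between the two boundaries: the greatest of all
#' directed nearest boundary-to-boundary distances.  Empty-mask handling as
#' in [assd()].
#'
#' @inheritParams assd
#' @return scalar mm.
#' @export
mssd <- function(pred, ref) {
  check_same_geometry(pred, ref)
  s <- surface_distance_sets(pred, ref)
  if (is.null(s)) return(degenerate_surface_distance(pred, ref))
  max(s$pred_to_ref, s$ref_to_pred)
}

degenerate_surface_distance <- function(pred, ref) {
  if (sum(pred$voxels) == 0L && sum(ref$voxels) == 0L) 0 else grid_diagonal(ref)
}

#' Evaluate one prediction against a reference
#'
#' Bundles the four metrics into one metric record.  Degenerate cases:
#' both masks empty counts as perfect agreement (DSC 1, RVD 0, distances 0);
#' exactly one empty mask gives DSC 0, RVD 1 (empty prediction) or `NA`
#' (empty reference, formula undefined), and surface distances capped at the
#' grid's physical diagonal.  `surface_defined` is `FALSE` whenever any
#' fallback was applied.
#'
#' @param pred,ref [binary_mask()] objects on the same grid.
#' @param organ,image_id,source_id identifiers copied into the record
#'   (`source_id` is a model id or a fusion-scheme name).
#' @param ref_edt optional precomputed distance transform of the reference
#'   boundary (see [evaluate_against()]).
#' @return one-row `data.frame` with columns
#'   `organ, image_id, source_id, dsc, rvd, assd_mm, mssd_mm, surface_defined`.
#' @export
evaluate <- function(pred, ref, organ = "organ", image_id = "img", source_id = "model",
                     ref_edt = NULL) {
  check_same_geometry(pred, ref)
  np <- sum(pred$voxels)
  nr <- sum(ref$voxels)
  d <- dice(pred, ref)
  v <- rvd(pred, ref)
  s <- surface_distance_sets(pred, ref, ref_edt = ref_edt)
  degenerate <- is.null(s)
  if (degenerate) {
    a <- degenerate_surface_distance(pred, ref)
    m <- a
  } else {
    a <- mean(c(s$pred_to_ref, s$ref_to_pred))
    m <- max(s$pred_to_ref, s$ref_to_pred)
  }
  data.frame(organ = organ, image_id = image_id, source_id = source_id,
             dsc = d, rvd = v, assd_mm = a, mssd_mm = m,
             surface_defined = !degenerate,
             stringsAsFactors = FALSE)
}

#' Evaluate many predictions against one reference
#'
#' Scores a list of candidate masks against a single reference, computing
#' the reference boundary's distance transform once.
#'
#' @param preds named list of [binary_mask()] objects.
#' @param ref the reference [binary_mask()].
#' @param organ,image_id identifiers for the records.
#' @return `data.frame` of metric records, one row per prediction.
#' @export
evaluate_against <- function(preds, ref, organ = "organ", image_id = "img") {
  check_mask_list(c(list(ref), unname(preds)))
  br <- boundary_array(ref$voxels)
  ref_edt <- if (any(br)) distance_transform(br, ref$spacing) else NULL
  ids <- names(preds) %||% paste0("model_", seq_along(preds))
  do.call(rbind, lapply(seq_along(preds), function(i) {
    evaluate(preds[[i]], ref, organ = organ, image_id = image_id,
             source_id = ids[i], ref_edt = ref_edt)
  }))
}

#' Write a metric table as CSV
#'
#' Fixed schema, one metric record per row:
#' `organ,image_id,source_id,dsc,rvd,assd_mm,mssd_mm,surface_defined`.
#'
#' @param records metric `data.frame` as returned by [evaluate()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(records, path) {
  cols <- c("organ", "image_id", "source_id", "dsc", "rvd", "assd_mm", "mssd_mm",
            "surface_defined")
  missing <- setdiff(cols, names(records))
  if (length(missing)) stop("metric table misses columns: ", paste(missing, collapse = ", "), call. = FALSE)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.csv(records[, cols], path, row.names = FALSE)
  invisible(path)
}
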