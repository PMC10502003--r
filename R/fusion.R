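# Label fusion: combine J candidate masks of one image into a consensus.

#' Voxel-wise (weighted) mean of candidate segmentations
#'
#' The standard ensemble consensus before thresholding:
#' `S_ens = (1/J) * sum_j S_j`, optionally with non-negative weights
#' (normalised internally).  The result can be read voxel-wise as the
#' probability that the voxel belongs to the structure.
#'
#' @param masks list of [binary_mask()] / [probability_map()] objects on a
#'   common grid.
#' @param weights optional non-negative numeric vector, one per mask, with
#'   positive sum.
#' @return a [probability_map()].
#' @export
average_probability <- function(masks, weights = NULL) {
  check_mask_list(masks, min_n = 1L)
  J <- length(masks)
  if (is.null(weights)) {
    weights <- rep(1 / J, J)
  } else {
    weights <- as.numeric(weights)
    if (length(weights) != J) stop("need one weight per mask", call. = FALSE)
    if (any(weights < 0) || any(!is.finite(weights))) stop("weights must be non-negative and finite", call. = FALSE)
    if (sum(weights) <= 0) stop("weights must have positive sum", call. = FALSE)
    weights <- weights / sum(weights)
  }
  acc <- array(0, dim(masks[[1]]$voxels))
  for (j in seq_len(J)) acc <- acc + weights[j] * masks[[j]]$voxels
  acc <- pmin(pmax(acc, 0), 1)  # guard FP round-off at the box bounds
  prov <- vapply(masks, function(m) {
    if (!is.null(m$label) && nzchar(m$label %||% "")) m$label else ""
  }, "")
  probability_map(acc, spacing = masks[[1]]$spacing, provenance = prov)
}

#' Threshold a probability map into a binary mask
#'
#' A voxel is foreground iff its probability is `>= p_thr` (a tie at exactly
#' `p_thr` counts as foreground).  The default 0.35 is the threshold that
#' maximises the ensemble Dice score on average across organs.
#'
#' @param p a [probability_map()] (or a [binary_mask()], returned as-is
#'   when every value clears the threshold logic).
#' @param p_thr threshold in (0, 1].
#' @param label label for the resulting mask.
#' @return a [binary_mask()].
#' @export
threshold_mask <- function(p, p_thr = 0.35, label = "ensemble") {
  if (!is.numeric(p_thr) || length(p_thr) != 1 || !is.finite(p_thr) ||
      p_thr <= 0 || p_thr > 1) {
    stop("p_thr must be a single value in (0, 1]; got ", format(p_thr), call. = FALSE)
  }
  binary_mask((p$voxels >= p_thr) * 1L, spacing = p$spacing, label = label)
}

#' Majority vote over candidate masks
#'
#' Foreground where strictly more than half of the masks vote foreground;
#' an exact tie (even J) is background.  For odd J this is identical to
#' `threshold_mask(average_probability(masks), 0.5 + eps)` for any
#' `eps` in `(0, 1/(2J)]`.
#'
#' @param masks list of [binary_mask()] objects on a common grid.
#' @return a [binary_mask()].
#' @export
majority_vote <- function(masks) {
  check_mask_list(masks, min_n = 1L)
  J <- length(masks)
  acc <- array(0L, dim(masks[[1]]$voxels))
  for (m in masks) acc <- acc + m$voxels
  binary_mask((acc > J / 2) * 1L, spacing = masks[[1]]$spacing, label = "vote")
}

#' Sweep the ensemble probability threshold
#'
#' For every image the candidate masks are averaged once; the average is
#' then thresholded at each grid value and scored against the reference.
#' Returns per-threshold means over images and, per metric, the optimal
#' threshold (argmax for DSC, argmin for the loss metrics; ties broken
#' towards the smallest threshold).
#'
#' @param model_masks list over images; each element a list of that image's
#'   candidate [binary_mask()] objects.
#' @param references list of reference masks, same length/order as
#'   `model_masks`.
#' @param grid thresholds to evaluate, all in (0, 1].
#' @param metrics subset of `c("dsc", "rvd", "assd", "mssd")` to compute.
#' @return `data.frame` of class `threshold_sweep` with a row per threshold
#'   and columns `p_thr` plus the requested mean metrics; attribute
#'   `optimum` holds the per-metric optimal threshold.
#' @export
sweep_threshold <- function(model_masks, references,
                            grid = seq(0.05, 0.95, by = 0.05),
                            metrics = c("dsc", "rvd", "assd", "mssd")) {
  grid <- as.numeric(grid)
  if (length(grid) < 1) stop("threshold grid is empty", call. = FALSE)
  if (any(grid <= 0 | grid > 1)) stop("thresholds must lie in (0, 1]", call. = FALSE)
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (length(model_masks) != length(references) || length(model_masks) < 1) {
    stop("need the same positive number of images and references", call. = FALSE)
  }
  grid <- sort(grid)
  need_surface <- any(c("assd", "mssd") %in% metrics)

  per_image <- lapply(seq_along(model_masks), function(i) {
    p <- average_probability(model_masks[[i]])
    ref <- references[[i]]
    check_same_geometry(p, ref)
    ref_edt <- NULL
    if (need_surface) {
      br <- boundary_array(ref$voxels)
      if (any(br)) ref_edt <- distance_transform(br, ref$spacing)
    }
    res <- vapply(grid, function(thr) {
      m <- threshold_mask(p, thr)
      out <- c(dsc = NA_real_, rvd = NA_real_, assd = NA_real_, mssd = NA_real_)
      if ("dsc" %in% metrics) out["dsc"] <- dice(m, ref)
      if ("rvd" %in% metrics) out["rvd"] <- rvd(m, ref)
      if (need_surface) {
        s <- surface_distance_sets(m, ref, ref_edt = ref_edt)
        if (is.null(s)) {
          out["assd"] <- out["mssd"] <- degenerate_surface_distance(m, ref)
        } else {
          out["assd"] <- mean(c(s$pred_to_ref, s$ref_to_pred))
          out["mssd"] <- max(s$pred_to_ref, s$ref_to_pred)
        }
      }
      out[metrics]
    }, numeric(length(metrics)))
    if (is.matrix(res)) t(res) else matrix(res, ncol = 1)
  })

  means <- Reduce(`+`, per_image) / length(per_image)
  dimnames(means) <- list(NULL, metrics)
  tab <- data.frame(p_thr = grid, means)
  optimum <- vapply(metrics, function(m) {
    vals <- tab[[m]]
    idx <- if (m == "dsc") which(vals == max(vals)) else which(vals == min(vals))
    grid[min(idx)]
  }, numeric(1))
  attr(tab, "optimum") <- optimum
  class(tab) <- c("threshold_sweep", "data.frame")
  tab
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat("Ensemble probability-threshold sweep over", nrow(x), "thresholds\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  opt <- attr(x, "optimum")
  cat("optimal p_thr:", paste(sprintf("%s=%.2f", names(opt), opt), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.threshold_sweep <- function(x, metric = setdiff(names(x), "p_thr")[1], ...) {
  graphics::plot(x$p_thr, x[[metric]], type = "b", xlab = "probability threshold",
                 ylab = metric, ...)
  graphics::abline(v = attr(x, "optimum")[[metric]], lty = 2)
  invisible(x)
}
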