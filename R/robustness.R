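# Outlier / robustness analytics: percentile outlier boundaries over the
# pooled single-model metric distribution, high-risk images, ensemble
# rescue rates, gain statistics, and ensemble-size subsampling.

metric_columns <- c(dsc = "dsc", rvd = "rvd", assd = "assd_mm", mssd = "mssd_mm")

#' Percentile outlier boundaries of the single-model metric distribution
#'
#' For each organ and metric, the outlier cutoff over the pooled
#' (image x model) single-model values: DSC values below their
#' `percentile` quantile are outliers, RVD/ASSD/MSSD values above their
#' `1 - percentile` quantile.  Quantiles use linear interpolation between
#' order statistics (`stats::quantile` type 7); an observation is an
#' outlier only when strictly beyond the cutoff, so degenerate
#' all-equal samples yield no outliers.
#'
#' @param records metric `data.frame` of single-model records (see
#'   [evaluate()]); fusion records must not be included here.
#' @param percentile tail fraction in (0, 0.5]; default 0.05.
#' @param pooling `"pooled"` (one boundary per organ/metric over all
#'   models, as when drawing a single dashed boundary per panel) or
#'   `"per_model"` (a boundary per organ/metric/model).
#' @return `data.frame(organ, metric, source_id, percentile, cutoff,
#'   direction)`; `source_id` is `"*"` for pooled boundaries.
#' @export
outlier_boundaries <- function(records, percentile = 0.05,
                               pooling = c("pooled", "per_model")) {
  pooling <- match.arg(pooling)
  if (nrow(records) == 0) stop("empty record set", call. = FALSE)
  if (percentile <= 0 || percentile > 0.5) stop("percentile must lie in (0, 0.5]", call. = FALSE)
  groups <- if (pooling == "pooled") {
    split(records, records$organ)
  } else {
    split(records, interaction(records$organ, records$source_id, drop = TRUE))
  }
  out <- lapply(groups, function(g) {
    do.call(rbind, lapply(names(metric_columns), function(m) {
      vals <- g[[metric_columns[[m]]]]
      vals <- vals[is.finite(vals)]
      below <- m == "dsc"
      cutoff <- if (below) {
        unname(quantile(vals, percentile, type = 7))
      } else {
        unname(quantile(vals, 1 - percentile, type = 7))
      }
      data.frame(organ = g$organ[1], metric = m,
                 source_id = if (pooling == "pooled") "*" else g$source_id[1],
                 percentile = percentile, cutoff = cutoff,
                 direction = if (below) "below" else "above",
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Flag outlier metric records against precomputed boundaries
#'
#' Adds one logical column per metric (`outlier_dsc`, ..., `outlier_mssd`)
#' plus `outlier_any`.  A record is an outlier on a metric iff its value is
#' strictly beyond the boundary for its organ (a record exactly at the
#' cutoff is not an outlier).  Ensemble/fusion records are flagged against
#' the single-model boundaries, never against their own distribution.
#'
#' @param records metric `data.frame` (models and/or fusion schemes).
#' @param boundaries output of [outlier_boundaries()].
#' @return `records` with flag columns appended.
#' @export
flag_outliers <- function(records, boundaries) {
  for (m in names(metric_columns)) {
    col <- metric_columns[[m]]
    flags <- logical(nrow(records))
    for (i in seq_len(nrow(records))) {
      b <- boundaries[boundaries$organ == records$organ[i] & boundaries$metric == m, ]
      if (nrow(b) > 1) {  # per-model boundaries: use the matching model's
        bm <- b[b$source_id == records$source_id[i], ]
        if (nrow(bm) == 1) b <- bm else b <- b[1, ]
      }
      if (nrow(b) == 0) {
        stop("no outlier boundary for organ '", records$organ[i],
             "', metric '", m, "'", call. = FALSE)
      }
      v <- records[[col]][i]
      flags[i] <- if (!is.finite(v)) TRUE else if (b$direction == "below") v < b$cutoff else v > b$cutoff
    }
    records[[paste0("outlier_", m)]] <- flags
  }
  records$outlier_any <- Reduce(`|`, records[paste0("outlier_", names(metric_columns))])
  records
}

#' High-risk images
#'
#' An image is high-risk iff at least one single model produced an outlier
#' on any metric for it.  Fusion records must not be part of the input:
#' an ensemble-only outlier does not make an image high-risk.
#'
#' @param flagged_model_records single-model records with flags from
#'   [flag_outliers()].
#' @return `data.frame(organ, image_id)` of high-risk images (zero rows if
#'   none).
#' @export
high_risk_images <- function(flagged_model_records) {
  r <- flagged_model_records
  if (!"outlier_any" %in% names(r)) stop("records carry no outlier flags; run flag_outliers() first", call. = FALSE)
  hr <- unique(r[r$outlier_any, c("organ", "image_id")])
  rownames(hr) <- NULL
  hr
}

#' Ensemble rescue rates on high-risk images
#'
#' For each metric, the fraction of high-risk images on which the fused
#' segmentation is \emph{not} an outlier (flagged against the single-model
#' boundaries).  With an empty high-risk set the rates are undefined and
#' returned as an explicit null result (`NA` with `n_high_risk = 0`),
#' never as 0 or 1.
#'
#' @param high_risk output of [high_risk_images()].
#' @param flagged_ensemble_records ensemble records (one per image) with
#'   flags from [flag_outliers()].
#' @return list with `rates` (named per-metric fractions), `rate_any`
#'   (fraction of high-risk images with no ensemble outlier on any metric),
#'   `n_high_risk`, `n_images`, and `high_risk_fraction` (share of all
#'   scored images that are high-risk).
#' @export
rescue_rates <- function(high_risk, flagged_ensemble_records) {
  e <- flagged_ensemble_records
  n_images <- nrow(unique(e[, c("organ", "image_id")]))
  n_hr <- nrow(high_risk)
  if (n_hr == 0) {
    return(list(rates = stats::setNames(rep(NA_real_, 4), names(metric_columns)),
                rate_any = NA_real_, n_high_risk = 0L, n_images = n_images,
                high_risk_fraction = 0))
  }
  key <- paste(e$organ, e$image_id)
  sel <- key %in% paste(high_risk$organ, high_risk$image_id)
  ehr <- e[sel, ]
  rates <- vapply(names(metric_columns), function(m) {
    mean(!ehr[[paste0("outlier_", m)]])
  }, numeric(1))
  list(rates = rates,
       rate_any = mean(!ehr$outlier_any),
       n_high_risk = n_hr,
       n_images = n_images,
       high_risk_fraction = n_hr / n_images)
}

#' Ensemble gain over a reference single-model statistic
#'
#' Converts metric records to losses (Dice loss `1 - DSC`; RVD, ASSD, MSSD
#' are already losses) and computes, per image and metric, the gain
#' `g = L_ens - L_ref`, where the reference is the mean or the worst
#' (largest-loss) single model for that image.  Negative gains mean the
#' ensemble improved on the reference.
#'
#' @param records metric `data.frame` holding, per image, one record per
#'   single model and one record for the fused scheme.
#' @param ensemble_source `source_id` of the fused records (default
#'   `"ensemble"`).
#' @param reference `"mean"` or `"worst"`.
#' @param by `"image"` (per-image gains) or `"organ"` (gains of per-organ
#'   mean losses).
#' @return `data.frame(organ, image_id, metric, l_ens, l_ref, gain)`; for
#'   `by = "organ"` the `image_id` column is `"*"`.
#' @export
ensemble_gain <- function(records, ensemble_source = "ensemble",
                          reference = c("mean", "worst"),
                          by = c("image", "organ")) {
  reference <- match.arg(reference)
  by <- match.arg(by)
  is_ens <- records$source_id == ensemble_source
  if (!any(is_ens)) stop("no records with source_id '", ensemble_source, "'", call. = FALSE)
  loss <- function(tab, m) {
    v <- tab[[metric_columns[[m]]]]
    if (m == "dsc") 1 - v else v
  }
  units <- if (by == "image") {
    split(records, interaction(records$organ, records$image_id, drop = TRUE))
  } else {
    split(records, records$organ)
  }
  out <- lapply(units, function(u) {
    ens <- u[u$source_id == ensemble_source, ]
    mod <- u[u$source_id != ensemble_source, ]
    if (nrow(ens) == 0) {
      stop("missing ensemble record for ", u$organ[1], "/",
           paste(unique(u$image_id), collapse = ","), call. = FALSE)
    }
    do.call(rbind, lapply(names(metric_columns), function(m) {
      l_ens <- mean(loss(ens, m))
      lm_all <- loss(mod, m)
      l_ref <- if (reference == "mean") mean(lm_all) else max(lm_all)
      data.frame(organ = u$organ[1],
                 image_id = if (by == "image") u$image_id[1] else "*",
                 metric = m, l_ens = l_ens, l_ref = l_ref,
                 gain = l_ens - l_ref, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Ensemble-size subsampling experiment
#'
#' For each requested size, draws `n_rep` uniform subsets of the models
#' without replacement (distinct subsets whenever enough exist), fuses each
#' subset by probability averaging + thresholding, scores it against the
#' reference, and summarises mean and sd over the repeats.  Fully
#' reproducible from `seed`.
#'
#' @param model_masks list over images; each a named list of the full
#'   ensemble's candidate masks (same order everywhere).
#' @param references list of reference masks, one per image.
#' @param sizes ensemble sizes to test, all `<= J`.
#' @param n_rep subsets per size (default 10).
#' @param seed integer seed governing all subset draws.
#' @param p_thr fusion threshold (default 0.35).
#' @param metrics metrics to compute (subset of dsc/rvd/assd/mssd).
#' @param organ organ tag for the records.
#' @param image_ids optional image ids (default `img_1..n`).
#' @return list with `records` (per size/rep/image metric rows, columns
#'   `size` and `rep` prepended) and `summary` (per size/metric mean of the
#'   per-rep means, and sd over reps).
#' @export
subsample_ensembles <- function(model_masks, references, sizes, n_rep = 10L,
                                seed = 1L, p_thr = 0.35,
                                metrics = c("dsc", "rvd", "assd", "mssd"),
                                organ = "organ", image_ids = NULL) {
  J <- length(model_masks[[1]])
  sizes <- as.integer(sizes)
  if (any(sizes < 1 | sizes > J)) stop("sizes must lie in 1..J = ", J, call. = FALSE)
  if (n_rep < 1) stop("n_rep must be >= 1", call. = FALSE)
  metrics <- match.arg(metrics, several.ok = TRUE)
  n_img <- length(model_masks)
  if (is.null(image_ids)) image_ids <- paste0("img_", seq_len(n_img))
  need_surface <- any(c("assd", "mssd") %in% metrics)

  ref_edts <- if (need_surface) lapply(references, function(r) {
    br <- boundary_array(r$voxels)
    if (any(br)) distance_transform(br, r$spacing) else NULL
  }) else vector("list", n_img)

  rng <- local_rng(seed)
  records <- list()
  for (s in sizes) {
    subsets <- draw_subsets(J, s, n_rep, rng)
    for (r in seq_len(n_rep)) {
      idx <- subsets[[r]]
      for (i in seq_len(n_img)) {
        fused <- threshold_mask(average_probability(model_masks[[i]][idx]), p_thr)
        rec <- score_one(fused, references[[i]], ref_edts[[i]], metrics,
                         organ, image_ids[i], sprintf("subset_%d_%d", s, r))
        rec <- cbind(size = s, rep = r, rec)
        records[[length(records) + 1]] <- rec
      }
    }
  }
  records <- do.call(rbind, records)

  summ <- do.call(rbind, lapply(sort(unique(records$size)), function(s) {
    do.call(rbind, lapply(metrics, function(m) {
      col <- metric_columns[[m]]
      per_rep <- tapply(records[[col]][records$size == s],
                        records$rep[records$size == s], mean)
      data.frame(size = s, metric = m, mean = mean(per_rep),
                 sd = if (length(per_rep) > 1) sd(per_rep) else 0,
                 n_rep = length(per_rep), stringsAsFactors = FALSE)
    }))
  }))
  rownames(summ) <- NULL
  list(records = records, summary = summ)
}

# metric scoring with optional precomputed reference EDT, restricted metrics
score_one <- function(pred, ref, ref_edt, metrics, organ, image_id, source_id) {
  out <- data.frame(organ = organ, image_id = image_id, source_id = source_id,
                    dsc = NA_real_, rvd = NA_real_, assd_mm = NA_real_,
                    mssd_mm = NA_real_, surface_defined = NA,
                    stringsAsFactors = FALSE)
  if ("dsc" %in% metrics) out$dsc <- dice(pred, ref)
  if ("rvd" %in% metrics) out$rvd <- rvd(pred, ref)
  if (any(c("assd", "mssd") %in% metrics)) {
    s <- surface_distance_sets(pred, ref, ref_edt = ref_edt)
    if (is.null(s)) {
      out$assd_mm <- out$mssd_mm <- degenerate_surface_distance(pred, ref)
      out$surface_defined <- FALSE
    } else {
      out$assd_mm <- mean(c(s$pred_to_ref, s$ref_to_pred))
      out$mssd_mm <- max(s$pred_to_ref, s$ref_to_pred)
      out$surface_defined <- TRUE
    }
  }
  out
}

# subset draws: distinct where possible, deterministic under the rng
draw_subsets <- function(J, size, n_rep, rng) {
  n_distinct <- choose(J, size)
  subsets <- list()
  seen <- character(0)
  attempts <- 0L
  while (length(subsets) < n_rep) {
    s <- sort(rng$sample(J, size))
    key <- paste(s, collapse = ",")
    attempts <- attempts + 1L
    if (length(seen) < n_distinct && key %in% seen && attempts < 1000L * n_rep) next
    subsets[[length(subsets) + 1]] <- s
    seen <- c(seen, key)
  }
  subsets
}

# a private RNG stream that does not disturb the caller's .Random.seed
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(
    sample = function(n, k) with_state(function() sample.int(n, k)),
    runif = function(n, min = 0, max = 1) with_state(function() runif(n, min, max)),
    state = env
  )
}

#' Trend of ensembling gain with single-model difficulty
#'
#' Spearman rank correlation (with `cor.test`) between the per-image worst
#' single-model loss and the rescue magnitude `L_worst - L_ens`: a positive
#' correlation means the ensemble helps most exactly where a single model
#' can fail worst.
#'
#' @param records metric `data.frame` with single-model and ensemble rows.
#' @param metric one of `"dsc"` (as Dice loss), `"rvd"`, `"assd"`, `"mssd"`.
#' @param ensemble_source `source_id` of the fused records.
#' @return the `htest` object from [stats::cor.test()].
#' @export
gain_difficulty_trend <- function(records, metric = "mssd",
                                  ensemble_source = "ensemble") {
  g <- ensemble_gain(records, ensemble_source = ensemble_source,
                     reference = "worst", by = "image")
  g <- g[g$metric == metric, ]
  stats::cor.test(g$l_ref, g$l_ref - g$l_ens, method = "spearman", exact = FALSE,
                  alternative = "greater")
}
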