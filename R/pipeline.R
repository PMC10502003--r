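# End-to-end orchestration: simulate (or load) -> fuse -> evaluate ->
# robustness report, with a schema-validated configuration and
# deterministic, diff-able outputs (CSV tables, JSON reports).

fusion_methods <- c("average", "vote", "staple", "regression")

#' Fuse one image's candidate masks by a named scheme
#'
#' @param masks named list of candidate [binary_mask()] objects.
#' @param method one of `"average"`, `"vote"`, `"staple"`, `"regression"`.
#' @param p_thr threshold for the `"average"` scheme.
#' @param staple_p_thr threshold applied to the STAPLE weight field.
#' @param combiner fitted [fit_regression_combiner()] model (required for
#'   `"regression"`).
#' @param weights optional weights for `"average"`.
#' @return a [binary_mask()] labelled with the scheme name.
#' @export
fuse_masks <- function(masks, method = c("average", "vote", "staple", "regression"),
                       p_thr = 0.35, staple_p_thr = 0.5, combiner = NULL,
                       weights = NULL) {
  method <- match.arg(method)
  switch(method,
    average = threshold_mask(average_probability(masks, weights), p_thr, label = "average"),
    vote = majority_vote(masks),
    staple = staple_mask(staple(masks), p_thr = staple_p_thr),
    regression = {
      if (is.null(combiner)) stop("method 'regression' needs a fitted combiner", call. = FALSE)
      out <- apply_regression_combiner(combiner, masks)
      m <- out$mask
      m$label <- "regression"
      m
    })
}

#' Score every model and a fused consensus across a study
#'
#' @param study an `ensemble_study` ([simulate_study()] / [load_study()]).
#' @param method fusion scheme (see [fuse_masks()]); the fused record's
#'   `source_id` is the scheme's label (`"average"` fusion is recorded as
#'   `"ensemble"`).
#' @param include_models score the individual models too (default TRUE).
#' @inheritParams fuse_masks
#' @return metric `data.frame`, one row per (image, model) plus one per
#'   (image, scheme).
#' @export
evaluate_study <- function(study, method = "average", p_thr = 0.35,
                           staple_p_thr = 0.5, combiner = NULL,
                           include_models = TRUE) {
  source_label <- if (method == "average") "ensemble" else method
  do.call(rbind, lapply(study$images, function(img) {
    fused <- fuse_masks(img$models, method = method, p_thr = p_thr,
                        staple_p_thr = staple_p_thr, combiner = combiner)
    preds <- if (include_models) c(img$models, stats::setNames(list(fused), source_label))
             else stats::setNames(list(fused), source_label)
    evaluate_against(preds, img$reference, organ = img$organ, image_id = img$image_id)
  }))
}

#' Pipeline run configuration
#'
#' Validated configuration for [run_pipeline()].  Unknown keys are
#' rejected, as are out-of-range values, before any computation happens.
#'
#' @param study a [study_spec()] for synthetic input, or `NULL` when
#'   `manifest` is given.
#' @param manifest path to a study manifest on disk (see
#'   [load_manifest()]), or `NULL`.
#' @param method fusion scheme.
#' @param p_thr ensemble averaging threshold, in (0, 1].
#' @param staple_p_thr STAPLE binarisation threshold, in (0, 1].
#' @param percentile outlier tail fraction, in (0, 0.5].
#' @param subsample_sizes optional ensemble sizes for the subsampling
#'   experiment (`NULL` to skip).
#' @param n_rep subsets per size.
#' @param seed integer seed governing all randomness of the run.
#' @param save_consensus write the fused mask of every image as NIfTI.
#' @return list of class `run_config`.
#' @export
run_config <- function(study = NULL, manifest = NULL, method = "average",
                       p_thr = 0.35, staple_p_thr = 0.5, percentile = 0.05,
                       subsample_sizes = NULL, n_rep = 10L, seed = 1L,
                       save_consensus = FALSE) {
  if (is.null(study) && is.null(manifest)) stop("config needs a study spec or a manifest path", call. = FALSE)
  if (!is.null(study) && !inherits(study, "study_spec")) stop("study must be a study_spec", call. = FALSE)
  if (!method %in% fusion_methods) {
    stop("unknown fusion method '", method, "' (use ",
         paste(fusion_methods, collapse = "/"), ")", call. = FALSE)
  }
  for (nm in c("p_thr", "staple_p_thr")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v > 1) {
      stop("config field '", nm, "' must lie in (0, 1]; got ", format(v), call. = FALSE)
    }
  }
  if (percentile <= 0 || percentile > 0.5) stop("config field 'percentile' must lie in (0, 0.5]", call. = FALSE)
  if (n_rep < 1) stop("config field 'n_rep' must be >= 1", call. = FALSE)
  structure(list(study = study, manifest = manifest, method = method,
                 p_thr = p_thr, staple_p_thr = staple_p_thr,
                 percentile = percentile, subsample_sizes = subsample_sizes,
                 n_rep = as.integer(n_rep), seed = as.integer(seed),
                 save_consensus = isTRUE(save_consensus)),
            class = "run_config")
}

config_hash <- function(config) {
  ser <- jsonlite::toJSON(rapply(unclass(config), unclass, how = "replace"),
                          auto_unbox = TRUE, digits = NA, null = "null",
                          force = TRUE)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(ser), tf)
  unname(tools::md5sum(tf))
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> fuse -> evaluate -> robustness report.  The run is
#' idempotent given the config (including its seed): re-running produces a
#' byte-identical metrics CSV.  Any stage error aborts with the stage name
#' prepended.
#'
#' @param config a [run_config()].
#' @param out_dir output directory; receives `metrics.csv`,
#'   `robustness.json`, `log.txt` and (optionally) `consensus/` masks.
#' @return list with `records`, `boundaries`, `high_risk`, `rescue`,
#'   `gain_fits`, `subsampling` (or `NULL`) and the output paths,
#'   invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  study <- stage("input", {
    if (!is.null(config$study)) {
      spec <- config$study
      spec$seed <- config$seed
      simulate_study(spec)
    } else {
      load_study(config$manifest)
    }
  })

  combiner <- NULL
  if (config$method == "regression") {
    combiner <- stage("fit-combiner", {
      fit_regression_combiner(lapply(study$images, `[[`, "models"),
                              lapply(study$images, `[[`, "reference"))
    })
  }

  records <- stage("evaluate", {
    evaluate_study(study, method = config$method, p_thr = config$p_thr,
                   staple_p_thr = config$staple_p_thr, combiner = combiner)
  })
  ens_source <- if (config$method == "average") "ensemble" else config$method

  if (config$save_consensus) {
    stage("save-consensus", {
      for (img in study$images) {
        fused <- fuse_masks(img$models, method = config$method,
                            p_thr = config$p_thr,
                            staple_p_thr = config$staple_p_thr,
                            combiner = combiner)
        save_mask(fused, file.path(out_dir, "consensus",
                                   paste0(img$image_id, "_", ens_source, ".nii")))
      }
    })
  }

  rob <- stage("robustness", {
    model_rec <- records[!(records$source_id %in% c(ens_source, fusion_methods, "ensemble")), ]
    ens_rec <- records[records$source_id == ens_source, ]
    boundaries <- outlier_boundaries(model_rec, percentile = config$percentile)
    model_fl <- flag_outliers(model_rec, boundaries)
    ens_fl <- flag_outliers(ens_rec, boundaries)
    hr <- high_risk_images(model_fl)
    rr <- rescue_rates(hr, ens_fl)
    gains <- ensemble_gain(records, ensemble_source = ens_source,
                           reference = "mean", by = "image")
    fits <- gain_fits(records, ensemble_source = ens_source)
    list(boundaries = boundaries, high_risk = hr, rescue = rr,
         gains = gains, gain_fits = fits)
  })

  subsampling <- NULL
  if (!is.null(config$subsample_sizes)) {
    subsampling <- stage("subsample", {
      subsample_ensembles(lapply(study$images, `[[`, "models"),
                          lapply(study$images, `[[`, "reference"),
                          sizes = config$subsample_sizes, n_rep = config$n_rep,
                          seed = config$seed, p_thr = config$p_thr,
                          organ = study$images[[1]]$organ,
                          image_ids = vapply(study$images, `[[`, "", "image_id"))
    })
  }

  paths <- stage("write", {
    metrics_path <- file.path(out_dir, "metrics.csv")
    write_metrics_csv(records, metrics_path)
    report <- list(
      config_hash = config_hash(config),
      seed = config$seed,
      boundaries = rob$boundaries,
      high_risk_images = rob$high_risk,
      rescue_rates = rob$rescue,
      gain_fits = rob$gain_fits,
      subsampling_summary = if (!is.null(subsampling)) subsampling$summary
    )
    json_path <- file.path(out_dir, "robustness.json")
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows", na = "null")
    log_path <- file.path(out_dir, "log.txt")
    writeLines(c(
      paste0("ensembleseg ", as.character(utils::packageVersion("ensembleseg"))),
      paste0("R ", R.version.string),
      paste0("config hash ", config_hash(config)),
      paste0("seed ", config$seed),
      paste0("images ", length(study$images), ", models ", length(study$model_ids)),
      paste0("fusion method ", config$method, " (p_thr ", config$p_thr, ")")
    ), log_path)
    list(metrics = metrics_path, robustness = json_path, log = log_path)
  })

  invisible(c(list(records = records), rob,
              list(subsampling = subsampling, paths = paths)))
}

#' York line fits of ensemble gain against single-model loss
#'
#' For each metric (as a loss: Dice loss, RVD, ASSD, MSSD), fits
#' `g = a + b * <L>` across images, where `<L>` is the image's mean
#' single-model loss and `g = L_ens - <L>` the ensemble gain.  Both
#' coordinates carry the standard error of the model losses within the
#' image's ensemble, so the fit uses the errors-in-both-variables
#' [york_fit()].  The slope is the fraction of the single-model loss that
#' ensembling removes (a slope of -0.2 means 20 percent).
#'
#' @param records metric `data.frame` with single-model and ensemble rows.
#' @param ensemble_source `source_id` of the fused records.
#' @return named list, one entry per metric, each with `slope`,
#'   `intercept`, their sds and a `converged` flag (`NULL` if the fit
#'   failed).
#' @export
gain_fits <- function(records, ensemble_source = "ensemble") {
  model_rec <- records[!(records$source_id %in% c(ensemble_source, "ensemble")), ]
  out <- list()
  for (m in names(metric_columns)) {
    col <- metric_columns[[m]]
    to_loss <- function(v) if (m == "dsc") 1 - v else v
    by_img <- split(model_rec, model_rec$image_id)
    x <- vapply(by_img, function(g) mean(to_loss(g[[col]])), numeric(1))
    sx <- vapply(by_img, function(g) {
      stats::sd(to_loss(g[[col]])) / sqrt(nrow(g))
    }, numeric(1))
    ens <- records[records$source_id == ensemble_source, ]
    ens <- ens[match(names(by_img), ens$image_id), ]
    y <- to_loss(ens[[col]]) - x
    fit <- tryCatch(
      york_fit(x, y, sx = pmax(sx, 1e-6), sy = pmax(sx, 1e-6)),
      error = function(e) NULL)
    out[[m]] <- if (is.null(fit)) NULL else {
      list(metric = m, slope = fit$slope, intercept = fit$intercept,
           slope_sd = fit$slope_sd, intercept_sd = fit$intercept_sd,
           converged = fit$converged)
    }
  }
  out
}

#' Compare fusion schemes on one study
#'
#' Scores each requested scheme on the identical image set and reports the
#' per-metric mean with the standard deviation of the mean over images.
#'
#' @param study an `ensemble_study`.
#' @param methods two or more of `"average"`, `"vote"`, `"staple"`,
#'   `"regression"`.
#' @param p_thr,staple_p_thr fusion parameters.
#' @param combiner fitted regression combiner; if `NULL` and
#'   `"regression"` is requested, one is fitted on this study.
#' @return `data.frame` with one row per (method, metric): `mean`,
#'   `sd_of_mean` (`NA` when only one image) and `n_images`.
#' @export
compare_methods <- function(study, methods = c("average", "vote", "staple"),
                            p_thr = 0.35, staple_p_thr = 0.5, combiner = NULL) {
  if (length(methods) < 2) stop("need at least 2 fusion methods to compare", call. = FALSE)
  bad <- setdiff(methods, fusion_methods)
  if (length(bad)) stop("unknown fusion method(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if ("regression" %in% methods && is.null(combiner)) {
    combiner <- fit_regression_combiner(lapply(study$images, `[[`, "models"),
                                        lapply(study$images, `[[`, "reference"))
  }
  out <- lapply(methods, function(meth) {
    rec <- evaluate_study(study, method = meth, p_thr = p_thr,
                          staple_p_thr = staple_p_thr, combiner = combiner,
                          include_models = FALSE)
    do.call(rbind, lapply(names(metric_columns), function(m) {
      v <- rec[[metric_columns[[m]]]]
      data.frame(method = meth, metric = m, mean = mean(v),
                 sd_of_mean = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
                 n_images = length(v), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
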