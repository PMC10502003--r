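fake_records <- function(dsc, rvd = NULL, assd = NULL, mssd = NULL,
                         organ = "o", source = NULL, image = NULL) {
  n <- length(dsc)
  data.frame(organ = organ,
             image_id = if (is.null(image)) paste0("img_", seq_len(n)) else image,
             source_id = if (is.null(source)) paste0("m", seq_len(n)) else source,
             dsc = dsc,
             rvd = if (is.null(rvd)) rep(0.1, n) else rvd,
             assd_mm = if (is.null(assd)) rep(1, n) else assd,
             mssd_mm = if (is.null(mssd)) rep(5, n) else mssd,
             surface_defined = TRUE, stringsAsFactors = FALSE)
}

test_that("boundary cutoffs equal a hand-written interpolated quantile", {
  for (s in 1:20) {
    set.seed(700 + s)
    n <- sample(5:60, 1)
    rec <- fake_records(dsc = runif(n), rvd = rexp(n), assd = rexp(n),
                        mssd = rexp(n, 1 / 10))
    b <- outlier_boundaries(rec, percentile = 0.05)
    expect_equal(b$cutoff[b$metric == "dsc"], manual_quantile7(rec$dsc, 0.05))
    expect_equal(b$cutoff[b$metric == "mssd"], manual_quantile7(rec$mssd_mm, 0.95))
    expect_equal(b$cutoff[b$metric == "rvd"], manual_quantile7(rec$rvd, 0.95))
  }
  expect_error(outlier_boundaries(fake_records(0.5)[0, ]), "empty")
})

test_that("outliers are strictly beyond the boundary", {
  # all values identical: nothing can be strictly beyond the cutoff
  rec <- fake_records(dsc = rep(0.8, 20), rvd = rep(0.1, 20),
                      assd = rep(1, 20), mssd = rep(5, 20))
  fl <- flag_outliers(rec, outlier_boundaries(rec))
  expect_false(any(fl$outlier_any))

  # a record exactly at the cutoff is not an outlier
  vals <- seq(0.5, 0.97, length.out = 20)
  rec2 <- fake_records(dsc = vals)
  b2 <- outlier_boundaries(rec2)
  at_cut <- rec2[1, ]
  at_cut$dsc <- b2$cutoff[b2$metric == "dsc"]
  expect_false(flag_outliers(at_cut, b2)$outlier_dsc)

  # the maximum of a strictly increasing MSSD sample is flagged for n >= 21
  rec3 <- fake_records(dsc = rep(0.9, 25), mssd = seq(1, 25))
  fl3 <- flag_outliers(rec3, outlier_boundaries(rec3))
  expect_true(fl3$outlier_mssd[which.max(rec3$mssd_mm)])
  expect_equal(sum(fl3$outlier_mssd),
               sum(rec3$mssd_mm > manual_quantile7(rec3$mssd_mm, 0.95)))

  # flags do not depend on record order
  perm <- sample(nrow(rec3))
  fl_perm <- flag_outliers(rec3[perm, ], outlier_boundaries(rec3))
  expect_equal(fl_perm$outlier_mssd, fl3$outlier_mssd[perm])

  # a degenerate-mask record capped at the grid diagonal exceeds any cutoff
  cap <- fake_records(dsc = 0, mssd = sqrt(3) * 64, source = "mX", image = "img_9")
  cap$surface_defined <- FALSE
  expect_true(flag_outliers(cap, outlier_boundaries(rec3))$outlier_mssd)
})

test_that("high-risk images are exactly those with a flagged model", {
  rec <- fake_records(dsc = c(0.9, 0.91, 0.92, 0.89), source = "m1")
  rec$outlier_dsc <- rec$outlier_rvd <- rec$outlier_assd <- rec$outlier_mssd <- FALSE
  rec$outlier_any <- FALSE
  expect_equal(nrow(high_risk_images(rec)), 0)

  rec$outlier_mssd[2] <- TRUE
  rec$outlier_any[2] <- TRUE
  hr <- high_risk_images(rec)
  expect_equal(hr$image_id, "img_2")

  expect_error(high_risk_images(fake_records(0.9)), "flag_outliers")
})

test_that("rescue rates follow the definition with an explicit null result", {
  hr <- data.frame(organ = "o", image_id = paste0("img_", 1:5))
  ens <- fake_records(dsc = rep(0.9, 6), source = "ensemble")
  ens$outlier_dsc <- ens$outlier_rvd <- ens$outlier_mssd <- FALSE
  ens$outlier_assd <- c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  ens$outlier_any <- ens$outlier_assd

  rr <- rescue_rates(hr, ens)
  expect_equal(unname(rr$rates["assd"]), 0.8)   # 4 of 5 high-risk rescued
  expect_equal(unname(rr$rates["mssd"]), 1)
  expect_equal(rr$high_risk_fraction, 5 / 6)

  rr0 <- rescue_rates(hr[0, ], ens)
  expect_true(all(is.na(rr0$rates)))
  expect_equal(rr0$n_high_risk, 0L)
})

test_that("ensemble gains are loss differences with the stated sign convention", {
  rec <- rbind(
    fake_records(dsc = c(0.70, 0.80), source = c("m1", "m2"), image = "img_1"),
    fake_records(dsc = 0.78, source = "ensemble", image = "img_1"))
  g <- ensemble_gain(rec, reference = "mean", by = "image")
  gd <- g[g$metric == "dsc", ]
  expect_equal(gd$l_ref, 0.25)   # mean Dice loss of the models
  expect_equal(gd$l_ens, 0.22)
  expect_equal(gd$gain, -0.03)   # negative = improvement

  gw <- ensemble_gain(rec, reference = "worst", by = "image")
  expect_equal(gw$l_ref[gw$metric == "dsc"], 0.30)

  expect_error(ensemble_gain(rec[rec$source_id != "ensemble", ]), "ensemble")

  # sorting the worst-reference gains is monotone (ordering postcondition)
  set.seed(81)
  many <- do.call(rbind, lapply(1:12, function(i) rbind(
    fake_records(dsc = runif(3, 0.6, 0.95), source = paste0("m", 1:3),
                 image = paste0("img_", i)),
    fake_records(dsc = runif(1, 0.8, 0.97), source = "ensemble",
                 image = paste0("img_", i)))))
  gm <- ensemble_gain(many, reference = "worst", by = "image")
  gm <- gm[gm$metric == "dsc", ]
  expect_true(all(diff(sort(gm$gain, decreasing = TRUE)) <= 0))
})

test_that("subsampled ensembles are reproducible and exhaustive at size J", {
  st <- tiny_study(seed = 10, n_images = 3, n_models = 4, shape = 24)
  masks <- lapply(st$images, `[[`, "models")
  refs <- lapply(st$images, `[[`, "reference")

  out <- subsample_ensembles(masks, refs, sizes = c(2, 4), n_rep = 3, seed = 5,
                             metrics = "dsc")
  out2 <- subsample_ensembles(masks, refs, sizes = c(2, 4), n_rep = 3, seed = 5,
                              metrics = "dsc")
  expect_identical(out$records$dsc, out2$records$dsc)

  # size = J: every rep is the same (full) subset, metrics identical
  full <- out$records[out$records$size == 4, ]
  per_image <- split(full$dsc, full$image_id)
  for (v in per_image) expect_true(all(v == v[1]))
  fused_full <- threshold_mask(average_probability(masks[[1]]), 0.35)
  expect_equal(full$dsc[full$image_id == "img_1"][1], dice(fused_full, refs[[1]]))

  # distinct subsets drawn when enough exist
  expect_error(subsample_ensembles(masks, refs, sizes = 5, seed = 1), "1..J")
})

test_that("gain_difficulty_trend reports a one-sided Spearman test", {
  set.seed(91)
  rec <- do.call(rbind, lapply(1:20, function(i) {
    worst <- runif(1, 0.1, 0.5)
    rbind(fake_records(dsc = 1 - c(worst, worst / 2), source = c("m1", "m2"),
                       image = paste0("img_", i)),
          fake_records(dsc = 1 - worst / 4, source = "ensemble",
                       image = paste0("img_", i)))
  }))
  ht <- gain_difficulty_trend(rec, metric = "dsc")
  expect_s3_class(ht, "htest")
  expect_lt(ht$p.value, 0.01)  # rescue grows with difficulty by construction
})
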