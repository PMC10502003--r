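test_that("ellipsoid phantoms match the analytic volume and are deterministic", {
  m <- make_phantom(phantom_spec(shape = c(64, 64, 64), semi_axes = c(10, 10, 10)))
  expect_lt(abs(mask_volume(m) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.05)
  expect_equal(n_components(m), 1)

  m2 <- make_phantom(phantom_spec(shape = c(64, 64, 64), semi_axes = c(12, 9, 8)))
  expect_lt(abs(mask_volume(m2) - 4 / 3 * pi * 12 * 9 * 8) / (4 / 3 * pi * 12 * 9 * 8), 0.05)

  expect_error(phantom_spec(semi_axes = c(0, 5, 5)), "semi-axes")

  b1 <- make_phantom(phantom_spec(family = "blob", seed = 7))
  b2 <- make_phantom(phantom_spec(family = "blob", seed = 7))
  expect_identical(b1$voxels, b2$voxels)
  expect_equal(n_components(b1), 1)
  expect_error(phantom_spec(family = "blob", volume_fraction = 0.7), "volume fraction")
})

test_that("an identity profile reproduces the truth exactly", {
  gt <- make_phantom(phantom_spec(shape = c(32, 32, 32), semi_axes = c(8, 6, 5)))
  quiet <- model_profile(max_rotation_deg = 0, max_scale = 0,
                         max_translation_vox = 0, boundary_iter_max = 0,
                         p_spurious = 0, p_dropout = 0)
  out <- simulate_model_output(gt, quiet, seed = 1)
  expect_identical(out$voxels, gt$voxels)
})

test_that("simulated model outputs are a pure function of the seed", {
  gt <- make_phantom(phantom_spec(shape = c(32, 32, 32), semi_axes = c(8, 6, 5)))
  prof <- model_profile()
  a <- simulate_model_output(gt, prof, seed = 42)
  b <- simulate_model_output(gt, prof, seed = 42)
  expect_identical(a$voxels, b$voxels)
  c2 <- simulate_model_output(gt, prof, seed = 43)
  expect_false(identical(a$voxels, c2$voxels))
})

test_that("forced spurious components are distant and disconnect the mask", {
  gt <- make_phantom(phantom_spec(shape = c(64, 64, 64), semi_axes = c(9, 8, 7)))
  prof <- model_profile(max_rotation_deg = 0, max_scale = 0,
                        max_translation_vox = 0, boundary_iter_max = 0,
                        p_dropout = 0, p_spurious = 1,
                        spurious_min_dist_mm = 20)
  out <- simulate_model_output(gt, prof, seed = 3)
  expect_gte(n_components(out), 2)
  expect_gte(mssd(out, gt), 20)

  # impossible placement is a named error
  small_gt <- make_phantom(phantom_spec(shape = c(24, 24, 24), semi_axes = c(8, 7, 6)))
  prof_far <- model_profile(max_rotation_deg = 0, max_scale = 0,
                            max_translation_vox = 0, boundary_iter_max = 0,
                            p_dropout = 0, p_spurious = 1,
                            spurious_min_dist_mm = 200)
  expect_error(simulate_model_output(small_gt, prof_far, seed = 1),
               "placement impossible")
})

test_that("dropouts remove the configured connected fraction", {
  gt <- make_phantom(phantom_spec(shape = c(48, 48, 48), semi_axes = c(11, 9, 8)))
  prof <- model_profile(max_rotation_deg = 0, max_scale = 0,
                        max_translation_vox = 0, boundary_iter_max = 0,
                        p_spurious = 0, p_dropout = 1,
                        dropout_fraction_range = c(0.3, 0.3))
  out <- simulate_model_output(gt, prof, seed = 5)
  expect_equal(mask_volume(out) / mask_volume(gt), 0.7, tolerance = 0.01)
  expect_true(attr(out, "failures")[["dropout"]])
})

test_that("the iid rater model hits its operating point", {
  gt <- make_phantom(phantom_spec(shape = c(48, 48, 48), semi_axes = c(12, 10, 9)))
  exact <- simulate_rater(gt, 1, 1, seed = 1)
  expect_identical(exact$voxels, gt$voxels)
  none <- simulate_rater(gt, 0, 1, seed = 2)
  expect_equal(sum(none$voxels), 0)

  r <- simulate_rater(gt, 0.9, 0.95, seed = 3)
  fg <- gt$voxels == 1L
  n_bg <- sum(!fg)
  expect_gt(n_bg, 1e5)
  flip_rate <- sum(r$voxels[!fg]) / n_bg
  tol <- 3 * sqrt(0.05 * 0.95 / n_bg)
  expect_lt(abs(flip_rate - 0.05), tol)
  keep_rate <- sum(r$voxels[fg]) / sum(fg)
  expect_lt(abs(keep_rate - 0.9), 3 * sqrt(0.9 * 0.1 / sum(fg)))
})

test_that("studies have the declared layout and are byte-stable on disk", {
  st <- tiny_study(seed = 12, n_images = 2, n_models = 3, shape = 16)
  expect_length(st$images, 2)
  expect_length(st$images[[1]]$models, 3)

  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_study(st, dir1)
  write_study(simulate_study(st$spec), dir2)
  for (f in list.files(dir1)) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     label = paste("md5 of", f))
  }
})

test_that("injected failures are independent across models (binomial counts)", {
  # pool per-image counts of spurious-failure models over several small
  # studies; under independence the count is Binomial(J, p_spurious)
  J <- 8
  p_sp <- 0.3  # raised rate so desk-scale counts populate several bins
  counts <- integer(0)
  for (s in 1:6) {
    spec <- study_spec(
      n_images = 10, n_models = J,
      phantom = phantom_spec(shape = c(32, 32, 32), semi_axes = c(6, 5, 4)),
      profiles = model_profile(p_spurious = p_sp, p_dropout = 0,
                               spurious_min_dist_mm = 6,
                               spurious_size_range = c(27, 64)),
      seed = 3000 + s)
    st <- simulate_study(spec)
    counts <- c(counts, vapply(st$images, function(img) {
      sum(vapply(img$models, function(m) attr(m, "failures")[["spurious"]],
                 logical(1)))
    }, integer(1)))
  }
  # chi-square GOF against Binomial(J, p_sp), tail bins merged
  probs <- dbinom(0:J, J, p_sp)
  obs <- tabulate(counts + 1L, nbins = J + 1)
  grp <- c(1, 2, 3, 4, rep(5, J - 3))  # bins: 0,1,2,3,>=4
  o <- tapply(obs, grp, sum)
  e <- tapply(probs * length(counts), grp, sum)
  chi2 <- sum((o - e)^2 / e)
  pval <- pchisq(chi2, df = length(o) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("any single mask can be regenerated in isolation", {
  st <- tiny_study(seed = 17, n_images = 3, n_models = 3, shape = 24)
  img <- st$images[[2]]
  regen <- simulate_model_output(img$reference, st$spec$profiles[[3]],
                                 seed = ensembleseg:::derive_seed(17, 2L, 3L),
                                 label = "m03")
  expect_identical(regen$voxels, img$models[[3]]$voxels)
})
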