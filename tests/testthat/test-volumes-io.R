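test_that("mask constructors enforce their invariants", {
  expect_error(binary_mask(array(c(0, 2), c(2, 1, 1))), "0, 1")
  expect_error(binary_mask(matrix(0, 2, 2)), "3-D")
  expect_error(binary_mask(array(0, c(2, 2, 2)), spacing = c(1, 1)), "spacing")
  expect_error(binary_mask(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)), "spacing")
  expect_error(probability_map(array(1.2, c(2, 2, 2))), "\\[0, 1\\]")

  m <- binary_mask(array(TRUE, c(2, 3, 4)), spacing = c(1, 1, 5), label = "x")
  expect_identical(dim(m), c(2L, 3L, 4L))
  expect_equal(mask_volume(m), 24)
  expect_equal(mask_volume(m, physical = TRUE), 120)
})

test_that("NIfTI round trips are lossless for voxels and spacing", {
  dir <- withr::local_tempdir()

  zero <- binary_mask(array(0L, c(4, 4, 4)), spacing = c(1, 1, 5))
  f <- file.path(dir, "zero.nii")
  save_mask(zero, f)
  back <- load_mask(f)
  expect_identical(back$voxels, zero$voxels)
  expect_equal(back$spacing, zero$spacing, tolerance = 1e-6)

  m <- rand_mask(c(8, 8, 8), p = 0.4, seed = 3, spacing = c(1.25, 0.7, 3))
  f2 <- file.path(dir, "sub", "rand.nii.gz")
  save_mask(m, f2)
  back2 <- load_mask(f2)
  expect_identical(back2$voxels, m$voxels)
  expect_equal(back2$spacing, m$spacing, tolerance = 1e-6)

  p <- probability_map(array(0.35, c(3, 3, 3)), spacing = c(2, 2, 2))
  f3 <- file.path(dir, "prob.nii")
  save_mask(p, f3)
  back3 <- load_probability_map(f3)
  expect_lt(max(abs(back3$voxels - p$voxels)), 1e-6)
})

test_that("load_mask binarizes at the requested threshold and rejects non-3D input", {
  dir <- withr::local_tempdir()
  vals <- array(0, c(3, 3, 3))
  vals[1, 1, 1] <- 0.7
  vals[2, 2, 2] <- 0.4
  img <- RNifti::asNifti(vals, datatype = "double")
  f <- file.path(dir, "frac.nii")
  RNifti::writeNifti(img, f)

  m <- load_mask(f, binarize_threshold = 0.5)
  expect_equal(sum(m$voxels), 1)
  expect_equal(m$voxels[1, 1, 1], 1L)
  m2 <- load_mask(f, binarize_threshold = 0.4)  # tie at threshold is foreground
  expect_equal(sum(m2$voxels), 2)

  img2d <- RNifti::asNifti(matrix(1, 4, 4))
  f2 <- file.path(dir, "flat.nii")
  RNifti::writeNifti(img2d, f2)
  expect_error(load_mask(f2), "dimension")
  expect_error(load_mask(file.path(dir, "absent.nii")), "exist")
})

test_that("NIfTI output is readable by an independent reader", {
  skip_if_not_installed("oro.nifti")
  dir <- withr::local_tempdir()
  m <- rand_mask(c(6, 5, 4), p = 0.5, seed = 9, spacing = c(1, 2, 3))
  f <- file.path(dir, "x.nii.gz")
  save_mask(m, f)
  img <- oro.nifti::readNIfTI(f)
  expect_equal(array(as.numeric(img@.Data), dim(m$voxels)),
               array(as.numeric(m$voxels), dim(m$voxels)))
  expect_equal(oro.nifti::pixdim(img)[2:4], m$spacing, tolerance = 1e-6)
})

test_that("manifests load, preserve model order, and reject broken entries", {
  dir <- withr::local_tempdir()
  st <- tiny_study(seed = 4, n_images = 2, n_models = 3, shape = 16)
  manifest_path <- write_study(st, dir)
  man <- load_manifest(manifest_path)
  expect_length(man, 2)
  expect_identical(names(man[[1]]$models), c("m01", "m02", "m03"))

  back <- load_study(man)
  expect_identical(back$images[[1]]$reference$voxels, st$images[[1]]$reference$voxels)
  expect_identical(back$images[[2]]$models[[3]]$voxels, st$images[[2]]$models[[3]]$voxels)

  raw <- jsonlite::read_json(manifest_path)
  broken <- raw
  broken[[1]]$reference <- NULL
  jsonlite::write_json(broken, file.path(dir, "noref.json"), auto_unbox = TRUE)
  expect_error(load_manifest(file.path(dir, "noref.json")), "img_001")

  # duplicated model ids within one image (CSV layout keeps duplicates)
  csv <- data.frame(
    image_id = "img_001", organ = "phantom",
    role = c("reference", "model:m01", "model:m01"),
    path = c(raw[[1]]$reference, raw[[1]]$models$m01, raw[[1]]$models$m02))
  write.csv(csv, file.path(dir, "dup.csv"), row.names = FALSE)
  expect_error(load_manifest(file.path(dir, "dup.csv")), "duplicated")

  incons <- raw
  incons[[2]]$models <- incons[[2]]$models[1:2]
  jsonlite::write_json(incons, file.path(dir, "incons.json"), auto_unbox = TRUE)
  expect_error(load_manifest(file.path(dir, "incons.json")), "inconsistent")

  missing <- raw
  missing[[1]]$models[["m02"]] <- "nope.nii"
  jsonlite::write_json(missing, file.path(dir, "missing.json"), auto_unbox = TRUE)
  expect_error(load_manifest(file.path(dir, "missing.json")), "missing files")
})

test_that("geometry mismatches are rejected everywhere downstream", {
  a <- binary_mask(array(0L, c(4, 4, 4)))
  b <- binary_mask(array(0L, c(4, 4, 5)))
  c_sp <- binary_mask(array(0L, c(4, 4, 4)), spacing = c(1, 1, 2))
  expect_error(dice(a, b), "geometry mismatch")
  expect_error(rvd(a, c_sp), "geometry mismatch")
  expect_error(assd(a, b), "geometry mismatch")
  expect_error(mssd(a, c_sp), "geometry mismatch")
  expect_error(average_probability(list(a, b)), "geometry mismatch")
  expect_error(majority_vote(list(a, c_sp)), "geometry mismatch")
  expect_error(staple(list(a, b)), "geometry mismatch")
  # sub-ppm spacing differences are tolerated
  d <- binary_mask(array(0L, c(4, 4, 4)), spacing = c(1, 1, 1 + 1e-8))
  expect_silent(dice(a, d))
})
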