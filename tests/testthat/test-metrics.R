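mask_from_voxels <- function(coords, dims = c(8, 8, 8), spacing = c(1, 1, 1)) {
  v <- array(0L, dims)
  v[coords] <- 1L
  binary_mask(v, spacing = spacing)
}

test_that("dice matches hand counts and conventions", {
  a <- mask_from_voxels(rbind(c(1, 1, 1), c(2, 1, 1)))
  b <- mask_from_voxels(rbind(c(2, 1, 1), c(3, 1, 1)))
  expect_equal(dice(a, b), 0.5)  # 2*1 / (2+2)
  expect_equal(dice(a, a), 1)
  disjoint <- mask_from_voxels(rbind(c(5, 5, 5)))
  expect_equal(dice(a, disjoint), 0)
  empty <- mask_from_voxels(matrix(numeric(0), 0, 3))
  expect_equal(dice(empty, empty), 1)  # both-empty convention
})

test_that("rvd is the absolute volume discrepancy, with a signed variant", {
  ref <- rand_mask(c(10, 10, 10), p = 0.1, seed = 2)
  n_ref <- sum(ref$voxels)
  pred <- ref
  expect_equal(rvd(pred, ref), 0)

  v <- array(0L, c(10, 10, 10))
  v[seq_len(120)] <- 1L
  r <- array(0L, c(10, 10, 10))
  r[901:1000] <- 1L  # disjoint: overlap must not matter
  expect_equal(rvd(binary_mask(v), binary_mask(r)), 0.2)
  expect_equal(rvd(binary_mask(r), binary_mask(v), signed = TRUE), -1 / 6)

  empty <- binary_mask(array(0L, c(10, 10, 10)))
  expect_equal(rvd(empty, ref), 1)
  expect_true(is.na(rvd(ref, empty)))
  expect_equal(rvd(empty, empty), 0)
})

test_that("boundary voxels are exactly the 6-neighbour surface", {
  single <- mask_from_voxels(rbind(c(4, 4, 4)))
  expect_equal(unname(boundary_voxels(single)), rbind(c(4L, 4L, 4L)))

  cube <- binary_mask(array(0L, c(7, 7, 7)))
  cube$voxels[3:5, 3:5, 3:5] <- 1L
  b <- boundary_voxels(cube)
  expect_equal(nrow(b), 26)  # all but the centre
  expect_false(any(b[, 1] == 4 & b[, 2] == 4 & b[, 3] == 4))

  full <- binary_mask(array(1L, c(4, 4, 4)))
  bf <- boundary_voxels(full)
  expect_equal(nrow(bf), 4^3 - 2^3)  # grid border counts as background

  # random masks agree with the loop-based oracle
  for (s in 1:5) {
    m <- rand_mask(c(9, 8, 7), p = 0.3, seed = s)
    got <- boundary_voxels(m)
    want <- brute_boundary(m$voxels)
    expect_equal(got[order(got[, 1], got[, 2], got[, 3]), , drop = FALSE],
                 want[order(want[, 1], want[, 2], want[, 3]), , drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("surface distances match hand-computable cases", {
  a <- mask_from_voxels(rbind(c(2, 4, 4)))
  b <- mask_from_voxels(rbind(c(5, 4, 4)))
  expect_equal(assd(a, b), 3)
  expect_equal(mssd(a, b), 3)

  a5 <- mask_from_voxels(rbind(c(4, 4, 2)), spacing = c(1, 1, 5))
  b5 <- mask_from_voxels(rbind(c(4, 4, 3)), spacing = c(1, 1, 5))
  expect_equal(assd(a5, b5), 5)
  expect_equal(mssd(a5, b5), 5)

  ref <- binary_mask(array(0L, c(20, 8, 8)))
  ref$voxels[2:4, 2:4, 2:4] <- 1L
  pred <- ref
  pred$voxels[18, 4, 4] <- 1L  # one far spurious voxel
  expect_equal(assd(ref, ref), 0)
  o <- brute_surface_metrics(pred, ref)
  expect_equal(mssd(pred, ref), o$mssd)
  expect_equal(assd(pred, ref), o$assd)
  expect_gt(mssd(pred, ref), 10)
  expect_lt(assd(pred, ref), 1)  # MSSD jumps, ASSD barely moves
})

test_that("metric invariants hold on random pairs", {
  for (s in 1:12) {
    sp <- if (s %% 2) c(1, 1, 1) else c(1, 1.5, 3)
    a <- rand_mask(c(10, 9, 8), p = 0.25, seed = 100 + s, spacing = sp)
    b <- rand_mask(c(10, 9, 8), p = 0.25, seed = 200 + s, spacing = sp)
    expect_equal(dice(a, b), dice(b, a))
    expect_equal(assd(a, b), assd(b, a))
    expect_equal(mssd(a, b), mssd(b, a))
    expect_gte(mssd(a, b), assd(a, b))
    expect_gte(dice(a, b), 0)
    expect_lte(dice(a, b), 1)
    # scaling spacing by k scales distances by k and leaves overlap alone
    k <- 2.5
    ak <- binary_mask(a$voxels, spacing = sp * k)
    bk <- binary_mask(b$voxels, spacing = sp * k)
    expect_equal(assd(ak, bk), k * assd(a, b), tolerance = 1e-12)
    expect_equal(mssd(ak, bk), k * mssd(a, b), tolerance = 1e-12)
    expect_equal(dice(ak, bk), dice(a, b))
    expect_equal(rvd(ak, bk), rvd(a, b))
  }
})

test_that("dice equals 1 only for voxel-identical nonempty masks", {
  a <- rand_mask(c(8, 8, 8), p = 0.3, seed = 5)
  b <- a
  b$voxels[which(b$voxels == 1L)[1]] <- 0L
  expect_lt(dice(a, b), 1)
  expect_equal(dice(a, a), 1)
})

test_that("evaluate bundles the metrics and flags degenerate masks", {
  ref <- rand_mask(c(8, 8, 8), p = 0.3, seed = 7)
  r <- evaluate(ref, ref, organ = "o", image_id = "i", source_id = "s")
  expect_equal(r$dsc, 1)
  expect_equal(r$rvd, 0)
  expect_equal(r$assd_mm, 0)
  expect_equal(r$mssd_mm, 0)
  expect_true(r$surface_defined)

  pred <- rand_mask(c(8, 8, 8), p = 0.3, seed = 8)
  r2 <- evaluate(pred, ref)
  expect_equal(r2$dsc, dice(pred, ref))
  expect_equal(r2$rvd, rvd(pred, ref))
  expect_equal(r2$assd_mm, assd(pred, ref))
  expect_equal(r2$mssd_mm, mssd(pred, ref))

  empty <- binary_mask(array(0L, c(8, 8, 8)))
  r3 <- evaluate(empty, empty)
  expect_equal(r3$dsc, 1)
  expect_equal(r3$rvd, 0)
  expect_false(r3$surface_defined)

  r4 <- evaluate(empty, ref)  # catastrophic empty prediction stays rankable
  expect_equal(r4$dsc, 0)
  expect_equal(r4$rvd, 1)
  expect_equal(r4$mssd_mm, grid_diagonal(ref))
  expect_false(r4$surface_defined)

  r5 <- evaluate(ref, empty)
  expect_true(is.na(r5$rvd))
  expect_false(r5$surface_defined)
})

test_that("evaluate_against matches individual evaluation and fixes the CSV schema", {
  dir <- withr::local_tempdir()
  ref <- rand_mask(c(8, 8, 8), p = 0.3, seed = 11)
  preds <- list(a = rand_mask(c(8, 8, 8), p = 0.3, seed = 12),
                b = rand_mask(c(8, 8, 8), p = 0.25, seed = 13))
  tab <- evaluate_against(preds, ref, organ = "o", image_id = "img")
  expect_equal(tab$source_id, c("a", "b"))
  expect_equal(tab$assd_mm[2], assd(preds$b, ref))

  f <- write_metrics_csv(tab, file.path(dir, "m.csv"))
  back <- read.csv(f)
  expect_identical(names(back),
                   c("organ", "image_id", "source_id", "dsc", "rvd",
                     "assd_mm", "mssd_mm", "surface_defined"))
  expect_equal(back$mssd_mm, tab$mssd_mm)
})
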