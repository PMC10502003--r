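# Synthetic study generator: ground-truth phantoms plus ensembles of
# simulated model outputs with the statistical structure the analysis
# assumes -- mostly-accurate boundary-perturbed masks with rare,
# cross-model-independent catastrophic failures (distant spurious
# components, partial dropouts) -- and an iid per-voxel rater model with
# known sensitivity/specificity for consensus-recovery experiments.

# evaluate `code` under `seed` without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

# hierarchical seed derivation: any single mask can be regenerated in
# isolation from (master, image index, model index); model 0 = the phantom
derive_seed <- function(master, image = 0L, model = 0L) {
  as.integer((as.numeric(master) %% 100000) * 20011 + image * 211 + model) %% 2147483647L
}

#' Phantom specification
#'
#' @param shape grid dimensions (3 positive integers).
#' @param spacing voxel spacing in mm.
#' @param family `"ellipsoid"` (analytic, deterministic) or `"blob"`
#'   (thresholded smoothed noise, organic outline).
#' @param semi_axes ellipsoid semi-axes in voxels (all >= 1).
#' @param center ellipsoid/blob centre (default: grid midpoint).
#' @param blob_scale Gaussian smoothing scale (voxels) for the blob family.
#' @param volume_fraction target foreground fraction for the blob family,
#'   in (0, 0.5).
#' @param seed RNG seed (blob family only).
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = c(1, 1, 1),
                         family = c("ellipsoid", "blob"),
                         semi_axes = c(14, 11, 9), center = NULL,
                         blob_scale = 6, volume_fraction = 0.05, seed = 1L) {
  family <- match.arg(family)
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 4)) stop("shape must be 3 dimensions of at least 4 voxels", call. = FALSE)
  if (family == "ellipsoid" && (length(semi_axes) != 3 || any(semi_axes < 1))) {
    stop("ellipsoid semi-axes must be 3 values >= 1 voxel", call. = FALSE)
  }
  if (family == "blob" && (volume_fraction <= 0 || volume_fraction >= 0.5)) {
    stop("blob volume fraction must lie in (0, 0.5)", call. = FALSE)
  }
  structure(list(shape = shape, spacing = check_spacing(spacing), family = family,
                 semi_axes = as.numeric(semi_axes),
                 center = if (is.null(center)) (shape + 1) / 2 else as.numeric(center),
                 blob_scale = blob_scale, volume_fraction = volume_fraction,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a ground-truth phantom mask
#'
#' Ellipsoid phantoms are analytic (voxel centres inside the ellipsoid);
#' their voxel volume matches `(4/3) pi a b c` to within a few percent for
#' semi-axes of 8 voxels and up.  Blob phantoms threshold Gaussian-smoothed
#' white noise at the target volume fraction and keep the largest
#' 6-connected component, giving an organic, connected outline.
#'
#' @param spec a [phantom_spec()].
#' @return a [binary_mask()] with a connected foreground.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  if (spec$family == "ellipsoid") {
    cx <- spec$center
    ax <- spec$semi_axes
    u1 <- ((seq_len(d[1]) - cx[1]) / ax[1])^2
    u2 <- ((seq_len(d[2]) - cx[2]) / ax[2])^2
    u3 <- ((seq_len(d[3]) - cx[3]) / ax[3])^2
    vox <- outer(outer(u1, u2, `+`), u3, `+`) <= 1
    if (!any(vox)) stop("degenerate ellipsoid: no voxel centre falls inside", call. = FALSE)
    binary_mask(vox, spacing = spec$spacing, label = "phantom")
  } else {
    vox <- with_seed(spec$seed, {
      noise <- array(rnorm(prod(d)), d)
      sm <- gaussian_smooth3(noise, spec$blob_scale)
      thr <- quantile(sm, 1 - spec$volume_fraction, type = 7)
      sm >= thr
    })
    lab <- connected_components(vox)
    if (max(lab) == 0) stop("degenerate blob: empty after thresholding", call. = FALSE)
    keep <- which.max(tabulate(lab[lab > 0]))
    binary_mask(lab == keep, spacing = spec$spacing, label = "phantom")
  }
}

# periodic FFT Gaussian smoothing, separable kernel
gaussian_smooth3 <- function(x, sigma) {
  d <- dim(x)
  kern <- lapply(d, function(n) {
    i <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) # wrap-around offsets
    g <- exp(-i^2 / (2 * sigma^2))
    g / sum(g)
  })
  K <- outer(outer(stats::fft(kern[[1]]), stats::fft(kern[[2]])), stats::fft(kern[[3]]))
  Re(stats::fft(stats::fft(x) * K, inverse = TRUE)) / prod(d)
}

#' Simulated-model behaviour profile
#'
#' Parameters of the per-model error process applied to a ground-truth
#' phantom: small random affine jitter (emulating legitimate inter-model
#' disagreement), random boundary dilation/erosion, and two rare
#' catastrophic failure modes -- deletion of a connected chunk of the organ
#' and injection of a spatially distant spurious component.
#'
#' Defaults: rotation up to 5 degrees and scaling up to 5 percent per axis;
#' translation up to 2 voxels (translation ranges quoted for 192-voxel
#' crops scale down with the default 64-voxel grid and its smaller organ
#' radii); 0-2 dilate and 0-2 erode passes, each flipping 20-60 percent of
#' a boundary layer with a random structuring element; `p_spurious = 0.05`
#' and `p_dropout = 0.02` per model per image.
#'
#' @param max_rotation_deg max 3-D rotation per axis, degrees.
#' @param max_scale max per-axis scale deviation (0.05 = +-5 percent).
#' @param max_translation_vox max per-axis translation, voxels.
#' @param boundary_iter_max max dilate and max erode passes (each drawn
#'   uniformly from `0:boundary_iter_max`).
#' @param boundary_amplitude range of the fraction of the candidate
#'   boundary layer flipped per pass.
#' @param p_spurious probability of injecting a disconnected false-positive
#'   component.
#' @param spurious_size_range volume range of the spurious component,
#'   voxels.
#' @param spurious_min_dist_mm minimum distance of the spurious component
#'   from the truth, mm.
#' @param p_dropout probability of deleting a connected chunk of the organ.
#' @param dropout_fraction_range volume fraction range removed by a
#'   dropout.
#' @return list of class `model_profile`.
#' @export
model_profile <- function(max_rotation_deg = 5, max_scale = 0.05,
                          max_translation_vox = 2, boundary_iter_max = 2L,
                          boundary_amplitude = c(0.2, 0.6),
                          p_spurious = 0.05, spurious_size_range = c(64, 512),
                          spurious_min_dist_mm = 20, p_dropout = 0.02,
                          dropout_fraction_range = c(0.2, 0.5)) {
  stopifnot(max_rotation_deg >= 0, max_scale >= 0, max_translation_vox >= 0,
            boundary_iter_max >= 0,
            length(boundary_amplitude) == 2, all(boundary_amplitude >= 0),
            all(boundary_amplitude <= 1),
            p_spurious >= 0, p_spurious <= 1, p_dropout >= 0, p_dropout <= 1,
            length(spurious_size_range) == 2, length(dropout_fraction_range) == 2)
  structure(list(max_rotation_deg = max_rotation_deg, max_scale = max_scale,
                 max_translation_vox = max_translation_vox,
                 boundary_iter_max = as.integer(boundary_iter_max),
                 boundary_amplitude = as.numeric(boundary_amplitude),
                 p_spurious = p_spurious,
                 spurious_size_range = as.numeric(spurious_size_range),
                 spurious_min_dist_mm = spurious_min_dist_mm,
                 p_dropout = p_dropout,
                 dropout_fraction_range = as.numeric(dropout_fraction_range)),
            class = "model_profile")
}

rotation_matrix3 <- function(deg) {
  a <- deg * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
  Ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
  Rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# nearest-neighbour resample of a binary array under y = M (x - c) + c + t
affine_resample <- function(vox, M, trans, center) {
  d <- dim(vox)
  fg <- which(vox != 0, arr.ind = TRUE)
  if (nrow(fg) == 0) return(vox)
  # forward-transform the source bbox corners to bound the output region
  lo <- apply(fg, 2, min)
  hi <- apply(fg, 2, max)
  corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]), c(lo[3], hi[3])))
  fwd <- t(M %*% (t(corners) - center) + center + trans)
  blo <- pmax(1, floor(apply(fwd, 2, min)) - 1)
  bhi <- pmin(d, ceiling(apply(fwd, 2, max)) + 1)
  out <- array(0L, d)
  if (any(blo > bhi)) return(out)  # pushed entirely off-grid
  gx <- blo[1]:bhi[1]; gy <- blo[2]:bhi[2]; gz <- blo[3]:bhi[3]
  tgt <- as.matrix(expand.grid(gx, gy, gz))
  Minv <- solve(M)
  src <- round(t(Minv %*% (t(tgt) - center - trans) + center))
  ok <- src[, 1] >= 1 & src[, 1] <= d[1] &
        src[, 2] >= 1 & src[, 2] <= d[2] &
        src[, 3] >= 1 & src[, 3] <= d[3]
  vals <- integer(nrow(tgt))
  vals[ok] <- vox[src[ok, , drop = FALSE]]
  out[tgt] <- vals
  out
}

#' Simulate one model's segmentation of a phantom
#'
#' Pipeline (all draws from a generator seeded by `seed`, so failures are
#' independent across models): affine jitter of the truth about its
#' centroid, random boundary dilate/erode passes, then with probability
#' `p_dropout` removal of a connected chunk and with probability
#' `p_spurious` injection of a disconnected component at the configured
#' minimum distance from the truth.
#'
#' @param gt ground-truth [binary_mask()] (nonempty).
#' @param profile a [model_profile()].
#' @param seed integer seed for this (image, model) draw.
#' @param label label for the output mask.
#' @return a [binary_mask()].
#' @export
simulate_model_output <- function(gt, profile, seed, label = "model") {
  stopifnot(inherits(gt, "binary_mask"), inherits(profile, "model_profile"))
  if (sum(gt$voxels) == 0) stop("ground-truth mask is empty", call. = FALSE)
  with_seed(seed, {
    d <- dim(gt$voxels)
    fg <- which(gt$voxels != 0, arr.ind = TRUE)
    center <- colMeans(fg)

    rot <- runif(3, -profile$max_rotation_deg, profile$max_rotation_deg)
    scl <- runif(3, 1 - profile$max_scale, 1 + profile$max_scale)
    trn <- runif(3, -profile$max_translation_vox, profile$max_translation_vox)
    M <- rotation_matrix3(rot) %*% diag(scl)
    v <- affine_resample(gt$voxels, M, trn, center) != 0

    # boundary noise: random dilate/erode passes in random order with a
    # random structuring element (6- or 26-neighbourhood); each pass flips
    # only a random fraction of the candidate boundary layer, so the
    # perturbation stays boundary-scale even on small grids
    n_dil <- sample.int(profile$boundary_iter_max + 1L, 1L) - 1L
    n_ero <- sample.int(profile$boundary_iter_max + 1L, 1L) - 1L
    ops <- sample(c(rep("d", n_dil), rep("e", n_ero)))
    for (op in ops) {
      conn <- sample(c(6L, 26L), 1L)
      frac <- runif(1, profile$boundary_amplitude[1], profile$boundary_amplitude[2])
      v <- if (op == "d") noisy_dilate(v, conn, frac) else noisy_erode(v, conn, frac)
    }

    did_dropout <- runif(1) < profile$p_dropout && any(v)
    if (did_dropout) {
      v <- apply_dropout(v, gt$spacing, profile$dropout_fraction_range)
    }
    did_spurious <- runif(1) < profile$p_spurious
    if (did_spurious) {
      v <- add_spurious(v, gt, profile)
    }
    out <- binary_mask(v, spacing = gt$spacing, label = label)
    # record which failure modes fired so studies can audit failure rates
    attr(out, "failures") <- c(dropout = did_dropout, spurious = did_spurious)
    out
  })
}

# flip a random fraction of the dilation (erosion) candidate layer
noisy_dilate <- function(v, conn, frac) {
  cand <- which(dilate_mask(v, conn) & !v)
  if (length(cand) == 0 || frac <= 0) return(v)
  k <- round(frac * length(cand))
  if (k >= 1) v[cand[sample.int(length(cand), k)]] <- TRUE
  v
}

noisy_erode <- function(v, conn, frac) {
  cand <- which(v & !erode_mask(v, conn))
  if (length(cand) == 0 || frac <= 0) return(v)
  k <- round(frac * length(cand))
  if (k >= 1) v[cand[sample.int(length(cand), k)]] <- FALSE
  v
}

# remove the connected chunk of foreground nearest a random boundary seed
apply_dropout <- function(v, spacing, fraction_range) {
  b <- which(boundary_array(v), arr.ind = TRUE)
  if (nrow(b) == 0) return(v)
  seed_vox <- b[sample.int(nrow(b), 1L), ]
  fg <- which(v, arr.ind = TRUE)
  d2 <- ((fg[, 1] - seed_vox[1]) * spacing[1])^2 +
        ((fg[, 2] - seed_vox[2]) * spacing[2])^2 +
        ((fg[, 3] - seed_vox[3]) * spacing[3])^2
  frac <- runif(1, fraction_range[1], fraction_range[2])
  k <- max(1L, round(frac * nrow(fg)))
  drop_idx <- fg[order(d2)[seq_len(k)], , drop = FALSE]
  v[drop_idx] <- FALSE
  v
}

# inject an ellipsoidal false-positive component at >= min distance from gt
add_spurious <- function(v, gt, profile) {
  size <- runif(1, profile$spurious_size_range[1], profile$spurious_size_range[2])
  r_mm <- (3 * size * prod(gt$spacing) / (4 * pi))^(1 / 3)
  d <- dim(gt$voxels)
  edt <- distance_transform(gt$voxels, gt$spacing)
  r_vox <- ceiling(r_mm / gt$spacing)
  margin_ok <- array(FALSE, d)
  xs <- (r_vox[1] + 1):(d[1] - r_vox[1])
  ys <- (r_vox[2] + 1):(d[2] - r_vox[2])
  zs <- (r_vox[3] + 1):(d[3] - r_vox[3])
  if (length(xs) < 1 || length(ys) < 1 || length(zs) < 1 ||
      any(r_vox[1] + 1 > d[1] - r_vox[1], r_vox[2] + 1 > d[2] - r_vox[2],
          r_vox[3] + 1 > d[3] - r_vox[3])) {
    stop("spurious component placement impossible: component of radius ",
         round(r_mm, 1), " mm does not fit inside the grid", call. = FALSE)
  }
  margin_ok[xs, ys, zs] <- TRUE
  cand <- which(edt >= profile$spurious_min_dist_mm + r_mm & margin_ok)
  if (length(cand) == 0) {
    stop("spurious component placement impossible: no voxel at >= ",
         profile$spurious_min_dist_mm, " mm from the truth fits a ",
         round(r_mm, 1), " mm component inside the grid", call. = FALSE)
  }
  ctr_idx <- cand[sample.int(length(cand), 1L)]
  ctr <- arrayInd(ctr_idx, d)[1, ]
  ax <- r_mm / gt$spacing  # sphere in mm = ellipsoid in voxel units
  u1 <- ((seq_len(d[1]) - ctr[1]) / ax[1])^2
  u2 <- ((seq_len(d[2]) - ctr[2]) / ax[2])^2
  u3 <- ((seq_len(d[3]) - ctr[3]) / ax[3])^2
  blob <- outer(outer(u1, u2, `+`), u3, `+`) <= 1
  v | blob
}

#' Simulate an iid binary rater
#'
#' Generative model of consensus estimation: every true-foreground voxel is
#' kept with probability `sensitivity`, every true-background voxel turned
#' on with probability `1 - specificity`, independently per voxel given the
#' truth.
#'
#' @param gt ground-truth [binary_mask()].
#' @param sensitivity,specificity rater operating point, in \[0, 1\].
#' @param seed integer seed.
#' @param label label for the output mask.
#' @return a [binary_mask()].
#' @export
simulate_rater <- function(gt, sensitivity, specificity, seed, label = "rater") {
  stopifnot(inherits(gt, "binary_mask"),
            sensitivity >= 0, sensitivity <= 1, specificity >= 0, specificity <= 1)
  with_seed(seed, {
    u <- runif(length(gt$voxels))
    fg <- gt$voxels != 0
    out <- ifelse(fg, u <= sensitivity, u <= 1 - specificity)
    binary_mask(array(out, dim(gt$voxels)), spacing = gt$spacing, label = label)
  })
}

#' Study specification for the synthetic generator
#'
#' @param n_images number of images (>= 1).
#' @param n_models ensemble size J (>= 1).
#' @param phantom [phantom_spec()] template; per-image variation scales the
#'   semi-axes by `runif(3, 1 - size_jitter, 1 + size_jitter)` and shifts
#'   the centre by up to `center_jitter` voxels per axis.
#' @param profiles a single [model_profile()] applied to every model, or a
#'   list of `n_models` profiles.
#' @param size_jitter,center_jitter per-image phantom variation (see
#'   above).
#' @param organ organ tag used in manifests and metric records.
#' @param seed master seed; all per-(image, model) seeds derive from it
#'   deterministically.
#' @return list of class `study_spec`.
#' @export
study_spec <- function(n_images = 40L, n_models = 16L,
                       phantom = phantom_spec(), profiles = model_profile(),
                       size_jitter = 0.2, center_jitter = 3, organ = "phantom",
                       seed = 1L) {
  n_images <- as.integer(n_images)
  n_models <- as.integer(n_models)
  if (n_images < 1 || n_models < 1) stop("need n_images >= 1 and n_models >= 1", call. = FALSE)
  if (inherits(profiles, "model_profile")) profiles <- rep(list(profiles), n_models)
  if (length(profiles) != n_models) stop("need one profile, or one per model", call. = FALSE)
  structure(list(n_images = n_images, n_models = n_models, phantom = phantom,
                 profiles = profiles, size_jitter = size_jitter,
                 center_jitter = center_jitter, organ = organ,
                 seed = as.integer(seed)),
            class = "study_spec")
}

#' Simulate a full synthetic study in memory
#'
#' Generates `n_images` phantoms with per-image shape variation and J model
#' outputs per image.  Every artifact is a pure function of the spec
#' (including the master seed); any single mask can be regenerated in
#' isolation via the hierarchical per-(image, model) seeds.
#'
#' @param spec a [study_spec()].
#' @return an `ensemble_study` (see [load_study()]) with `spec` attached.
#' @export
simulate_study <- function(spec) {
  stopifnot(inherits(spec, "study_spec"))
  model_ids <- sprintf("m%02d", seq_len(spec$n_models))
  images <- lapply(seq_len(spec$n_images), function(i) {
    ps <- spec$phantom
    pseed <- derive_seed(spec$seed, i, 0L)
    var <- with_seed(pseed, list(
      size = runif(3, 1 - spec$size_jitter, 1 + spec$size_jitter),
      shift = round(runif(3, -spec$center_jitter, spec$center_jitter))
    ))
    ps$semi_axes <- pmax(1, ps$semi_axes * var$size)
    ps$center <- ps$center + var$shift
    ps$seed <- pseed
    ref <- make_phantom(ps)
    ref$label <- spec$organ
    models <- lapply(seq_len(spec$n_models), function(j) {
      simulate_model_output(ref, spec$profiles[[j]],
                            seed = derive_seed(spec$seed, i, j),
                            label = model_ids[j])
    })
    list(image_id = sprintf("img_%03d", i), organ = spec$organ, reference = ref,
         models = stats::setNames(models, model_ids))
  })
  structure(list(images = images, model_ids = model_ids,
                 spacing = spec$phantom$spacing, spec = spec, seed = spec$seed),
            class = "ensemble_study")
}

#' Write a study to disk as NIfTI volumes plus a JSON manifest
#'
#' @param study an `ensemble_study`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.  Also writes `study-metadata.json`
#'   recording the generator settings and master seed.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- lapply(study$images, function(img) {
    ref_path <- file.path(dir, paste0(img$image_id, "_ref.nii"))
    save_mask(img$reference, ref_path)
    model_paths <- stats::setNames(vapply(names(img$models), function(id) {
      p <- file.path(dir, paste0(img$image_id, "_", id, ".nii"))
      save_mask(img$models[[id]], p)
      basename(p)
    }, ""), names(img$models))
    list(image_id = img$image_id, organ = img$organ,
         reference = basename(ref_path), models = as.list(model_paths))
  })
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(study$spec)) {
    meta <- study$spec
    meta$profiles <- lapply(meta$profiles, unclass)
    meta$phantom <- unclass(meta$phantom)
    jsonlite::write_json(list(master_seed = study$seed, spec = unclass(meta)),
                         file.path(dir, "study-metadata.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(manifest_path)
}

#' The package's default synthetic study
#'
#' 40 images x 16 models on a 64-voxel cubic grid at 1 mm spacing, with the
#' default [model_profile()] (catastrophic-failure rates
#' `p_spurious = 0.05`, `p_dropout = 0.02`).
#'
#' @param seed master seed.
#' @param n_images,n_models optional overrides.
#' @return a [study_spec()].
#' @export
default_study_spec <- function(seed = 1L, n_images = 40L, n_models = 16L) {
  study_spec(n_images = n_images, n_models = n_models,
             phantom = phantom_spec(shape = c(64, 64, 64), spacing = c(1, 1, 1),
                                    family = "ellipsoid", semi_axes = c(14, 11, 9)),
             profiles = model_profile(), seed = seed)
}
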