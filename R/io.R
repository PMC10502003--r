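#' Load a segmentation mask from a NIfTI volume
#'
#' Reads a 3-D NIfTI file, binarises it at `binarize_threshold` and attaches
#' the voxel spacing from the header.  Volumes are treated as already
#' co-registered; the affine is recorded on the returned object (attribute
#' `affine`) but never used for computation — all physical distances are
#' driven by spacing alone.
#'
#' @param path path to a readable `.nii` / `.nii.gz` file.
#' @param binarize_threshold voxels with value `>= binarize_threshold`
#'   become foreground.  Default 0.5 (symmetric rounding of probabilistic
#'   or anti-aliased inputs).
#' @param label optional label; defaults to the file name.
#' @return a [binary_mask()].
#' @export
load_mask <- function(path, binarize_threshold = 0.5, label = NULL) {
  if (!file.exists(path)) stop("mask file does not exist: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  vox <- as.array(img)
  if (length(dim(vox)) == 4 && dim(vox)[4] == 1L) vox <- vox[, , , 1, drop = TRUE]
  if (length(dim(vox)) != 3) {
    stop("NIfTI volume must have 3 spatial dimensions; '", basename(path),
         "' has dimensionality ", length(dim(vox)), call. = FALSE)
  }
  if (any(!is.finite(vox))) stop("NIfTI volume contains non-finite voxel values: ", path, call. = FALSE)
  spacing <- RNifti::pixdim(img)[1:3]
  m <- binary_mask((vox >= binarize_threshold) * 1L, spacing = spacing,
                   label = if (is.null(label)) basename(path) else label)
  attr(m, "affine") <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  m
}

#' Load a probability map from a NIfTI volume
#'
#' @inheritParams load_mask
#' @return a [probability_map()].
#' @export
load_probability_map <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  vox <- as.array(img)
  if (length(dim(vox)) != 3) {
    stop("NIfTI volume must have 3 spatial dimensions; got ", length(dim(vox)), call. = FALSE)
  }
  probability_map(vox, spacing = RNifti::pixdim(img)[1:3], provenance = basename(path))
}

#' Save a mask or probability map as NIfTI
#'
#' Binary masks are written as `uint8`, probability maps as `double`, so a
#' reload reproduces voxels exactly and spacing to better than 1e-6 mm.
#'
#' @param mask a [binary_mask()] or [probability_map()].
#' @param path output path (`.nii` or `.nii.gz`); the parent directory is
#'   created if needed.
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path) {
  stopifnot(inherits(mask, "seg_volume"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  datatype <- if (inherits(mask, "binary_mask")) "uint8" else "double"
  img <- RNifti::asNifti(mask$voxels)
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  if (!file.exists(path)) stop("could not write NIfTI file: ", path, call. = FALSE)
  invisible(path)
}

#' Load a study manifest
#'
#' A manifest ties images, model outputs and reference masks together.  Two
#' on-disk layouts are accepted:
#' \itemize{
#'   \item JSON: a list of image objects `{image_id, organ, reference,
#'     models: {model_id: path, ...}}` (model order preserved as written);
#'   \item CSV with columns `image_id, organ, role, path` where `role` is
#'     `reference` or `model:<id>`.
#' }
#' Paths are resolved relative to the manifest's directory.
#'
#' @param path manifest file (`.json` or `.csv`).
#' @param check_files if `TRUE` (default), every referenced file must exist.
#' @return object of class `study_manifest`: a list of image records, each
#'   with `image_id`, `organ`, `reference` (path) and `models` (named vector
#'   of paths in model order).
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("manifest does not exist: ", path, call. = FALSE)
  base <- dirname(normalizePath(path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    raw <- jsonlite::read_json(path)
    images <- lapply(raw, function(rec) {
      list(image_id = as.character(rec$image_id),
           organ = as.character(rec$organ %||% "organ"),
           reference = as.character(rec$reference %||% NA_character_),
           models = unlist(rec$models))
    })
  } else if (ext == "csv") {
    tab <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("image_id", "organ", "role", "path")
    if (!all(need %in% names(tab))) {
      stop("manifest CSV must have columns ", paste(need, collapse = ", "), call. = FALSE)
    }
    images <- lapply(split(tab, factor(tab$image_id, levels = unique(tab$image_id))),
                     function(rows) {
      is_ref <- rows$role == "reference"
      is_mod <- startsWith(rows$role, "model:")
      list(image_id = rows$image_id[1],
           organ = rows$organ[1],
           reference = if (any(is_ref)) rows$path[which(is_ref)[1]] else NA_character_,
           models = stats::setNames(rows$path[is_mod], sub("^model:", "", rows$role[is_mod])))
    })
    names(images) <- NULL
  } else {
    stop("unsupported manifest format '.", ext, "' (use .json or .csv)", call. = FALSE)
  }

  for (rec in images) {
    if (is.na(rec$reference) || !nzchar(rec$reference)) {
      stop("manifest image '", rec$image_id, "' has no reference mask entry", call. = FALSE)
    }
    if (length(rec$models) < 1) {
      stop("manifest image '", rec$image_id, "' lists no model masks", call. = FALSE)
    }
    if (anyDuplicated(names(rec$models))) {
      stop("manifest image '", rec$image_id, "' lists duplicated model ids", call. = FALSE)
    }
  }
  by_organ <- split(images, vapply(images, `[[`, "", "organ"))
  for (grp in by_organ) {
    ids <- lapply(grp, function(r) names(r$models))
    if (length(unique(ids)) > 1) {
      stop("inconsistent model sets across images of organ '", grp[[1]]$organ, "'", call. = FALSE)
    }
  }
  images <- lapply(images, function(rec) {
    rec$reference <- resolve_path(rec$reference, base)
    rec$models <- vapply(rec$models, resolve_path, "", base = base)
    rec
  })
  if (check_files) {
    for (rec in images) {
      missing <- !file.exists(c(rec$reference, rec$models))
      if (any(missing)) {
        stop("manifest image '", rec$image_id, "': missing files: ",
             paste(c(rec$reference, rec$models)[missing], collapse = ", "), call. = FALSE)
      }
    }
  }
  structure(images, class = "study_manifest")
}

resolve_path <- function(p, base) {
  if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.study_manifest <- function(x, ...) {
  cat(sprintf("<study_manifest> %d image(s), organs: %s\n", length(x),
              paste(unique(vapply(x, `[[`, "", "organ")), collapse = ", ")))
  invisible(x)
}

#' Load a full study (all masks) from a manifest
#'
#' @param manifest a path or a `study_manifest`.
#' @return an `ensemble_study`: list with `images` (each `image_id`, `organ`,
#'   `reference` mask, `models` named list of masks) and `model_ids`.
#' @seealso [simulate_study()] for the synthetic counterpart.
#' @export
load_study <- function(manifest) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  images <- lapply(manifest, function(rec) {
    ref <- load_mask(rec$reference, label = rec$organ)
    models <- lapply(rec$models, load_mask)
    for (m in models) check_same_geometry(ref, m, what = paste0("masks of image '", rec$image_id, "'"))
    list(image_id = rec$image_id, organ = rec$organ, reference = ref,
         models = stats::setNames(models, names(rec$models)))
  })
  structure(list(images = images,
                 model_ids = names(images[[1]]$models),
                 spacing = images[[1]]$reference$spacing),
            class = "ensemble_study")
}

#' @export
print.ensemble_study <- function(x, ...) {
  cat(sprintf("<ensemble_study> %d image(s) x %d model(s), grid %s\n",
              length(x$images), length(x$model_ids),
              paste(dim(x$images[[1]]$reference$voxels), collapse = "x")))
  invisible(x)
}
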