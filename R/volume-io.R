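#' CT volume container
#'
#' A 3D grid of Hounsfield-unit intensities with physical geometry: voxel
#' spacing in mm, the physical coordinate of the first voxel, and a 3x3
#' axis-direction matrix.
#'
#' @param data finite numeric 3D array (Hounsfield units).
#' @param spacing positive mm triple.
#' @param origin physical coordinate triple of voxel (1,1,1).
#' @param orientation 3x3 direction matrix (default identity).
#' @return An object of class `"ct_volume"`.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      orientation = diag(3)) {
  d <- dim(data)
  if (is.null(d) || length(d) != 3L) {
    stop("non-3D payload: CT volumes must have exactly 3 dimensions",
         call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("CT volume contains non-finite values", call. = FALSE)
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be a strictly positive mm triple", call. = FALSE)
  }
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), orientation = orientation),
            class = "ct_volume")
}

#' Label mask container
#'
#' An integer 3D grid aligned to a [ct_volume()]; every voxel must belong
#' to the allowed label vocabulary (binary \{0, 1\} by default, 1 = tumor).
#'
#' @param data integer-valued 3D array.
#' @param labels allowed integer labels.
#' @inheritParams ct_volume
#' @return An object of class `"label_mask"`.
#' @export
label_mask <- function(data, labels = c(0L, 1L), spacing = c(1, 1, 1),
                       origin = c(0, 0, 0), orientation = diag(3)) {
  d <- dim(data)
  if (is.null(d) || length(d) != 3L) {
    stop("non-3D payload: masks must have exactly 3 dimensions", call. = FALSE)
  }
  storage.mode(data) <- "integer"
  bad <- which(!(data %in% as.integer(labels)))
  if (length(bad)) {
    loc <- arrayInd(bad[1], d)
    stop(sprintf(
      "out-of-vocabulary label %d at voxel (%d, %d, %d)",
      data[bad[1]], loc[1], loc[2], loc[3]), call. = FALSE)
  }
  structure(list(data = data, labels = as.integer(labels),
                 spacing = as.numeric(spacing), origin = as.numeric(origin),
                 orientation = orientation),
            class = "label_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing %s mm, HU range [%.1f, %.1f]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %s voxels, labels {%s}, foreground %d\n",
              paste(dim(x$data), collapse = "x"),
              paste(x$labels, collapse = ", "), sum(x$data != 0L)))
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

volume_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) "nifti"
  else if (grepl("\\.(mha|mhd)$", lp)) "metaimage"
  else stop(sprintf("unsupported format: '%s' (expected .nii, .nii.gz, .mha or .mhd)",
                    basename(path)), call. = FALSE)
}

#' Read a CT volume
#'
#' Reads NIfTI (`.nii`, `.nii.gz`) or MetaImage (`.mha`, `.mhd`) files,
#' preserving voxel spacing and origin from the header.
#'
#' @param path path to an existing volume file.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("missing file: '%s'", path), call. = FALSE)
  }
  fmt <- volume_format(path)
  if (fmt == "nifti") {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L) {
      stop(sprintf("non-3D payload: '%s' has %d dimensions", basename(path),
                   length(d)), call. = FALSE)
    }
    sp <- RNifti::pixdim(img)[seq_len(3)]
    xf <- try(RNifti::xform(img), silent = TRUE)
    org <- if (inherits(xf, "try-error")) c(0, 0, 0) else xf[1:3, 4]
    ct_volume(array(as.numeric(img), d), spacing = sp, origin = org)
  } else {
    mi <- read_metaimage(path)
    if (length(dim(mi$data)) != 3L) {
      stop(sprintf("non-3D payload: '%s'", basename(path)), call. = FALSE)
    }
    ct_volume(mi$data, spacing = mi$spacing, origin = mi$origin,
              orientation = mi$orientation)
  }
}

#' Write a CT volume
#'
#' @param vol a [ct_volume()] (or [label_mask()], written as integers).
#' @param path destination ending in `.nii`, `.nii.gz`, `.mha` or `.mhd`.
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path))) {
    stop(sprintf("unwritable path: parent directory '%s' does not exist",
                 dirname(path)), call. = FALSE)
  }
  if (file.access(dirname(path), 2L) != 0L) {
    stop(sprintf("unwritable path: no write permission in '%s'",
                 dirname(path)), call. = FALSE)
  }
  fmt <- volume_format(path)
  is_mask <- inherits(vol, "label_mask")
  if (fmt == "nifti") {
    dat <- vol$data
    storage.mode(dat) <- if (is_mask) "integer" else "double"
    img <- RNifti::asNifti(dat)
    RNifti::pixdim(img) <- vol$spacing
    m <- rbind(cbind(vol$orientation %*% diag(vol$spacing), vol$origin),
               c(0, 0, 0, 1))
    img <- RNifti::`sform<-`(img, structure(m, code = 2L))
    RNifti::writeNifti(img, path,
                       datatype = if (is_mask) "int16" else "double")
  } else {
    write_metaimage(vol$data, path, spacing = vol$spacing, origin = vol$origin,
                    orientation = vol$orientation,
                    element_type = if (is_mask) "MET_SHORT" else "MET_DOUBLE")
  }
  invisible(path)
}

#' Read a label mask
#'
#' Reads a mask volume and validates its voxel values (after integer cast)
#' against the allowed label vocabulary; the first offending voxel is
#' reported with its index.
#'
#' @param path path to a mask volume.
#' @param labels allowed integer labels (default binary \{0, 1\}).
#' @return A [label_mask()].
#' @export
read_mask <- function(path, labels = c(0L, 1L)) {
  v <- read_volume(path)
  label_mask(array(as.integer(round(v$data)), dim(v$data)), labels = labels,
             spacing = v$spacing, origin = v$origin,
             orientation = v$orientation)
}

# ---- dataset manifest ------------------------------------------------------

manifest_columns <- c("patient_id", "split", "image_path", "mask_path",
                      "has_tumor", "tumor_slices", "nontumor_slices")

#' Dataset manifest
#'
#' A data frame describing one case per row: patient id, split assignment
#' (`train` / `validation` / `test`), image and mask paths, tumor flag and
#' per-case slice tallies. A patient may appear in only one split.
#'
#' @param records data frame with the columns `patient_id`, `split`,
#'   `image_path`, `mask_path`, `has_tumor`, `tumor_slices`,
#'   `nontumor_slices`.
#' @return The validated data frame with class `"seg_manifest"` prepended.
#' @export
manifest <- function(records) {
  miss <- setdiff(manifest_columns, names(records))
  if (length(miss)) {
    stop(sprintf("manifest is missing columns: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  ok <- records$split %in% c("train", "validation", "test")
  if (!all(ok)) {
    stop(sprintf("invalid split value '%s'", records$split[!ok][1]),
         call. = FALSE)
  }
  if (any(!nzchar(records$image_path)) || any(!nzchar(records$mask_path))) {
    stop("manifest paths must be non-empty", call. = FALSE)
  }
  leaks <- tapply(records$split, records$patient_id,
                  function(s) length(unique(s)))
  if (any(leaks > 1L)) {
    stop(sprintf("patient '%s' appears in more than one split",
                 names(leaks)[leaks > 1L][1]), call. = FALSE)
  }
  class(records) <- unique(c("seg_manifest", class(records)))
  records
}

#' @rdname manifest
#' @param path CSV path.
#' @export
read_manifest <- function(path) {
  manifest(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname manifest
#' @param m a manifest.
#' @export
write_manifest <- function(m, path) {
  utils::write.csv(as.data.frame(m)[manifest_columns], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-split and grand totals of a manifest
#'
#' Tallies patients, tumor slices, non-tumor slices and all slices per
#' split and overall, the way a dataset composition table is reported.
#'
#' @param m a [manifest()].
#' @param slice_counts optional two-column data frame / matrix of
#'   `(tumor_slices, nontumor_slices)` overriding the manifest columns.
#' @return Data frame with one row per split plus a `"total"` row and
#'   columns `split`, `patients`, `tumor_slices`, `nontumor_slices`,
#'   `all_slices`.
#' @export
manifest_totals <- function(m, slice_counts = NULL) {
  if (!is.null(slice_counts)) {
    m$tumor_slices <- slice_counts[, 1]
    m$nontumor_slices <- slice_counts[, 2]
  }
  if (any(m$tumor_slices < 0) || any(m$nontumor_slices < 0)) {
    stop("slice tallies must be non-negative", call. = FALSE)
  }
  splits <- c("train", "test", "validation")
  rows <- lapply(splits, function(s) {
    r <- m[m$split == s, , drop = FALSE]
    data.frame(split = s, patients = length(unique(r$patient_id)),
               tumor_slices = sum(r$tumor_slices),
               nontumor_slices = sum(r$nontumor_slices))
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(split = "total",
                               patients = sum(out$patients),
                               tumor_slices = sum(out$tumor_slices),
                               nontumor_slices = sum(out$nontumor_slices)))
  out$all_slices <- out$tumor_slices + out$nontumor_slices
  out
}

#' Assign patients to train/validation/test splits
#'
#' Splitting is by patient (never by slice, to avoid leakage). Split sizes
#' follow the fractions under largest-remainder rounding with ties broken
#' by the seeded shuffle order; the same seed always yields the same
#' assignment.
#'
#' @param m a [manifest()] (existing `split` values are overwritten).
#' @param fractions `(train, validation, test)` fractions, positive and
#'   summing to 1.
#' @param seed integer seed.
#' @return The manifest with `split` reassigned.
#' @export
split_dataset <- function(m, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(fractions) != 3L || any(fractions <= 0)) {
    stop("fractions must be three positive values", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  patients <- unique(m$patient_id)
  n <- length(patients)
  if (n < 3L) stop("fewer patients than splits", call. = FALSE)
  counts <- with_seed(seed, {
    shuffled <- sample(patients)
    quota <- fractions * n
    base <- floor(quota)
    left <- n - sum(base)
    if (left > 0) {
      tie <- sample(3L)  # seeded tie-break on equal remainders
      ord <- order(-(quota - base), tie)
      base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1L
    }
    list(shuffled = shuffled, sizes = base)
  })
  splits <- rep(c("train", "validation", "test"), counts$sizes)
  assign_map <- stats::setNames(splits, counts$shuffled)
  m$split <- unname(assign_map[as.character(m$patient_id)])
  manifest(m)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
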