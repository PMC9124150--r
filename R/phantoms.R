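#' Synthetic thorax phantom specification
#'
#' Parameters of the geometric thorax phantom: an air background, a body
#' ellipsoid of soft tissue, two lung ellipsoids, a tubular trachea
#' splitting into two bronchi, and spherical tumor nodules placed strictly
#' inside the lungs. Intensities are in Hounsfield units (air -1000, lung
#' about -800, soft tissue about 0-100); nodule diameters default to the
#' 5-32 mm range typical of lung-cancer screening.
#'
#' @param shape voxel triple (default 64^3).
#' @param spacing mm triple (default 1.5 mm isotropic, a desk-scale grid;
#'   use 128^3 at 1 mm to mirror a full-resolution pipeline).
#' @param body_hu,lung_hu,nodule_hu `(mean, sd)` pairs for per-voxel
#'   tissue texture.
#' @param airway_hu constant HU of air and airway lumen.
#' @param nodule_diameter_mm `(min, max)` diameter range in mm.
#' @param nodules_per_case `(min, max)` nodule count range; a draw of 0
#'   yields a tumor-free case.
#' @param lobulated when `TRUE`, each nodule is a union of 2-4 overlapping
#'   spheres (a crude lobulated margin) instead of a single sphere; the
#'   recorded diameter is the envelope's.
#' @param noise_sigma_hu sd of additive Gaussian acquisition noise.
#' @param seed default seed used when [generate_phantom()] is not given one.
#' @return A list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = c(1.5, 1.5, 1.5),
                         body_hu = c(40, 20), lung_hu = c(-800, 50),
                         airway_hu = -1000, nodule_hu = c(30, 15),
                         nodule_diameter_mm = c(5, 32),
                         nodules_per_case = c(1, 3), lobulated = FALSE,
                         noise_sigma_hu = 10, seed = 1L) {
  stopifnot(length(shape) == 3, all(shape >= 16), all(spacing > 0),
            body_hu[2] >= 0, lung_hu[2] >= 0, nodule_hu[2] >= 0,
            noise_sigma_hu >= 0, nodule_diameter_mm[1] > 0,
            nodule_diameter_mm[1] <= nodule_diameter_mm[2],
            nodule_diameter_mm[2] < min(shape * spacing),
            all(nodules_per_case >= 0))
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 body_hu = body_hu, lung_hu = lung_hu, airway_hu = airway_hu,
                 nodule_hu = nodule_hu,
                 nodule_diameter_mm = nodule_diameter_mm,
                 nodules_per_case = as.integer(nodules_per_case),
                 lobulated = isTRUE(lobulated),
                 noise_sigma_hu = noise_sigma_hu, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Physical voxel-center coordinate grids for a phantom grid.
coord_grids <- function(shape, spacing) {
  list(x = (seq_len(shape[1]) - 1) * spacing[1],
       y = (seq_len(shape[2]) - 1) * spacing[2],
       z = (seq_len(shape[3]) - 1) * spacing[3])
}

ellipsoid_mask <- function(shape, spacing, center, semi) {
  g <- coord_grids(shape, spacing)
  dx2 <- ((g$x - center[1]) / semi[1])^2
  dy2 <- ((g$y - center[2]) / semi[2])^2
  dz2 <- ((g$z - center[3]) / semi[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

# Cylinder along a straight segment from p0 to p1 with given radius (mm).
tube_mask <- function(shape, spacing, p0, p1, radius) {
  g <- coord_grids(shape, spacing)
  pts <- as.matrix(expand.grid(x = g$x, y = g$y, z = g$z))
  v <- p1 - p0
  len2 <- sum(v^2)
  w <- sweep(pts, 2, p0)
  t <- pmin(pmax((w %*% v) / len2, 0), 1)
  proj <- sweep(t %*% t(v), 2, p0, `+`)
  d2 <- rowSums((pts - proj)^2)
  array(d2 <= radius^2, shape)
}

#' Rasterize a sphere onto a voxel grid
#'
#' A voxel belongs to the sphere iff its center lies within `diameter/2`
#' of the sphere center; a sphere smaller than one voxel degenerates to
#' the single voxel containing its center. The sphere must lie fully
#' inside the grid.
#'
#' @param center physical mm triple.
#' @param diameter sphere diameter in mm.
#' @param shape,spacing grid geometry.
#' @return A [label_mask()] with the rasterized sphere as foreground.
#' @export
rasterize_sphere <- function(center, diameter, shape, spacing = c(1, 1, 1)) {
  r <- diameter / 2
  extent <- (shape - 1) * spacing
  if (any(center - r < -spacing / 2) || any(center + r > extent + spacing / 2)) {
    stop("sphere extends outside the grid", call. = FALSE)
  }
  g <- coord_grids(shape, spacing)
  d2 <- outer(outer((g$x - center[1])^2, (g$y - center[2])^2, `+`),
              (g$z - center[3])^2, `+`)
  m <- d2 <= r^2
  if (!any(m)) m[arrayInd(which.min(d2), shape)] <- TRUE
  label_mask(array(as.integer(m), shape), spacing = spacing)
}

#' Generate one thorax phantom case
#'
#' Builds the HU volume (air background, body ellipsoid, two lung
#' ellipsoids, trachea and bronchi, spherical nodules inside the lungs,
#' additive Gaussian noise) with its paired ground-truth nodule mask. The
#' same seed always yields a bit-identical case.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed (defaults to `spec$seed`).
#' @return A list of class `"phantom_case"`: `volume` ([ct_volume()]),
#'   `mask` ([label_mask()], 1 = nodule), and `metadata` (nodule centers
#'   mm, diameters mm, lung region, seed).
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = spec$seed) {
  with_seed(seed, {
    sh <- spec$shape; sp <- spec$spacing
    extent <- (sh - 1) * sp
    ctr <- extent / 2
    n <- prod(sh)
    vol <- array(spec$airway_hu, sh)
    body <- ellipsoid_mask(sh, sp, ctr, extent * c(0.42, 0.38, 0.46))
    vol[body] <- stats::rnorm(sum(body), spec$body_hu[1], spec$body_hu[2])
    lungs <- ellipsoid_mask(sh, sp, ctr + c(-extent[1] * 0.21, 0, 0),
                            extent * c(0.17, 0.24, 0.36)) |
             ellipsoid_mask(sh, sp, ctr + c(extent[1] * 0.21, 0, 0),
                            extent * c(0.17, 0.24, 0.36))
    lungs <- lungs & body
    vol[lungs] <- stats::rnorm(sum(lungs), spec$lung_hu[1], spec$lung_hu[2])
    # airway tree: vertical trachea to the carina, then one bronchus per lung
    carina <- c(ctr[1], ctr[2], ctr[3] + extent[3] * 0.1)
    airway <- tube_mask(sh, sp, c(ctr[1], ctr[2], extent[3] * 0.95), carina,
                        0.035 * extent[1]) |
              tube_mask(sh, sp, carina,
                        ctr + c(-extent[1] * 0.21, 0, -extent[3] * 0.1),
                        0.025 * extent[1]) |
              tube_mask(sh, sp, carina,
                        ctr + c(extent[1] * 0.21, 0, -extent[3] * 0.1),
                        0.025 * extent[1])
    vol[airway] <- spec$airway_hu
    lungs <- lungs & !airway
    # nodules
    n_nod <- if (spec$nodules_per_case[1] == spec$nodules_per_case[2]) {
      spec$nodules_per_case[1]
    } else {
      sample(spec$nodules_per_case[1]:spec$nodules_per_case[2], 1)
    }
    mask <- array(0L, sh)
    centers <- NULL; diams <- numeric(0)
    lung_idx <- which(lungs)
    g <- coord_grids(sh, sp)
    for (k in seq_len(n_nod)) {
      d <- stats::runif(1, spec$nodule_diameter_mm[1], spec$nodule_diameter_mm[2])
      placed <- FALSE
      while (!placed) {
        for (a in 1:20) {
          ci <- arrayInd(sample(lung_idx, 1), sh)
          cmm <- c(g$x[ci[1]], g$y[ci[2]], g$z[ci[3]])
          if (any(cmm - d / 2 < 0) || any(cmm + d / 2 > extent)) next
          sph <- if (spec$lobulated) {
            # union of overlapping lobes inside the envelope sphere
            n_lobe <- sample(2:4, 1)
            acc <- array(FALSE, sh)
            for (lb in seq_len(n_lobe)) {
              off <- stats::runif(3, -d / 6, d / 6)
              acc <- acc |
                (rasterize_sphere(cmm + off, d * 2 / 3, sh, sp)$data == 1L)
            }
            acc
          } else {
            rasterize_sphere(cmm, d, sh, sp)$data == 1L
          }
          if (all(lungs[sph])) {
            mask[sph] <- 1L
            vol[sph] <- stats::rnorm(sum(sph), spec$nodule_hu[1],
                                     spec$nodule_hu[2])
            centers <- rbind(centers, cmm)
            diams <- c(diams, d)
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          if (d <= spec$nodule_diameter_mm[1] + 1e-9) {
            stop("cannot place requested nodules: too large for the lung region",
                 call. = FALSE)
          }
          # keep the draw inside the stated range but try a smaller nodule
          d <- max(spec$nodule_diameter_mm[1], d * 0.8)
        }
      }
    }
    if (spec$noise_sigma_hu > 0) {
      vol <- vol + stats::rnorm(n, 0, spec$noise_sigma_hu)
    }
    structure(list(volume = ct_volume(vol, spacing = sp),
                   mask = label_mask(mask, spacing = sp),
                   metadata = list(centers = centers, diameters = diams,
                                   lung_region = lungs, seed = seed)),
              class = "phantom_case")
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s voxels, %d nodule(s), seed %d\n",
              paste(dim(x$volume$data), collapse = "x"),
              length(x$metadata$diameters), x$metadata$seed))
  invisible(x)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_cases` phantom volumes and masks (NIfTI) plus a CSV manifest
#' with patient-level train/validation/test splits. Case seeds derive
#' deterministically from `seed`, so regeneration reproduces the dataset
#' byte for byte.
#'
#' @param n_cases number of cases.
#' @param spec a [phantom_spec()].
#' @param seed integer master seed.
#' @param fractions split fractions passed to [split_dataset()].
#' @param dir output directory (created if needed).
#' @return The [manifest()] (also written to `dir/manifest.csv`),
#'   invisibly with attribute `dir`.
#' @export
generate_dataset <- function(n_cases, spec = phantom_spec(), seed = 1L,
                             fractions = c(0.8, 0.1, 0.1),
                             dir = tempfile("phantoms")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  recs <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    cs <- generate_phantom(spec, seed = (seed * 1000L + i) %% .Machine$integer.max)
    iv <- file.path(dir, sprintf("case%03d_image.nii.gz", i))
    im <- file.path(dir, sprintf("case%03d_mask.nii.gz", i))
    write_volume(cs$volume, iv)
    write_volume(cs$mask, im)
    z_any <- apply(cs$mask$data, 3, function(s) any(s != 0L))
    recs[[i]] <- data.frame(patient_id = sprintf("P%03d", i), split = "train",
                            image_path = iv, mask_path = im,
                            has_tumor = any(z_any),
                            tumor_slices = sum(z_any),
                            nontumor_slices = sum(!z_any))
  }
  m <- split_dataset(manifest(do.call(rbind, recs)), fractions, seed = seed)
  write_manifest(m, file.path(dir, "manifest.csv"))
  attr(m, "dir") <- dir
  invisible(m)
}
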