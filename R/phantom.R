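#' Specification of a synthetic spine phantom
#'
#' Describes a cranio-caudal stack of ellipsoidal "vertebral bodies" of bright
#' bone-like intensity on a darker soft-tissue background, with optional
#' field-of-view truncation and additive Gaussian intensity noise. The phantom
#' emulates the statistical structure the segmentation/identification method
#' assumes (bright disjoint bodies in anatomical order, Hounsfield-like
#' intensities, partial-FOV index shifts) without any claim to anatomical
#' realism.
#'
#' Vertebral bodies are axis-aligned ellipsoids with in-plane semi-axes
#' `body_radius_mm` and cranio-caudal semi-axis `0.8 * body_radius_mm`,
#' stacked along depth with `gap_mm` of background between adjacent bodies.
#' Body positions are deterministic given the spec, so a given anatomical
#' level always sits at the same depth; truncation removes extreme bodies
#' without moving the remainder.
#'
#' @param n_vertebrae number of vertebrae in the untruncated stack (2-25).
#' @param body_radius_mm in-plane semi-axis of each body, mm.
#' @param gap_mm background gap between adjacent bodies, mm.
#' @param grid_shape integer vector `(depth, height, width)` in voxels.
#' @param spacing_mm isotropic voxel size, mm.
#' @param bone_hu,background_hu mean intensities (Hounsfield-like).
#' @param noise_sd standard deviation of additive Gaussian intensity noise.
#' @param truncate_top,truncate_bottom number of vertebrae removed from the
#'   cranial / caudal end of the field of view.
#' @param first_level anatomical index of the most cranial vertebra before
#'   truncation (1 = C1 ... 24 = L5).
#' @param seed integer RNG seed for the noise field.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_vertebrae = 4, body_radius_mm = 3.5, gap_mm = 3,
                         grid_shape = c(48L, 24L, 24L), spacing_mm = 1.0,
                         bone_hu = 400, background_hu = -50, noise_sd = 25,
                         truncate_top = 0L, truncate_bottom = 0L,
                         first_level = 1L, seed = 1L) {
  spec <- list(n_vertebrae = as.integer(n_vertebrae),
               body_radius_mm = body_radius_mm, gap_mm = gap_mm,
               grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
               bone_hu = bone_hu, background_hu = background_hu,
               noise_sd = noise_sd, truncate_top = as.integer(truncate_top),
               truncate_bottom = as.integer(truncate_bottom),
               first_level = as.integer(first_level), seed = as.integer(seed))
  if (spec$n_vertebrae < 2 || spec$n_vertebrae > 25)
    stop("n_vertebrae must be in 2..25")
  if (spec$n_vertebrae - spec$truncate_top - spec$truncate_bottom < 1)
    stop("truncation removes every vertebra")
  if (spec$first_level < 1 || spec$first_level + spec$n_vertebrae - 1 > 24)
    stop("anatomical levels must stay within 1..24 (C1..L5)")
  if (spec$spacing_mm <= 0) stop("spacing_mm must be positive")
  if (spec$body_radius_mm <= 0 || spec$gap_mm < 0 || spec$noise_sd < 0)
    stop("body_radius_mm must be positive; gap_mm and noise_sd non-negative")
  class(spec) <- "phantom_spec"
  spec
}

# Analytic body centres in mm, for the full (untruncated) stack.
phantom_geometry <- function(spec) {
  a_d <- 0.8 * spec$body_radius_mm           # cranio-caudal semi-axis
  pitch <- 2 * a_d + spec$gap_mm
  top_margin <- spec$gap_mm
  centers_d <- top_margin + a_d + pitch * (seq_len(spec$n_vertebrae) - 1)
  list(a_d = a_d, a_hw = spec$body_radius_mm, pitch = pitch,
       centers_d = centers_d,
       center_h = (spec$grid_shape[2] * spec$spacing_mm) / 2,
       center_w = (spec$grid_shape[3] * spec$spacing_mm) / 2)
}

#' Generate a synthetic spine phantom
#'
#' Renders the phantom described by a [phantom_spec()]: an intensity volume in
#' Hounsfield-like units, an integer label map carrying anatomical indices
#' (0 = background), and the list of body centroids in 0-based voxel
#' coordinates. Deterministic for a fixed spec (including seed).
#'
#' @param spec a [phantom_spec()].
#' @return a list of class `phantom_sample` with elements `volume`
#'   (intensity [volume_grid()]), `labels` (label [volume_grid()]) and
#'   `centroids` (data.frame with columns `label`, `d`, `h`, `w`).
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  g <- phantom_geometry(spec)
  shp <- spec$grid_shape
  sp <- spec$spacing_mm
  extent_d <- g$centers_d[spec$n_vertebrae] + g$a_d + spec$gap_mm
  if (extent_d > shp[1] * sp)
    stop(sprintf("phantom stack (%.1f mm) does not fit grid depth (%.1f mm)",
                 extent_d, shp[1] * sp))
  if (g$a_hw + spec$gap_mm > min(shp[2], shp[3]) * sp / 2)
    stop("body radius does not fit the in-plane grid extent")

  keep <- seq_len(spec$n_vertebrae)
  if (spec$truncate_top > 0) keep <- keep[-seq_len(spec$truncate_top)]
  if (spec$truncate_bottom > 0)
    keep <- keep[seq_len(length(keep) - spec$truncate_bottom)]

  # voxel-centre coordinates in mm
  cd <- (seq_len(shp[1]) - 0.5) * sp
  ch <- (seq_len(shp[2]) - 0.5) * sp
  cw <- (seq_len(shp[3]) - 0.5) * sp

  labels <- array(0L, shp)
  cents <- NULL
  for (i in keep) {
    lvl <- spec$first_level + i - 1L
    dd2 <- ((cd - g$centers_d[i]) / g$a_d)^2
    hh2 <- ((ch - g$center_h) / g$a_hw)^2
    ww2 <- ((cw - g$center_w) / g$a_hw)^2
    inside <- outer(outer(dd2, hh2, "+"), ww2, "+") <= 1
    labels[inside] <- lvl
    cents <- rbind(cents, data.frame(
      label = lvl,
      d = g$centers_d[i] / sp - 0.5,
      h = g$center_h / sp - 0.5,
      w = g$center_w / sp - 0.5))
  }

  vol <- array(spec$background_hu, shp)
  vol[labels > 0L] <- spec$bone_hu
  if (spec$noise_sd > 0)
    vol <- vol + with_seed(spec$seed,
                           array(rnorm(prod(shp), 0, spec$noise_sd), shp))

  structure(list(volume = volume_grid(vol, sp, "intensity"),
                 labels = volume_grid(labels, sp, "label"),
                 centroids = cents, spec = spec),
            class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %d vertebrae (levels %s), grid %s\n",
              nrow(x$centroids),
              paste(range(x$centroids$label), collapse = "-"),
              paste(dim(x$volume$data), collapse = "x")))
  invisible(x)
}

#' Write a phantom sample to disk
#'
#' Writes the intensity volume and label map as NIfTI (`.nii.gz`) and the
#' centroid table as JSON (`[{"label": k, "voxel": [d, h, w]}, ...]`, 0-based
#' voxel coordinates). Labels round-trip losslessly through [read_volume()].
#'
#' @param sample a `phantom_sample` from [generate_phantom()].
#' @param directory output directory, created if missing.
#' @param stem file name stem.
#' @return invisibly, a named list of the three file paths.
#' @export
phantom_to_files <- function(sample, directory, stem = "phantom") {
  if (!inherits(sample, "phantom_sample")) stop("`sample` must be a phantom_sample")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  paths <- list(
    volume = file.path(directory, paste0(stem, "_ct.nii.gz")),
    labels = file.path(directory, paste0(stem, "_seg.nii.gz")),
    centroids = file.path(directory, paste0(stem, "_centroids.json")))
  write_volume(sample$volume, paths$volume)
  write_volume(sample$labels, paths$labels)
  write_centroids(sample$centroids, paths$centroids)
  invisible(paths)
}

#' Read a phantom sample written by [phantom_to_files()]
#' @param directory directory holding the files.
#' @param stem file name stem used when writing.
#' @return a list with `volume`, `labels`, `centroids`.
#' @export
phantom_from_files <- function(directory, stem = "phantom") {
  list(volume = read_volume(file.path(directory, paste0(stem, "_ct.nii.gz")),
                            kind = "intensity"),
       labels = read_volume(file.path(directory, paste0(stem, "_seg.nii.gz")),
                            kind = "label"),
       centroids = read_centroids(file.path(directory,
                                            paste0(stem, "_centroids.json"))))
}

#' Generate a batch of phantoms with varied geometry
#'
#' Convenience sampler used for training/evaluation experiments: draws
#' `n_cases` specs with `n_vertebrae` sampled uniformly from `n_range` and a
#' per-case noise/seed, all other fields from `base`.
#'
#' @param n_cases number of phantoms.
#' @param seed master seed; each case derives its own sub-seed.
#' @param n_range integer range of vertebra counts to sample from.
#' @param noise_sd noise level applied to every case.
#' @param ... further overrides passed to [phantom_spec()].
#' @return list of `phantom_sample`.
#' @export
sample_phantoms <- function(n_cases, seed = 1L, n_range = c(3L, 5L),
                            noise_sd = 25, ...) {
  with_seed(seed, {
    ns <- sample(seq(n_range[1], n_range[2]), n_cases, replace = TRUE)
  })
  lapply(seq_len(n_cases), function(i) {
    generate_phantom(phantom_spec(n_vertebrae = ns[i], noise_sd = noise_sd,
                                  seed = derive_seed(seed, i), ...))
  })
}
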