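#' Geometric augmentation record
#'
#' A weak (geometry-only) augmentation is fully determined by three axis
#' flips and one in-plane rotation angle. Flips are applied before the
#' rotation, a fixed composition order chosen for reproducibility. The
#' in-plane axes are `(height, width)`; depth is the cranio-caudal axis.
#'
#' @param flip_d,flip_h,flip_w logical axis flips.
#' @param rot_xy_deg rotation angle in degrees, within \[-22.5, 22.5\].
#' @return an object of class `geometry_record`.
#' @export
geometry_record <- function(flip_d = FALSE, flip_h = FALSE, flip_w = FALSE,
                            rot_xy_deg = 0) {
  if (abs(rot_xy_deg) > 22.5 + 1e-9)
    stop("rot_xy_deg must lie within [-22.5, 22.5]")
  structure(list(flip_d = isTRUE(flip_d), flip_h = isTRUE(flip_h),
                 flip_w = isTRUE(flip_w), rot_xy_deg = rot_xy_deg),
            class = "geometry_record")
}

#' Sample a weak (geometry-only) augmentation
#'
#' In-plane flips are drawn with probability 0.5 each, the cranio-caudal flip
#' with probability 0.25, and the in-plane rotation angle uniformly from
#' \[-22.5, +22.5\] degrees. Deterministic for a fixed seed.
#'
#' @param seed integer RNG seed.
#' @return a [geometry_record()].
#' @export
sample_weak_geometry <- function(seed) {
  with_seed(seed, {
    geometry_record(flip_d = runif(1) < 0.25,
                    flip_h = runif(1) < 0.5,
                    flip_w = runif(1) < 0.5,
                    rot_xy_deg = runif(1, -22.5, 22.5))
  })
}

#' Apply a geometric augmentation to a volume
#'
#' Flips are exact axis reversals; the in-plane rotation uses bilinear
#' interpolation per axial slice for intensity/probability volumes and
#' nearest-neighbour for label maps (so label values are never blended).
#' Voxels rotated in from outside the grid are filled with 0.
#'
#' @param vol a [volume_grid()].
#' @param g a [geometry_record()].
#' @return the transformed [volume_grid()].
#' @export
apply_geometry <- function(vol, g) {
  stopifnot_volume(vol)
  if (!inherits(g, "geometry_record")) stop("`g` must be a geometry_record")
  dat <- vol$data
  if (g$flip_d) dat <- dat[rev(seq_len(dim(dat)[1])), , , drop = FALSE]
  if (g$flip_h) dat <- dat[, rev(seq_len(dim(dat)[2])), , drop = FALSE]
  if (g$flip_w) dat <- dat[, , rev(seq_len(dim(dat)[3])), drop = FALSE]
  if (abs(g$rot_xy_deg) > 1e-12) {
    linear <- vol$kind != "label"
    dat <- .cpp_rotate_inplane(array(as.double(dat), dim(dat)),
                               g$rot_xy_deg, linear, 0)
    if (vol$kind == "label") storage.mode(dat) <- "integer"
  } else if (vol$kind == "label") {
    storage.mode(dat) <- "integer"
  }
  if (vol$kind == "probability") dat <- pmin(pmax(dat, 0), 1)
  volume_grid(dat, vol$spacing_mm, vol$kind)
}

#' Strong photometric augmentation policy
#'
#' A RandAugment-style policy over intensity-only operations: per call,
#' `n_ops` operations are drawn from the pool (without replacement) with
#' magnitudes sampled uniformly from the per-op ranges. Every operation
#' leaves voxel positions untouched; none may be applied to label maps.
#'
#' @param op_pool character vector of operation names; see Details.
#' @param n_ops_choices integer vector; the number of ops per call is drawn
#'   uniformly from it.
#' @param magnitude_ranges named list of `c(lo, hi)` magnitude intervals,
#'   merged over the defaults.
#' @param seed integer RNG seed.
#' @details Available operations: `scale` (multiplicative, \[0.9, 1.1\]),
#'   `shift` (additive, \[-0.1, 0.1\]), `gamma` (\[0.7, 1.5\]),
#'   `gauss_noise` (additive sd \[0.01, 0.1\]), `salt_pepper` (density
#'   \[0.001, 0.01\]), `poisson` (shot noise at scaled counts), `speckle`
#'   (multiplicative Gaussian, sd \[0.05, 0.2\]), `blur` (Gaussian sd
#'   \[0.5, 1.5\] voxels), `median` (3x3x3), `unsharp` (amount \[0.5, 1.5\]),
#'   `clahe` (slice-wise contrast-limited histogram equalization, clip limit
#'   \[1, 3\]). Inputs are assumed normalized to \[0, 1\]; outputs are
#'   clamped back to \[0, 1\].
#' @return an object of class `strong_policy`.
#' @export
strong_policy <- function(op_pool = c("scale", "shift", "gamma", "gauss_noise",
                                      "salt_pepper", "poisson", "speckle",
                                      "blur", "median", "unsharp", "clahe"),
                          n_ops_choices = 1:3,
                          magnitude_ranges = list(), seed = 1L) {
  defaults <- list(scale = c(0.9, 1.1), shift = c(-0.1, 0.1),
                   gamma = c(0.7, 1.5), gauss_noise = c(0.01, 0.1),
                   salt_pepper = c(0.001, 0.01), poisson = c(100, 400),
                   speckle = c(0.05, 0.2), blur = c(0.5, 1.5),
                   median = c(1, 1), unsharp = c(0.5, 1.5),
                   clahe = c(1, 3))
  unknown <- setdiff(op_pool, names(defaults))
  if (length(unknown)) stop("unknown ops: ", paste(unknown, collapse = ", "))
  structure(list(op_pool = op_pool, n_ops_choices = as.integer(n_ops_choices),
                 magnitude_ranges = modifyList(defaults, magnitude_ranges),
                 seed = as.integer(seed)),
            class = "strong_policy")
}

apply_photometric_op <- function(x, op, m) {
  n <- length(x)
  out <- switch(op,
    scale = x * m,
    shift = x + m,
    gamma = pmin(pmax(x, 0), 1)^m,
    gauss_noise = x + rnorm(n, 0, m),
    salt_pepper = {
      y <- x
      idx <- which(runif(n) < m)
      if (length(idx)) y[idx] <- rbinom(length(idx), 1, 0.5)
      y
    },
    poisson = rpois(n, pmin(pmax(x, 0), 1) * m) / m,
    speckle = x * (1 + rnorm(n, 0, m)),
    blur = .cpp_gaussian_blur3(x, m),
    median = .cpp_median3(x),
    unsharp = x + m * (x - .cpp_gaussian_blur3(x, 1.0)),
    clahe = {
      y <- x
      # tile grid scaled to the slice so tiles stay >= 8 px; slices too
      # small to tile are left untouched
      nt <- max(2L, min(8L, min(dim(x)[2:3]) %/% 8L))
      if (min(dim(x)[2:3]) >= 16L) {
        for (d in seq_len(dim(x)[1])) {
          sl <- x[d, , ]
          eq <- tryCatch(EBImage::clahe(sl, nx = nt, limit = m,
                                        keep.range = TRUE),
                         error = function(e) sl)
          y[d, , ] <- as.numeric(eq)
        }
      }
      y
    },
    stop("unknown op: ", op))
  array(pmin(pmax(out, 0), 1), dim(x))
}

#' Apply a strong photometric augmentation
#'
#' Applies the sampled intensity/noise operations of a [strong_policy()] to a
#' normalized intensity volume. Voxel positions are never moved, so any
#' paired label map remains valid unchanged; calling this on a label map is
#' a contract violation and errors.
#'
#' @param vol an intensity or probability [volume_grid()] with values in
#'   \[0, 1\].
#' @param policy a [strong_policy()].
#' @return the augmented [volume_grid()] (same kind, shape and spacing).
#' @export
strong_photometric <- function(vol, policy) {
  stopifnot_volume(vol)
  if (vol$kind == "label")
    stop("photometric operations apply only to image intensities, never labels")
  if (!inherits(policy, "strong_policy")) stop("`policy` must be a strong_policy")
  dat <- array(as.double(vol$data), dim(vol$data))
  dat <- with_seed(policy$seed, {
    n_ops <- if (length(policy$n_ops_choices) == 1L) policy$n_ops_choices else
      sample(policy$n_ops_choices, 1L)
    n_ops <- min(n_ops, length(policy$op_pool))
    if (n_ops > 0L && length(policy$op_pool) > 0L) {
      ops <- if (length(policy$op_pool) == 1L) rep(policy$op_pool, n_ops) else
        sample(policy$op_pool, n_ops)
      for (op in ops) {
        rng <- policy$magnitude_ranges[[op]]
        m <- runif(1, rng[1], rng[2])
        dat <- apply_photometric_op(dat, op, m)
      }
    }
    dat
  })
  volume_grid(pmin(pmax(dat, 0), 1), vol$spacing_mm, vol$kind)
}

#' Build synchronized weak/strong views of an unlabeled volume
#'
#' The teacher consumes the weak (geometry-only) view; the student consumes
#' the strong view, which inherits the *same* geometry and differs only
#' photometrically. Teacher pseudo-labels therefore align voxel-wise with the
#' student input by construction.
#'
#' @param vol a normalized intensity/probability [volume_grid()].
#' @param seed integer seed controlling both the geometry and the policy.
#' @param policy optional [strong_policy()]; by default one is derived from
#'   `seed`.
#' @return list with `weak`, `strong` ([volume_grid()]s), `geometry`
#'   ([geometry_record()]) and `policy`.
#' @export
build_unlabeled_views <- function(vol, seed, policy = NULL) {
  g <- sample_weak_geometry(seed)
  if (is.null(policy)) policy <- strong_policy(seed = derive_seed(seed, 7919L))
  weak <- apply_geometry(vol, g)
  strong <- strong_photometric(weak, policy)
  list(weak = weak, strong = strong, geometry = g, policy = policy)
}

#' Geometry-consistent augmentation of a labeled pair
#'
#' One geometry record is sampled and applied identically to volume and label
#' map (bilinear vs. nearest-neighbour interpolation). Photometrically, with
#' probability 0.5 the full strong pipeline is applied to the volume;
#' otherwise, with probability 0.5, a mild global intensity scaling drawn
#' from \[0.95, 1.05\] is applied. Labels are never photometrically modified.
#'
#' @param vol normalized intensity/probability [volume_grid()].
#' @param labels aligned label [volume_grid()].
#' @param seed integer RNG seed.
#' @return list with `volume`, `labels`, `geometry`, `branch` (one of
#'   `"strong"`, `"mild"`, `"none"`).
#' @export
augment_labeled <- function(vol, labels, seed) {
  stopifnot_volume(labels, "label")
  if (!all(dim(vol$data) == dim(labels$data)))
    stop("volume and labels must share a grid")
  g <- sample_weak_geometry(seed)
  vol_g <- apply_geometry(vol, g)
  lab_g <- apply_geometry(labels, g)
  draws <- with_seed(derive_seed(seed, 13L), runif(2))
  if (draws[1] < 0.5) {
    branch <- "strong"
    vol_g <- strong_photometric(vol_g,
                                strong_policy(seed = derive_seed(seed, 17L)))
  } else if (draws[2] < 0.5) {
    branch <- "mild"
    f <- with_seed(derive_seed(seed, 19L), runif(1, 0.95, 1.05))
    vol_g <- volume_grid(pmin(pmax(vol_g$data * f, 0), 1),
                         vol_g$spacing_mm, vol_g$kind)
  } else {
    branch <- "none"
  }
  list(volume = vol_g, labels = lab_g, geometry = g, branch = branch)
}
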