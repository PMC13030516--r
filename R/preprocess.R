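#' Resample a volume to isotropic spacing
#'
#' Rescales the grid so every axis has voxel size `target_mm`. Intensity and
#' probability volumes use trilinear interpolation; label maps use
#' nearest-neighbour so no new label values are invented. The output shape is
#' `round(dim * spacing / target)` per axis.
#'
#' @param vol a [volume_grid()].
#' @param target_mm positive target voxel size in mm.
#' @return a resampled [volume_grid()].
#' @export
resample_isotropic <- function(vol, target_mm = 1.0) {
  stopifnot_volume(vol)
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    stop("`target_mm` must be a single positive number")
  in_shape <- dim(vol$data)
  out_shape <- as.integer(pmax(1L, round(in_shape * vol$spacing_mm / target_mm)))
  if (all(out_shape == in_shape) && all(abs(vol$spacing_mm - target_mm) < 1e-12))
    return(vol)
  trilinear <- vol$kind != "label"
  dat <- .cpp_resize3d(array(as.double(vol$data), in_shape), out_shape, trilinear)
  if (vol$kind == "label") storage.mode(dat) <- "integer"
  volume_grid(dat, target_mm, vol$kind)
}

#' Clip and normalize CT intensities
#'
#' Clips Hounsfield-unit intensities to `[lo, hi]` and linearly maps them to
#' `[0, 1]`: `(clip(x, lo, hi) - lo) / (hi - lo)`. The defaults are the bone
#' window used throughout the pipeline.
#'
#' @param vol an intensity [volume_grid()].
#' @param lo,hi clipping bounds in HU, `hi > lo`.
#' @return a probability-kind [volume_grid()] with values in \[0, 1\].
#' @export
clip_normalize_hu <- function(vol, lo = -500, hi = 1500) {
  stopifnot_volume(vol, "intensity")
  if (hi <= lo) stop("`hi` must exceed `lo`")
  out <- (pmin(pmax(vol$data, lo), hi) - lo) / (hi - lo)
  volume_grid(array(out, dim(vol$data)), vol$spacing_mm, "probability")
}

#' Plan patch positions over a volume
#'
#' Produces the fixed-size patch corner positions used for training (random
#' crops) and inference (sliding window). Corners are 0-based and may be
#' negative or extend past the volume: [extract_patch()] zero-pads outside
#' voxels, which realizes the symmetric depth padding used when a volume is
#' shallower than the patch.
#'
#' In sliding mode the per-axis corners form a regular grid with stride
#' `round(patch * (1 - overlap_fraction))`, with the last window clamped to
#' the boundary so every voxel is covered. Axes not larger than the patch get
#' a single centred corner.
#'
#' @param vol a [volume_grid()] (only its shape is used).
#' @param mode `"sliding"` or `"random"`.
#' @param patch_shape integer patch size `(depth, height, width)`.
#' @param overlap_fraction sliding-window overlap in `[0, 1)`.
#' @param n_random number of random corners (random mode).
#' @param seed RNG seed for random mode.
#' @return an object of class `patch_plan`: list with `patch_shape`,
#'   `positions` (n x 3 matrix of 0-based corners), `mode`, `vol_shape`.
#' @export
plan_patches <- function(vol, mode = c("sliding", "random"),
                         patch_shape = c(128L, 64L, 64L),
                         overlap_fraction = 0.5, n_random = 1L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot_volume(vol)
  patch_shape <- as.integer(patch_shape)
  if (any(patch_shape <= 0)) stop("patch_shape must be positive")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  vs <- dim(vol$data)

  axis_corners <- function(n, p) {
    if (n <= p) return(-((p - n) %/% 2L))  # symmetric padding, single window
    stride <- max(1L, as.integer(round(p * (1 - overlap_fraction))))
    cs <- seq.int(0L, n - p, by = stride)
    if (cs[length(cs)] != n - p) cs <- c(cs, n - p)
    cs
  }

  if (mode == "sliding") {
    cd <- axis_corners(vs[1], patch_shape[1])
    ch <- axis_corners(vs[2], patch_shape[2])
    cw <- axis_corners(vs[3], patch_shape[3])
    pos <- as.matrix(expand.grid(d = cd, h = ch, w = cw))
  } else {
    pos <- with_seed(seed, {
      draw <- function(n, p) {
        if (n <= p) rep(-((p - n) %/% 2L), n_random)
        else sample.int(n - p + 1L, n_random, replace = TRUE) - 1L
      }
      cbind(d = draw(vs[1], patch_shape[1]),
            h = draw(vs[2], patch_shape[2]),
            w = draw(vs[3], patch_shape[3]))
    })
  }
  structure(list(patch_shape = patch_shape, positions = pos, mode = mode,
                 overlap_fraction = overlap_fraction, vol_shape = vs),
            class = "patch_plan")
}

#' Extract a fixed-size patch
#'
#' Copies the `patch_shape` window starting at 0-based `corner`; voxels
#' outside the volume are filled with `pad_value` (0 for normalized images
#' and label maps alike).
#'
#' @param vol a [volume_grid()].
#' @param corner integer 0-based corner `(d, h, w)`, possibly negative.
#' @param patch_shape integer patch size.
#' @param pad_value fill value outside the volume.
#' @return a [volume_grid()] of exactly `patch_shape`.
#' @export
extract_patch <- function(vol, corner, patch_shape, pad_value = 0) {
  stopifnot_volume(vol)
  corner <- as.integer(corner)
  patch_shape <- as.integer(patch_shape)
  vs <- dim(vol$data)
  out <- array(pad_value, patch_shape)
  if (vol$kind == "label") storage.mode(out) <- "integer"
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    lo <- max(0L, corner[ax])
    hi <- min(vs[ax], corner[ax] + patch_shape[ax])
    if (lo >= hi) return(volume_grid(out, vol$spacing_mm, vol$kind))
    src[[ax]] <- (lo + 1L):hi
    dst[[ax]] <- (lo - corner[ax] + 1L):(hi - corner[ax])
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol$data[src[[1]], src[[2]], src[[3]]]
  volume_grid(out, vol$spacing_mm, vol$kind)
}

#' Stitch patches back into a volume
#'
#' Inverse of [extract_patch()] for probability fields produced by
#' sliding-window inference: overlapping voxels are averaged, so a constant
#' field is reproduced exactly and probabilities stay in \[0, 1\]. Voxels
#' covered by no patch (possible only for degenerate plans) are 0.
#'
#' @param patches list of probability [volume_grid()] patches (or plain
#'   arrays), in the order of `plan$positions`.
#' @param plan the [plan_patches()] result used for extraction.
#' @param out_shape shape of the reassembled volume; defaults to the planned
#'   volume shape.
#' @param spacing_mm spacing of the output.
#' @return a probability [volume_grid()].
#' @export
stitch_patches <- function(patches, plan, out_shape = plan$vol_shape,
                           spacing_mm = 1.0) {
  if (length(patches) != nrow(plan$positions))
    stop("number of patches does not match the plan")
  acc <- array(0, out_shape)
  cnt <- array(0, out_shape)
  ps <- plan$patch_shape
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    dat <- if (is_volume_grid(p)) p$data else p
    if (!all(dim(dat) == ps)) stop("patch ", i, " does not match patch_shape")
    corner <- plan$positions[i, ]
    src <- dst <- vector("list", 3)
    ok <- TRUE
    for (ax in 1:3) {
      lo <- max(0L, corner[ax])
      hi <- min(out_shape[ax], corner[ax] + ps[ax])
      if (lo >= hi) { ok <- FALSE; break }
      dst[[ax]] <- (lo + 1L):hi
      src[[ax]] <- (lo - corner[ax] + 1L):(hi - corner[ax])
    }
    if (!ok) next
    acc[dst[[1]], dst[[2]], dst[[3]]] <-
      acc[dst[[1]], dst[[2]], dst[[3]]] + dat[src[[1]], src[[2]], src[[3]]]
    cnt[dst[[1]], dst[[2]], dst[[3]]] <- cnt[dst[[1]], dst[[2]], dst[[3]]] + 1
  }
  out <- acc / pmax(cnt, 1)
  volume_grid(pmin(pmax(out, 0), 1), spacing_mm, "probability")
}
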