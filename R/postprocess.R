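#' Threshold a probability volume
#'
#' Foreground is `p > thr` (strict: a voxel exactly at the threshold is
#' background).
#'
#' @param prob probability [volume_grid()] or array.
#' @param thr threshold, default 0.5.
#' @return integer binary array.
#' @export
binarize <- function(prob, thr = 0.5) {
  p <- if (is_volume_grid(prob)) prob$data else prob
  out <- array(0L, dim(p))
  out[p > thr] <- 1L
  out
}

#' Extract candidate vertebra instances by connected components
#'
#' 26-connected component labeling of a binary mask, removal of components
#' smaller than `min_fragment` voxels, and cranio-caudal sorting by centroid
#' depth.
#'
#' @param mask binary integer array.
#' @param min_fragment minimum component size in voxels.
#' @return an object of class `instance_set`: list with `n`, `shape`, `map`
#'   (integer array, values 1..n in sorted order) and `table` (data.frame
#'   with `instance`, `size`, `d`, `h`, `w`, `confidence`, `raw_id`, `id`).
#' @export
extract_instances <- function(mask, min_fragment = 200L) {
  m <- mask
  storage.mode(m) <- "integer"
  lab <- .cpp_label_components26(m)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_fragment)
  tab <- NULL
  map <- array(0L, dim(mask))
  if (length(keep) > 0L) {
    cents <- lapply(keep, function(k) {
      idx <- which(lab == k)
      colMeans(arrayInd(idx, dim(mask)) - 1L)
    })
    cd <- vapply(cents, `[`, numeric(1), 1L)
    ord <- order(cd)
    for (j in seq_along(ord)) map[lab == keep[ord[j]]] <- j
    tab <- data.frame(instance = seq_along(ord),
                      size = sizes[keep][ord],
                      d = vapply(cents[ord], `[`, numeric(1), 1L),
                      h = vapply(cents[ord], `[`, numeric(1), 2L),
                      w = vapply(cents[ord], `[`, numeric(1), 3L),
                      confidence = NA_real_, raw_id = NA_integer_,
                      id = NA_integer_)
  } else {
    tab <- data.frame(instance = integer(), size = integer(), d = numeric(),
                      h = numeric(), w = numeric(), confidence = numeric(),
                      raw_id = integer(), id = integer())
  }
  structure(list(n = nrow(tab), shape = dim(mask), map = map, table = tab),
            class = "instance_set")
}

#' Per-class spatial distributions from identification logits
#'
#' Per-channel spatial softmax: each class channel becomes a non-negative
#' map summing to 1, the predicted spatial distribution of that vertebra's
#' centroid.
#'
#' @param id_logits (D,H,W,K) logit array.
#' @return (D,H,W,K) array of per-channel distributions.
#' @export
id_logits_to_heatmaps <- function(id_logits) {
  d <- dim(id_logits)
  out <- array(0, d)
  for (k in seq_len(d[4])) {
    z <- id_logits[, , , k]
    z <- exp(z - max(z))
    out[, , , k] <- z / sum(z)
  }
  out
}

#' Per-class peak centroids from class heatmaps
#'
#' Upsamples the class-wise heatmaps to the segmentation resolution
#' (trilinear) when needed and takes each channel's maximum as the predicted
#' centroid. Classes whose peak falls below `floor_frac` of the per-volume
#' maximum peak are reported absent. Ties take the lowest linear index.
#'
#' @param heatmaps (D,H,W,K) non-negative array (e.g.
#'   [id_logits_to_heatmaps()] output), at 1/4 or full resolution.
#' @param out_shape target (segmentation) grid shape.
#' @param floor_frac relative peak floor for calling a class present.
#' @return data.frame with columns `label`, `d`, `h`, `w` (0-based voxel
#'   coordinates at `out_shape` resolution) and `confidence`.
#' @export
heatmap_centroids <- function(heatmaps, out_shape, floor_frac = 0.1) {
  K <- dim(heatmaps)[4]
  peaks <- data.frame(label = seq_len(K), d = NA_real_, h = NA_real_,
                      w = NA_real_, confidence = 0)
  for (k in seq_len(K)) {
    ch <- heatmaps[, , , k]
    if (!all(dim(ch) == out_shape))
      ch <- .cpp_resize3d(array(ch, dim(ch)), as.integer(out_shape), TRUE)
    i <- which.max(ch)  # lowest linear index on ties
    v <- ch[i]
    if (v > 0) {
      co <- arrayInd(i, out_shape) - 1L
      peaks[k, c("d", "h", "w")] <- co
      peaks$confidence[k] <- v
    }
  }
  top <- max(peaks$confidence)
  present <- peaks$confidence > floor_frac * top & peaks$confidence > 0
  peaks[present, , drop = FALSE]
}

#' Assign foreground voxels to the nearest centroid
#'
#' Every foreground voxel receives the class of its nearest predicted
#' centroid (Euclidean distance in voxel units); ties go to the more cranial
#' centroid. With zero centroids the foreground is left unassigned (id 0)
#' and a warning is raised.
#'
#' @param mask binary foreground array.
#' @param centroids data.frame with `label`, `d`, `h`, `w` (0-based).
#' @return integer array of per-voxel class ids (0 = background).
#' @export
assign_voxels <- function(mask, centroids) {
  out <- array(0L, dim(mask))
  idx <- which(mask > 0)
  if (length(idx) == 0L) return(out)
  if (is.null(centroids) || nrow(centroids) == 0L) {
    warning("no centroids: foreground left unassigned")
    return(out)
  }
  co <- arrayInd(idx, dim(mask)) - 1L
  # more cranial centroids first so strict comparison resolves ties
  cen <- centroids[order(centroids$d, centroids$h, centroids$w), ]
  best_d2 <- rep(Inf, length(idx))
  best_lab <- integer(length(idx))
  for (i in seq_len(nrow(cen))) {
    d2 <- (co[, 1] - cen$d[i])^2 + (co[, 2] - cen$h[i])^2 + (co[, 3] - cen$w[i])^2
    hit <- d2 < best_d2
    best_d2[hit] <- d2[hit]
    best_lab[hit] <- cen$label[i]
  }
  out[idx] <- best_lab
  out
}

#' Enforce cranio-caudal sequence continuity on instance ids
#'
#' Final anatomical ids must increase by exactly 1 down the cranio-caudally
#' sorted instances. The instance with the highest confidence keeps its raw
#' id (the anchor; ties go to the more cranial instance) and the others are
#' renumbered around it, which resolves duplicates by confidence-then-
#' spatial-order and fills gaps from superior to inferior. The run is
#' shifted if it would leave `1..K`; if there are more instances than
#' available labels the caudal extras are flagged unassigned.
#'
#' @param inst an `instance_set` whose table has `raw_id` and `confidence`
#'   filled in.
#' @param K number of anatomical labels (24 = C1..L5).
#' @return the `instance_set` with final `id` column filled (NA =
#'   unassigned overflow).
#' @export
enforce_sequence <- function(inst, K = 24L) {
  tab <- inst$table
  n <- nrow(tab)
  if (n == 0L) return(inst)
  conf <- ifelse(is.na(tab$confidence), -Inf, tab$confidence)
  anchor <- which.max(conf)  # ties: first = more cranial
  anchor_id <- tab$raw_id[anchor]
  if (is.na(anchor_id)) anchor_id <- anchor  # no information: start at C1
  ids <- anchor_id + (seq_len(n) - anchor)
  if (min(ids) < 1L) ids <- ids + (1L - min(ids))
  if (max(ids) > K) ids <- ids - (max(ids) - K)
  ids <- as.integer(ids)
  if (n > K) {
    overflow <- ids < 1L | ids > K | seq_len(n) > K
    ids[ids < 1L] <- NA_integer_
    ids[!is.na(ids) & ids > K] <- NA_integer_
    warning(sprintf("%d instances exceed the %d-label range: extras unassigned",
                    sum(is.na(ids)), K))
  }
  tab$id <- ids
  inst$table <- tab
  inst
}

#' Assemble a labeled instance map from raw network outputs
#'
#' The inference post-processing chain: threshold the segmentation
#' probability, extract 26-connected instances with fragment removal, find
#' per-class heatmap peak centroids, assign foreground voxels to the nearest
#' centroid, give each instance its majority-vote raw id and that id's peak
#' confidence, and enforce the sequence-continuity prior.
#'
#' @param seg_prob foreground probability (array or [volume_grid()]).
#' @param heatmaps per-class heatmaps (1/4 or full resolution).
#' @param thr foreground threshold.
#' @param min_fragment minimum instance size in voxels.
#' @param floor_frac heatmap peak floor (fraction of the volume maximum).
#' @param K number of anatomical labels.
#' @return list with `labels` (integer array of final anatomical ids),
#'   `instances` (the finalized `instance_set`) and `centroids` (data.frame
#'   of predicted instance centroids with final ids).
#' @export
assemble_prediction <- function(seg_prob, heatmaps, thr = 0.5,
                                min_fragment = 200L, floor_frac = 0.1,
                                K = 24L) {
  p <- if (is_volume_grid(seg_prob)) seg_prob$data else seg_prob
  mask <- binarize(p, thr)
  inst <- extract_instances(mask, min_fragment)
  peaks <- heatmap_centroids(heatmaps, dim(mask), floor_frac)
  if (inst$n > 0L) {
    idmap <- if (nrow(peaks) > 0L) assign_voxels(mask, peaks) else
      array(0L, dim(mask))
    for (j in seq_len(inst$n)) {
      vox <- inst$map == j
      ids <- idmap[vox]
      ids <- ids[ids > 0L]
      if (length(ids) > 0L) {
        raw <- as.integer(names(which.max(table(ids))))
        inst$table$raw_id[j] <- raw
        pk <- peaks$confidence[peaks$label == raw]
        inst$table$confidence[j] <- if (length(pk)) pk[1] else 0
      }
    }
    inst <- enforce_sequence(inst, K)
  }
  labels <- array(0L, dim(mask))
  if (inst$n > 0L) {
    for (j in seq_len(inst$n)) {
      if (!is.na(inst$table$id[j])) labels[inst$map == j] <- inst$table$id[j]
    }
  }
  cents <- inst$table[!is.na(inst$table$id),
                      c("id", "d", "h", "w", "confidence")]
  names(cents)[1] <- "label"
  list(labels = labels, instances = inst, centroids = cents)
}

#' Run inference on a preprocessed volume
#'
#' Sliding-window forward passes with probability stitching, followed by the
#' full post-processing chain of [assemble_prediction()]. Deterministic.
#'
#' @param volume normalized intensity/probability [volume_grid()].
#' @param model list with `config` ([network_config()]) and `params`, e.g. a
#'   loaded checkpoint or `fit()$best`.
#' @param patch_shape sliding patch size.
#' @param overlap_fraction sliding overlap.
#' @param ... further arguments passed to [assemble_prediction()].
#' @return as [assemble_prediction()], with `labels` wrapped in a
#'   [volume_grid()].
#' @export
infer_volume <- function(volume, model, patch_shape = c(128L, 64L, 64L),
                         overlap_fraction = 0.5, ...) {
  stopifnot_volume(volume)
  plan <- plan_patches(volume, "sliding", patch_shape, overlap_fraction)
  K <- model$config$n_classes
  seg_patches <- vector("list", nrow(plan$positions))
  hm_patches <- lapply(seq_len(K), function(k) vector("list", nrow(plan$positions)))
  for (i in seq_len(nrow(plan$positions))) {
    patch <- extract_patch(volume, plan$positions[i, ], patch_shape)
    out <- forward_full(patch, model$params, model$config)
    seg_patches[[i]] <- 1 / (1 + exp(-out$seg$full[, , , 1]))
    hm <- id_logits_to_heatmaps(out$id)
    for (k in seq_len(K)) {
      up <- .cpp_resize3d(array(hm[, , , k], dim(hm)[1:3]),
                          as.integer(patch_shape), TRUE)
      hm_patches[[k]][[i]] <- up
    }
  }
  seg_prob <- stitch_patches(seg_patches, plan, spacing_mm = volume$spacing_mm[1])
  vshape <- dim(volume$data)
  heat <- array(0, c(vshape, K))
  for (k in seq_len(K)) {
    st <- stitch_patches(hm_patches[[k]], plan, spacing_mm = volume$spacing_mm[1])
    heat[, , , k] <- st$data
  }
  res <- assemble_prediction(seg_prob, heat, K = K, ...)
  res$labels <- volume_grid(res$labels, volume$spacing_mm, "label")
  res$seg_prob <- seg_prob
  res
}
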