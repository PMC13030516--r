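#' Consistency-training schedule configuration
#'
#' Houses every ramp constant of the semi-supervised objective: the warm-up
#' end `E_cons` (consistency activation epoch), the ramp end `E_ramp`, the
#' pseudo-label confidence threshold ranges, the teacher softmax temperature,
#' and the EMA decay. Defaults follow the 100-epoch protocol: 40 supervised
#' warm-up epochs, a 40-epoch linear ramp, then 20 stable epochs.
#'
#' @param E_cons epoch at which consistency training starts.
#' @param E_ramp epoch at which every ramp reaches its endpoint.
#' @param tau_cls_range identification confidence threshold ramp `(lo, hi)`.
#' @param tau_seg_range segmentation confidence threshold ramp `(lo, hi)`.
#' @param temperature teacher softmax temperature T.
#' @param ema_alpha EMA teacher decay.
#' @param total_epochs total training epochs.
#' @return an object of class `schedule_config`.
#' @export
schedule_config <- function(E_cons = 40L, E_ramp = 80L,
                            tau_cls_range = c(0.30, 0.55),
                            tau_seg_range = c(0.50, 0.90),
                            temperature = 0.5, ema_alpha = 0.99,
                            total_epochs = 100L) {
  cfg <- list(E_cons = as.integer(E_cons), E_ramp = as.integer(E_ramp),
              tau_cls_range = tau_cls_range, tau_seg_range = tau_seg_range,
              temperature = temperature, ema_alpha = ema_alpha,
              total_epochs = as.integer(total_epochs))
  if (!(cfg$E_cons < cfg$E_ramp && cfg$E_ramp <= cfg$total_epochs))
    stop("need E_cons < E_ramp <= total_epochs")
  if (diff(tau_cls_range) < 0 || diff(tau_seg_range) < 0)
    stop("threshold ranges must be non-decreasing")
  if (temperature <= 0 || ema_alpha <= 0 || ema_alpha >= 1)
    stop("need temperature > 0 and 0 < ema_alpha < 1")
  class(cfg) <- "schedule_config"
  cfg
}

#' Rescale a schedule to a different epoch budget
#'
#' Preserves the 40:40:20 warm-up:ramp:stable proportion when training runs
#' for fewer (or more) than 100 epochs, e.g. for desk-scale experiments.
#'
#' @param cfg a [schedule_config()].
#' @param total_epochs new total epoch count.
#' @return a rescaled [schedule_config()].
#' @export
scale_schedule <- function(cfg, total_epochs) {
  r <- total_epochs / cfg$total_epochs
  schedule_config(E_cons = max(1L, round(cfg$E_cons * r)),
                  E_ramp = max(2L, round(cfg$E_ramp * r)),
                  tau_cls_range = cfg$tau_cls_range,
                  tau_seg_range = cfg$tau_seg_range,
                  temperature = cfg$temperature, ema_alpha = cfg$ema_alpha,
                  total_epochs = as.integer(total_epochs))
}

#' Consistency weight schedule
#'
#' Zero during warm-up, then a linear ramp from 0 to 1 over
#' `[E_cons, E_ramp]`, fixed at 1 thereafter.
#'
#' @param t epoch (>= 0).
#' @param cfg a [schedule_config()].
#' @return weight in `[0, 1]`, non-decreasing in `t`.
#' @export
lambda_schedule <- function(t, cfg) {
  ifelse(t < cfg$E_cons, 0,
         pmin(1, (t - cfg$E_cons) / (cfg$E_ramp - cfg$E_cons)))
}

ramp_between <- function(t, cfg, range_) {
  range_[1] + diff(range_) * pmin(1, pmax(0, (t - cfg$E_cons) /
                                            (cfg$E_ramp - cfg$E_cons)))
}

#' Pseudo-label confidence threshold schedules
#'
#' Both thresholds ramp linearly between their range endpoints over
#' `[E_cons, E_ramp]` and stay clamped at the top thereafter. The
#' identification threshold ramps over `tau_cls_range` (default 0.30 to
#' 0.55), the segmentation threshold over `tau_seg_range` (default 0.50 to
#' 0.90). Before `E_cons` consistency is inactive; the lower endpoint is
#' returned with a warning.
#'
#' @inheritParams lambda_schedule
#' @return the threshold at epoch `t`.
#' @export
tau_cls_schedule <- function(t, cfg) {
  if (any(t < cfg$E_cons))
    warning("tau_cls requested before E_cons; consistency is inactive there")
  ramp_between(t, cfg, cfg$tau_cls_range)
}

#' @rdname tau_cls_schedule
#' @export
tau_seg_schedule <- function(t, cfg) {
  if (any(t < cfg$E_cons))
    warning("tau_seg requested before E_cons; consistency is inactive there")
  ramp_between(t, cfg, cfg$tau_seg_range)
}

#' Loss weighting configuration
#'
#' @param alpha_cls weight of the identification term in the supervised loss.
#' @param alpha_seg Dice-vs-CE mixing weight inside the segmentation loss
#'   (0.5 = equal-weighted sum).
#' @param scale_weights deep-supervision weights over scales (full, 1/2,
#'   1/4); normalized to sum 1, larger at higher resolution.
#' @param epsilon Dice smoothing constant.
#' @param kl_inst_mix pair of non-negative weights for the heatmap-KL and
#'   instance-consistency identification terms.
#' @return an object of class `loss_config`.
#' @export
loss_config <- function(alpha_cls = 1.0, alpha_seg = 0.5,
                        scale_weights = c(4, 2, 1) / 7, epsilon = 1e-6,
                        kl_inst_mix = c(1, 1)) {
  if (alpha_cls < 0 || alpha_seg < 0 || alpha_seg > 1 || epsilon <= 0)
    stop("invalid loss weights")
  if (length(scale_weights) != 3L || any(scale_weights < 0))
    stop("scale_weights must be 3 non-negative values")
  structure(list(alpha_cls = alpha_cls, alpha_seg = alpha_seg,
                 scale_weights = scale_weights / sum(scale_weights),
                 epsilon = epsilon, kl_inst_mix = kl_inst_mix),
            class = "loss_config")
}

# ---------------------------------------------------------------------------
# Heatmap targets
# ---------------------------------------------------------------------------

#' Render Gaussian heatmap targets for vertebra centroids
#'
#' Each centroid is rendered as an isotropic 3D Gaussian with `sigma` voxels
#' on the (low-resolution) grid and normalized so the channel sums to exactly
#' 1; channels of absent classes are all zero. One centroid per class.
#'
#' @param centroids data.frame with columns `label` (class in 1..K) and `d`,
#'   `h`, `w` (0-based voxel coordinates on the target grid).
#' @param K number of classes.
#' @param shape integer target grid shape `(depth, height, width)`.
#' @param sigma Gaussian standard deviation in voxels.
#' @return object of class `heatmap_target`: list with `H` ((D,H,W,K) array),
#'   `present_classes`, `sigma`.
#' @export
render_heatmap_target <- function(centroids, K, shape, sigma = 2.0) {
  if (anyDuplicated(centroids$label))
    stop("duplicate class in centroid table: one centroid per vertebra")
  if (any(centroids$label < 1 | centroids$label > K))
    stop("centroid class outside 1..K")
  H <- array(0, c(shape, K))
  d2g <- function(c_, n) (seq_len(n) - 1 - c_)^2
  for (i in seq_len(nrow(centroids))) {
    g <- exp(-outer(outer(d2g(centroids$d[i], shape[1]),
                          d2g(centroids$h[i], shape[2]), "+"),
                    d2g(centroids$w[i], shape[3]), "+") / (2 * sigma^2))
    H[, , , centroids$label[i]] <- g / sum(g)
  }
  structure(list(H = H, present_classes = sort(centroids$label), sigma = sigma),
            class = "heatmap_target")
}

# map full-resolution 0-based voxel coordinates to the 1/4-resolution grid
#' Convert full-resolution voxel coordinates to quarter-resolution
#' @param x numeric 0-based coordinates at full resolution.
#' @return coordinates on the 1/4 grid (voxel-centre aligned).
#' @export
coords_to_quarter <- function(x) (x + 0.5) / 4 - 0.5

# ---------------------------------------------------------------------------
# Elementary supervised terms
# ---------------------------------------------------------------------------

#' Soft Dice and binary cross-entropy terms
#'
#' `dice_term` is `1 - (2*sum(p*g) + eps) / (sum(p) + sum(g) + eps)`, in
#' `[0, 1]`. `ce_term` is the mean binary cross-entropy with probabilities
#' clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @param p predicted foreground probabilities in `[0, 1]`.
#' @param g binary ground truth of the same shape.
#' @param eps smoothing constant.
#' @return scalar loss value.
#' @export
dice_term <- function(p, g, eps = 1e-6) {
  if (length(p) != length(g)) stop("shape mismatch")
  1 - (2 * sum(p * g) + eps) / (sum(p) + sum(g) + eps)
}

#' @rdname dice_term
#' @export
ce_term <- function(p, g) {
  if (length(p) != length(g)) stop("shape mismatch")
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(g * log(pc) + (1 - g) * log(1 - pc))
}

#' Multi-scale deep-supervised segmentation loss
#'
#' Weighted sum over scales of the equal-weighted Dice + cross-entropy on the
#' sigmoid of each head's logits against the ground-truth mask downsampled to
#' that head's resolution.
#'
#' @param seg_out list of logit arrays `full`, `half`, `quarter`.
#' @param gt_masks list of binary masks at the same three scales.
#' @param cfg a [loss_config()].
#' @return non-negative scalar.
#' @export
seg_supervised_loss <- function(seg_out, gt_masks, cfg = loss_config()) {
  scales <- c("full", "half", "quarter")
  total <- 0
  for (i in seq_along(scales)) {
    z <- seg_out[[scales[i]]]
    g <- gt_masks[[scales[i]]]
    p <- 1 / (1 + exp(-as.vector(z)))
    total <- total + cfg$scale_weights[i] *
      (cfg$alpha_seg * dice_term(p, as.vector(g), cfg$epsilon) +
       (1 - cfg$alpha_seg) * ce_term(p, as.vector(g)))
  }
  total
}

#' Downsample a label map to the deep-supervision scales
#'
#' Nearest-neighbour downsampling of the binary foreground (labels > 0) to
#' full, 1/2 and 1/4 resolution.
#'
#' @param labels a label [volume_grid()] or integer array.
#' @return list of binary arrays `full`, `half`, `quarter`.
#' @export
gt_masks_at_scales <- function(labels) {
  lab <- if (is_volume_grid(labels)) labels$data else labels
  fg <- array(as.double(lab > 0), dim(lab))
  list(full = fg,
       half = .cpp_resize3d(fg, as.integer(dim(lab) / 2L), FALSE),
       quarter = .cpp_resize3d(fg, as.integer(dim(lab) / 4L), FALSE))
}

#' Downsample a label map (nearest-neighbour) to 1/4 resolution
#' @param labels a label [volume_grid()] or integer array.
#' @return integer array at 1/4 resolution.
#' @export
labels_at_quarter <- function(labels) {
  lab <- if (is_volume_grid(labels)) labels$data else labels
  q <- .cpp_resize3d(array(as.double(lab), dim(lab)),
                     as.integer(dim(lab) / 4L), FALSE)
  storage.mode(q) <- "integer"
  q
}

#' Heatmap distribution-alignment loss (KL divergence)
#'
#' Per present class, the KL divergence between the target Gaussian heatmap
#' channel and the spatial softmax of the predicted logits, averaged over
#' present classes. Zero iff the predicted distribution equals the target;
#' invariant to per-channel constant logit shifts.
#'
#' @param H a [render_heatmap_target()] result.
#' @param id_logits (D,H,W,K) logit array at the heatmap resolution.
#' @return non-negative scalar (0 with a warning if no class is present).
#' @export
kl_heatmap_loss <- function(H, id_logits) {
  pres <- H$present_classes
  if (length(pres) == 0L) {
    warning("no present classes; KL heatmap loss is 0")
    return(0)
  }
  d <- dim(id_logits)
  total <- 0
  for (k in pres) {
    z <- as.vector(id_logits[, , , k])
    z <- z - max(z)
    logP <- z - log(sum(exp(z)))
    h <- as.vector(H$H[, , , k])
    nz <- h > 0
    total <- total + sum(h[nz] * (log(h[nz]) - logP[nz]))
  }
  total / length(pres)
}

#' Instance-consistency loss on low-resolution instance maps
#'
#' Mean over ground-truth vertebra instances of `1 - Dice` between the
#' ground-truth voxel set of each anatomical id and the predicted voxel set
#' assigned the same id; ids absent from the prediction contribute 1. This
#' penalizes merging and fragmentation of adjacent vertebrae.
#'
#' @param gt_instances,pred_instances integer arrays on the same grid holding
#'   per-voxel anatomical ids (0 = background).
#' @return scalar in `[0, 1]`.
#' @export
instance_consistency_loss <- function(gt_instances, pred_instances) {
  if (!all(dim(gt_instances) == dim(pred_instances))) stop("grid mismatch")
  ids <- sort(unique(gt_instances[gt_instances > 0]))
  if (length(ids) == 0L) return(0)
  mean(vapply(ids, function(m) {
    gm <- gt_instances == m
    pm <- pred_instances == m
    den <- sum(gm) + sum(pm)
    if (den == 0) return(1)
    1 - 2 * sum(gm & pm) / den
  }, numeric(1)))
}

#' Supervised multi-task loss
#'
#' `L_seg + alpha_cls * (m1 * L_KL + m2 * L_inst)` with `(m1, m2)` the
#' `kl_inst_mix` weights.
#'
#' @param l_seg segmentation loss value ([seg_supervised_loss()]).
#' @param l_kl heatmap KL loss value ([kl_heatmap_loss()]).
#' @param l_inst instance-consistency loss value.
#' @param cfg a [loss_config()].
#' @return scalar.
#' @export
supervised_loss <- function(l_seg, l_kl, l_inst, cfg = loss_config()) {
  l_seg + cfg$alpha_cls * (cfg$kl_inst_mix[1] * l_kl +
                           cfg$kl_inst_mix[2] * l_inst)
}

#' Class-frequency weights
#'
#' Inverse-frequency class weights normalized to sum to K, so equal
#' frequencies give unit weights. Classes with zero observed frequency are
#' assigned the smallest positive frequency before inversion (plus an
#' optional additive smoothing).
#'
#' @param frequencies non-negative per-class frequency vector.
#' @param smooth additive smoothing constant.
#' @return weight vector `wk` with `sum(wk) == length(wk)`.
#' @export
class_frequency_weights <- function(frequencies, smooth = 0) {
  K <- length(frequencies)
  if (all(frequencies <= 0)) stop("all class frequencies are zero")
  f <- frequencies
  f[f <= 0] <- min(f[f > 0])
  w <- 1 / (f + smooth)
  w * K / sum(w)
}

#' Total semi-supervised loss
#'
#' `L_sup + lambda(t) * L_cons`: during warm-up (`t < E_cons`) it equals the
#' supervised loss exactly.
#'
#' @param l_sup supervised loss value.
#' @param l_cons total consistency loss value (seg + id terms).
#' @param t epoch.
#' @param cfg a [schedule_config()].
#' @return scalar.
#' @export
total_loss <- function(l_sup, l_cons, t, cfg) {
  l_sup + lambda_schedule(t, cfg) * l_cons
}

# ---------------------------------------------------------------------------
# Pseudo-labels and consistency terms
# ---------------------------------------------------------------------------

class_softmax <- function(logits, temperature = 1) {
  d <- dim(logits)
  m <- matrix(logits, prod(d[1:3]), d[4]) / temperature
  m <- exp(m - apply(m, 1, max))
  m / rowSums(m)
}

#' Build confidence-filtered pseudo-labels from teacher outputs
#'
#' Segmentation: the pseudo-mask thresholds the teacher foreground
#' probability at 0.5, retained only on voxels whose confidence passes the
#' ramped threshold (`prob > tau_seg(t)` or `prob < 1 - tau_seg(t)`, i.e.
#' confident foreground or confident background). Identification: classes
#' are the argmax of the temperature-T softmax over the teacher heatmap
#' logits, retained where the maximum confidence exceeds `tau_cls(t)` and
#' the voxel is teacher foreground.
#'
#' @param teacher_seg_prob teacher foreground probability array (full res).
#' @param teacher_id_logits teacher (D,H,W,K) heatmap logits (1/4 res).
#' @param t epoch (must be >= `E_cons`).
#' @param cfg a [schedule_config()].
#' @param fg_quarter optional binary teacher-foreground mask at 1/4
#'   resolution used to exclude background from identification pseudo-labels;
#'   if `NULL` no foreground restriction is applied.
#' @return an object of class `consistency_inputs`: masks `omega_seg`,
#'   `omega_cls` (logical arrays), pseudo-labels `pseudo_seg` (binary array)
#'   and `pseudo_cls` (integer array of argmax classes), and the thresholds.
#' @export
make_pseudo_labels <- function(teacher_seg_prob, teacher_id_logits, t, cfg,
                               fg_quarter = NULL) {
  if (t < cfg$E_cons) stop("pseudo-labels are only defined for t >= E_cons")
  tau_s <- tau_seg_schedule(t, cfg)
  tau_c <- tau_cls_schedule(t, cfg)
  p <- teacher_seg_prob
  omega_seg <- p > tau_s | p < 1 - tau_s
  pseudo_seg <- array(as.double(p > 0.5), dim(p))
  probs <- class_softmax(teacher_id_logits, cfg$temperature)
  conf <- apply(probs, 1, max)
  cls <- max.col(probs, ties.method = "first")
  dq <- dim(teacher_id_logits)[1:3]
  omega_cls <- array(conf > tau_c, dq)
  if (!is.null(fg_quarter)) omega_cls <- omega_cls & (fg_quarter > 0)
  structure(list(omega_seg = omega_seg, pseudo_seg = pseudo_seg,
                 omega_cls = omega_cls, pseudo_cls = array(cls, dq),
                 tau_seg = tau_s, tau_cls = tau_c, t = t,
                 K = dim(teacher_id_logits)[4]),
            class = "consistency_inputs")
}

#' Consistency losses on confidence-filtered voxels
#'
#' `seg_consistency_loss` is the mean binary cross-entropy between the
#' teacher pseudo-mask and the sigmoid of the student's full-resolution
#' segmentation logits over the retained voxel set (0 when the set is
#' empty). `id_consistency_loss` is the class-weighted sum over classes of
#' the mean cross-entropy between teacher pseudo-classes and the student's
#' class softmax over each class's retained voxels, excluding background by
#' construction of the masks.
#'
#' @param ci a [make_pseudo_labels()] result.
#' @param student_seg_logit student full-resolution segmentation logits.
#' @return non-negative scalar.
#' @export
seg_consistency_loss <- function(ci, student_seg_logit) {
  m <- which(ci$omega_seg)
  if (length(m) == 0L) return(0)
  p <- 1 / (1 + exp(-as.vector(student_seg_logit)[m]))
  ce_term(p, as.vector(ci$pseudo_seg)[m])
}

#' @rdname seg_consistency_loss
#' @param student_id_logits student (D,H,W,K) heatmap logits.
#' @param wk class weights summing to K ([class_frequency_weights()]).
#' @export
id_consistency_loss <- function(ci, student_id_logits, wk = NULL) {
  K <- ci$K
  if (is.null(wk)) wk <- rep(1, K)
  probs <- class_softmax(student_id_logits)
  pc <- pmin(pmax(probs, 1e-12), 1)
  sel <- which(as.vector(ci$omega_cls))
  if (length(sel) == 0L) return(0)
  cls <- as.vector(ci$pseudo_cls)[sel]
  total <- 0
  for (k in sort(unique(cls))) {
    vx <- sel[cls == k]
    total <- total + wk[k] * mean(-log(pc[vx, k]))
  }
  total
}

# ---------------------------------------------------------------------------
# Gradient-bearing loss variants used by the trainer. Each returns
# list(value, grad) with grad w.r.t. the relevant logits.
# ---------------------------------------------------------------------------

grad_seg_supervised <- function(seg_out, gt_masks, cfg) {
  scales <- c("full", "half", "quarter")
  value <- 0
  grads <- list()
  for (i in seq_along(scales)) {
    z <- seg_out[[scales[i]]]
    g <- as.vector(gt_masks[[scales[i]]])
    p <- 1 / (1 + exp(-as.vector(z)))
    N <- length(p)
    num <- 2 * sum(p * g) + cfg$epsilon
    den <- sum(p) + sum(g) + cfg$epsilon
    dice <- 1 - num / den
    ddice_dp <- -(2 * g * den - num) / den^2
    ce <- ce_term(p, g)
    dce_dz <- (p - g) / N
    value <- value + cfg$scale_weights[i] *
      (cfg$alpha_seg * dice + (1 - cfg$alpha_seg) * ce)
    gz <- cfg$scale_weights[i] *
      (cfg$alpha_seg * ddice_dp * p * (1 - p) + (1 - cfg$alpha_seg) * dce_dz)
    grads[[scales[i]]] <- array(gz, dim(z))
  }
  list(value = value, grads = grads)
}

grad_kl_heatmap <- function(H, id_logits) {
  pres <- H$present_classes
  d <- dim(id_logits)
  grad <- array(0, d)
  if (length(pres) == 0L) return(list(value = 0, grad = grad))
  value <- 0
  for (k in pres) {
    z <- as.vector(id_logits[, , , k])
    z <- z - max(z)
    P <- exp(z) / sum(exp(z))
    logP <- z - log(sum(exp(z)))
    h <- as.vector(H$H[, , , k])
    nz <- h > 0
    value <- value + sum(h[nz] * (log(h[nz]) - logP[nz]))
    grad[, , , k] <- array((P - h) / length(pres), d[1:3])
  }
  list(value = value / length(pres), grad = grad)
}

# Soft (differentiable) counterpart of the instance-consistency term: per-
# voxel class softmax restricted to the ground-truth foreground, soft Dice
# against the one-hot instance map, averaged over present instances.
grad_soft_instance <- function(id_logits, gt_inst_quarter) {
  d <- dim(id_logits)
  V <- prod(d[1:3]); K <- d[4]
  fg <- which(as.vector(gt_inst_quarter) > 0)
  grad <- array(0, d)
  if (length(fg) == 0L) return(list(value = 0, grad = grad))
  zm <- matrix(id_logits, V, K)[fg, , drop = FALSE]
  zm <- zm - apply(zm, 1, max)
  Q <- exp(zm); Q <- Q / rowSums(Q)
  ids <- sort(unique(as.vector(gt_inst_quarter)[fg]))
  dQ <- matrix(0, length(fg), K)
  value <- 0
  for (m in ids) {
    inm <- as.vector(gt_inst_quarter)[fg] == m
    qm <- Q[, m]
    num <- 2 * sum(qm[inm])
    den <- sum(qm) + sum(inm)
    value <- value + (1 - num / den)
    dQ[, m] <- dQ[, m] + (-(2 * inm * den - num) / den^2) / length(ids)
  }
  value <- value / length(ids)
  gz <- Q * (dQ - rowSums(dQ * Q))
  gm <- matrix(0, V, K)
  gm[fg, ] <- gz
  list(value = value, grad = array(gm, d))
}

grad_seg_consistency <- function(ci, student_seg_logit) {
  m <- which(ci$omega_seg)
  grad <- array(0, dim(student_seg_logit))
  if (length(m) == 0L) return(list(value = 0, grad = grad))
  z <- as.vector(student_seg_logit)[m]
  p <- 1 / (1 + exp(-z))
  y <- as.vector(ci$pseudo_seg)[m]
  value <- ce_term(p, y)
  grad[m] <- (p - y) / length(m)
  list(value = value, grad = grad)
}

grad_id_consistency <- function(ci, student_id_logits, wk = NULL) {
  K <- ci$K
  if (is.null(wk)) wk <- rep(1, K)
  d <- dim(student_id_logits)
  V <- prod(d[1:3])
  grad <- array(0, d)
  sel <- which(as.vector(ci$omega_cls))
  if (length(sel) == 0L) return(list(value = 0, grad = grad))
  zm <- matrix(student_id_logits, V, K)[sel, , drop = FALSE]
  zm <- zm - apply(zm, 1, max)
  Q <- exp(zm); Q <- Q / rowSums(Q)
  cls <- as.vector(ci$pseudo_cls)[sel]
  value <- 0
  gsel <- matrix(0, length(sel), K)
  for (k in sort(unique(cls))) {
    rows <- which(cls == k)
    qk <- pmin(pmax(Q[rows, k], 1e-12), 1)
    value <- value + wk[k] * mean(-log(qk))
    onehot <- matrix(0, length(rows), K)
    onehot[, k] <- 1
    gsel[rows, ] <- gsel[rows, ] +
      wk[k] * (Q[rows, , drop = FALSE] - onehot) / length(rows)
  }
  gm <- matrix(0, V, K)
  gm[sel, ] <- gsel
  list(value = value, grad = array(gm, d))
}
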