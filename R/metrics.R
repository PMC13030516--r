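#' Global Dice similarity coefficient
#'
#' `2|S intersect GT| / (|S| + |GT|)` over binary masks. Both masks empty is
#' defined as 1 (perfect agreement); empty vs non-empty is 0. Symmetric in
#' its arguments.
#'
#' @param pred,gt binary arrays (logical or 0/1) on the same grid.
#' @return Dice fraction in `[0, 1]`.
#' @export
dice_global <- function(pred, gt) {
  if (length(pred) != length(gt)) stop("grid mismatch")
  s <- sum(pred > 0)
  g <- sum(gt > 0)
  if (s + g == 0) return(1)
  2 * sum(pred > 0 & gt > 0) / (s + g)
}

#' Instance matching configuration
#' @param tau_iou IoU threshold in (0, 1] below which a pair cannot match.
#' @return list of class `match_config`.
#' @export
match_config <- function(tau_iou = 0.5) {
  if (tau_iou <= 0 || tau_iou > 1) stop("tau_iou must be in (0, 1]")
  structure(list(tau_iou = tau_iou), class = "match_config")
}

instance_voxel_sets <- function(x) {
  if (inherits(x, "instance_set")) {
    lapply(seq_len(x$n), function(j) which(x$map == j))
  } else if (is.array(x)) {  # id map: one instance per positive value
    ids <- sort(unique(x[x > 0]))
    stats::setNames(lapply(ids, function(k) which(x == k)), ids)
  } else stop("expected an instance_set or an integer id map")
}

#' Match predicted to ground-truth instances by IoU
#'
#' One-to-one matching that maximizes total IoU subject to every matched
#' pair having IoU >= `tau_iou`, solved with the Hungarian algorithm on the
#' IoU matrix (pairs below the threshold carry zero weight and are dropped
#' from the solution, which preserves optimality for non-negative weights).
#'
#' @param gt,pred `instance_set`s (or integer id maps) on the same grid.
#' @param cfg a [match_config()].
#' @return object of class `match_result`: `iou_matrix` (m x n), `matching`
#'   (data.frame `gt`, `pred`, `iou`), `unmatched_gt`, `unmatched_pred`.
#' @export
match_instances <- function(gt, pred, cfg = match_config()) {
  gs <- instance_voxel_sets(gt)
  ps <- instance_voxel_sets(pred)
  m <- length(gs); n <- length(ps)
  iou <- matrix(0, m, n)
  if (m > 0 && n > 0) {
    for (i in seq_len(m)) for (j in seq_len(n)) {
      inter <- length(intersect(gs[[i]], ps[[j]]))
      if (inter > 0)
        iou[i, j] <- inter / (length(gs[[i]]) + length(ps[[j]]) - inter)
    }
  }
  pairs <- NULL
  if (m > 0 && n > 0) {
    w <- iou
    w[w < cfg$tau_iou] <- 0
    # minimize negative IoU; pad so rows <= cols with zero-weight dummies
    if (m <= n) {
      assign <- .cpp_hungarian_min(-w)
      cand <- data.frame(gt = seq_len(m), pred = assign)
    } else {
      assign <- .cpp_hungarian_min(-t(w))
      cand <- data.frame(gt = assign, pred = seq_len(n))
    }
    cand$iou <- iou[cbind(cand$gt, cand$pred)]
    pairs <- cand[cand$iou >= cfg$tau_iou, , drop = FALSE]
    rownames(pairs) <- NULL
  }
  if (is.null(pairs))
    pairs <- data.frame(gt = integer(), pred = integer(), iou = numeric())
  structure(list(iou_matrix = iou, matching = pairs,
                 unmatched_gt = setdiff(seq_len(m), pairs$gt),
                 unmatched_pred = setdiff(seq_len(n), pairs$pred),
                 tau_iou = cfg$tau_iou),
            class = "match_result")
}

#' Instance-level identification accuracy
#'
#' The fraction of ground-truth vertebrae that are matched to a predicted
#' instance whose predicted anatomical index equals the ground-truth index.
#' Unmatched or mis-identified instances count as errors.
#'
#' @param gt_ids integer anatomical ids of the ground-truth instances (in
#'   instance order).
#' @param pred_ids integer anatomical ids of the predicted instances (NA =
#'   unassigned).
#' @param match a [match_instances()] result.
#' @return accuracy fraction in `[0, 1]`.
#' @export
id_accuracy <- function(gt_ids, pred_ids, match) {
  m <- length(gt_ids)
  if (m == 0L) stop("identification accuracy is undefined with no ground-truth instances")
  correct <- 0L
  for (r in seq_len(nrow(match$matching))) {
    gi <- match$matching$gt[r]
    pj <- match$matching$pred[r]
    if (!is.na(pred_ids[pj]) && pred_ids[pj] == gt_ids[gi])
      correct <- correct + 1L
  }
  correct / m
}

#' Region-stratified evaluation report
#'
#' Groups per-instance results into cervical (C1-C7, ids 1-7), thoracic
#' (T1-T12, ids 8-19) and lumbar (L1-L5, ids 20-24) plus an overall row.
#'
#' @param per_instance data.frame with columns `gt_id` (1..24), `correct`
#'   (logical) and optionally `dice` (per-instance Dice).
#' @return data.frame with columns `region`, `n_instances`, `dice`,
#'   `accuracy` (NA where a region is empty).
#' @export
region_report <- function(per_instance) {
  if (any(per_instance$gt_id < 1 | per_instance$gt_id > 24))
    stop("anatomical ids must lie in 1..24")
  reg <- cut(per_instance$gt_id, c(0, 7, 19, 24),
             labels = c("cervical", "thoracic", "lumbar"))
  rows <- lapply(c("cervical", "thoracic", "lumbar"), function(r) {
    sel <- reg == r
    data.frame(region = r, n_instances = sum(sel),
               dice = if (sum(sel) && !is.null(per_instance$dice))
                 mean(per_instance$dice[sel]) else NA_real_,
               accuracy = if (sum(sel)) mean(per_instance$correct[sel])
               else NA_real_)
  })
  overall <- data.frame(region = "overall", n_instances = nrow(per_instance),
                        dice = if (!is.null(per_instance$dice))
                          mean(per_instance$dice) else NA_real_,
                        accuracy = mean(per_instance$correct))
  do.call(rbind, c(rows, list(overall)))
}

#' Evaluate a predicted label map against ground truth
#'
#' Computes the global foreground Dice and the IoU-matched instance-level
#' identification accuracy between two anatomical id maps, treating each
#' positive id as one instance.
#'
#' @param gt_labels,pred_labels integer id arrays (or label
#'   [volume_grid()]s) on the same grid.
#' @param tau_iou IoU matching threshold.
#' @return list with `dice`, `accuracy`, `match`, `per_instance` (data.frame
#'   for [region_report()]) and `tau_iou`.
#' @export
evaluate_prediction <- function(gt_labels, pred_labels, tau_iou = 0.5) {
  g <- if (is_volume_grid(gt_labels)) gt_labels$data else gt_labels
  p <- if (is_volume_grid(pred_labels)) pred_labels$data else pred_labels
  if (!all(dim(g) == dim(p))) stop("grid mismatch")
  dice <- dice_global(p > 0, g > 0)
  gt_ids <- sort(unique(g[g > 0]))
  pred_ids <- sort(unique(p[p > 0]))
  match <- match_instances(g, p, match_config(tau_iou))
  acc <- if (length(gt_ids)) id_accuracy(gt_ids, pred_ids, match) else NA_real_
  correct <- rep(FALSE, length(gt_ids))
  inst_dice <- rep(0, length(gt_ids))
  for (r in seq_len(nrow(match$matching))) {
    gi <- match$matching$gt[r]
    pj <- match$matching$pred[r]
    if (pred_ids[pj] == gt_ids[gi]) correct[gi] <- TRUE
    inst_dice[gi] <- dice_global(p == pred_ids[pj], g == gt_ids[gi])
  }
  per_instance <- data.frame(gt_id = gt_ids, correct = correct,
                             dice = inst_dice)
  list(dice = dice, accuracy = acc, match = match,
       per_instance = per_instance, tau_iou = tau_iou)
}
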