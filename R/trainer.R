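#' Training configuration
#'
#' Bundles the network, schedule and loss configurations with the optimizer
#' settings (SGD with momentum, initial learning rate 0.01, momentum 0.9)
#' and desk-scale data handling choices.
#'
#' @param network a [network_config()].
#' @param schedule a [schedule_config()]; scale with [scale_schedule()] for
#'   shorter runs.
#' @param loss a [loss_config()].
#' @param lr,momentum SGD hyper-parameters.
#' @param seed master RNG seed.
#' @param batch_labeled,batch_unlabeled samples per step.
#' @param steps_per_epoch labeled steps per epoch; default covers the
#'   labeled set once.
#' @param patch_shape training patch size (axes divisible by 8).
#' @param augment logical; apply geometric/photometric augmentation to
#'   labeled samples.
#' @return an object of class `train_config`.
#' @export
train_config <- function(network = network_config(),
                         schedule = schedule_config(),
                         loss = loss_config(),
                         lr = 0.01, momentum = 0.9, seed = 42L,
                         batch_labeled = 2L, batch_unlabeled = 2L,
                         steps_per_epoch = NULL,
                         patch_shape = c(128L, 64L, 64L),
                         augment = TRUE) {
  structure(list(network = network, schedule = schedule, loss = loss,
                 lr = lr, momentum = momentum, seed = as.integer(seed),
                 batch_labeled = as.integer(batch_labeled),
                 batch_unlabeled = as.integer(batch_unlabeled),
                 steps_per_epoch = steps_per_epoch,
                 patch_shape = as.integer(patch_shape),
                 augment = isTRUE(augment)),
            class = "train_config")
}

zeros_like <- function(params) lapply(params, function(p) p * 0)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exponential-moving-average teacher update
#'
#' `theta_ema <- alpha * theta_ema + (1 - alpha) * theta_student`,
#' elementwise over index-compatible parameter collections. The teacher
#' never receives gradients; this is the only way its weights move.
#'
#' @param teacher,student named `model_params` lists with identical layout.
#' @param alpha EMA decay in (0, 1).
#' @return the updated teacher parameter list.
#' @export
ema_update <- function(teacher, student, alpha = 0.99) {
  if (!identical(names(teacher), names(student)))
    stop("teacher and student parameter collections are not index-compatible")
  out <- mapply(function(te, st) {
    if (!identical(dim(te), dim(st)) || length(te) != length(st))
      stop("parameter shape mismatch in EMA update")
    alpha * te + (1 - alpha) * st
  }, teacher, student, SIMPLIFY = FALSE)
  class(out) <- class(teacher)
  out
}

#' Create the initial training state
#'
#' @param cfg a [train_config()].
#' @return a `train_state` list: epoch counter, student/teacher parameters,
#'   optimizer velocity, and the phase (`warmup`/`ramp`/`stable`).
#' @export
init_train_state <- function(cfg) {
  params <- init_params(cfg$network, seed = cfg$seed)
  structure(list(epoch = 0L, student = params, teacher = NULL,
                 velocity = zeros_like(params), cfg = cfg,
                 phase = "warmup", step = 0L),
            class = "train_state")
}

train_phase <- function(t, sched) {
  if (t < sched$E_cons) "warmup" else if (t < sched$E_ramp) "ramp" else "stable"
}

#' Initialize the EMA teacher from the current student
#'
#' Called once at the end of the supervised warm-up (epoch `E_cons`); the
#' teacher starts as an exact copy of the student and is thereafter updated
#' only via [ema_update()].
#'
#' @param state a `train_state`.
#' @return the updated state.
#' @export
init_teacher <- function(state) {
  if (!is.null(state$teacher)) stop("teacher already initialized")
  if (state$epoch < state$cfg$schedule$E_cons)
    stop("teacher can only be initialized at the end of warm-up (t >= E_cons)")
  state$teacher <- state$student
  state
}

sgd_update <- function(state, grads) {
  cfg <- state$cfg
  for (n in names(state$student)) {
    g <- grads[[n]]
    if (is.null(g)) next
    v <- cfg$momentum * state$velocity[[n]] + g
    state$velocity[[n]] <- v
    state$student[[n]] <- state$student[[n]] - cfg$lr * v
  }
  state
}

accumulate_grads <- function(total, g, w = 1) {
  for (n in names(g)) {
    total[[n]] <- if (is.null(total[[n]])) w * g[[n]] else total[[n]] + w * g[[n]]
  }
  total
}

# Build training targets for one (already augmented) labeled patch.
labeled_targets <- function(labels, K) {
  lab <- if (is_volume_grid(labels)) labels$data else labels
  gt_masks <- gt_masks_at_scales(lab)
  gt_q <- labels_at_quarter(lab)
  cents <- compute_centroids_from_labels(lab)
  H <- if (nrow(cents) > 0) {
    cq <- data.frame(label = cents$label, d = coords_to_quarter(cents$d),
                     h = coords_to_quarter(cents$h),
                     w = coords_to_quarter(cents$w))
    render_heatmap_target(cq, K, dim(lab) %/% 4L)
  } else NULL
  list(gt_masks = gt_masks, gt_quarter = gt_q, heatmap = H)
}

#' Mean voxel coordinates (0-based) of each label in a label map
#' @param lab integer label array or label [volume_grid()].
#' @return data.frame with columns `label`, `d`, `h`, `w`.
#' @export
compute_centroids_from_labels <- function(lab) {
  if (is_volume_grid(lab)) lab <- lab$data
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0L)
    return(data.frame(label = integer(), d = numeric(), h = numeric(),
                      w = numeric()))
  d <- dim(lab)
  idx <- which(lab > 0)
  co <- arrayInd(idx, d) - 1L
  vals <- lab[idx]
  do.call(rbind, lapply(ids, function(k) {
    sel <- vals == k
    data.frame(label = k, d = mean(co[sel, 1]), h = mean(co[sel, 2]),
               w = mean(co[sel, 3]))
  }))
}

# Supervised gradients for one sample; returns loss components + param grads.
supervised_grads <- function(state, volume, labels) {
  cfg <- state$cfg
  tape <- ad_tape(TRUE)
  out <- net_forward(state$student, volume, cfg$network, tape)
  tg <- labeled_targets(labels, cfg$network$n_classes)
  seg_vals <- lapply(out$seg, ad_value)
  gseg <- grad_seg_supervised(seg_vals, tg$gt_masks, cfg$loss)
  id_val <- ad_value(out$id)
  if (!is.null(tg$heatmap)) {
    gkl <- grad_kl_heatmap(tg$heatmap, id_val)
    gin <- grad_soft_instance(id_val, tg$gt_quarter)
  } else {
    gkl <- list(value = 0, grad = array(0, dim(id_val)))
    gin <- gkl
  }
  mix <- cfg$loss$kl_inst_mix
  id_grad <- cfg$loss$alpha_cls * (mix[1] * gkl$grad + mix[2] * gin$grad)
  l_sup <- supervised_loss(gseg$value, gkl$value, gin$value, cfg$loss)
  if (!is.finite(l_sup))
    stop(sprintf("non-finite supervised loss at epoch %d (seg=%g kl=%g inst=%g)",
                 state$epoch, gseg$value, gkl$value, gin$value))
  seeds <- list(list(node = out$seg$full, grad = gseg$grads$full),
                list(node = out$seg$half, grad = gseg$grads$half),
                list(node = out$seg$quarter, grad = gseg$grads$quarter))
  if (cfg$loss$alpha_cls > 0)
    seeds <- c(seeds, list(list(node = out$id, grad = id_grad)))
  ad_backward(tape, seeds)
  list(loss = l_sup, seg = gseg$value, kl = gkl$value, inst = gin$value,
       grads = ad_param_grads(tape))
}

#' One supervised optimization step
#'
#' Computes the supervised multi-task loss on a batch of labeled patches,
#' averages parameter gradients over the batch, and applies one SGD-with-
#' momentum update to the student.
#'
#' @param state a `train_state`.
#' @param batch list of samples, each a list with `volume` (normalized
#'   patch, [volume_grid()] or array) and `labels` (label map).
#' @return list with the updated `state` and the logged loss components.
#' @export
labeled_step <- function(state, batch) {
  total <- list()
  comp <- c(loss = 0, seg = 0, kl = 0, inst = 0)
  for (s in batch) {
    g <- supervised_grads(state, s$volume, s$labels)
    total <- accumulate_grads(total, g$grads, 1 / length(batch))
    comp <- comp + unlist(g[c("loss", "seg", "kl", "inst")]) / length(batch)
  }
  state <- sgd_update(state, total)
  state$step <- state$step + 1L
  list(state = state, losses = as.list(comp))
}

#' One consistency (unlabeled) optimization step
#'
#' Builds synchronized weak/strong views, runs the teacher on the weak view
#' (no gradients), forms confidence-filtered pseudo-labels at the current
#' epoch's thresholds, trains the student on the strong view with the
#' ramp-weighted consistency losses, and finally updates the EMA teacher.
#' When the ramp weight is zero the optimizer update is skipped so the step
#' is a true no-op for the student.
#'
#' @param state a `train_state` with an initialized teacher.
#' @param volumes list of normalized unlabeled patches.
#' @param step_seed integer seed controlling the augmentation draws.
#' @return list with updated `state` and logged components.
#' @export
unlabeled_step <- function(state, volumes, step_seed = 1L) {
  cfg <- state$cfg
  sched <- cfg$schedule
  if (state$epoch < sched$E_cons)
    stop("consistency steps are only defined for t >= E_cons")
  if (is.null(state$teacher)) stop("teacher not initialized")
  lam <- lambda_schedule(state$epoch, sched)
  total <- list()
  comp <- c(cons_seg = 0, cons_cls = 0, lambda = lam)
  for (i in seq_along(volumes)) {
    views <- build_unlabeled_views(volumes[[i]], derive_seed(step_seed, i))
    t_out <- net_forward(state$teacher, views$weak, cfg$network)
    t_prob <- 1 / (1 + exp(-ad_value(t_out$seg$full)))
    fg_q <- (1 / (1 + exp(-ad_value(t_out$seg$quarter)))) > 0.5
    ci <- make_pseudo_labels(array(t_prob, dim(t_prob)[1:3]),
                             ad_value(t_out$id), state$epoch, sched,
                             fg_quarter = array(fg_q, dim(fg_q)[1:3]))
    tape <- ad_tape(TRUE)
    s_out <- net_forward(state$student, views$strong, cfg$network, tape)
    gs <- grad_seg_consistency(ci, ad_value(s_out$seg$full))
    gi <- grad_id_consistency(ci, ad_value(s_out$id))
    comp["cons_seg"] <- comp["cons_seg"] + gs$value / length(volumes)
    comp["cons_cls"] <- comp["cons_cls"] + gi$value / length(volumes)
    if (lam > 0) {
      ad_backward(tape, list(
        list(node = s_out$seg$full, grad = lam * gs$grad),
        list(node = s_out$id, grad = lam * gi$grad)))
      total <- accumulate_grads(total, ad_param_grads(tape), 1 / length(volumes))
    }
  }
  if (lam > 0) state <- sgd_update(state, total)
  state$teacher <- ema_update(state$teacher, state$student, sched$ema_alpha)
  state$step <- state$step + 1L
  list(state = state, losses = as.list(comp))
}

prepare_labeled_patch <- function(sample, cfg, seed) {
  vol <- sample$volume
  lab <- sample$labels
  if (cfg$augment) {
    aug <- augment_labeled(vol, lab, seed)
    vol <- aug$volume
    lab <- aug$labels
  }
  if (!all(dim(vol$data) == cfg$patch_shape)) {
    plan <- plan_patches(vol, "random", cfg$patch_shape, n_random = 1L,
                         seed = derive_seed(seed, 2L))
    corner <- plan$positions[1, ]
    vol <- extract_patch(vol, corner, cfg$patch_shape)
    lab <- extract_patch(lab, corner, cfg$patch_shape)
  }
  list(volume = vol, labels = lab)
}

validate_dice <- function(state, val) {
  if (length(val) == 0L) return(NA_real_)
  mean(vapply(val, function(s) {
    out <- forward_full(s$volume, state$student, state$cfg$network)
    p <- 1 / (1 + exp(-out$seg$full[, , , 1]))
    dice_global(p > 0.5, (if (is_volume_grid(s$labels)) s$labels$data
                          else s$labels) > 0)
  }, numeric(1)))
}

#' Train the dual-branch network
#'
#' Runs the full semi-supervised protocol: supervised-only warm-up for the
#' first `E_cons` epochs, then interleaved labeled and unlabeled steps (1:1
#' per iteration) with the consistency weight and confidence thresholds
#' ramped to their endpoints at `E_ramp`. The EMA teacher is initialized
#' from the student when consistency starts. With an empty unlabeled set
#' the run degrades (with a warning) to fully supervised training, the FSL
#' protocol. The best epoch by validation Dice is kept.
#'
#' @param labeled list of samples (`volume`, `labels`), normalized patches
#'   or whole volumes.
#' @param unlabeled list of normalized unlabeled volumes (possibly empty).
#' @param val list of validation samples (`volume`, `labels`) used for model
#'   selection; may be empty.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch log lines.
#' @return an object of class `spinessl_fit`: list with `state`, `best`
#'   (parameters, epoch, dice), `history` (per-epoch data.frame) and
#'   `config`.
#' @export
fit <- function(labeled, unlabeled = list(), val = list(),
                cfg = train_config(), verbose = FALSE) {
  if (length(labeled) == 0L) stop("labeled set must be non-empty")
  ssl <- length(unlabeled) > 0L
  if (!ssl)
    warning("empty unlabeled set: training degrades to fully supervised (FSL)")
  sched <- cfg$schedule
  state <- init_train_state(cfg)
  steps <- cfg$steps_per_epoch %||%
    max(1L, ceiling(length(labeled) / cfg$batch_labeled))
  history <- NULL
  best <- list(params = state$student, epoch = -1L, dice = -Inf)

  for (t in seq.int(0L, sched$total_epochs - 1L)) {
    state$epoch <- t
    state$phase <- train_phase(t, sched)
    if (ssl && t == sched$E_cons && is.null(state$teacher))
      state <- init_teacher(state)
    ep <- c(loss = 0, seg = 0, kl = 0, inst = 0, cons_seg = 0, cons_cls = 0)
    order_seed <- derive_seed(cfg$seed, 1000L + t)
    idx <- with_seed(order_seed, sample(seq_along(labeled)))
    for (s in seq_len(steps)) {
      pick <- idx[((s - 1L) * cfg$batch_labeled + seq_len(cfg$batch_labeled) - 1L) %%
                    length(labeled) + 1L]
      batch <- lapply(seq_along(pick), function(j) {
        prepare_labeled_patch(labeled[[pick[j]]], cfg,
                              derive_seed(cfg$seed, t * 10000L + s * 100L + j))
      })
      res <- labeled_step(state, batch)
      state <- res$state
      ep[c("loss", "seg", "kl", "inst")] <-
        ep[c("loss", "seg", "kl", "inst")] + unlist(res$losses) / steps
      if (ssl && t >= sched$E_cons) {
        upick <- with_seed(derive_seed(cfg$seed, 2000L + t * 100L + s),
                           sample(seq_along(unlabeled),
                                  min(cfg$batch_unlabeled, length(unlabeled))))
        ures <- unlabeled_step(state, unlabeled[upick],
                               derive_seed(cfg$seed, 3000L + t * 100L + s))
        state <- ures$state
        ep[c("cons_seg", "cons_cls")] <- ep[c("cons_seg", "cons_cls")] +
          unlist(ures$losses[c("cons_seg", "cons_cls")]) / steps
      }
    }
    vd <- validate_dice(state, val)
    if (!is.na(vd) && vd > best$dice)
      best <- list(params = state$student, epoch = t, dice = vd)
    row <- data.frame(epoch = t, phase = state$phase,
                      lambda = lambda_schedule(t, sched),
                      tau_cls = if (t >= sched$E_cons)
                        tau_cls_schedule(t, sched) else NA_real_,
                      tau_seg = if (t >= sched$E_cons)
                        tau_seg_schedule(t, sched) else NA_real_,
                      loss = ep["loss"], seg = ep["seg"], kl = ep["kl"],
                      inst = ep["inst"], cons_seg = ep["cons_seg"],
                      cons_cls = ep["cons_cls"], val_dice = vd)
    history <- rbind(history, row)
    if (verbose)
      message(sprintf(
        "epoch %3d [%s] loss=%.4f seg=%.4f kl=%.4f inst=%.4f cons=%.4f/%.4f val=%.3f",
        t, state$phase, ep["loss"], ep["seg"], ep["kl"], ep["inst"],
        ep["cons_seg"], ep["cons_cls"], vd))
  }
  if (best$epoch < 0L) best <- list(params = state$student,
                                    epoch = sched$total_epochs - 1L,
                                    dice = NA_real_)
  rownames(history) <- NULL
  structure(list(state = state, best = best, history = history,
                 config = cfg),
            class = "spinessl_fit")
}
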