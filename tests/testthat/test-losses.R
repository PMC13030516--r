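sched <- schedule_config()

test_that("ramp schedules follow their closed forms at all integer epochs", {
  ts <- 0:100
  lam <- vapply(ts, lambda_schedule, numeric(1), cfg = sched)
  ref <- ifelse(ts < 40, 0, pmin(1, (ts - 40) / 40))
  expect_equal(lam, ref)
  expect_equal(lambda_schedule(20, sched), 0)
  expect_equal(lambda_schedule(60, sched), 0.5)
  expect_equal(lambda_schedule(95, sched), 1)
  # thresholds: endpoints and midpoints
  expect_equal(tau_cls_schedule(40, sched), 0.30)
  expect_equal(tau_cls_schedule(80, sched), 0.55)
  expect_equal(tau_seg_schedule(80, sched), 0.90)
  expect_equal(tau_seg_schedule(60, sched), 0.70)
  expect_equal(tau_cls_schedule(100, sched), 0.55)  # clamped after ramp
  # nondecreasing and piecewise linear over the active range
  tc <- vapply(40:100, tau_cls_schedule, numeric(1), cfg = sched)
  tsg <- vapply(40:100, tau_seg_schedule, numeric(1), cfg = sched)
  expect_true(all(diff(tc) >= 0) && all(diff(tsg) >= 0))
  expect_warning(tau_cls_schedule(10, sched), "E_cons")
  # scaled schedule preserves the 40:40:20 proportion
  s12 <- scale_schedule(sched, 12L)
  expect_equal(s12$E_cons, 5L)
  expect_equal(s12$E_ramp, 10L)
  expect_equal(tau_cls_schedule(s12$E_ramp, s12), 0.55)
})

test_that("heatmap targets are normalized Gaussians peaked at the centroid", {
  H <- render_heatmap_target(data.frame(label = 3, d = 8, h = 8, w = 8),
                             K = 5, shape = c(16, 16, 16), sigma = 2)
  expect_lt(abs(sum(H$H[, , , 3]) - 1), 1e-6)
  expect_equal(sum(H$H[, , , c(1, 2, 4, 5)]), 0)
  peak <- which.max(H$H[, , , 3])
  expect_equal(arrayInd(peak, c(16, 16, 16)) - 1L,
               matrix(c(8L, 8L, 8L), 1))
  # Gaussian ratio at 2 voxels from the peak with sigma = 2: exp(-0.5)
  expect_equal(H$H[11, 9, 9, 3] / H$H[9, 9, 9, 3], exp(-0.5), tolerance = 1e-12)
  expect_error(render_heatmap_target(
    data.frame(label = c(1, 1), d = c(2, 4), h = c(2, 2), w = c(2, 2)),
    K = 5, shape = c(8, 8, 8)), "duplicate")
})

test_that("dice and cross-entropy terms have their closed-form values", {
  g <- c(1, 1, 0, 0)
  expect_lt(dice_term(g, g), 1e-6)
  expect_gt(dice_term(c(0, 0, 1, 1), g), 1 - 1e-4)
  expect_equal(ce_term(rep(0.5, 10), rep(c(0, 1), 5)), log(2), tolerance = 1e-12)
  expect_error(dice_term(1:3, 1:4), "mismatch")
})

test_that("deep-supervised segmentation loss behaves at its fixed points", {
  set.seed(8)
  g <- list(full = array(rbinom(64, 1, 0.4), c(4, 4, 4)),
            half = array(rbinom(8, 1, 0.4), c(2, 2, 2)),
            quarter = array(rbinom(1, 1, 0.4), c(1, 1, 1)))
  perfect <- lapply(g, function(m) array(ifelse(m > 0, 50, -50), dim(m)))
  expect_lt(seg_supervised_loss(perfect, g), 1e-4)
  # degenerate weights reduce to the single-scale loss
  lc1 <- loss_config(scale_weights = c(1, 0, 0))
  z <- lapply(g, function(m) array(rnorm(length(m)), dim(m)))
  single <- loss_config()$alpha_seg *
    dice_term(1 / (1 + exp(-as.vector(z$full))), as.vector(g$full)) +
    0.5 * ce_term(1 / (1 + exp(-as.vector(z$full))), as.vector(g$full))
  expect_equal(seg_supervised_loss(z, g, lc1), single, tolerance = 1e-12)
  # scale weights are normalized: scaling them changes nothing
  lc2 <- loss_config(scale_weights = 10 * c(4, 2, 1) / 7)
  expect_equal(seg_supervised_loss(z, g, lc2), seg_supervised_loss(z, g),
               tolerance = 1e-12)
})

test_that("heatmap KL loss matches a direct-summation oracle", {
  set.seed(9)
  H <- render_heatmap_target(data.frame(label = c(1, 3), d = c(2, 5),
                                        h = c(3, 4), w = c(4, 3)),
                             K = 4, shape = c(8, 8, 8), sigma = 2)
  z <- array(rnorm(8 * 8 * 8 * 4), c(8, 8, 8, 4))
  # independent oracle: explicit softmax + double sum per present channel
  oracle <- 0
  for (k in c(1, 3)) {
    zz <- as.vector(z[, , , k])
    P <- exp(zz) / sum(exp(zz))
    h <- as.vector(H$H[, , , k])
    oracle <- oracle + sum(h[h > 0] * log(h[h > 0] / P[h > 0]))
  }
  oracle <- oracle / 2
  expect_lt(abs(kl_heatmap_loss(H, z) - oracle), 1e-9)
  # zero at the self-consistent fixed point: logits = log H
  zfix <- array(0, dim(z))
  for (k in c(1, 3)) zfix[, , , k] <- log(H$H[, , , k])
  expect_lt(kl_heatmap_loss(H, zfix), 1e-6)
  # invariance to per-channel constant logit shifts
  zshift <- z
  zshift[, , , 1] <- zshift[, , , 1] + 7.3
  expect_equal(kl_heatmap_loss(H, zshift), kl_heatmap_loss(H, z),
               tolerance = 1e-9)
  # uniform prediction against a target: KL = sum H log(H V)
  zu <- array(0, dim(z))
  V <- 512
  ku <- sapply(c(1, 3), function(k) {
    h <- as.vector(H$H[, , , k])
    sum(h[h > 0] * log(h[h > 0] * V))
  })
  expect_equal(kl_heatmap_loss(H, zu), mean(ku), tolerance = 1e-9)
})

test_that("instance-consistency loss penalizes merges and misses", {
  gt <- array(0L, c(8, 8, 8))
  gt[2:3, 2:6, 2:6] <- 1L
  gt[5:6, 2:6, 2:6] <- 2L
  expect_equal(instance_consistency_loss(gt, gt), 0)
  # empty prediction: every instance fully missed
  expect_equal(instance_consistency_loss(gt, array(0L, dim(gt))), 1)
  # two instances merged into one predicted id
  merged <- gt
  merged[merged == 2L] <- 1L
  v <- instance_consistency_loss(gt, merged)
  d1 <- 2 * sum(gt == 1) / (sum(gt == 1) + sum(merged == 1))
  expect_equal(v, mean(c(1 - d1, 1)), tolerance = 1e-12)
  expect_gt(v, 0)
})

test_that("supervised loss composes linearly in the identification weight", {
  expect_equal(supervised_loss(0.3, 0.2, 0.1, loss_config(alpha_cls = 0)), 0.3)
  l1 <- supervised_loss(0.3, 0.2, 0.1, loss_config(alpha_cls = 1))
  l2 <- supervised_loss(0.3, 0.2, 0.1, loss_config(alpha_cls = 2))
  expect_equal(l2 - 0.3, 2 * (l1 - 0.3), tolerance = 1e-12)
  expect_lt(supervised_loss(1e-6, 1e-6, 0, loss_config()), 1e-4)
})

test_that("class-frequency weights invert frequencies and sum to K", {
  expect_equal(class_frequency_weights(rep(7, 24)), rep(1, 24))
  expect_equal(class_frequency_weights(c(2, 1)), c(2 / 3, 4 / 3))
  set.seed(10)
  for (i in 1:20) {
    f <- runif(24, 0.1, 10)
    expect_lt(abs(sum(class_frequency_weights(f)) - 24), 1e-9)
  }
  expect_error(class_frequency_weights(c(0, 0)), "zero")
})

test_that("pseudo-label masks follow the confidence thresholds", {
  K <- 4
  zid <- array(rnorm(4 * 4 * 4 * K), c(4, 4, 4, K))
  # teacher probability exactly 0.5 everywhere: no confident voxels
  ci <- make_pseudo_labels(array(0.5, c(4, 4, 4)), zid, 60, sched)
  expect_equal(sum(ci$omega_seg), 0)
  expect_equal(seg_consistency_loss(ci, array(rnorm(64), c(4, 4, 4, 1))), 0)
  # extreme confidence at the top of the ramp covers the grid
  ci2 <- make_pseudo_labels(array(0.99, c(4, 4, 4)), zid, 100, sched)
  expect_true(all(ci2$omega_seg))
  # temperature never changes the argmax class
  p1 <- ns$class_softmax(zid, 1)
  p2 <- ns$class_softmax(zid, 0.5)
  expect_identical(max.col(p1), max.col(p2))
  expect_error(make_pseudo_labels(array(0.9, c(4, 4, 4)), zid, 10, sched),
               "E_cons")
})

test_that("consistency losses match hand-computed values and empty-set rules", {
  # hand-built 3-voxel example
  ci <- structure(list(
    omega_seg = array(c(TRUE, TRUE, TRUE), c(3, 1, 1)),
    pseudo_seg = array(c(1, 0, 1), c(3, 1, 1)),
    omega_cls = array(FALSE, c(1, 1, 1)),
    pseudo_cls = array(1L, c(1, 1, 1)), K = 2L), class = "consistency_inputs")
  z <- array(stats::qlogis(c(0.9, 0.2, 0.6)), c(3, 1, 1))
  expect_equal(seg_consistency_loss(ci, z),
               mean(-log(c(0.9, 0.8, 0.6))), tolerance = 1e-9)
  # student equal to pseudo-labels: near-zero loss
  zfit <- array(c(50, -50, 50), c(3, 1, 1))
  expect_lt(seg_consistency_loss(ci, zfit), 1e-4)
  # empty masks define a zero loss
  expect_equal(id_consistency_loss(ci, array(0, c(1, 1, 1, 2))), 0)
  # id consistency at its fixed point
  K <- 3
  zid <- array(0, c(2, 2, 2, K))
  zid[, , , 2] <- 50
  ci2 <- structure(list(
    omega_cls = array(TRUE, c(2, 2, 2)),
    pseudo_cls = array(2L, c(2, 2, 2)), K = K), class = "consistency_inputs")
  expect_lt(id_consistency_loss(ci2, zid), 1e-4)
  expect_gt(id_consistency_loss(ci2, array(rnorm(24), c(2, 2, 2, K))), 0)
})

test_that("total loss honours the ramp weight", {
  expect_equal(total_loss(1.5, 99, 20, sched), 1.5)
  expect_equal(total_loss(1.5, 2, 90, sched), 3.5)
  expect_equal(total_loss(1.5, 0, 60, sched), 1.5)
  expect_equal(total_loss(1, 1, 60, sched), 1.5)
})

test_that("analytic loss gradients agree with finite differences", {
  set.seed(12)
  lc <- loss_config()
  z <- list(full = array(rnorm(64), c(4, 4, 4, 1)),
            half = array(rnorm(8), c(2, 2, 2, 1)),
            quarter = array(rnorm(1), c(1, 1, 1, 1)))
  g <- list(full = array(rbinom(64, 1, 0.4), c(4, 4, 4)),
            half = array(rbinom(8, 1, 0.4), c(2, 2, 2)),
            quarter = array(1, c(1, 1, 1)))
  gr <- ns$grad_seg_supervised(z, g, lc)
  for (i in c(3, 17)) {
    zp <- z; zp$full[i] <- z$full[i] + 1e-6
    zm <- z; zm$full[i] <- z$full[i] - 1e-6
    fd <- (seg_supervised_loss(zp, g, lc) - seg_supervised_loss(zm, g, lc)) / 2e-6
    expect_lt(abs(fd - gr$grads$full[i]) / max(1e-6, abs(fd)), 1e-3)
  }
  H <- render_heatmap_target(data.frame(label = 2, d = 3, h = 3, w = 3),
                             K = 3, shape = c(8, 8, 8))
  zid <- array(rnorm(8 * 8 * 8 * 3), c(8, 8, 8, 3))
  gk <- ns$grad_kl_heatmap(H, zid)
  i <- 600
  zp <- zid; zp[i] <- zid[i] + 1e-6
  zm <- zid; zm[i] <- zid[i] - 1e-6
  fd <- (kl_heatmap_loss(H, zp) - kl_heatmap_loss(H, zm)) / 2e-6
  expect_lt(abs(fd - gk$grad[i]) / max(1e-6, abs(fd)), 1e-3)
})
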