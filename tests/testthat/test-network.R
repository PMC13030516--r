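test_that("encoder and decoders obey the resolution ledger", {
  cfg <- network_config(base_channels = 2L, n_classes = 24L)
  params <- init_params(cfg, seed = 1)
  feats <- encode(array(0, c(128, 64, 64)), params, cfg)
  expect_identical(dim(feats[[4]])[1:3], c(16L, 8L, 8L))
  expect_identical(dim(feats[[1]])[1:3], c(128L, 64L, 64L))
  expect_identical(dim(feats[[2]])[4], 4L)  # width doubles per stage
  # constant-zero input stays finite
  expect_true(all(is.finite(feats[[4]])))
  out <- forward_full(array(0, c(64, 32, 32)), init_params(cfg, 1), cfg)
  expect_identical(dim(out$seg$full)[1:3], c(64L, 32L, 32L))
  expect_identical(dim(out$seg$half)[1:3], c(32L, 16L, 16L))
  expect_identical(dim(out$seg$quarter)[1:3], c(16L, 8L, 8L))
  expect_identical(dim(out$id), c(16L, 8L, 8L, 24L))
  expect_error(encode(array(0, c(20, 16, 16)), params, cfg), "divisible by 8")
})

test_that("forward is deterministic and the branches separate correctly", {
  cfg <- tiny_net()
  params <- init_params(cfg, seed = 2)
  x <- tiny_input()
  a <- forward_full(x, params, cfg)
  b <- forward_full(x, params, cfg)
  expect_identical(a, b)
  # perturbing only the id decoder leaves the segmentation output unchanged
  p2 <- params
  p2[["idhead.w"]] <- p2[["idhead.w"]] + 0.1
  c_ <- forward_full(x, p2, cfg)
  expect_identical(c_$seg, a$seg)
  expect_false(identical(c_$id, a$id))
  # perturbing the shared encoder changes both outputs
  p3 <- params
  p3[["enc1.A.conv.w"]] <- p3[["enc1.A.conv.w"]] + 0.1
  d_ <- forward_full(x, p3, cfg)
  expect_false(identical(d_$seg$full, a$seg$full))
  expect_false(identical(d_$id, a$id))
})

test_that("bottleneck operators are shape-preserving and interchangeable", {
  x <- tiny_input(3)
  outs <- lapply(c("state_space", "self_attention", "none"), function(op) {
    cfg <- tiny_net(bottleneck_op = op)
    forward_full(x, init_params(cfg, seed = 4), cfg)
  })
  shapes <- lapply(outs, function(o) lapply(o$seg, dim))
  expect_identical(shapes[[1]], shapes[[2]])
  expect_identical(shapes[[1]], shapes[[3]])
  # op = none is the identity on the deepest features
  cfg0 <- tiny_net(bottleneck_op = "none")
  p0 <- init_params(cfg0, 5)
  f <- array(rnorm(2 * 2 * 2 * 32), c(2, 2, 2, 32))
  expect_identical(bottleneck_context(f, p0, cfg0), f)
  # permuting in-plane axes commutes with the identity op
  fp <- aperm(f, c(1, 3, 2, 4))
  expect_identical(aperm(bottleneck_context(fp, p0, cfg0), c(1, 3, 2, 4)), f)
})

test_that("state-space cost is linear in sequence length, attention quadratic", {
  C <- 16
  L <- 4096
  r_ssm <- bottleneck_flops("state_space", 2 * L, C) /
    bottleneck_flops("state_space", L, C)
  r_att <- bottleneck_flops("self_attention", 2 * L, C) /
    bottleneck_flops("self_attention", L, C)
  expect_lt(abs(r_ssm - 2), 0.01)
  expect_gt(r_att, 3.5)
  expect_equal(bottleneck_flops("none", L, C), 0)
})

test_that("cbam placement controls which attention parameters exist", {
  p_none <- init_params(tiny_net(cbam_placement = "none"), 1)
  p_id <- init_params(tiny_net(cbam_placement = "id_only"), 1)
  p_both <- init_params(tiny_net(cbam_placement = "both"), 1)
  expect_false(any(grepl("cbam", names(p_none))))
  expect_true(any(grepl("idd.cbam", names(p_id), fixed = TRUE)))
  expect_false(any(grepl("segd", names(p_id)) & grepl("cbam", names(p_id))))
  expect_true(any(grepl("segd1.cbam", names(p_both), fixed = TRUE)))
  # forcing identity gates reproduces the attention-free block output
  x <- array(rnorm(4 * 4 * 4 * 16), c(4, 4, 4, 16))
  gated <- ns$fw_cbam(NULL, p_id, "idd.cbamA", x, force_identity_gates = TRUE)
  expect_identical(gated, x)
  # real gates lie in (0, 1): attenuation only
  out <- ns$fw_cbam(NULL, p_id, "idd.cbamA", x)
  expect_true(all(abs(out) <= abs(x) + 1e-12))
})

test_that("tiny configuration stays under the CPU-trainable parameter budget", {
  p <- init_params(network_config(base_channels = 8L), 1)
  expect_lt(param_count(p), 2e6)
  # index compatibility of two initializations
  p2 <- init_params(network_config(base_channels = 8L), 99)
  expect_identical(names(p), names(p2))
  expect_identical(lapply(p, dim), lapply(p2, dim))
})

test_that("autodiff gradients match finite differences through the full model", {
  cfg <- tiny_net(cbam_placement = "both")
  params <- init_params(cfg, seed = 3)
  x <- tiny_input(2)
  loss_of <- function(p) {
    o <- forward_full(x, p, cfg)
    sum(o$seg$full^2) + sum(o$id^2) + sum(o$seg$half^2)
  }
  tape <- ns$ad_tape(TRUE)
  o <- ns$net_forward(params, x, cfg, tape)
  ns$ad_backward(tape, list(
    list(node = o$seg$full, grad = 2 * ns$ad_value(o$seg$full)),
    list(node = o$seg$half, grad = 2 * ns$ad_value(o$seg$half)),
    list(node = o$id, grad = 2 * ns$ad_value(o$id))))
  g <- ns$ad_param_grads(tape)
  for (nm in c("enc1.A.conv.w", "enc4.B.in.g", "bn4.wa", "segd2.A.conv.w",
               "idd.cbamA.w2", "idhead.w")) {
    i <- min(2, length(params[[nm]]))
    pp <- params; pp[[nm]][i] <- pp[[nm]][i] + 1e-5
    pm <- params; pm[[nm]][i] <- pm[[nm]][i] - 1e-5
    fd <- (loss_of(pp) - loss_of(pm)) / 2e-5
    expect_lt(abs(fd - g[[nm]][i]) / max(1, abs(fd)), 1e-4)
  }
  # gradient flows to every encoder stage from the deepest seg head alone
  tape2 <- ns$ad_tape(TRUE)
  o2 <- ns$net_forward(params, x, cfg, tape2)
  ns$ad_backward(tape2, list(list(node = o2$seg$quarter,
                                  grad = array(1, dim(ns$ad_value(o2$seg$quarter))))))
  g2 <- ns$ad_param_grads(tape2)
  for (s in 1:4) {
    gs <- g2[[sprintf("enc%d.A.conv.w", s)]]
    expect_true(!is.null(gs) && all(is.finite(gs)) && any(gs != 0))
  }
})

test_that("checkpoints round-trip config and parameters", {
  dir <- withr::local_tempdir()
  cfg <- tiny_net()
  model <- list(config = cfg, params = init_params(cfg, 6))
  path <- file.path(dir, "ck.rds")
  save_checkpoint(model, path, epoch = 3L, seed = 42L)
  ck <- load_checkpoint(path)
  expect_identical(ck$params, model$params)
  expect_identical(ck$config, cfg)
  expect_identical(ck$epoch, 3L)
})
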