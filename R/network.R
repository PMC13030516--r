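#' Dual-branch 3D network configuration
#'
#' Configures the shared 4-stage 3D convolutional encoder, the long-range
#' bottleneck sequence operator, the deep-supervised segmentation decoder and
#' the attention-augmented identification decoder. Stage 1 operates at full
#' resolution and stages 2-4 each downsample by 2, so the bottleneck sits at
#' 1/8 resolution and the segmentation decoder upsamples three times back to
#' full resolution. Channel widths are `base_channels * c(1, 2, 4, 8)`.
#'
#' @param in_channels number of input channels (CT intensity: 1).
#' @param base_channels stage-1 channel width.
#' @param n_classes number of anatomical classes K (24 = C1..L5).
#' @param bottleneck_op long-range operator over the flattened cranio-caudal
#'   sequence at the bottleneck: `"state_space"` (gated diagonal state-space
#'   scan, linear-time in sequence length), `"self_attention"` (scaled
#'   dot-product attention, quadratic), or `"none"` (identity).
#' @param bottleneck_placement `"bottleneck_only"` or `"all_encoder_stages"`.
#' @param cbam_placement where channel-then-spatial attention blocks are
#'   inserted: `"none"`, `"id_only"` (default) or `"both"`.
#' @param cbam_reduction channel-attention bottleneck reduction ratio.
#' @return an object of class `network_config`.
#' @export
network_config <- function(in_channels = 1L, base_channels = 16L,
                           n_classes = 24L,
                           bottleneck_op = c("state_space", "self_attention", "none"),
                           bottleneck_placement = c("bottleneck_only", "all_encoder_stages"),
                           cbam_placement = c("id_only", "none", "both"),
                           cbam_reduction = 4L) {
  bottleneck_op <- match.arg(bottleneck_op)
  bottleneck_placement <- match.arg(bottleneck_placement)
  cbam_placement <- match.arg(cbam_placement)
  if (n_classes < 1) stop("n_classes must be >= 1")
  structure(list(in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 n_stages = 4L, n_classes = as.integer(n_classes),
                 bottleneck_op = bottleneck_op,
                 bottleneck_placement = bottleneck_placement,
                 cbam_placement = cbam_placement,
                 cbam_reduction = as.integer(cbam_reduction)),
            class = "network_config")
}

# ---------------------------------------------------------------------------
# Parameter initialization (He-style for LeakyReLU), stable name ordering.
# ---------------------------------------------------------------------------

init_conv <- function(params, name, k, cin, cout) {
  fan_in <- k^3 * cin
  params[[paste0(name, ".w")]] <-
    array(rnorm(k^3 * cin * cout, 0, sqrt(2 / fan_in)), c(k, k, k, cin, cout))
  params[[paste0(name, ".b")]] <- numeric(cout)
  params
}

init_in <- function(params, name, c_) {
  params[[paste0(name, ".g")]] <- rep(1, c_)
  params[[paste0(name, ".be")]] <- numeric(c_)
  params
}

init_block <- function(params, name, cin, cout) {
  params <- init_conv(params, paste0(name, ".conv"), 3L, cin, cout)
  init_in(params, paste0(name, ".in"), cout)
}

init_cbam <- function(params, name, c_, r) {
  hid <- max(1L, c_ %/% r)
  params[[paste0(name, ".w1")]] <- matrix(rnorm(hid * c_, 0, sqrt(2 / c_)), hid, c_)
  params[[paste0(name, ".b1")]] <- numeric(hid)
  params[[paste0(name, ".w2")]] <- matrix(rnorm(c_ * hid, 0, sqrt(2 / hid)), c_, hid)
  params[[paste0(name, ".b2")]] <- numeric(c_)
  params <- init_conv(params, paste0(name, ".sp"), 3L, 2L, 1L)
  params
}

init_bottleneck <- function(params, name, c_, op) {
  if (op == "none") return(params)
  sd_ <- sqrt(1 / c_)
  mats <- if (op == "self_attention") c("wq", "wk", "wv", "wo") else
    c("wa", "wb", "wg", "wo")
  for (m in mats)
    params[[paste0(name, ".", m)]] <- matrix(rnorm(c_ * c_, 0, sd_), c_, c_)
  if (op == "state_space") params[[paste0(name, ".ba")]] <- rep(1, c_)
  params
}

#' Initialize network parameters
#'
#' Returns the ordered, named flat collection of parameter arrays for a
#' [network_config()]. Two calls with the same config are index-compatible;
#' initialization is deterministic for a fixed seed.
#'
#' @param cfg a [network_config()].
#' @param seed integer RNG seed.
#' @return named list of numeric arrays (class `model_params`).
#' @export
init_params <- function(cfg, seed = 42L) {
  ch <- cfg$base_channels * c(1L, 2L, 4L, 8L)
  with_seed(seed, {
    p <- list()
    # encoder: stage 1 full res, stages 2-4 downsample via strided first conv
    p <- init_block(p, "enc1.A", cfg$in_channels, ch[1])
    p <- init_block(p, "enc1.B", ch[1], ch[1])
    for (s in 2:4) {
      p <- init_block(p, sprintf("enc%d.A", s), ch[s - 1], ch[s])
      p <- init_block(p, sprintf("enc%d.B", s), ch[s], ch[s])
    }
    if (cfg$bottleneck_placement == "all_encoder_stages" &&
        cfg$bottleneck_op != "none") {
      for (s in 1:4) p <- init_bottleneck(p, sprintf("bn%d", s), ch[s], cfg$bottleneck_op)
    } else {
      p <- init_bottleneck(p, "bn4", ch[4], cfg$bottleneck_op)
    }
    # segmentation decoder with deep supervision
    p <- init_block(p, "segd3.A", ch[4] + ch[3], ch[3])
    p <- init_block(p, "segd3.B", ch[3], ch[3])
    p <- init_conv(p, "seghead.q", 1L, ch[3], 1L)
    p <- init_block(p, "segd2.A", ch[3] + ch[2], ch[2])
    p <- init_block(p, "segd2.B", ch[2], ch[2])
    p <- init_conv(p, "seghead.h", 1L, ch[2], 1L)
    p <- init_block(p, "segd1.A", ch[2] + ch[1], ch[1])
    p <- init_block(p, "segd1.B", ch[1], ch[1])
    p <- init_conv(p, "seghead.f", 1L, ch[1], 1L)
    if (cfg$cbam_placement == "both") {
      for (nm in c("segd3", "segd2", "segd1")) {
        cw <- switch(nm, segd3 = ch[3], segd2 = ch[2], segd1 = ch[1])
        p <- init_cbam(p, paste0(nm, ".cbam"), cw, cfg$cbam_reduction)
      }
    }
    # identification decoder: one upsampling step from 1/8 to 1/4
    p <- init_block(p, "idd.A", ch[4] + ch[3], ch[3])
    p <- init_block(p, "idd.B", ch[3], ch[3])
    if (cfg$cbam_placement %in% c("id_only", "both")) {
      p <- init_cbam(p, "idd.cbamA", ch[3], cfg$cbam_reduction)
      p <- init_cbam(p, "idd.cbamB", ch[3], cfg$cbam_reduction)
    }
    p <- init_conv(p, "idhead", 1L, ch[3], cfg$n_classes)
    class(p) <- "model_params"
    p
  })
}

#' Count network parameters
#' @param params a `model_params` list.
#' @return integer total number of scalar parameters.
#' @export
param_count <- function(params) sum(vapply(params, length, numeric(1)))

# ---------------------------------------------------------------------------
# Forward passes (tape-aware): blocks
# ---------------------------------------------------------------------------

fw_block <- function(tape, pl, name, x, stride = 1L) {
  y <- nn_conv3d(tape, x, pl[[paste0(name, ".conv.w")]],
                 pl[[paste0(name, ".conv.b")]], stride)
  y <- nn_instance_norm(tape, y, pl[[paste0(name, ".in.g")]],
                        pl[[paste0(name, ".in.be")]])
  nn_leaky_relu(tape, y)
}

fw_cbam <- function(tape, pl, name, x, force_identity_gates = FALSE) {
  if (force_identity_gates) return(x)
  mlp <- function(v) {
    h <- nn_relu(tape, nn_dense(tape, v, pl[[paste0(name, ".w1")]],
                                pl[[paste0(name, ".b1")]]))
    nn_dense(tape, h, pl[[paste0(name, ".w2")]], pl[[paste0(name, ".b2")]])
  }
  gate <- nn_sigmoid(tape, nn_add(tape, mlp(nn_global_avg(tape, x)),
                                  mlp(nn_global_max(tape, x))))
  x1 <- nn_scale_channels(tape, x, gate)
  smap <- nn_sigmoid(tape, nn_conv3d(tape, nn_channel_pool(tape, x1),
                                     pl[[paste0(name, ".sp.w")]],
                                     pl[[paste0(name, ".sp.b")]], 1L))
  nn_scale_spatial(tape, x1, smap)
}

fw_bottleneck <- function(tape, pl, name, x, cfg) {
  op <- cfg$bottleneck_op
  if (op == "none") return(x)
  d <- dim(ad_value(x))
  seq_ <- nn_to_sequence(tape, x)
  if (op == "self_attention") {
    C <- d[4]
    q <- nn_matmul(tape, seq_, pl[[paste0(name, ".wq")]])
    k <- nn_matmul(tape, seq_, pl[[paste0(name, ".wk")]])
    v <- nn_matmul(tape, seq_, pl[[paste0(name, ".wv")]])
    att <- nn_softmax_rows(tape, nn_scalar_mul(tape, nn_matmul_bt(tape, q, k),
                                               1 / sqrt(C)))
    y <- nn_matmul(tape, nn_matmul(tape, att, v), pl[[paste0(name, ".wo")]])
    out <- nn_add(tape, y, seq_)
  } else {
    out <- nn_ssm_scan(tape, seq_, pl[[paste0(name, ".wa")]],
                       pl[[paste0(name, ".ba")]], pl[[paste0(name, ".wb")]],
                       pl[[paste0(name, ".wg")]], pl[[paste0(name, ".wo")]])
  }
  nn_from_sequence(tape, out, d[1:3])
}

nn_matmul_bt <- function(tape, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  y <- tcrossprod(av, bv)
  ad_op(tape, y, list(a, b), function(gy) {
    list(gy %*% bv, crossprod(gy, av))
  })
}

fw_encoder <- function(tape, pl, x, cfg) {
  all_stages <- cfg$bottleneck_placement == "all_encoder_stages" &&
    cfg$bottleneck_op != "none"
  f1 <- fw_block(tape, pl, "enc1.B", fw_block(tape, pl, "enc1.A", x))
  if (all_stages) f1 <- fw_bottleneck(tape, pl, "bn1", f1, cfg)
  f2 <- fw_block(tape, pl, "enc2.B", fw_block(tape, pl, "enc2.A", f1, 2L))
  if (all_stages) f2 <- fw_bottleneck(tape, pl, "bn2", f2, cfg)
  f3 <- fw_block(tape, pl, "enc3.B", fw_block(tape, pl, "enc3.A", f2, 2L))
  if (all_stages) f3 <- fw_bottleneck(tape, pl, "bn3", f3, cfg)
  f4 <- fw_block(tape, pl, "enc4.B", fw_block(tape, pl, "enc4.A", f3, 2L))
  f4 <- fw_bottleneck(tape, pl, "bn4", f4, cfg)
  list(f1, f2, f3, f4)
}

fw_seg_decoder <- function(tape, pl, feats, cfg) {
  with_cbam <- cfg$cbam_placement == "both"
  d3 <- nn_concat_channels(tape, nn_upsample2(tape, feats[[4]]), feats[[3]])
  d3 <- fw_block(tape, pl, "segd3.B", fw_block(tape, pl, "segd3.A", d3))
  if (with_cbam) d3 <- fw_cbam(tape, pl, "segd3.cbam", d3)
  q <- nn_conv3d(tape, d3, pl[["seghead.q.w"]], pl[["seghead.q.b"]], 1L)
  d2 <- nn_concat_channels(tape, nn_upsample2(tape, d3), feats[[2]])
  d2 <- fw_block(tape, pl, "segd2.B", fw_block(tape, pl, "segd2.A", d2))
  if (with_cbam) d2 <- fw_cbam(tape, pl, "segd2.cbam", d2)
  h <- nn_conv3d(tape, d2, pl[["seghead.h.w"]], pl[["seghead.h.b"]], 1L)
  d1 <- nn_concat_channels(tape, nn_upsample2(tape, d2), feats[[1]])
  d1 <- fw_block(tape, pl, "segd1.B", fw_block(tape, pl, "segd1.A", d1))
  if (with_cbam) d1 <- fw_cbam(tape, pl, "segd1.cbam", d1)
  f <- nn_conv3d(tape, d1, pl[["seghead.f.w"]], pl[["seghead.f.b"]], 1L)
  list(full = f, half = h, quarter = q)
}

fw_id_decoder <- function(tape, pl, feats, cfg) {
  with_cbam <- cfg$cbam_placement %in% c("id_only", "both")
  u <- nn_concat_channels(tape, nn_upsample2(tape, feats[[4]]), feats[[3]])
  u <- fw_block(tape, pl, "idd.A", u)
  if (with_cbam) u <- fw_cbam(tape, pl, "idd.cbamA", u)
  u <- fw_block(tape, pl, "idd.B", u)
  if (with_cbam) u <- fw_cbam(tape, pl, "idd.cbamB", u)
  nn_conv3d(tape, u, pl[["idhead.w"]], pl[["idhead.b"]], 1L)
}

as_input_tensor <- function(x) {
  if (is_volume_grid(x)) x <- x$data
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  storage.mode(x) <- "double"
  if (any(dim(x)[1:3] %% 8L != 0L))
    stop("input spatial axes must be divisible by 8 (four-stage encoder)")
  x
}

# Tape-aware full forward; returns node handles when tape is active.
net_forward <- function(params, x, cfg, tape = NULL) {
  x <- as_input_tensor(x)
  pl <- params
  if (!is.null(tape) && tape$grad_on)
    pl <- mapply(function(v, n) ad_leaf(tape, v, name = n), params,
                 names(params), SIMPLIFY = FALSE)
  xin <- ad_leaf(tape, x, requires = FALSE)
  feats <- fw_encoder(tape, pl, if (is.null(tape)) x else xin, cfg)
  seg <- fw_seg_decoder(tape, pl, feats, cfg)
  id <- fw_id_decoder(tape, pl, feats, cfg)
  list(seg = seg, id = id, feats = feats)
}

#' Encode a patch into the 4-scale feature pyramid
#'
#' @param x input patch: a [volume_grid()] or (D,H,W)\[,1\] array whose axes
#'   are divisible by 8.
#' @param params `model_params` from [init_params()].
#' @param cfg the matching [network_config()].
#' @return list of 4 feature arrays at scales 1, 1/2, 1/4, 1/8 (channel-last).
#' @export
encode <- function(x, params, cfg) {
  lapply(net_forward(params, x, cfg)$feats, ad_value)
}

#' Apply the bottleneck long-range operator to a feature grid
#'
#' Shape-preserving sequence mixing over the flattened spatial sequence in
#' cranio-caudal-major order. With `bottleneck_op = "none"` this is the
#' identity.
#'
#' @param features a (D,H,W,C) feature array (deepest encoder stage).
#' @param params `model_params`; uses the `bn4.*` parameters.
#' @param cfg a [network_config()].
#' @return feature array of identical shape.
#' @export
bottleneck_context <- function(features, params, cfg) {
  ad_value(fw_bottleneck(NULL, params, "bn4", features, cfg))
}

#' Full dual-branch forward pass
#'
#' One shared encoder pass feeding both decoders. Returns segmentation logits
#' at full, 1/2 and 1/4 resolution (deep supervision, single channel) and the
#' K-channel identification heatmap logits at 1/4 resolution.
#'
#' @inheritParams encode
#' @return list with `seg` (list `full`, `half`, `quarter` of (D,H,W,1)
#'   logit arrays) and `id` ((D/4,H/4,W/4,K) logit array).
#' @export
forward_full <- function(x, params, cfg) {
  out <- net_forward(params, x, cfg)
  list(seg = lapply(out$seg, ad_value), id = ad_value(out$id))
}

#' Analytic floating-point operation count of the bottleneck operator
#'
#' Used to verify the complexity contract: the state-space scan is linear in
#' sequence length L while self-attention is quadratic.
#'
#' @param op `"state_space"`, `"self_attention"` or `"none"`.
#' @param L sequence length; @param C channel width.
#' @param C channel width.
#' @return approximate FLOP count (multiply-adds counted as 2).
#' @export
bottleneck_flops <- function(op, L, C) {
  switch(op,
         none = 0,
         state_space = 8 * L * C^2 + 12 * L * C,
         self_attention = 8 * L * C^2 + 4 * L^2 * C + 5 * L^2,
         stop("unknown bottleneck op"))
}

#' Save / load a model checkpoint
#'
#' A checkpoint stores the [network_config()], the parameter collection, the
#' epoch it was taken at, and the training seed.
#'
#' @param model list with `config` and `params` (and optionally more fields).
#' @param path file path (`.rds`).
#' @param epoch,seed metadata stored alongside.
#' @return `load_checkpoint` returns the checkpoint list.
#' @export
save_checkpoint <- function(model, path, epoch = NA_integer_, seed = NA_integer_) {
  ck <- list(config = model$config, params = model$params,
             epoch = epoch, seed = seed)
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
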