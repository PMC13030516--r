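# Minimal reverse-mode autodiff tape for the dual-branch network.
#
# Nodes are environments holding a value array, an accumulated gradient, and
# a backward closure mapping the output gradient to parent gradients. The
# tape records nodes in creation order; backward sweeps in reverse. With
# `grad = FALSE` (teacher / inference forwards) ops compute values only and
# record nothing.

ad_tape <- function(grad = TRUE) {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e$grad_on <- grad
  class(e) <- "ad_tape"
  e
}

ad_record <- function(tape, node) {
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    length(tape$nodes) <- 2L * length(tape$nodes)
  tape$nodes[[tape$n]] <- node
  node$id <- tape$n
  node
}

# A leaf (input or parameter). `name` ties parameter leaves back to the
# model's parameter list for gradient collection.
ad_leaf <- function(tape, value, name = NULL, requires = !is.null(name)) {
  if (is.null(tape) || !tape$grad_on) return(value)
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- list()
  node$bw <- NULL
  node$name <- name
  node$requires <- requires
  class(node) <- "ad_node"
  ad_record(tape, node)
}

is_ad_node <- function(x) inherits(x, "ad_node")
ad_value <- function(x) if (is_ad_node(x)) x$value else x

# Record an op. `backward` takes the incoming gradient and returns a list of
# gradients aligned with `parents` (NULL entries allowed).
ad_op <- function(tape, value, parents, backward) {
  if (is.null(tape) || !tape$grad_on) return(value)
  req <- any(vapply(parents, function(p) is_ad_node(p) && p$requires, logical(1)))
  if (!req) return(value)
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$bw <- backward
  node$name <- NULL
  node$requires <- TRUE
  class(node) <- "ad_node"
  ad_record(tape, node)
}

ad_accumulate <- function(node, g) {
  if (!is_ad_node(node) || !node$requires) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Seed one or more output nodes with gradients and sweep the tape backward.
# `seeds` is a list of (node, grad) pairs.
ad_backward <- function(tape, seeds) {
  for (s in seeds) ad_accumulate(s$node, s$grad)
  if (tape$n == 0L) return(invisible(NULL))
  for (i in seq.int(tape$n, 1L)) {
    node <- tape$nodes[[i]]
    if (is.null(node$grad) || is.null(node$bw)) next
    pg <- node$bw(node$grad)
    for (j in seq_along(node$parents)) {
      if (!is.null(pg[[j]])) ad_accumulate(node$parents[[j]], pg[[j]])
    }
    node$grad <- NULL  # release memory as we go
    node$bw <- NULL
  }
  invisible(NULL)
}

# Collect gradients of named parameter leaves into a named list.
ad_param_grads <- function(tape) {
  out <- list()
  if (tape$n == 0L) return(out)
  for (i in seq_len(tape$n)) {
    node <- tape$nodes[[i]]
    if (!is.null(node$name) && !is.null(node$grad)) out[[node$name]] <- node$grad
  }
  out
}

# ---------------------------------------------------------------------------
# Tensor ops. Feature tensors are (D,H,W,C) arrays; vectors are plain.
# ---------------------------------------------------------------------------

nn_conv3d <- function(tape, x, w, b, stride = 1L) {
  xv <- ad_value(x); wv <- ad_value(w); bv <- ad_value(b)
  y <- .cpp_conv3d_fwd(xv, wv, bv, as.integer(stride))
  ad_op(tape, y, list(x, w, b), function(gy) {
    g <- .cpp_conv3d_bwd(xv, wv, gy, as.integer(stride))
    list(g$gx, g$gw, g$gb)
  })
}

nn_instance_norm <- function(tape, x, gamma, beta, eps = 1e-5) {
  xv <- ad_value(x); gv <- ad_value(gamma); bv <- ad_value(beta)
  d <- dim(xv); V <- prod(d[1:3]); C <- d[4]
  xm <- matrix(xv, V, C)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  sd_ <- sqrt(colMeans(xc * xc) + eps)
  xhat <- sweep(xc, 2, sd_, "/")
  y <- array(sweep(sweep(xhat, 2, gv, "*"), 2, bv, "+"), d)
  ad_op(tape, y, list(x, gamma, beta), function(gy) {
    gm <- matrix(gy, V, C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    dxh <- sweep(gm, 2, gv, "*")
    m1 <- colMeans(dxh)
    m2 <- colMeans(dxh * xhat)
    dx <- sweep(dxh, 2, m1) - sweep(xhat, 2, m2, "*")
    dx <- sweep(dx, 2, sd_, "/")
    list(array(dx, d), dgamma, dbeta)
  })
}

nn_leaky_relu <- function(tape, x, slope = 0.01) {
  xv <- ad_value(x)
  m <- slope + (1 - slope) * (xv > 0)
  y <- xv * m
  ad_op(tape, y, list(x), function(gy) list(gy * m))
}

nn_relu <- function(tape, x) nn_leaky_relu(tape, x, 0)

nn_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-ad_value(x)))
  ad_op(tape, s, list(x), function(gy) list(gy * s * (1 - s)))
}

nn_add <- function(tape, a, b) {
  y <- ad_value(a) + ad_value(b)
  ad_op(tape, y, list(a, b), function(gy) list(gy, gy))
}

# nearest-neighbour x2 upsampling of each spatial axis
nn_upsample2 <- function(tape, x) {
  xv <- ad_value(x)
  d <- dim(xv)
  y <- xv[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2),
          rep(seq_len(d[3]), each = 2), , drop = FALSE]
  ad_op(tape, y, list(x), function(gy) {
    # sum over 2x2x2 blocks
    gd <- dim(gy)
    g <- array(gy, c(2L, gd[1] %/% 2L, 2L, gd[2] %/% 2L, 2L, gd[3] %/% 2L, gd[4]))
    list(array(colSums(aperm(g, c(1, 3, 5, 2, 4, 6, 7)), dims = 3L), dim(xv)))
  })
}

nn_concat_channels <- function(tape, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  da <- dim(av); db <- dim(bv)
  y <- array(c(av, bv), c(da[1:3], da[4] + db[4]))
  ad_op(tape, y, list(a, b), function(gy) {
    n <- prod(da)
    list(array(gy[seq_len(n)], da), array(gy[-seq_len(n)], db))
  })
}

# multiply each channel by a scalar gate (CBAM channel attention)
nn_scale_channels <- function(tape, x, gate) {
  xv <- ad_value(x); gv <- ad_value(gate)
  d <- dim(xv); V <- prod(d[1:3])
  y <- array(sweep(matrix(xv, V, d[4]), 2, gv, "*"), d)
  ad_op(tape, y, list(x, gate), function(gy) {
    gm <- matrix(gy, V, d[4])
    list(array(sweep(gm, 2, gv, "*"), d), colSums(gm * matrix(xv, V, d[4])))
  })
}

# multiply all channels by one spatial map (D,H,W,1)
nn_scale_spatial <- function(tape, x, map) {
  xv <- ad_value(x); mv <- ad_value(map)
  d <- dim(xv)
  y <- xv * as.vector(mv)   # recycles over channels (column-major)
  ad_op(tape, y, list(x, map), function(gy) {
    dmap <- array(rowSums(matrix(gy * xv, prod(d[1:3]), d[4])), dim(mv))
    list(gy * as.vector(mv), dmap)
  })
}

# global average + max pooling over spatial dims -> length-C vectors
nn_global_avg <- function(tape, x) {
  xv <- ad_value(x); d <- dim(xv); V <- prod(d[1:3])
  y <- colMeans(matrix(xv, V, d[4]))
  ad_op(tape, y, list(x), function(gy) {
    list(array(rep(gy / V, each = V), d))
  })
}

nn_global_max <- function(tape, x) {
  xv <- ad_value(x); d <- dim(xv); V <- prod(d[1:3])
  xm <- matrix(xv, V, d[4])
  idx <- max.col(t(xm), ties.method = "first")
  y <- xm[cbind(idx, seq_len(d[4]))]
  ad_op(tape, y, list(x), function(gy) {
    g <- matrix(0, V, d[4])
    g[cbind(idx, seq_len(d[4]))] <- gy
    list(array(g, d))
  })
}

# mean and max over channels -> (D,H,W,2) map (CBAM spatial attention)
nn_channel_pool <- function(tape, x) {
  xv <- ad_value(x); d <- dim(xv); V <- prod(d[1:3]); C <- d[4]
  xm <- matrix(xv, V, C)
  mx <- max.col(xm, ties.method = "first")
  y <- array(c(rowMeans(xm), xm[cbind(seq_len(V), mx)]), c(d[1:3], 2L))
  ad_op(tape, y, list(x), function(gy) {
    g1 <- gy[, , , 1L]
    g2 <- gy[, , , 2L]
    g <- matrix(as.vector(g1) / C, V, C)
    g[cbind(seq_len(V), mx)] <- g[cbind(seq_len(V), mx)] + as.vector(g2)
    list(array(g, d))
  })
}

# dense layer on a vector: y = W x + b, W is (out x in)
nn_dense <- function(tape, x, w, b) {
  xv <- ad_value(x); wv <- ad_value(w); bv <- ad_value(b)
  y <- as.vector(wv %*% xv + bv)
  ad_op(tape, y, list(x, w, b), function(gy) {
    list(as.vector(crossprod(wv, gy)), outer(gy, xv), gy)
  })
}

# matrix product of sequence features: y = A %*% B
nn_matmul <- function(tape, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  y <- av %*% bv
  ad_op(tape, y, list(a, b), function(gy) {
    list(gy %*% t(bv), crossprod(av, gy))
  })
}

nn_softmax_rows <- function(tape, x) {
  xv <- ad_value(x)
  e <- exp(xv - apply(xv, 1, max))
  p <- e / rowSums(e)
  ad_op(tape, p, list(x), function(gy) {
    list(p * (gy - rowSums(gy * p)))
  })
}

nn_scalar_mul <- function(tape, x, s) {
  y <- ad_value(x) * s
  ad_op(tape, y, list(x), function(gy) list(gy * s))
}

# reshape a (D,H,W,C) tensor into an (L x C) cranio-caudal-major sequence:
# the sequence index runs over in-plane positions fastest and depth slowest.
nn_to_sequence <- function(tape, x) {
  xv <- ad_value(x); d <- dim(xv)
  L <- prod(d[1:3])
  y <- matrix(aperm(xv, c(3, 2, 1, 4)), L, d[4])
  ad_op(tape, y, list(x), function(gy) {
    list(aperm(array(gy, c(d[3], d[2], d[1], d[4])), c(3, 2, 1, 4)))
  })
}

nn_from_sequence <- function(tape, x, spatial) {
  xv <- ad_value(x); C <- ncol(xv)
  y <- aperm(array(xv, c(spatial[3], spatial[2], spatial[1], C)), c(3, 2, 1, 4))
  ad_op(tape, y, list(x), function(gy) {
    list(matrix(aperm(gy, c(3, 2, 1, 4)), nrow(xv), C))
  })
}

# Gated diagonal state-space scan over an (L x C) sequence (selective-scan
# style): input-dependent per-channel decay and gate, linear-time in L.
#   A = sigmoid(X Wa + ba); U = X Wb; G = sigmoid(X Wg)
#   h_t = A_t * h_{t-1} + (1 - A_t) * U_t;  Y = (H * G) Wo + X
nn_ssm_scan <- function(tape, x, wa, ba, wb, wg, wo) {
  xv <- ad_value(x)
  wav <- ad_value(wa); bav <- ad_value(ba); wbv <- ad_value(wb)
  wgv <- ad_value(wg); wov <- ad_value(wo)
  L <- nrow(xv); C <- ncol(xv)
  A <- 1 / (1 + exp(-sweep(xv %*% wav, 2, bav, "+")))
  U <- xv %*% wbv
  G <- 1 / (1 + exp(-(xv %*% wgv)))
  H <- matrix(0, L, C)
  h <- numeric(C)
  for (t in seq_len(L)) {
    h <- A[t, ] * h + (1 - A[t, ]) * U[t, ]
    H[t, ] <- h
  }
  Z <- H * G
  Y <- Z %*% wov + xv
  ad_op(tape, Y, list(x, wa, ba, wb, wg, wo), function(gy) {
    dwo <- crossprod(Z, gy)
    dZ <- gy %*% t(wov)
    dH <- dZ * G
    dG <- dZ * H
    dA <- matrix(0, L, C)
    dU <- matrix(0, L, C)
    carry <- numeric(C)
    for (t in seq.int(L, 1L)) {
      dht <- dH[t, ] + carry
      hprev <- if (t > 1L) H[t - 1L, ] else numeric(C)
      dA[t, ] <- dht * (hprev - U[t, ])
      dU[t, ] <- dht * (1 - A[t, ])
      carry <- dht * A[t, ]
    }
    dSa <- dA * A * (1 - A)
    dSg <- dG * G * (1 - G)
    dx <- gy + dU %*% t(wbv) + dSa %*% t(wav) + dSg %*% t(wgv)
    list(dx, crossprod(xv, dSa), colSums(dSa), crossprod(xv, dU),
         crossprod(xv, dSg), dwo)
  })
}
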