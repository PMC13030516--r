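# Shared fixtures: all built in code at test time.

ns <- asNamespace("spinessl")

# tiny network configuration used across network/trainer tests
tiny_net <- function(...) network_config(base_channels = 4L, n_classes = 5L, ...)

tiny_input <- function(seed = 1) {
  set.seed(seed)
  array(runif(16 * 8 * 8), c(16, 8, 8))
}

# a smooth blob volume for interpolation-tolerance checks
smooth_phantom <- function(shape = c(4L, 24L, 24L)) {
  h <- (seq_len(shape[2]) - (shape[2] + 1) / 2)
  w <- (seq_len(shape[3]) - (shape[3] + 1) / 2)
  sl <- exp(-outer(h^2, w^2, "+") / 50)
  arr <- array(rep(sl, each = shape[1]), shape)
  volume_grid(arr / max(arr), 1, "probability")
}

# small labeled training sample on a 16x16x16 grid (axes divisible by 8)
tiny_labeled_sample <- function(seed = 1, noise = 0.02) {
  set.seed(seed)
  lab <- array(0L, c(16, 16, 16))
  lab[3:6, 6:11, 6:11] <- 1L
  lab[10:13, 6:11, 6:11] <- 2L
  vol <- array(0.1 + rnorm(16^3, 0, noise), c(16, 16, 16))
  vol[lab > 0] <- vol[lab > 0] + 0.6
  list(volume = volume_grid(pmin(pmax(vol, 0), 1), 1, "probability"),
       labels = volume_grid(lab, 1, "label"))
}

# exhaustive maximum-total-IoU matching oracle for m, n <= 5
oracle_match <- function(iou, tau) {
  m <- nrow(iou); n <- ncol(iou)
  best <- list(total = 0, pairs = NULL)
  recurse <- function(i, used, pairs, total) {
    if (i > m) {
      if (total > best$total + 1e-12) best <<- list(total = total, pairs = pairs)
      return(invisible(NULL))
    }
    recurse(i + 1L, used, pairs, total)  # leave gt i unmatched
    for (j in seq_len(n)) {
      if (!used[j] && iou[i, j] >= tau) {
        used[j] <- TRUE
        recurse(i + 1L, used, rbind(pairs, c(i, j)), total + iou[i, j])
        used[j] <- FALSE
      }
    }
  }
  if (m > 0 && n > 0) recurse(1L, rep(FALSE, n), NULL, 0)
  best
}

# random disjoint 1D instance layouts embedded in a (len,1,1) grid
random_layout <- function(n_inst, len = 40L) {
  arr <- array(0L, c(len, 1L, 1L))
  if (n_inst == 0L) return(arr)
  starts <- sort(sample.int(len - 3L, n_inst))
  for (i in seq_len(n_inst)) {
    a <- starts[i]
    b <- min(len, a + sample(2:6, 1))
    arr[a:b, 1, 1] <- i
  }
  arr
}
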