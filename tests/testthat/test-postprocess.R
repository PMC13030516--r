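test_that("binarization uses a strict threshold", {
  expect_equal(sum(binarize(array(0.4, c(3, 3, 3)))), 0)
  expect_equal(sum(binarize(array(0.9, c(3, 3, 3)))), 27)
  expect_equal(sum(binarize(array(0.5, c(3, 3, 3)))), 0)  # ties -> background
})

test_that("connected components are 26-connected, filtered and depth-sorted", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0))
  inst <- extract_instances(binarize(array(as.double(ph$labels$data > 0),
                                           dim(ph$labels$data)), 0.5),
                            min_fragment = 50L)
  expect_equal(inst$n, nrow(ph$centroids))
  expect_true(all(diff(inst$table$d) > 0))
  # a small speck is removed
  m <- array(0L, c(20, 20, 20))
  m[2:8, 2:8, 2:8] <- 1L
  m[15, 15, 15] <- 1L
  inst2 <- extract_instances(m, min_fragment = 200L)
  expect_equal(inst2$n, 1L)
  # a single diagonal voxel bridges two blobs under 26-connectivity
  b <- array(0L, c(12, 8, 8))
  b[2:4, 2:4, 2:4] <- 1L
  b[6:8, 6:8, 6:8] <- 1L
  b[5, 5, 5] <- 1L  # touches both only diagonally
  inst3 <- extract_instances(b, min_fragment = 1L)
  expect_equal(inst3$n, 1L)
  # without the bridge they separate
  b[5, 5, 5] <- 0L
  expect_equal(extract_instances(b, min_fragment = 1L)$n, 2L)
})

test_that("component labeling agrees with a brute-force flood fill", {
  flood_count <- function(mask) {
    d <- dim(mask)
    seen <- array(FALSE, d)
    cnt <- 0
    for (start in which(mask > 0)) {
      if (seen[start]) next
      cnt <- cnt + 1
      queue <- start
      seen[start] <- TRUE
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        co <- arrayInd(v, d)
        for (dd in -1:1) for (hh in -1:1) for (ww in -1:1) {
          p <- co + c(dd, hh, ww)
          if (all(p >= 1) && all(p <= d)) {
            li <- p[1] + d[1] * (p[2] - 1) + d[1] * d[2] * (p[3] - 1)
            if (mask[li] > 0 && !seen[li]) { seen[li] <- TRUE; queue <- c(queue, li) }
          }
        }
      }
    }
    cnt
  }
  set.seed(16)
  for (trial in 1:5) {
    m <- array(as.integer(runif(6 * 6 * 6) < 0.3), c(6, 6, 6))
    expect_equal(extract_instances(m, min_fragment = 1L)$n, flood_count(m))
  }
})

test_that("heatmap peaks recover centroids with documented tie rules", {
  H <- render_heatmap_target(data.frame(label = 2, d = 5, h = 3, w = 3),
                             K = 3, shape = c(16, 8, 8), sigma = 2)
  peaks <- heatmap_centroids(H$H, c(64, 32, 32), floor_frac = 0.1)
  expect_equal(peaks$label, 2L)
  # peak within 1 voxel of the upsampled centroid (quarter coord 5 -> ~21.5)
  expect_lt(abs(peaks$d - (4 * 5 + 1.5)), 2)
  # all-zero channels are absent; equal maxima take the lowest linear index
  flat <- array(0, c(4, 4, 4, 2))
  flat[, , , 1] <- 1
  p2 <- heatmap_centroids(flat, c(4, 4, 4), floor_frac = 0.1)
  expect_equal(p2$label, 1L)
  expect_equal(unlist(p2[1, c("d", "h", "w")]), c(d = 0, h = 0, w = 0))
})

test_that("voxel assignment matches exhaustive nearest-centroid search", {
  set.seed(17)
  mask <- array(as.integer(runif(12^3) < 0.5), c(12, 12, 12))
  cen <- data.frame(label = c(4L, 7L, 9L),
                    d = c(2, 6, 10), h = c(3, 8, 4), w = c(5, 2, 9))
  out <- assign_voxels(mask, cen)
  idx <- which(mask > 0)
  co <- arrayInd(idx, dim(mask)) - 1L
  for (i in sample(seq_along(idx), 200)) {
    d2 <- (co[i, 1] - cen$d)^2 + (co[i, 2] - cen$h)^2 + (co[i, 3] - cen$w)^2
    expect_equal(out[idx[i]], cen$label[which.min(d2)])
  }
  # a single centroid captures the whole foreground
  one <- assign_voxels(mask, cen[2, ])
  expect_true(all(one[idx] == 7L))
  # equidistant voxel goes to the more cranial centroid
  m2 <- array(0L, c(9, 3, 3)); m2[5, 2, 2] <- 1L
  two <- data.frame(label = c(1L, 2L), d = c(2, 6), h = c(1, 1), w = c(1, 1))
  expect_equal(assign_voxels(m2, two)[5, 2, 2], 1L)
  # assignment partitions the foreground exactly
  expect_true(all(out[idx] > 0))
  expect_true(all(out[-idx] == 0))
  expect_warning(assign_voxels(mask, cen[0, ]), "unassigned")
})

make_inst <- function(raw, conf, d = seq_along(raw)) {
  tab <- data.frame(instance = seq_along(raw), size = 300L, d = d,
                    h = 0, w = 0, confidence = conf, raw_id = raw,
                    id = NA_integer_)
  structure(list(n = length(raw), shape = c(8L, 8L, 8L),
                 map = array(0L, c(8, 8, 8)), table = tab),
            class = "instance_set")
}

test_that("sequence enforcement resolves duplicates and gaps around the anchor", {
  # duplicates: highest-confidence instance keeps its id
  r <- enforce_sequence(make_inst(c(5L, 5L, 7L), c(0.9, 0.6, 0.8)))
  expect_equal(r$table$id, c(5L, 6L, 7L))
  # already continuous: unchanged
  expect_equal(enforce_sequence(make_inst(c(3L, 4L, 5L), c(0.5, 0.5, 0.5)))$table$id,
               c(3L, 4L, 5L))
  # gap: anchor keeps its id, others renumber around it
  expect_equal(enforce_sequence(make_inst(c(3L, 5L, 6L), c(0.9, 0.5, 0.5)))$table$id,
               c(3L, 4L, 5L))
  expect_equal(enforce_sequence(make_inst(c(3L, 5L, 6L), c(0.5, 0.9, 0.5)))$table$id,
               c(4L, 5L, 6L))
})

test_that("randomized corrupted sequences agree with the enumeration oracle", {
  # oracle: over all contiguous runs inside 1..K, keep the one whose id for
  # the anchor (highest-confidence instance) is closest to its raw id
  oracle_ids <- function(raw, conf, K = 24L) {
    n <- length(raw)
    anchor <- which.max(conf)
    starts <- 1:(K - n + 1)
    dev <- abs((starts + anchor - 1) - raw[anchor])
    r <- starts[which.min(dev)]
    r + seq_len(n) - 1L
  }
  set.seed(18)
  for (trial in 1:1000) {
    n <- sample(1:8, 1)
    raw <- sample(1:24, n, replace = TRUE)
    conf <- runif(n)
    got <- enforce_sequence(make_inst(raw, conf))$table$id
    # one-to-one, contiguous, within range
    expect_false(any(duplicated(got)))
    expect_true(all(diff(got) == 1))
    expect_true(all(got >= 1 & got <= 24))
    expect_equal(got, oracle_ids(raw, conf))
    # anchor stability whenever its raw id admits a feasible run
    anchor <- which.max(conf)
    if (raw[anchor] - (anchor - 1) >= 1 && raw[anchor] + (n - anchor) <= 24)
      expect_equal(got[anchor], raw[anchor])
  }
})

test_that("oracle-grade outputs are recovered exactly end to end", {
  for (fl in c(1L, 4L)) {
    ph <- generate_phantom(phantom_spec(noise_sd = 0, first_level = fl))
    lab <- ph$labels$data
    prob <- array(0.05, dim(lab)); prob[lab > 0] <- 0.95
    cq <- data.frame(label = ph$centroids$label,
                     d = coords_to_quarter(ph$centroids$d),
                     h = coords_to_quarter(ph$centroids$h),
                     w = coords_to_quarter(ph$centroids$w))
    H <- render_heatmap_target(cq, 24, dim(lab) %/% 4L)
    res <- assemble_prediction(prob, H$H, K = 24, min_fragment = 50L)
    expect_identical(res$labels, array(lab, dim(lab)))
    # ids form a contiguous run starting at the first level
    expect_equal(res$instances$table$id,
                 seq(fl, length.out = nrow(ph$centroids)))
  }
})

test_that("inference is deterministic", {
  cfg <- tiny_net()
  model <- list(config = cfg, params = init_params(cfg, 31))
  v <- volume_grid(array(runif(16 * 8 * 8), c(16, 8, 8)), 1, "probability")
  a <- infer_volume(v, model, patch_shape = c(16L, 8L, 8L), min_fragment = 10L)
  b <- infer_volume(v, model, patch_shape = c(16L, 8L, 8L), min_fragment = 10L)
  expect_identical(a$labels$data, b$labels$data)
  expect_identical(a$centroids, b$centroids)
})
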