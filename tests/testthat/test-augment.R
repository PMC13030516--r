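test_that("weak geometry sampling is deterministic and respects bounds", {
  a <- sample_weak_geometry(123)
  b <- sample_weak_geometry(123)
  expect_identical(a, b)
  expect_true(abs(a$rot_xy_deg) <= 22.5)
  expect_error(geometry_record(rot_xy_deg = 30), "22.5")
})

test_that("flip probabilities and rotation distribution match the policy", {
  recs <- lapply(1:10000, sample_weak_geometry)
  fh <- mean(vapply(recs, `[[`, logical(1), "flip_h"))
  fw <- mean(vapply(recs, `[[`, logical(1), "flip_w"))
  fd <- mean(vapply(recs, `[[`, logical(1), "flip_d"))
  expect_lt(abs(fh - 0.5), 0.02)
  expect_lt(abs(fw - 0.5), 0.02)
  expect_lt(abs(fd - 0.25), 0.02)
  ang <- vapply(recs, `[[`, numeric(1), "rot_xy_deg")
  ks <- suppressWarnings(stats::ks.test(ang, "punif", -22.5, 22.5))
  expect_gt(ks$p.value, 0.01)
})

test_that("geometric transforms compose and invert as expected", {
  v <- smooth_phantom()
  # identity record
  expect_equal(apply_geometry(v, geometry_record())$data, v$data)
  # double flip is the identity
  g <- geometry_record(flip_h = TRUE)
  expect_equal(apply_geometry(apply_geometry(v, g), g)$data, v$data)
  # rotate +10 then -10 returns the original within interpolation tolerance
  r1 <- apply_geometry(v, geometry_record(rot_xy_deg = 10))
  r2 <- apply_geometry(r1, geometry_record(rot_xy_deg = -10))
  inner <- v$data[, 5:20, 5:20]
  inner2 <- r2$data[, 5:20, 5:20]
  expect_lt(max(abs(inner - inner2)), 0.05)
})

test_that("labels are flipped exactly and never interpolated", {
  s <- tiny_labeled_sample()
  g <- geometry_record(flip_d = TRUE, flip_h = TRUE)
  out <- apply_geometry(s$labels, g)
  ref <- s$labels$data[16:1, 16:1, ]
  expect_identical(out$data, ref)
  gr <- geometry_record(rot_xy_deg = 15)
  rot <- apply_geometry(s$labels, gr)
  expect_true(all(unique(as.vector(rot$data)) %in%
                    unique(as.vector(s$labels$data))))
})

test_that("geometry roughly preserves per-instance voxel counts", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0))
  g <- geometry_record(flip_h = TRUE, rot_xy_deg = 18)
  rot <- apply_geometry(ph$labels, g)
  for (k in sort(unique(ph$labels$data[ph$labels$data > 0]))) {
    n0 <- sum(ph$labels$data == k)
    n1 <- sum(rot$data == k)
    if (n0 >= 100) expect_lt(abs(n1 - n0) / n0, 0.05)
  }
})

test_that("strong photometric ops are intensity-only with identity cases", {
  v <- smooth_phantom()
  # zero ops -> identity
  p0 <- strong_policy(op_pool = character(0), n_ops_choices = 0L, seed = 1)
  expect_equal(strong_photometric(v, p0)$data, v$data)
  # gamma with unit magnitude -> identity
  pg <- strong_policy(op_pool = "gamma", n_ops_choices = 1L,
                      magnitude_ranges = list(gamma = c(1, 1)), seed = 1)
  expect_equal(strong_photometric(v, pg)$data, v$data, tolerance = 1e-12)
  # label maps are rejected
  lab <- volume_grid(array(1L, c(4, 4, 4)), 1, "label")
  expect_error(strong_photometric(lab, strong_policy(seed = 1)), "label")
  # deterministic per seed, shape-preserving, clamped
  ps <- strong_policy(seed = 42)
  a <- strong_photometric(v, ps)
  b <- strong_photometric(v, ps)
  expect_identical(a$data, b$data)
  expect_identical(dim(a$data), dim(v$data))
  expect_true(min(a$data) >= 0 && max(a$data) <= 1)
})

test_that("unlabeled views share one geometry and differ only photometrically", {
  v <- smooth_phantom(c(8L, 24L, 24L))
  views <- build_unlabeled_views(v, seed = 7)
  expect_identical(dim(views$weak$data), dim(views$strong$data))
  # weak view equals plain geometry application
  expect_equal(views$weak$data, apply_geometry(v, views$geometry)$data)
  # a zero-op policy makes strong == weak (pure composition)
  views0 <- build_unlabeled_views(v, seed = 7,
                                  policy = strong_policy(op_pool = character(0),
                                                         n_ops_choices = 0L))
  expect_equal(views0$strong$data, views0$weak$data)
  # reproducible pair
  again <- build_unlabeled_views(v, seed = 7)
  expect_identical(again$strong$data, views$strong$data)
})

test_that("labeled augmentation applies one geometry to both and labels stay clean", {
  s <- tiny_labeled_sample()
  out <- augment_labeled(s$volume, s$labels, seed = 5)
  expect_identical(dim(out$volume$data), dim(out$labels$data))
  expect_true(all(unique(as.vector(out$labels$data)) %in%
                    unique(as.vector(s$labels$data))))
  expect_equal(out$labels$data, apply_geometry(s$labels, out$geometry)$data)
})

test_that("labeled photometric branches fire at the stated rates with mild scaling in range", {
  s <- tiny_labeled_sample()
  small_v <- volume_grid(s$volume$data[1:8, 1:8, 1:8], 1, "probability")
  small_l <- volume_grid(s$labels$data[1:8, 1:8, 1:8], 1, "label")
  branches <- vapply(1:10000, function(i)
    augment_labeled(small_v, small_l, seed = i)$branch, character(1))
  expect_lt(abs(mean(branches == "strong") - 0.5), 0.02)
  # mild branch fires with p = 0.5 among the non-strong half
  expect_lt(abs(mean(branches == "mild") - 0.25), 0.02)
  # mild branch: per-voxel ratio is a constant within [0.95, 1.05]
  i <- which(branches == "mild")[1]
  out <- augment_labeled(small_v, small_l, seed = i)
  base <- apply_geometry(small_v, out$geometry)$data
  ok <- base > 0.01 & out$volume$data < 1
  ratio <- out$volume$data[ok] / base[ok]
  expect_lt(diff(range(ratio)), 1e-9)
  expect_true(all(ratio >= 0.95 & ratio <= 1.05))
})
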