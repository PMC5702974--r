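test_that("configuration rejects out-of-range thresholds", {
  expect_error(tract_config(fa_threshold = 0), "thresholds")
  expect_error(tract_config(inner_product_threshold = 1.5), "thresholds")
  expect_error(tract_config(max_length_mm = -1), "positive")
})

test_that("a uniform field yields a straight line capped by mask or length", {
  dims <- c(64L, 8L, 8L); vs <- c(0.5, 0.5, 0.5)
  tens <- synthetic_tensor_field(dims, c(1, 0, 0), c(0, 0, 1))
  mask <- array(TRUE, dims)
  tk <- fact_track(tens, c(32L, 4L, 4L), mask, tract_config(), vs)
  expect_equal(diff(range(tk$points[, 2])), 0)
  expect_equal(diff(range(tk$points[, 3])), 0)
  expect_setequal(unname(tk$termination_reason), "mask")
  expect_equal(tk$length_mm, 31.5, tolerance = 0.5)  # grid extent minus seed offset

  # long grid: cap dominates
  dims2 <- c(256L, 8L, 8L)
  tens2 <- synthetic_tensor_field(dims2, c(1, 0, 0), c(0, 0, 1))
  tk2 <- fact_track(tens2, c(128L, 4L, 4L), array(TRUE, dims2),
                    tract_config(max_length_mm = 40), vs)
  expect_setequal(unname(tk2$termination_reason), "length")
  expect_lte(tk2$length_mm, 40 + max(vs))
})

test_that("an abrupt 90-degree rotation stops the track with reason angle", {
  dims <- c(40L, 8L, 8L); vs <- c(1, 1, 1)
  e1 <- matrix(rep(c(1, 0, 0), each = prod(dims)), ncol = 3)
  idx <- arrayInd(seq_len(prod(dims)), dims)
  e1[idx[, 1] > 20, ] <- matrix(rep(c(0, 1, 0), each = sum(idx[, 1] > 20)), ncol = 3)
  tens <- synthetic_tensor_field(dims, e1, c(0, 0, 1))
  tk <- fact_track(tens, c(10L, 4L, 4L), array(TRUE, dims),
                   tract_config(max_length_mm = 100), vs)
  expect_equal(unname(tk$termination_reason[["forward"]]), "angle")
  expect_lt(max(tk$points[, 1]), 21)
})

test_that("a circumferential field produces tracks of the seed's curvature radius", {
  dims <- c(64L, 64L, 5L); vs <- c(0.5, 0.5, 0.5)
  idx <- arrayInd(seq_len(prod(dims)), dims)
  co <- sweep(idx, 2, (dims + 1) / 2)
  co <- sweep(co, 2, vs, `*`)
  r <- sqrt(co[, 1]^2 + co[, 2]^2)
  mask <- array(r >= 10 & r <= 14, dims)
  e1 <- cbind(-co[, 2], co[, 1], 0) / pmax(r, 1e-9)
  tens <- synthetic_tensor_field(dims, e1[mask, ], c(0, 0, 1),
                                 index = which(mask))
  sv <- idx[as.vector(mask), , drop = FALSE][which.min(abs(r[mask] - 12)), ]
  tk <- fact_track(tens, sv, mask, tract_config(), vs)
  seed_r <- sqrt(sum(((sv[1:2] - (dims[1:2] + 1) / 2) * vs[1:2])^2))
  # Kasa circle fit to the emitted polyline
  P <- tk$points[, 1:2]
  A <- cbind(2 * P[, 1], 2 * P[, 2], 1)
  sol <- qr.solve(A, P[, 1]^2 + P[, 2]^2)
  R_fit <- sqrt(sol[3] + sol[1]^2 + sol[2]^2)
  expect_lt(abs(R_fit - seed_r), sqrt(sum(vs^2)))
})

test_that("tracks stay inside the mask and every end carries one reason", {
  ph <- coarse_phantom()
  an <- coarse_analysis()
  mask <- ph$geometry$myocardium
  seeds <- which(mask, arr.ind = TRUE)
  set.seed(3)
  seeds <- seeds[sample.int(nrow(seeds), 25), , drop = FALSE]
  tks <- track_many(an$tensors, seeds, mask, tract_config(),
                    ph$spec$voxel_size)
  vs <- ph$spec$voxel_size
  for (tk in tks) {
    expect_true(all(tk$termination_reason %in% c("fa", "angle", "mask", "length")))
    expect_equal(length(tk$termination_reason), 2L)
    expect_lte(tk$length_mm, tract_config()$max_length_mm + max(vs))
    if (nrow(tk$points) < 2) next
    # each segment lies inside one voxel, so its midpoint must be in-mask
    mids <- (tk$points[-1, , drop = FALSE] +
               tk$points[-nrow(tk$points), , drop = FALSE]) / 2
    vi <- pmin(pmax(ceiling(sweep(mids, 2, vs, `/`)), 1),
               matrix(rep(dim(mask), each = nrow(mids)), ncol = 3))
    expect_true(all(mask[vi]))
  }
})

test_that("tracks align with the ground-truth fibre field on the phantom", {
  ph <- coarse_phantom()
  an <- coarse_analysis()
  tr <- ph$truth
  mask <- ph$geometry$myocardium
  fmap <- integer(prod(dim(mask))); fmap[tr$index] <- seq_along(tr$index)
  eq <- an$frames$slices[["equatorial"]]
  seeds <- which(mask[, , eq], arr.ind = TRUE)
  set.seed(7)
  seeds <- cbind(seeds[sample.int(nrow(seeds), 15), , drop = FALSE], eq)
  vs <- ph$spec$voxel_size
  errs <- c()
  for (i in seq_len(nrow(seeds))) {
    tk <- fact_track(an$tensors, seeds[i, ], mask, tract_config(), vs)
    if (nrow(tk$points) < 3) next
    segs <- diff(tk$points)
    mids <- (tk$points[-1, , drop = FALSE] + tk$points[-nrow(tk$points), , drop = FALSE]) / 2
    vi <- pmin(pmax(ceiling(sweep(mids, 2, vs, `/`)), 1),
               matrix(rep(dim(mask), each = nrow(mids)), ncol = 3))
    li <- vi[, 1] + (vi[, 2] - 1) * dim(mask)[1] +
      (vi[, 3] - 1) * dim(mask)[1] * dim(mask)[2]
    ti <- fmap[li]
    ok <- ti > 0 & sqrt(rowSums(segs^2)) > 1e-6
    if (!any(ok)) next
    u <- segs[ok, , drop = FALSE] / sqrt(rowSums(segs[ok, , drop = FALSE]^2))
    f <- tr$fibre[ti[ok], , drop = FALSE]
    errs <- c(errs, acos(pmin(1, abs(rowSums(u * f)))) * 180 / pi)
  }
  expect_gt(length(errs), 50)
  expect_lt(mean(errs), 5)
})

test_that("seed regions are named, deterministic, and warn when empty", {
  ph <- coarse_phantom()
  an <- coarse_analysis()
  s1 <- seed_regions(ph$geometry$zone_map, an$frames, n_per = 10L, rng_seed = 4L)
  s2 <- seed_regions(ph$geometry$zone_map, an$frames, n_per = 10L, rng_seed = 4L)
  expect_identical(s1, s2)
  expect_setequal(names(s1), c("rv_rightmost", "rv_anterior", "rv_posterior",
                               "septal_rv"))
  expect_true(all(vapply(s1, nrow, 1L) > 0))
  # LV-only phantom: RV sets empty with a warning
  sp <- coarse_spec(rv_crescent_extent = 0)
  ph0 <- build_phantom(sp)
  fr0 <- build_frames(ph0$geometry$zone_map, sp$voxel_size)
  # LV-only phantom has neither RV free wall nor septum
  w <- capture_warnings(s0 <- seed_regions(ph0$geometry$zone_map, fr0))
  expect_true(any(grepl("RV", w)))
  expect_equal(nrow(s0$rv_rightmost), 0L)
})

test_that("track TSV export writes one row per point", {
  dims <- c(16L, 4L, 4L)
  tens <- synthetic_tensor_field(dims, c(1, 0, 0), c(0, 0, 1))
  tk <- fact_track(tens, c(8L, 2L, 2L), array(TRUE, dims), tract_config(),
                   c(1, 1, 1))
  f <- withr::local_tempfile()
  write_tracks(list(tk), f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), nrow(tk$points))
  expect_equal(names(tab), c("track", "point", "x", "y", "z"))
})
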