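frame_x <- local_frame(c(1, 0, 0))  # circ = +y, long = +z, radial = +x

test_that("helical angle follows the stated convention", {
  expect_equal(helical_angle(frame_x$circumferential, frame_x), 0)
  expect_equal(helical_angle(frame_x$longitudinal, frame_x), 90)
  v <- (frame_x$circumferential + frame_x$longitudinal) / sqrt(2)
  expect_equal(helical_angle(v, frame_x), 45, tolerance = 1e-9)
  expect_equal(helical_angle(-v, frame_x), 45, tolerance = 1e-9)
  # nearly radial: projection degenerate
  v2 <- c(cos(1 * pi / 180), sin(1 * pi / 180), 0)  # 1 deg off radial
  expect_true(is.na(helical_angle(v2, frame_x)))
})

test_that("intrusion angle follows the stated convention", {
  expect_equal(intrusion_angle(frame_x$circumferential, frame_x), 0)
  expect_equal(intrusion_angle(frame_x$longitudinal, frame_x), 0)
  expect_equal(intrusion_angle(frame_x$radial_outward, frame_x), 90)
  expect_equal(intrusion_angle(-frame_x$radial_outward, frame_x), 90)
  # 10-degree outward tilt from the circumferential direction
  v <- cos(10 * pi / 180) * frame_x$circumferential +
    sin(10 * pi / 180) * frame_x$radial_outward
  expect_equal(intrusion_angle(v, frame_x), 10, tolerance = 1e-9)
  expect_equal(abs(intrusion_angle(-v, frame_x)), 10, tolerance = 1e-9)
})

test_that("E3 angle respects both reference planes", {
  expect_equal(e3_angle(frame_x$radial_outward, frame_x), 90)
  expect_equal(e3_angle(frame_x$circumferential, frame_x), 0)
  expect_equal(e3_angle(frame_x$longitudinal, frame_x), 0)
  expect_equal(e3_angle(frame_x$radial_outward, frame_x,
                        reference = "radial_longitudinal"), 0)
  expect_equal(e3_angle(frame_x$circumferential, frame_x,
                        reference = "radial_longitudinal"), 90)
  v <- cos(25 * pi / 180) * frame_x$circumferential +
    sin(25 * pi / 180) * frame_x$radial_outward
  expect_equal(abs(e3_angle(v, frame_x)), 25, tolerance = 1e-9)
})

test_that("all three angles are antipodally invariant", {
  set.seed(101)
  V <- runit(10000)
  fr <- list(circumferential = matrix(rep(c(0, 1, 0), each = 10000), ncol = 3),
             longitudinal = matrix(rep(c(0, 0, 1), each = 10000), ncol = 3),
             radial = matrix(rep(c(1, 0, 0), each = 10000), ncol = 3))
  h1 <- myoarch:::.helical_angles(V, fr); h2 <- myoarch:::.helical_angles(-V, fr)
  expect_equal(h1, h2)
  i1 <- myoarch:::.intrusion_angles(V, fr); i2 <- myoarch:::.intrusion_angles(-V, fr)
  expect_equal(i1, i2)
  for (ref in c("tangential", "radial_longitudinal")) {
    e1 <- myoarch:::.e3_angles(V, fr, ref); e2 <- myoarch:::.e3_angles(-V, fr, ref)
    expect_equal(e1, e2)
  }
  # orthogonality coupling: radial e1 -> helical undefined, intrusion 90;
  # in-plane e1 -> intrusion 0
  expect_true(all(abs(i1[abs(V[, 1]) > 0.99999]) > 89))
  inpl <- abs(V[, 1]) < 1e-6
  if (any(inpl)) expect_true(all(abs(i1[inpl]) < 1e-3))
})

test_that("noiseless phantom recovery reproduces the prescribed profiles", {
  # piecewise-constant thirds: binned medians recover the plateau values
  sp <- coarse_spec(helix_profile = profile_thirds(c(40, 0, -40)))
  ph <- build_phantom(sp)
  an <- analyse_subject(ph$dwi, ph$scheme, ph$geometry$zone_map, sp$voxel_size)
  prof <- an$summary$profile
  hel <- prof[prof$angle_type == "helical" & prof$region == "lv", ]
  expect_lt(max(abs(hel$median_deg[hel$depth_bin %in% 1:3] - 40)), 1)
  expect_lt(max(abs(hel$median_deg[hel$depth_bin %in% 5:6] - 0)), 1)
  expect_lt(max(abs(hel$median_deg[hel$depth_bin %in% 8:10] + 40)), 1)

  # linear ramp at the acquisition-scale grid: binned medians track the
  # ramp within a degree away from its ends
  spr <- phantom_spec(helix_profile = profile_ramp(60, -60))
  phr <- build_phantom(spr)
  anr <- analyse_subject(phr$dwi, phr$scheme, phr$geometry$zone_map, spr$voxel_size)
  pr <- anr$summary$profile
  hl <- pr[pr$angle_type == "helical" & pr$region == "lv", ]
  centres <- (hl$bin_lo + hl$bin_hi) / 2
  expect_lt(max(abs(hl$median_deg - (60 - 1.2 * centres))[hl$depth_bin %in% 2:9]), 1)
})

test_that("round trip through synthesis and fit is exact at the truth frames", {
  sp <- coarse_spec(helix_profile = profile_ramp(60, -60), intrusion_offset = 7,
                    e3_profile = profile_thirds(c(-30, 10, 45)))
  ph <- build_phantom(sp)
  tens <- fit_tensor(ph$dwi, ph$scheme, ph$geometry$myocardium)
  expect_identical(tens$index, ph$truth$index)
  ta <- truth_frame_angles(ph$truth, tens$e1, tens$e3)
  ok <- ta$frame_valid
  expect_lt(max(abs(ta$helical - ta$helix_deg)[ok]), 1e-6)
  expect_lt(max(abs(abs(ta$intrusion) - 7)[ok]), 1e-6)
  expect_lt(max(abs(ta$e3 - ta$e3_deg)[ok]), 1e-6)
})

test_that("pooled histograms are density-normalized and profiles sane", {
  an <- coarse_analysis()
  h <- an$summary$histograms
  for (reg in unique(h$region)) for (at in unique(h$angle_type)) {
    d <- h$density[h$region == reg & h$angle_type == at]
    if (length(d)) expect_equal(sum(d), 1, tolerance = 1e-9)
  }
  # E3 is pooled but never depth-binned
  expect_false("e3" %in% an$summary$profile$angle_type)
  # excluded zones contribute nothing to the pooled statistics
  used <- an$maps[!an$maps$excluded, ]
  expect_false(any(used$zone %in% excluded_zones()))
})

test_that("uniform angles produce a statistically flat histogram", {
  set.seed(55)
  n <- 1e4
  v <- runif(n, -90, 90)
  maps <- data.frame(index = seq_len(n), level = "equatorial", zone = 11L,
                     region = "lv", excluded = FALSE, sector = 1L,
                     depth_pct = runif(n, 0, 100), fa = 0.67,
                     helical = v, intrusion = 0, e3 = 0)
  class(maps) <- c("angle_maps", "data.frame")
  s <- suppressWarnings(pool_and_bin(maps))
  cnt <- s$histograms$count[s$histograms$region == "lv" &
                              s$histograms$angle_type == "helical"]
  p <- stats::chisq.test(cnt)$p.value
  expect_gt(p, 0.001)
  prof <- s$profile[s$profile$angle_type == "helical", ]
  expect_true(all(abs(prof$median_deg) < 15))
})

test_that("all-zero angles collapse to a single histogram bin and zero medians", {
  n <- 500
  maps <- data.frame(index = seq_len(n), level = "equatorial", zone = 11L,
                     region = "lv", excluded = FALSE, sector = 1L,
                     depth_pct = runif(n, 0, 100), fa = 0.67,
                     helical = 0, intrusion = 0, e3 = 0)
  class(maps) <- c("angle_maps", "data.frame")
  s <- suppressWarnings(pool_and_bin(maps))
  hh <- s$histograms[s$histograms$region == "lv" &
                       s$histograms$angle_type == "helical", ]
  expect_equal(sum(hh$count > 0), 1L)
  prof <- s$profile[s$profile$region == "lv" & s$profile$angle_type == "helical", ]
  expect_true(all(prof$median_deg[prof$n >= 10] == 0))
})
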