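test_that("long-axis alignment is identity on an aligned phantom", {
  geom <- coarse_phantom()$geometry
  aln <- align_long_axis(geom$lv_mask, geom$voxel_size)
  expect_lt(aln$angle_deg, 1)
})

test_that("a known rotation is recovered and inverted within a degree", {
  geom <- coarse_phantom()$geometry
  R30 <- myoarch:::rotation_about(c(1, 0, 0), 30)
  rot <- rotate_volume_nn(geom$lv_mask, R30, geom$voxel_size)
  aln <- align_long_axis(rot, geom$voxel_size)
  resid <- aln$rotation %*% R30   # should compose to identity
  ang <- acos(min(1, max(-1, (sum(diag(resid)) - 1) / 2))) * 180 / pi
  expect_lt(ang, 1)
})

test_that("alignment refuses masks that are too small", {
  m <- array(FALSE, c(10, 10, 10))
  expect_error(align_long_axis(m), "100 voxels")
  m[5, 5, 5] <- TRUE
  expect_error(align_long_axis(m), "100 voxels")
})

test_that("slice selection returns the middle of each third", {
  m <- array(FALSE, c(4, 4, 30))
  m[2, 2, 1:30] <- TRUE
  expect_equal(unname(select_slices(m)), c(5L, 15L, 25L))  # indices 1-based
  m3 <- array(FALSE, c(4, 4, 3)); m3[2, 2, 1:3] <- TRUE
  expect_equal(unname(select_slices(m3)), c(1L, 2L, 3L))
  m2 <- array(FALSE, c(4, 4, 2)); m2[2, 2, 1:2] <- TRUE
  expect_error(select_slices(m2), "extent")
})

test_that("sectorization divides an annulus into equal 5.625-degree bins", {
  n <- 129
  xy <- expand.grid(i = 1:n, j = 1:n)
  r <- sqrt((xy$i - 65)^2 + (xy$j - 65)^2)
  ann <- matrix(r >= 40 & r <= 60, n, n)
  sec <- sectorize(ann, n_lv = 64L)
  ids <- sec[!is.na(sec)]
  expect_equal(sort(unique(ids)), 1:64)
  # each sector's angular span is 360/64 degrees
  idx <- which(!is.na(sec), arr.ind = TRUE)
  th <- (atan2(idx[, 2] - 65, idx[, 1] - 65) * 180 / pi) %% 360
  for (k in c(2, 17, 40)) {
    spank <- th[ids == k]
    expect_lt(max(spank) - min(spank), 5.625 + 1e-9)
  }
  # quadrant assignment at n_lv = 4
  sec4 <- sectorize(ann, n_lv = 4L)
  expect_equal(sec4[115, 65], 1L)  # +x
  expect_equal(sec4[65, 115], 2L)  # +y
  expect_equal(sec4[15, 65], 3L)   # -x
})

test_that("an open contour is rejected", {
  n <- 65
  xy <- expand.grid(i = 1:n, j = 1:n)
  r <- sqrt((xy$i - 33)^2 + (xy$j - 33)^2)
  half <- matrix(r >= 15 & r <= 25 & xy$i >= 33, n, n)  # half-annulus
  expect_error(sectorize(half, centre = c(0, 0), n_lv = 64L), "open contour")
})

test_that("RV sector count follows the crescent extent", {
  # crescent of 90 degrees at the default sector width -> 90 / 5.625 = 16
  # sectors (crescent aligned to the bin layout)
  n <- 129
  xy <- expand.grid(i = 1:n, j = 1:n)
  dx <- xy$i - 65; dy <- xy$j - 65
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  cres <- matrix(r >= 50 & r <= 58 & th >= 0 & th < pi / 2, n, n)
  sec <- sectorize(cres, centre = c(0, 0), n_lv = 64L, closed = FALSE)
  expect_equal(length(unique(sec[!is.na(sec)])), 16L)
})

test_that("tangent-plane normals are exact on cylinder, sphere and cone", {
  # cylinder: normal equals the radial direction
  ctr <- c(0, 0, 0)
  R <- 20
  for (ak in c(0.1, 1.2, 3.9)) {
    d <- 2 * pi / 64
    p2 <- c(R * cos(ak - d / 2), R * sin(ak - d / 2), 0)
    p1 <- c(R * cos(ak + d / 2), R * sin(ak + d / 2), 2)
    p3 <- c(R * cos(ak + d / 2), R * sin(ak + d / 2), -2)
    pl <- epicardial_tangent_plane(p1, p2, p3, ctr)
    expect_false(pl$fallback)
    rad <- c(cos(ak), sin(ak), 0)
    expect_lt(acos(min(1, sum(pl$normal * rad))) * 180 / pi, 1)
  }
  # sphere: the normal points radially away from the centre
  th0 <- 0.7; dphi <- 0.05; dz <- 0.02
  sph <- function(phi, lat) 20 * c(cos(lat) * cos(phi), cos(lat) * sin(phi), sin(lat))
  p2 <- sph(th0 - dphi, 0)
  p1 <- sph(th0 + dphi, dz); p3 <- sph(th0 + dphi, -dz)
  pl <- epicardial_tangent_plane(p1, p2, p3, c(0, 0, 0))
  rad <- c(cos(th0), sin(th0), 0)
  ang <- acos(min(1, sum(pl$normal * rad)))
  expect_lt(ang * 180 / pi, 2)
  # cone with half-angle 10 degrees: normal tilts 10 degrees off horizontal
  half <- 10 * pi / 180
  cone <- function(phi, z) c((30 - z * tan(half)) * cos(phi),
                             (30 - z * tan(half)) * sin(phi), z)
  p2 <- cone(-0.05, 0); p1 <- cone(0.05, 2); p3 <- cone(0.05, -2)
  pl <- epicardial_tangent_plane(p1, p2, p3, c(0, 0, 0))
  tilt <- asin(abs(pl$normal[3])) * 180 / pi
  expect_equal(tilt, 10, tolerance = 0.2)
})

test_that("collinear points fall back to the flagged in-slice construction", {
  p <- c(10, 0, 0)
  pl <- epicardial_tangent_plane(p, p + c(0, 0, 1), p + c(0, 0, 2), c(0, 0, 0))
  expect_true(pl$fallback)
  expect_equal(pl$normal, c(1, 0, 0), tolerance = 1e-9)
})

test_that("local frames obey the stated conventions and handedness", {
  fr <- local_frame(c(1, 0, 0))
  expect_equal(fr$longitudinal, c(0, 0, 1))
  expect_equal(fr$radial_outward, c(1, 0, 0))
  expect_equal(fr$circumferential, c(0, 1, 0))  # counterclockwise from base
  # right-handed: circumferential x longitudinal = radial
  expect_equal(myoarch:::cross3(fr$circumferential, fr$longitudinal),
               fr$radial_outward, tolerance = 1e-12)
  # tilted normal: longitudinal stays unit and inside plane A
  fr2 <- local_frame(c(sin(80 * pi / 180), 0, cos(80 * pi / 180)))
  expect_equal(sqrt(sum(fr2$longitudinal^2)), 1, tolerance = 1e-12)
  expect_lt(abs(sum(fr2$longitudinal * fr2$radial_outward)), 1e-12)
  expect_error(local_frame(c(0, 0, 1)), "apex cap")
})

test_that("frame orthonormality holds at every analysed sector", {
  fra <- coarse_analysis()$frames
  s <- fra$sectors[fra$sectors$valid, ]
  C <- cbind(s$cx, s$cy, s$cz); L <- cbind(s$lx, s$ly, s$lz)
  N <- cbind(s$nx, s$ny, s$nz)
  expect_lt(max(abs(rowSums(C * L))), 1e-8)
  expect_lt(max(abs(rowSums(C * N))), 1e-8)
  expect_lt(max(abs(rowSums(L * N))), 1e-8)
  expect_equal(sqrt(rowSums(C^2)), rep(1, nrow(s)), tolerance = 1e-8)
  # right-handedness
  rh <- myoarch:::row_cross(C, L)
  expect_lt(max(abs(rh - N)), 1e-8)
})

test_that("transmural depth is the in-slice radial fraction", {
  fra <- coarse_analysis()$frames
  ph <- coarse_phantom()
  # probe along +y in the equatorial slice: LV free wall
  lev <- "equatorial"
  tab <- fra$sectors[fra$sectors$level == lev & fra$sectors$region == "lv", ]
  k <- tab$sector[which.min(abs((tab$sector - 0.5) * 360 / 64 - 90))]
  row <- tab[tab$sector == k, ]
  ak <- (k - 0.5) * 2 * pi / 64
  mid_r <- (row$r_endo + row$r_epi) / 2
  ctr <- fra$centres[[lev]]
  d <- transmural_depth(fra, lev, "lv",
                        cbind(ctr[1] + c(row$r_endo, mid_r, row$r_epi) * cos(ak),
                              ctr[2] + c(row$r_endo, mid_r, row$r_epi) * sin(ak)))
  # boundary voxel centres sit half a voxel inside the true surfaces
  expect_lt(d[1], 8)
  expect_lt(abs(d[2] - 50), 3)
  expect_gt(d[3], 92)
})

test_that("wall thickness recovers the prescribed wall within a voxel diagonal", {
  an <- coarse_analysis()
  ph <- coarse_phantom()
  diagv <- sqrt(sum(ph$spec$voxel_size[1:2]^2))
  # equatorial LV zones: prescribed 8 mm
  for (z in c(11L, 14L)) {
    th <- wall_thickness(an$frames, ph$geometry$zone_map, z)
    expect_lt(abs(th - ph$spec$lv_wall_thickness), diagv)
  }
  for (z in c(15L, 16L)) {
    th <- wall_thickness(an$frames, ph$geometry$zone_map, z)
    expect_lt(abs(th - ph$spec$rv_wall_thickness), diagv)
  }
  expect_error(wall_thickness(an$frames, ph$geometry$zone_map, 10L), "excluded")
  expect_error(wall_thickness(an$frames, ph$geometry$zone_map, 17L), "excluded")
})

test_that("a rigid rotation leaves depth and thickness essentially unchanged", {
  ph <- coarse_phantom()
  zm <- ph$geometry$zone_map
  an <- coarse_analysis()
  R30 <- myoarch:::rotation_about(c(0, 1, 0), 30)
  zr <- rotate_volume_nn(zm, R30, ph$spec$voxel_size)
  lvr <- array(zr > 0 & !(zr %in% zone_definitions()$zone[zone_definitions()$region == "rv"]),
               dim(zr))
  aln <- align_long_axis(lvr, ph$spec$voxel_size)
  ang <- acos(min(1, max(-1, (sum(diag(aln$rotation %*% R30)) - 1) / 2))) * 180 / pi
  expect_lt(ang, 2)
  zb <- rotate_volume_nn(zr, t(R30), ph$spec$voxel_size)
  frb <- build_frames(zb, ph$spec$voxel_size)
  for (z in c(11L, 14L)) {
    t0 <- wall_thickness(an$frames, zm, z)
    t1 <- wall_thickness(frb, zb, z)
    expect_lt(abs(t1 - t0), sqrt(sum(ph$spec$voxel_size^2)))
  }
})
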