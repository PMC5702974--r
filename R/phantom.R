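#' Transmural angle profiles
#'
#' Helper constructors for the per-region maps from transmural depth
#' (0 = sub-endocardium, 1 = sub-epicardium) to a prescribed angle in
#' degrees. `profile_constant()` is flat, `profile_thirds()` is
#' piecewise-constant over the endocardial / midwall / epicardial thirds,
#' and `profile_ramp()` interpolates linearly from endocardium to
#' epicardium.
#'
#' @param value,values,endo,epi angles in degrees; `values` is a length-3
#'   vector `(endocardial, midwall, epicardial)`.
#' @return A function mapping depth in `[0, 1]` to degrees.
#' @export
profile_constant <- function(value) {
  force(value)
  function(depth) rep(value, length(depth))
}

#' @rdname profile_constant
#' @export
profile_thirds <- function(values) {
  stopifnot(length(values) == 3L)
  force(values)
  function(depth) values[pmin(3L, 1L + floor(depth * 3))]
}

#' @rdname profile_constant
#' @export
profile_ramp <- function(endo, epi) {
  force(endo); force(epi)
  function(depth) endo + (epi - endo) * depth
}

# Regional transmural-third median helical angles (degrees) observed in
# porcine ventricles: "control" = normal hearts, "dilated" = chronic
# right-ventricular volume overload from pulmonary valve regurgitation.
.helix_medians <- data.frame(
  group  = rep(c("control", "dilated"), each = 9),
  region = rep(rep(c("lv", "rv", "septum"), each = 3), 2),
  third  = rep(c("endo", "mid", "epi"), 6),
  median_deg = c(
    37.7,  -2.4, -37.1,   # control LV
    33.3,   8.4, -13.3,   # control RV
    33.6,  -6.2, -42.6,   # control septum
    31.0,  -5.8, -35.7,   # dilated LV
    23.2,  -3.1, -15.3,   # dilated RV
    36.4,  -6.9, -41.2)   # dilated septum
)

#' Reference regional helical-angle medians
#'
#' Median helical angles per region and transmural third for normal
#' ("control") and right-ventricular volume-overloaded ("dilated") porcine
#' hearts. These medians parameterize the default phantom ground truth
#' (piecewise-constant over transmural thirds) for parameter-recovery
#' experiments.
#'
#' @param group `"control"` or `"dilated"`; `reference_helix_medians()`
#'   returns the full table when `group` is omitted.
#' @return `reference_helix_medians()`: a data.frame with columns `group`,
#'   `region`, `third`, `median_deg`. `reference_helix_profiles()`: a named
#'   list of depth-profile functions (`lv`, `septum`, `rv`).
#' @export
reference_helix_medians <- function(group = NULL) {
  if (is.null(group)) return(.helix_medians)
  group <- match.arg(group, c("control", "dilated"))
  .helix_medians[.helix_medians$group == group, ]
}

#' @rdname reference_helix_medians
#' @export
reference_helix_profiles <- function(group = c("control", "dilated")) {
  group <- match.arg(group)
  tab <- reference_helix_medians(group)
  take <- function(reg) {
    t3 <- tab[tab$region == reg, ]
    profile_thirds(t3$median_deg[match(c("endo", "mid", "epi"), t3$third)])
  }
  list(lv = take("lv"), septum = take("septum"), rv = take("rv"))
}

.as_region_profiles <- function(p) {
  if (is.function(p)) p <- list(lv = p, septum = p, rv = p)
  stopifnot(is.list(p), all(c("lv", "septum", "rv") %in% names(p)))
  lapply(p[c("lv", "septum", "rv")], match.fun)
}

#' Specify a synthetic biventricular DT-CMR phantom
#'
#' The phantom is an idealized truncated-ellipsoid left-ventricular shell
#' with a thinner crescent-shaped right-ventricular free wall appended over
#' part of the circumference; the shared wall sector is the septum.
#' Ground-truth fibre and sheet-normal fields are prescribed per region as
#' functions of transmural depth, and diffusion-weighted signals follow the
#' single-tensor Stejskal-Tanner model, optionally with Rician noise.
#'
#' @param lv_outer_radii ellipsoid semi-axes of the LV epicardial surface,
#'   mm (x, y, long-axis z).
#' @param lv_wall_thickness LV wall thickness at the equator, mm.
#' @param lv_apex_thickness wall thickness of the apical cap along z, mm.
#' @param rv_wall_thickness RV free-wall thickness, mm.
#' @param rv_cavity_gap distance between LV epicardium and RV endocardium
#'   across the RV cavity, mm.
#' @param rv_crescent_extent degrees of circumference covered by the RV
#'   free wall (0 gives an LV-only phantom).
#' @param base_truncation_fraction fraction of the full ellipsoid height
#'   removed at the base, in (0, 1).
#' @param voxel_size voxel dimensions in mm (default 0.4 x 0.4 in-plane,
#'   0.8 slices, the ex-vivo acquisition this phantom emulates).
#' @param dims grid matrix size; the default 96 x 96 x 48 is a reduced
#'   desk-scale matrix, pass e.g. `c(128, 128, 125)` for a full-scale
#'   emulation.
#' @param helix_profile per-region depth profile of the helical angle:
#'   either one function or `list(lv=, septum=, rv=)` (degrees). Default:
#'   the control-group reference medians, piecewise-constant per third.
#' @param intrusion_offset out-of-tangential-plane tilt of the fibres,
#'   degrees.
#' @param e3_profile per-region depth profile of the E3 angle, degrees.
#' @param eigenvalues diffusion tensor eigenvalues, mm^2/s, strictly
#'   positive and non-increasing.
#' @param s0 non-diffusion-weighted signal, arbitrary units.
#' @param noise_sigma Rician noise level in the same units as `s0`
#'   (0 = noiseless).
#' @param rng_seed integer seed used when `noise_sigma > 0`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(lv_outer_radii = c(12.5, 12.5, 22),
                         lv_wall_thickness = 8,
                         lv_apex_thickness = 4,
                         rv_wall_thickness = 3.4,
                         rv_cavity_gap = 2.5,
                         rv_crescent_extent = 150,
                         base_truncation_fraction = 0.25,
                         voxel_size = c(0.4, 0.4, 0.8),
                         dims = c(96L, 96L, 48L),
                         helix_profile = reference_helix_profiles("control"),
                         intrusion_offset = 0,
                         e3_profile = profile_constant(0),
                         eigenvalues = c(1.7e-3, 0.7e-3, 0.3e-3),
                         s0 = 1000,
                         noise_sigma = 0,
                         rng_seed = 1L) {
  stopifnot(length(lv_outer_radii) == 3L, all(lv_outer_radii > 0),
            length(voxel_size) == 3L, all(voxel_size > 0),
            length(dims) == 3L, all(dims >= 8),
            length(eigenvalues) == 3L)
  if (any(eigenvalues <= 0) || any(diff(eigenvalues) > 0))
    stop("eigenvalues must be strictly positive and non-increasing")
  if (lv_wall_thickness >= min(lv_outer_radii))
    stop("lv_wall_thickness must be smaller than the smallest LV radius")
  if (base_truncation_fraction <= 0 || base_truncation_fraction >= 1)
    stop("base_truncation_fraction must be in (0, 1)")
  if (rv_crescent_extent < 0 || rv_crescent_extent > 360)
    stop("rv_crescent_extent must be in [0, 360] degrees")
  helix_profile <- .as_region_profiles(helix_profile)
  e3_profile <- .as_region_profiles(e3_profile)
  # helical prescriptions must stay within the principal range
  probe <- seq(0, 1, length.out = 101)
  for (f in helix_profile)
    if (any(abs(f(probe)) > 90)) stop("helix_profile values must lie in [-90, 90]")
  spec <- list(lv_outer_radii = lv_outer_radii,
               lv_wall_thickness = lv_wall_thickness,
               lv_apex_thickness = lv_apex_thickness,
               rv_wall_thickness = rv_wall_thickness,
               rv_cavity_gap = rv_cavity_gap,
               rv_crescent_extent = rv_crescent_extent,
               base_truncation_fraction = base_truncation_fraction,
               voxel_size = voxel_size,
               dims = as.integer(dims),
               helix_profile = helix_profile,
               intrusion_offset = intrusion_offset,
               e3_profile = e3_profile,
               eigenvalues = eigenvalues,
               s0 = s0,
               noise_sigma = noise_sigma,
               rng_seed = as.integer(rng_seed))
  class(spec) <- "phantom_spec"
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom spec: LV radii (%g, %g, %g) mm, wall %g mm; RV wall %g mm over %g deg\n",
              x$lv_outer_radii[1], x$lv_outer_radii[2], x$lv_outer_radii[3],
              x$lv_wall_thickness, x$rv_wall_thickness, x$rv_crescent_extent))
  cat(sprintf("  grid %d x %d x %d at (%g, %g, %g) mm, noise sigma %g\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3], x$noise_sigma))
  invisible(x)
}

#' The 23-zone subdivision of the ventricular mass
#'
#' Documented zone convention: three short-axis levels (basal 1-8,
#' equatorial 9-16, apical 17-23). Zones 1 and 4 are the basal
#' interventricular hinge points, 10 and 12 the equatorial papillary-muscle
#' zones, and 17 the apical vortex; these five are excluded from angle
#' statistics. `region` is the statistical pooling region, `profile_region`
#' the region whose ground-truth profile applies in the phantom.
#'
#' @return data.frame with one row per zone: `zone`, `region`, `level`,
#'   `excluded`, `profile_region`.
#' @export
zone_definitions <- function() {
  z <- data.frame(
    zone = 1:23,
    region = c("junction", "septum", "septum", "junction", "lv", "lv", "rv", "rv",
               "septum", "lv", "lv", "lv", "septum", "lv", "rv", "rv",
               "vortex", "septum", "septum", "lv", "lv", "rv", "rv"),
    level = c(rep("basal", 8), rep("equatorial", 8), rep("apical", 7)),
    stringsAsFactors = FALSE
  )
  z$excluded <- z$zone %in% c(1L, 4L, 10L, 12L, 17L)
  z$profile_region <- ifelse(z$region == "junction", "septum",
                             ifelse(z$region == "vortex", "lv", z$region))
  z
}

#' Zones excluded from angle statistics
#' @return Integer vector of excluded zone ids.
#' @export
excluded_zones <- function() c(1L, 4L, 10L, 12L, 17L)

# heart-frame voxel-centre coordinates for the full grid (n x 3, mm);
# the ellipsoid centre sits at the origin of this frame
.grid_coords <- function(dims, voxel_size, z_offset) {
  ax <- lapply(1:3, function(k) (seq_len(dims[k]) - (dims[k] + 1) / 2) * voxel_size[k])
  n <- prod(dims)
  idx <- arrayInd(seq_len(n), dims)
  cbind(ax[[1]][idx[, 1]], ax[[2]][idx[, 2]], ax[[3]][idx[, 3]] - z_offset)
}

# elliptical cross-section radius along azimuth phi at height z for an
# ellipsoid with semi-axes (A, B, C); NA where |z| >= C
.ellipse_radius <- function(phi, z, A, B, C) {
  f <- 1 - (z / C)^2
  az <- A * sqrt(pmax(f, 0))
  bz <- B * sqrt(pmax(f, 0))
  r <- 1 / sqrt(cos(phi)^2 / az^2 + sin(phi)^2 / bz^2)
  r[f <= 0] <- NA_real_
  r
}

#' Build the phantom geometry
#'
#' Generates the LV and RV wall masks and the 23-zone label map from a
#' phantom specification.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_geometry`: logical arrays `lv_mask`,
#'   `rv_mask`, `myocardium`, integer array `zone_map` (0 = background),
#'   grid metadata and the analytic surface parameters.
#' @export
build_geometry <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  vs <- spec$voxel_size
  wall_min <- if (spec$rv_crescent_extent > 0)
    min(spec$lv_wall_thickness, spec$rv_wall_thickness) else spec$lv_wall_thickness
  if (max(vs) > wall_min)
    stop("voxel size exceeds wall thickness: wall unresolvable")
  a <- spec$lv_outer_radii[1]; b <- spec$lv_outer_radii[2]; cc <- spec$lv_outer_radii[3]
  t <- spec$lv_wall_thickness
  ai <- a - t; bi <- b - t; ci <- cc - spec$lv_apex_thickness
  zmax <- cc * (1 - 2 * spec$base_truncation_fraction)
  z_offset <- (cc - zmax) / 2   # grid-frame z of the ellipsoid centre
  dims <- spec$dims
  co <- .grid_coords(dims, vs, z_offset)
  x <- co[, 1]; y <- co[, 2]; z <- co[, 3]

  m_out <- sqrt((x / a)^2 + (y / b)^2 + (z / cc)^2)
  m_in  <- sqrt((x / ai)^2 + (y / bi)^2 + (z / ci)^2)
  lv <- m_out <= 1 & m_in >= 1 & z <= zmax

  ext <- spec$rv_crescent_extent
  phi <- atan2(y, x)
  rv <- rep(FALSE, length(x))
  arv_i <- a + spec$rv_cavity_gap; brv_i <- b + spec$rv_cavity_gap
  arv_o <- arv_i + spec$rv_wall_thickness; brv_o <- brv_i + spec$rv_wall_thickness
  if (ext > 0) {
    mo <- sqrt((x / arv_o)^2 + (y / brv_o)^2 + (z / cc)^2)
    mi <- sqrt((x / arv_i)^2 + (y / brv_i)^2 + (z / cc)^2)
    rv <- mo <= 1 & mi >= 1 & m_out > 1 &
      abs(wrap_pi(phi)) <= deg2rad(ext) / 2 &
      z >= -0.85 * cc & z <= zmax
  }

  geom <- list(spec = spec, dims = dims, voxel_size = vs, z_offset = z_offset,
               lv_axes_outer = c(a, b, cc), lv_axes_inner = c(ai, bi, ci),
               rv_axes_outer = c(arv_o, brv_o, cc), rv_axes_inner = c(arv_i, brv_i, cc),
               zmax = zmax,
               lv_mask = array(lv, dims), rv_mask = array(rv, dims),
               myocardium = array(lv | rv, dims))
  geom$zone_map <- array(.assign_zones(geom, co), dims)
  class(geom) <- "phantom_geometry"
  geom
}

# zone labelling: level from thirds of the apex-to-base extent, azimuthal
# subdivision within each level, vortex override at the apical tip
.assign_zones <- function(geom, co) {
  spec <- geom$spec
  lv <- as.vector(geom$lv_mask); rv <- as.vector(geom$rv_mask)
  myo <- lv | rv
  zone <- integer(length(lv))
  if (!any(myo)) return(zone)
  x <- co[, 1]; y <- co[, 2]; z <- co[, 3]
  cc <- geom$lv_axes_outer[3]
  zr <- range(z[myo])
  lev <- pmin(2L, pmax(0L, floor((z - zr[1]) / (diff(zr) / 3 + 1e-9))))  # 0 apical,1 eq,2 basal
  d <- wrap_pi(atan2(y, x))            # crescent centred on +x
  half <- deg2rad(spec$rv_crescent_extent) / 2
  hinge <- deg2rad(15)
  septal <- abs(d) <= half & spec$rv_crescent_extent > 0

  idx <- which(lv)
  for (i in idx) {
    zi <- 0L
    if (z[i] < -0.9 * cc) { zone[i] <- 17L; next }
    if (lev[i] == 2L) {           # basal: 1-8
      if (septal[i]) {
        if (d[i] > half - hinge) zi <- 1L
        else if (d[i] < -half + hinge) zi <- 4L
        else zi <- if (d[i] > 0) 2L else 3L
      } else zi <- if (d[i] > 0) 5L else 6L
    } else if (lev[i] == 1L) {    # equatorial: 9-16
      if (septal[i]) zi <- if (d[i] > 0) 9L else 13L
      else {
        # free-wall arc split in 4 equal parts, anterior edge first
        arc <- 2 * pi - 2 * half
        psi <- if (d[i] > 0) d[i] - half else d[i] + 2 * pi - half
        q <- pmin(3L, floor(4 * psi / arc))
        zi <- c(10L, 11L, 14L, 12L)[q + 1L]
      }
    } else {                      # apical: 18-21
      if (septal[i]) zi <- if (d[i] > 0) 18L else 19L
      else zi <- if (d[i] > 0) 20L else 21L
    }
    zone[i] <- zi
  }
  ridx <- which(rv)
  zone[ridx] <- ifelse(lev[ridx] == 2L, ifelse(d[ridx] > 0, 7L, 8L),
                ifelse(lev[ridx] == 1L, ifelse(d[ridx] > 0, 15L, 16L),
                       ifelse(d[ridx] > 0, 22L, 23L)))
  zone
}

# vectorized local frames: radial normals (n x 3) + long axis -> list of
# circumferential / longitudinal / radial matrices; invalid where the
# normal is within `apex_cap_deg` of the long axis
.local_frames <- function(normals, long_axis = c(0, 0, 1), apex_cap_deg = 5) {
  normals <- row_unitize(normals)
  la <- unitize(long_axis)
  dz <- normals %*% la
  valid <- abs(dz[, 1]) < cos(deg2rad(apex_cap_deg))
  lon <- matrix(rep(la, each = nrow(normals)), ncol = 3) - normals * dz[, 1]
  lon <- row_unitize(lon)
  circ <- row_cross(lon, normals)
  list(circumferential = circ, longitudinal = lon, radial = normals, valid = valid)
}

#' Prescribe the ground-truth fibre and sheet-normal fields
#'
#' At each myocardial voxel the fibre vector lies in the local epicardial
#' tangential plane, rotated by the helical profile at the voxel's
#' transmural depth away from the circumferential direction, then tilted
#' out of plane by the intrusion offset. The sheet normal is placed,
#' orthogonal to the fibre, so that the E3 angle equals the prescribed E3
#' profile. Transmural depth is the in-slice radial fraction between the
#' analytic endocardial and epicardial surfaces (for the septum: LV
#' endocardium to RV endocardium), the same definition the analysis
#' measures; apical-cap voxels with no in-slice endocardial boundary fall
#' back to the three-dimensional ray fraction.
#'
#' @param spec a [phantom_spec()].
#' @param geometry a [build_geometry()] result.
#' @return An object of class `ground_truth`: per-myocardial-voxel matrices
#'   `fibre`, `sheet_normal` (unit rows), vectors `depth_pct`, `zone`,
#'   `region`, linear `index` into the grid, and `frame_valid`.
#' @export
ground_truth_fields <- function(spec, geometry) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  dims <- geometry$dims
  co <- .grid_coords(dims, geometry$voxel_size, geometry$z_offset)
  myo <- as.vector(geometry$myocardium)
  idx <- which(myo)
  co <- co[idx, , drop = FALSE]
  is_rv <- as.vector(geometry$rv_mask)[idx]
  zone <- as.vector(geometry$zone_map)[idx]
  zdef <- zone_definitions()
  preg <- zdef$profile_region[zone]

  x <- co[, 1]; y <- co[, 2]; z <- co[, 3]
  phi <- atan2(y, x)
  r <- sqrt(x^2 + y^2)

  # transmural depth: in-slice radial fraction endo -> epi
  ax_o <- ifelse(is_rv, geometry$rv_axes_outer[1], geometry$lv_axes_outer[1])
  ay_o <- ifelse(is_rv, geometry$rv_axes_outer[2], geometry$lv_axes_outer[2])
  az_o <- ifelse(is_rv, geometry$rv_axes_outer[3], geometry$lv_axes_outer[3])
  ax_i <- ifelse(is_rv, geometry$rv_axes_inner[1], geometry$lv_axes_inner[1])
  ay_i <- ifelse(is_rv, geometry$rv_axes_inner[2], geometry$lv_axes_inner[2])
  az_i <- ifelse(is_rv, geometry$rv_axes_inner[3], geometry$lv_axes_inner[3])
  r_in  <- .ellipse_radius(phi, z, ax_i, ay_i, az_i)
  r_out <- .ellipse_radius(phi, z, ax_o, ay_o, az_o)
  depth <- (r - r_in) / pmax(r_out - r_in, 1e-9)
  # apex cap: no in-slice endocardium; 3-D ray fraction instead
  cap <- is.na(depth)
  if (any(cap)) {
    m_in  <- sqrt((x / ax_i)^2 + (y / ay_i)^2 + (z / az_i)^2)
    m_out <- sqrt((x / ax_o)^2 + (y / ay_o)^2 + (z / az_o)^2)
    d3 <- (1 - 1 / m_in) / pmax(1 / m_out - 1 / m_in, 1e-9)
    depth[cap] <- d3[cap]
  }
  depth <- pmin(1, pmax(0, depth))

  # outward normal of the epicardial surface at the voxel's in-slice ray
  # (all voxels along a transmural ray share the epicardial tangential
  # frame, the frame the angle definitions are referred to)
  r_ray <- ifelse(is.na(r_out), r, r_out)
  normals <- cbind(r_ray * cos(phi) / ax_o^2, r_ray * sin(phi) / ay_o^2,
                   z / az_o^2)
  fr <- .local_frames(normals)

  helix <- numeric(length(idx)); e3t <- numeric(length(idx))
  for (reg in c("lv", "septum", "rv")) {
    sel <- preg == reg
    if (!any(sel)) next
    helix[sel] <- spec$helix_profile[[reg]](depth[sel])
    e3t[sel] <- spec$e3_profile[[reg]](depth[sel])
  }
  h <- deg2rad(helix); iota <- deg2rad(spec$intrusion_offset)
  fibre <- cos(iota) * (cos(h) * fr$circumferential + sin(h) * fr$longitudinal) +
    sin(iota) * fr$radial

  sheet <- .solve_sheet_normal(fibre, fr, deg2rad(e3t))

  structure(list(index = idx, dims = dims, voxel_size = geometry$voxel_size,
                 fibre = fibre, sheet_normal = sheet,
                 depth_pct = 100 * depth, zone = zone,
                 region = zdef$region[zone], frame_valid = fr$valid,
                 helix_deg = helix, e3_deg = e3t, frames = fr),
            class = "ground_truth")
}

# place e3 orthogonal to the fibre so the folded tangential-reference E3
# angle equals `target` (radians); two antipodal-fold candidates are
# evaluated through the same folding rule the angle module applies
.solve_sheet_normal <- function(fibre, fr, target) {
  R <- fr$radial
  w1 <- R - fibre * rowSums(R * fibre)
  w1 <- row_unitize(w1)
  w2 <- row_cross(fibre, w1)
  a1 <- rowSums(w1 * R); b1 <- rowSums(w2 * R)
  Rm <- pmax(sqrt(a1^2 + b1^2), 1e-12)
  phb <- atan2(b1, a1)
  cand <- function(tt) {
    psi <- asin(pmin(1, pmax(-1, sin(tt) / Rm))) - phb
    sin(psi) * w1 + cos(psi) * w2
  }
  e1c <- cand(target); e2c <- cand(-target)
  a1d <- .e3_angles(e1c, fr, reference = "tangential")
  a2d <- .e3_angles(e2c, fr, reference = "tangential")
  use2 <- abs(deg2rad(a2d) - target) < abs(deg2rad(a1d) - target)
  out <- e1c
  out[use2, ] <- e2c[use2, ]
  row_unitize(out)
}

#' Angles of eigenvector fields against the analytic ground-truth frames
#'
#' Evaluates the helical, intrusion and E3 angle conventions against the
#' phantom's analytic local frames (rather than frames estimated from the
#' voxel masks). Used to validate the signal model, the tensor fit and
#' the angle conventions independently of the frame-estimation stage.
#'
#' @param gt a [ground_truth_fields()] result.
#' @param E1,E3 n x 3 matrices of primary / tertiary eigenvectors in the
#'   same voxel order as `gt$index` (default: the ground-truth fields
#'   themselves).
#' @return data.frame with `helical`, `intrusion`, `e3`, the prescribed
#'   `helix_deg`, `e3_deg`, `depth_pct`, `region` and `frame_valid`.
#' @export
truth_frame_angles <- function(gt, E1 = gt$fibre, E3 = gt$sheet_normal) {
  stopifnot(inherits(gt, "ground_truth"))
  fr <- gt$frames
  data.frame(helical = .helical_angles(E1, fr),
             intrusion = .intrusion_angles(E1, fr),
             e3 = .e3_angles(E3, fr, "tangential"),
             helix_deg = gt$helix_deg, e3_deg = gt$e3_deg,
             depth_pct = gt$depth_pct, region = gt$region,
             frame_valid = fr$valid)
}

#' Synthesize diffusion-weighted signals from the ground truth
#'
#' Per voxel the diffusion tensor is `D = R diag(l1, l2, l3) R'` with the
#' columns of `R` being (fibre, fibre x sheet_normal, sheet_normal), and the
#' signal follows `S(g) = s0 exp(-b g' D g)`. With `noise_sigma > 0`,
#' Rician noise is applied channel-wise under the spec's seed; background
#' voxels then carry noise-only signal.
#'
#' @param gt a [ground_truth_fields()] result.
#' @param spec the [phantom_spec()].
#' @param scheme a [gradient_scheme()].
#' @return 4-D array `dims x n_measurements` of signals.
#' @export
synthesize_dwi <- function(gt, spec, scheme) {
  stopifnot(inherits(gt, "ground_truth"), inherits(scheme, "gradient_scheme"))
  dirs <- scheme$directions; b <- scheme$bvalues
  nz <- b > 0
  if (any(abs(row_norms(dirs[nz, , drop = FALSE]) - 1) > 1e-6))
    stop("non-unit gradient direction")
  if (!any(!nz)) stop("scheme must contain a b = 0 measurement")
  f <- gt$fibre; s <- gt$sheet_normal
  m <- row_cross(f, s)
  ev <- spec$eigenvalues
  # tensor components (xx, yy, zz, xy, xz, yz) per voxel
  D6 <- cbind(ev[1] * f[, 1]^2 + ev[2] * m[, 1]^2 + ev[3] * s[, 1]^2,
              ev[1] * f[, 2]^2 + ev[2] * m[, 2]^2 + ev[3] * s[, 2]^2,
              ev[1] * f[, 3]^2 + ev[2] * m[, 3]^2 + ev[3] * s[, 3]^2,
              ev[1] * f[, 1] * f[, 2] + ev[2] * m[, 1] * m[, 2] + ev[3] * s[, 1] * s[, 2],
              ev[1] * f[, 1] * f[, 3] + ev[2] * m[, 1] * m[, 3] + ev[3] * s[, 1] * s[, 3],
              ev[1] * f[, 2] * f[, 3] + ev[2] * m[, 2] * m[, 3] + ev[3] * s[, 2] * s[, 3])
  A <- cbind(dirs[, 1]^2, dirs[, 2]^2, dirs[, 3]^2,
             2 * dirs[, 1] * dirs[, 2], 2 * dirs[, 1] * dirs[, 3],
             2 * dirs[, 2] * dirs[, 3]) * b
  S <- spec$s0 * exp(-A %*% t(D6))      # k x n_myo
  k <- length(b)
  vol <- array(0, c(gt$dims, k))
  nvox <- prod(gt$dims)
  for (j in seq_len(k)) vol[gt$index + (j - 1) * nvox] <- S[j, ]
  if (spec$noise_sigma > 0) {
    set.seed(spec$rng_seed)
    sg <- spec$noise_sigma
    n1 <- array(rnorm(length(vol), sd = sg), dim(vol))
    n2 <- array(rnorm(length(vol), sd = sg), dim(vol))
    vol <- sqrt((vol + n1)^2 + n2^2)
  }
  vol
}

#' Generate a complete phantom dataset
#'
#' Convenience wrapper running [build_geometry()], [ground_truth_fields()]
#' and [synthesize_dwi()].
#'
#' @param spec a [phantom_spec()].
#' @param scheme a [gradient_scheme()] (default: the built-in 30-direction
#'   b = 1000 scheme).
#' @return A list of class `phantom`: `spec`, `scheme`, `geometry`,
#'   `truth`, `dwi`.
#' @export
build_phantom <- function(spec = phantom_spec(), scheme = default_scheme()) {
  geometry <- build_geometry(spec)
  truth <- ground_truth_fields(spec, geometry)
  dwi <- synthesize_dwi(truth, spec, scheme)
  structure(list(spec = spec, scheme = scheme, geometry = geometry,
                 truth = truth, dwi = dwi), class = "phantom")
}

#' Write phantom artefacts to disk
#'
#' Writes the 4-D signal volume and zone labels as NIfTI, the gradient
#' table as FSL-style `bvecs`/`bvals`, the ground-truth fibre and
#' sheet-normal fields as 4-D NIfTI (3 components in the 4th dimension),
#' and the scalar spec parameters echoed to a YAML config.
#'
#' @param phantom a [build_phantom()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- phantom$spec$voxel_size
  paths <- c(dwi = file.path(dir, "dwi.nii.gz"),
             zones = file.path(dir, "zones.nii.gz"),
             fibre = file.path(dir, "fibre.nii.gz"),
             sheet = file.path(dir, "sheet_normal.nii.gz"),
             bvec = file.path(dir, "bvecs"), bval = file.path(dir, "bvals"),
             config = file.path(dir, "phantom.yaml"))
  RNifti::writeNifti(RNifti::asNifti(phantom$dwi, pixdim = vs), paths["dwi"])
  RNifti::writeNifti(RNifti::asNifti(phantom$geometry$zone_map, pixdim = vs),
                     paths["zones"])
  field_vol <- function(mat) {
    v <- array(0, c(phantom$truth$dims, 3))
    nv <- prod(phantom$truth$dims)
    for (j in 1:3) v[phantom$truth$index + (j - 1) * nv] <- mat[, j]
    v
  }
  RNifti::writeNifti(RNifti::asNifti(field_vol(phantom$truth$fibre), pixdim = vs),
                     paths["fibre"])
  RNifti::writeNifti(RNifti::asNifti(field_vol(phantom$truth$sheet_normal), pixdim = vs),
                     paths["sheet"])
  write_scheme(phantom$scheme, paths["bvec"], paths["bval"])
  sp <- phantom$spec
  scalars <- sp[!vapply(sp, is.function, TRUE)]
  scalars <- scalars[!names(scalars) %in% c("helix_profile", "e3_profile")]
  yaml::write_yaml(scalars, paths["config"])
  invisible(paths)
}
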