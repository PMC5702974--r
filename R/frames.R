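#' Long-axis alignment
#'
#' Estimates the left-ventricular long axis as the principal inertia axis
#' of the LV wall mask and returns the rigid rotation taking it onto +z,
#' with the apex-to-base direction pointing towards +z. The apex end is
#' identified as the end of the axis with the smaller radial spread of
#' wall voxels (the pointier end of the truncated ellipsoid).
#'
#' @param mask logical 3-D array of LV wall voxels.
#' @param voxel_size voxel dimensions, mm.
#' @return List with `rotation` (3x3 matrix), `axis` (unit apex-to-base
#'   direction in the input frame) and `angle_deg` (rotation magnitude).
#' @export
align_long_axis <- function(mask, voxel_size = c(1, 1, 1)) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 100L)
    stop("mask too small for a stable principal axis (< 100 voxels)")
  co <- sweep(idx, 2, (dim(mask) + 1) / 2)
  co <- sweep(co, 2, voxel_size, `*`)
  co <- sweep(co, 2, colMeans(co))
  ev <- eigen(crossprod(co) / nrow(co), symmetric = TRUE)
  v <- ev$vectors[, 1]
  tproj <- co %*% v
  radial <- sqrt(rowSums(co^2) - tproj[, 1]^2)
  qs <- quantile(tproj, c(1 / 3, 2 / 3))
  lo <- mean(radial[tproj <= qs[1]])
  hi <- mean(radial[tproj >= qs[2]])
  # apex (pointier end) must map to low z: apex-to-base = +v
  if (lo > hi) v <- -v
  R <- rotation_between(v, c(0, 0, 1))
  ang <- rad2deg(acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))))
  list(rotation = R, axis = v, angle_deg = ang)
}

#' Nearest-neighbour rigid resampling of a volume
#'
#' Rotates a volume about the grid centre; each target voxel takes the
#' value of the nearest source voxel under the inverse rotation. Intended
#' for masks and label maps.
#'
#' @param vol 3-D array (logical, integer or numeric).
#' @param rotation 3x3 rotation matrix.
#' @param voxel_size voxel dimensions, mm.
#' @return Array of the same dimensions and storage mode.
#' @export
rotate_volume_nn <- function(vol, rotation, voxel_size = c(1, 1, 1)) {
  dm <- dim(vol)
  idx <- arrayInd(seq_len(prod(dm)), dm)
  co <- sweep(idx, 2, (dm + 1) / 2)
  co <- sweep(co, 2, voxel_size, `*`)
  src <- co %*% rotation            # inverse rotation: R^-1 = t(R), applied as x R
  src <- sweep(src, 2, voxel_size, `/`)
  src <- round(sweep(src, 2, (dm + 1) / 2, `+`))
  ok <- src[, 1] >= 1 & src[, 1] <= dm[1] &
    src[, 2] >= 1 & src[, 2] <= dm[2] &
    src[, 3] >= 1 & src[, 3] <= dm[3]
  fill <- if (is.logical(vol)) FALSE else if (is.integer(vol)) 0L else 0
  out <- array(fill, dm)
  out[ok] <- vol[cbind(src[ok, 1], src[ok, 2], src[ok, 3])]
  out
}

#' Select the three short-axis slices of interest
#'
#' Splits the apex-to-base extent of the mask into thirds and returns the
#' middle slice of each third.
#'
#' @param mask logical 3-D array (aligned: long axis along z, apex at
#'   low z).
#' @return Named integer vector `c(apical=, equatorial=, basal=)`.
#' @export
select_slices <- function(mask) {
  zs <- which(apply(mask, 3, any))
  if (!length(zs)) stop("empty mask")
  lo <- min(zs); n <- max(zs) - lo + 1L
  if (n < 3L) stop("apex-to-base extent below 3 slices")
  b <- floor(c(0, 1, 2, 3) * n / 3)
  mids <- lo + as.integer(floor((b[1:3] + b[2:4] - 1) / 2))
  setNames(mids, c("apical", "equatorial", "basal"))
}

# iteratively refined LV cavity centre of a 2-D slice mask (mm, relative
# to the grid centre of the slice plane)
.cavity_centre <- function(mask2d, voxel_size2 = c(1, 1), n = 64L) {
  idx <- which(mask2d, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty slice mask")
  co <- sweep(idx, 2, (dim(mask2d) + 1) / 2)
  co <- sweep(co, 2, voxel_size2, `*`)
  ctr <- colMeans(co)
  for (it in 1:3) {
    rel <- sweep(co, 2, ctr)
    th <- atan2(rel[, 2], rel[, 1])
    r <- sqrt(rowSums(rel^2))
    k <- 1L + pmin(n - 1L, floor(((th %% (2 * pi)) / (2 * pi)) * n))
    rmin <- tapply(r, k, min)
    ak <- (as.numeric(names(rmin)) - 0.5) * 2 * pi / n
    endo <- cbind(ctr[1] + rmin * cos(ak), ctr[2] + rmin * sin(ak))
    ctr <- colMeans(endo)
  }
  ctr
}

#' Subdivide a short-axis slice into equal-angle sectors
#'
#' Assigns each mask voxel of a slice to one of `n_lv` equal-angle sectors
#' about the LV cavity centroid. RV free-wall voxels are binned with the
#' same angular width into the same circular bin layout, so a crescent
#' spanning 90 degrees occupies `90 / (360 / n_lv)` sectors.
#'
#' @param mask2d logical matrix (one slice).
#' @param centre cavity centre in mm relative to the slice grid centre;
#'   estimated from the mask when `NULL`.
#' @param n_lv number of sectors for the full circumference (default 64).
#' @param voxel_size2 in-plane voxel dimensions, mm.
#' @param closed require a closed contour (every sector occupied); an open
#'   contour is an error when `TRUE`.
#' @return Integer matrix of sector ids (1..`n_lv`), `NA` outside the
#'   mask; the centre used is attached as attribute `centre`.
#' @export
sectorize <- function(mask2d, centre = NULL, n_lv = 64L,
                      voxel_size2 = c(1, 1), closed = TRUE) {
  if (is.null(centre)) centre <- .cavity_centre(mask2d, voxel_size2, n_lv)
  idx <- which(mask2d, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty slice mask")
  co <- sweep(idx, 2, (dim(mask2d) + 1) / 2)
  co <- sweep(co, 2, voxel_size2, `*`)
  rel <- sweep(co, 2, centre)
  th <- atan2(rel[, 2], rel[, 1]) %% (2 * pi)
  k <- 1L + pmin(n_lv - 1L, as.integer(floor(th / (2 * pi) * n_lv)))
  if (closed && length(unique(k)) < n_lv)
    stop("open contour: not every sector is occupied")
  out <- matrix(NA_integer_, nrow(mask2d), ncol(mask2d))
  out[idx] <- k
  attr(out, "centre") <- centre
  out
}

#' Epicardial tangential plane from three boundary points
#'
#' The plane through the epicardial boundary point of a sector in the
#' slice of interest (P2) and the corresponding points in the slices
#' above (P1) and below (P3). The normal is oriented outward (positive
#' dot product with the cavity-centre-to-P2 direction). Collinear points
#' fall back to the in-slice tangent crossed with the long axis, flagged.
#'
#' @param p1,p2,p3 length-3 mm coordinates of the three epicardial points.
#' @param cavity_centre length-3 mm coordinates of the cavity centre in
#'   the slice of interest.
#' @param long_axis global long-axis direction (default +z).
#' @return List with `point` (= P2), `normal` (outward unit vector) and
#'   `fallback` flag.
#' @export
epicardial_tangent_plane <- function(p1, p2, p3, cavity_centre,
                                     long_axis = c(0, 0, 1)) {
  nrm <- cross3(p1 - p2, p3 - p2)
  outward <- p2 - cavity_centre
  fallback <- FALSE
  if (vnorm(nrm) < 1e-9 * max(vnorm(p1 - p2), vnorm(p3 - p2), 1e-12)) {
    tang <- cross3(unitize(long_axis), unitize(outward))  # in-slice tangent
    nrm <- cross3(tang, unitize(long_axis))
    fallback <- TRUE
  }
  nrm <- unitize(nrm)
  if (sum(nrm * outward) < 0) nrm <- -nrm
  list(point = p2, normal = nrm, fallback = fallback)
}

#' Local orthonormal frame from a tangential-plane normal
#'
#' `radial_outward` is the plane normal; `longitudinal` is the normalized
#' projection of the long axis onto the tangential plane (plane A);
#' `circumferential = longitudinal x radial_outward`, pointing
#' counterclockwise when viewed from the base. Planes A, B, C are the
#' circumferential-longitudinal (epicardial tangential),
#' radial-longitudinal, and circumferential-radial (local short-axis)
#' planes; their normals are the radial, circumferential and longitudinal
#' directions respectively.
#'
#' @param normal outward tangential-plane normal.
#' @param long_axis global apex-to-base long axis (default +z).
#' @param apex_cap_deg frames whose normal lies within this angle of the
#'   long axis are undefined (apex cap) and an error.
#' @return Object of class `local_frame` with `circumferential`,
#'   `longitudinal`, `radial_outward` and the three plane normals.
#' @export
local_frame <- function(normal, long_axis = c(0, 0, 1), apex_cap_deg = 5) {
  r <- unitize(normal)
  la <- unitize(long_axis)
  if (abs(sum(r * la)) >= cos(deg2rad(apex_cap_deg)))
    stop("frame undefined: normal within the apex cap of the long axis")
  lon <- unitize(la - sum(la * r) * r)
  circ <- cross3(lon, r)
  structure(list(circumferential = circ, longitudinal = lon,
                 radial_outward = r,
                 plane_a_normal = r, plane_b_normal = circ,
                 plane_c_normal = lon),
            class = "local_frame")
}

# in-plane mm coordinates (relative to slice grid centre) of 2-D indices
.slice_mm <- function(idx2, dims2, voxel_size2) {
  co <- sweep(idx2, 2, (dims2 + 1) / 2)
  sweep(co, 2, voxel_size2, `*`)
}

# sub-voxel endo-/epicardial boundary radii of one annular wedge from its
# voxel count (area) and mean radius: for an annular sector of angular
# width dphi, area = dphi/2 (ro^2 - ri^2) and mean radius
# = (2/3)(ro^3 - ri^3)/(ro^2 - ri^2); solving both for (ri, ro) gives
# boundary estimates unbiased by the voxel-centre quantization that
# afflicts min/max radii. Falls back to half-voxel-padded extremes for
# sparse wedges.
.wedge_boundaries <- function(r, dphi, voxel_area) {
  n <- length(r)
  h <- sqrt(voxel_area) / 2
  fb <- c(min(r) - h, max(r) + h)
  if (n < 6L) return(fb)
  Q <- 2 * n * voxel_area / dphi      # ro^2 - ri^2
  m <- mean(r)
  f <- function(u) 3 * u^3 * (2 * m - u) - Q^2
  lo <- sqrt(Q) * (1 + 1e-9); hi <- 2 * m * (1 - 1e-9)
  if (lo >= hi || f(lo) <= 0 || f(hi) >= 0) return(fb)
  u <- uniroot(f, c(lo, hi), tol = 1e-10)$root
  v <- Q / u
  ri <- (u - v) / 2; ro <- (u + v) / 2
  # voxel centres must lie inside the estimated annulus; a violation
  # signals partial angular coverage (e.g. crescent ends) -> fall back
  if (ri < 0 || ri > min(r) + 1e-6 || ro < max(r) - 1e-6) return(fb)
  c(ri, ro)
}

# per-sector epicardial radius profile, smoothed over +/- `halfwin`
# neighbouring occupied sectors (circular) to suppress voxel quantization
# noise in the plane fit; returns a named vector keyed by sector id
.epi_radius_profile <- function(r, sector, n, halfwin = 2L) {
  raw <- tapply(r, sector, max)
  keys <- as.integer(names(raw))
  out <- setNames(numeric(length(keys)), names(raw))
  for (i in seq_along(keys)) {
    nb <- ((keys[i] - 1L + (-halfwin:halfwin)) %% n) + 1L
    out[i] <- mean(raw[as.character(nb)], na.rm = TRUE)
  }
  out
}

# epicardial boundary point of one angular wedge at the requested azimuth;
# NULL when the wedge is empty
.epi_point <- function(rprof, k, azimuth, centre, z_mm) {
  rr <- rprof[as.character(k)]
  if (is.na(rr)) return(NULL)
  c(centre[1] + rr * cos(azimuth), centre[2] + rr * sin(azimuth), z_mm)
}

#' Build per-sector epicardial tangential frames for the slices of interest
#'
#' Runs the full frame construction: long-axis check, slice selection,
#' sectorization about the LV cavity centroid, epicardial tangential
#' planes from the slices nominally 2 mm above and below each slice of
#' interest (snapped to the nearest whole slice), local orthonormal
#' frames, and per-sector endo-/epicardial radii used for transmural
#' depth. The LV wall (including the septum) and the RV free wall are
#' sectorized separately against the same angular bins.
#'
#' @param zone_map integer 3-D array of zone labels (0 = background), as
#'   produced by [build_geometry()] or read from a label volume.
#' @param voxel_size voxel dimensions, mm.
#' @param n_lv number of circumferential sectors (default 64).
#' @param plane_offset_mm nominal slice offset for P1/P3 (default 2 mm).
#' @return Object of class `sector_frames`: data.frame `sectors` (one row
#'   per level x region x sector with centre, radii, frame basis and
#'   flags), list `slices`, per-level cavity `centres`, and grid metadata.
#' @export
build_frames <- function(zone_map, voxel_size = c(1, 1, 1), n_lv = 64L,
                         plane_offset_mm = 2) {
  zdef <- zone_definitions()
  lv_zones <- zdef$zone[zdef$region %in% c("lv", "septum", "junction", "vortex")]
  rv_zones <- zdef$zone[zdef$region == "rv"]
  lv_mask <- array(zone_map %in% lv_zones, dim(zone_map))
  rv_mask <- array(zone_map %in% rv_zones, dim(zone_map))
  myo <- lv_mask | rv_mask

  aln <- align_long_axis(lv_mask, voxel_size)
  slices <- select_slices(myo)
  soff <- max(1L, as.integer(floor(plane_offset_mm / voxel_size[3] + 1e-9)))
  dm <- dim(zone_map)
  zmm <- function(k) (k - (dm[3] + 1) / 2) * voxel_size[3]

  rows <- list()
  centres <- list()
  for (lev in names(slices)) {
    sl <- slices[[lev]]
    lv2 <- lv_mask[, , sl]
    ctr <- .cavity_centre(lv2, voxel_size[1:2], n_lv)
    centres[[lev]] <- ctr
    for (reg in c("lv", "rv")) {
      m2 <- if (reg == "lv") lv2 else rv_mask[, , sl]
      if (!any(m2)) next
      idx2 <- which(m2, arr.ind = TRUE)
      co <- .slice_mm(idx2, dm[1:2], voxel_size[1:2])
      rel <- sweep(co, 2, ctr)
      th <- atan2(rel[, 2], rel[, 1]) %% (2 * pi)
      r <- sqrt(rowSums(rel^2))
      sec <- 1L + pmin(n_lv - 1L, as.integer(floor(th / (2 * pi) * n_lv)))
      # neighbouring slices for the tangent-plane points
      nb <- lapply(c(-soff, soff), function(o) {
        s2 <- sl + o
        if (s2 < 1L || s2 > dm[3]) return(NULL)
        mm <- if (reg == "lv") lv_mask[, , s2] else rv_mask[, , s2]
        if (!any(mm)) return(NULL)
        i2 <- which(mm, arr.ind = TRUE)
        cc <- .slice_mm(i2, dm[1:2], voxel_size[1:2])
        rl <- sweep(cc, 2, ctr)
        t2 <- atan2(rl[, 2], rl[, 1]) %% (2 * pi)
        s2r <- sqrt(rowSums(rl^2))
        s2s <- 1L + pmin(n_lv - 1L, as.integer(floor(t2 / (2 * pi) * n_lv)))
        list(rprof = .epi_radius_profile(s2r, s2s, n_lv), z = zmm(s2))
      })
      rprof <- .epi_radius_profile(r, sec, n_lv)
      for (k in sort(unique(sec))) {
        in_k <- sec == k
        # discrete epicardial surface normal from two symmetric chords:
        # the circumferential chord across the sector within the slice of
        # interest, and the meridional chord between the epicardial points
        # of the slices above and below at the sector-centre azimuth.
        # Both chords are centred on the sector centre, so neither the
        # circumferential nor the meridional surface curvature biases the
        # normal's azimuth or tilt.
        a_mid <- (k - 0.5) * 2 * pi / n_lv
        a_lead <- k * 2 * pi / n_lv
        a_trail <- (k - 1) * 2 * pi / n_lv
        p2 <- .epi_point(rprof, k, a_mid, ctr, zmm(sl))
        p_lead <- .epi_point(rprof, k, a_lead, ctr, zmm(sl))
        p_trail <- .epi_point(rprof, k, a_trail, ctr, zmm(sl))
        p1 <- if (!is.null(nb[[2]])) .epi_point(nb[[2]]$rprof, k, a_mid, ctr,
                                                nb[[2]]$z) else NULL
        p3 <- if (!is.null(nb[[1]])) .epi_point(nb[[1]]$rprof, k, a_mid, ctr,
                                                nb[[1]]$z) else NULL
        cav3 <- c(ctr, zmm(sl))
        outward <- p2 - cav3
        fallback <- FALSE
        if (is.null(p1) || is.null(p3)) {
          # missing neighbour coverage: in-slice tangent crossed with the
          # long axis, flagged
          nrm <- cross3(cross3(c(0, 0, 1), outward), c(0, 0, 1))
          fallback <- TRUE
        } else {
          nrm <- cross3(p_lead - p_trail, p1 - p3)
          if (vnorm(nrm) < 1e-9) {
            nrm <- cross3(cross3(c(0, 0, 1), outward), c(0, 0, 1))
            fallback <- TRUE
          }
        }
        nrm <- unitize(nrm)
        if (sum(nrm * outward) < 0) nrm <- -nrm
        pl <- list(point = p2, normal = nrm, fallback = fallback)
        fr <- tryCatch(local_frame(pl$normal), error = function(e) NULL)
        wb <- .wedge_boundaries(r[in_k], 2 * pi / n_lv,
                                prod(voxel_size[1:2]))
        rows[[length(rows) + 1L]] <- data.frame(
          level = lev, region = reg, sector = k,
          centre_x = ctr[1], centre_y = ctr[2], z_mm = zmm(sl), slice = sl,
          r_endo = wb[1], r_epi = wb[2],
          r_endo_vox = min(r[in_k]), r_epi_vox = max(r[in_k]),
          n_voxels = sum(in_k),
          nx = pl$normal[1], ny = pl$normal[2], nz = pl$normal[3],
          cx = if (is.null(fr)) NA_real_ else fr$circumferential[1],
          cy = if (is.null(fr)) NA_real_ else fr$circumferential[2],
          cz = if (is.null(fr)) NA_real_ else fr$circumferential[3],
          lx = if (is.null(fr)) NA_real_ else fr$longitudinal[1],
          ly = if (is.null(fr)) NA_real_ else fr$longitudinal[2],
          lz = if (is.null(fr)) NA_real_ else fr$longitudinal[3],
          valid = !is.null(fr), fallback = pl$fallback)
      }
    }
  }
  sectors <- do.call(rbind, rows)
  structure(list(sectors = sectors, slices = slices, centres = centres,
                 n_lv = n_lv, dims = dm, voxel_size = voxel_size,
                 alignment = aln),
            class = "sector_frames")
}

#' @export
print.sector_frames <- function(x, ...) {
  cat(sprintf("sector frames: %d sectors over slices (apical %d, equatorial %d, basal %d)\n",
              nrow(x$sectors), x$slices[["apical"]], x$slices[["equatorial"]],
              x$slices[["basal"]]))
  cat(sprintf("  residual long-axis misalignment %.2f deg; %d fallback, %d invalid sectors\n",
              x$alignment$angle_deg, sum(x$sectors$fallback), sum(!x$sectors$valid)))
  invisible(x)
}

# sector-table row lookup for (level, region) pairs; returns a keyed
# data.frame indexable by sector id
.sector_rows <- function(frames, lev, reg) {
  s <- frames$sectors
  s[s$level == lev & s$region == reg, , drop = FALSE]
}

#' Transmural depth of in-slice positions
#'
#' Linear distance fraction along the in-slice radial ray between the
#' endocardial and epicardial boundary of the position's sector (for the
#' septum the epicardial boundary is the right-ventricular
#' sub-endocardium, which is the outer boundary of the LV wall mask
#' there). Clipped to `[0, 100]`; positions in sectors with no boundary
#' information are `NA` (excluded).
#'
#' @param frames a [build_frames()] result.
#' @param level `"apical"`, `"equatorial"` or `"basal"`.
#' @param region `"lv"` (LV wall including septum) or `"rv"`.
#' @param pos n x 2 (or n x 3; z ignored) mm coordinates relative to the
#'   slice grid centre.
#' @return Numeric vector of depths in percent.
#' @export
transmural_depth <- function(frames, level, region, pos) {
  stopifnot(inherits(frames, "sector_frames"))
  pos <- matrix(pos, ncol = max(2, ncol(as.matrix(pos))))
  ctr <- frames$centres[[level]]
  rel <- cbind(pos[, 1] - ctr[1], pos[, 2] - ctr[2])
  th <- atan2(rel[, 2], rel[, 1]) %% (2 * pi)
  r <- sqrt(rowSums(rel^2))
  k <- 1L + pmin(frames$n_lv - 1L, as.integer(floor(th / (2 * pi) * frames$n_lv)))
  tab <- .sector_rows(frames, level, region)
  row <- match(k, tab$sector)
  span <- tab$r_epi[row] - tab$r_endo[row]
  d <- 100 * (r - tab$r_endo[row]) / pmax(span, 1e-9)
  pmin(100, pmax(0, d))
}

#' Ex-vivo wall thickness of a zone
#'
#' Euclidean distance along the zone-centre radial ray between the most
#' endocardial and most epicardial voxel (plus one in-plane voxel, the
#' footprint of the boundary voxels themselves), in mm.
#'
#' @param frames a [build_frames()] result.
#' @param zone_map integer 3-D zone label array.
#' @param zone zone id (1-23); excluded zones are refused.
#' @return Thickness in mm.
#' @export
wall_thickness <- function(frames, zone_map, zone) {
  if (zone %in% excluded_zones())
    stop(sprintf("zone %d is excluded from analysis", zone))
  zdef <- zone_definitions()
  if (!zone %in% zdef$zone) stop("unknown zone")
  lev <- zdef$level[zdef$zone == zone]
  reg <- if (zdef$region[zdef$zone == zone] == "rv") "rv" else "lv"
  sl <- frames$slices[[lev]]
  m2 <- zone_map[, , sl] == zone
  if (!any(m2)) stop(sprintf("zone %d empty in the %s slice of interest", zone, lev))
  idx2 <- which(m2, arr.ind = TRUE)
  co <- .slice_mm(idx2, frames$dims[1:2], frames$voxel_size[1:2])
  ctr <- frames$centres[[lev]]
  rel <- sweep(co, 2, ctr)
  th <- atan2(rel[, 2], rel[, 1])
  # circular-mean centre angle of the zone
  ang <- atan2(mean(sin(th)), mean(cos(th))) %% (2 * pi)
  k <- 1L + min(frames$n_lv - 1L, as.integer(floor(ang / (2 * pi) * frames$n_lv)))
  tab <- .sector_rows(frames, lev, reg)
  row <- match(k, tab$sector)
  if (is.na(row)) stop("zone centre ray does not intersect the wall")
  # most-epicardial minus most-endocardial voxel centre, plus the one-voxel
  # footprint of the boundary voxels themselves
  (tab$r_epi_vox[row] - tab$r_endo_vox[row]) + mean(frames$voxel_size[1:2])
}

#' Wall thickness table for all analysed zones
#'
#' @param frames a [build_frames()] result.
#' @param zone_map integer 3-D zone label array.
#' @return data.frame with columns `zone`, `region`, `level`,
#'   `thickness_mm` (NA where a zone is absent), excluded zones omitted.
#' @export
wall_thickness_table <- function(frames, zone_map) {
  zdef <- zone_definitions()
  zdef <- zdef[!zdef$excluded, ]
  zdef$thickness_mm <- vapply(zdef$zone, function(z)
    tryCatch(wall_thickness(frames, zone_map, z), error = function(e) NA_real_),
    numeric(1))
  zdef[, c("zone", "region", "level", "thickness_mm")]
}
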