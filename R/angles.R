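# fold an angle in degrees into (-90, 90] (antipodal identification)
.fold90 <- function(x) {
  y <- (x + 90) %% 180 - 90
  y[y <= -90] <- 90
  y
}

# vectorized angle kernels; E1 / E3 are n x 3, fr is a .local_frames()
# list of n x 3 bases

.helical_angles <- function(E1, fr, degenerate_deg = 2) {
  rr <- rowSums(E1 * fr$radial)
  u <- E1 - fr$radial * rr
  un <- row_norms(u)
  h <- rad2deg(atan2(rowSums(u * fr$longitudinal), rowSums(u * fr$circumferential)))
  h <- .fold90(h)
  h[un < sin(deg2rad(degenerate_deg))] <- NA_real_   # e1 nearly radial
  h
}

.intrusion_angles <- function(E1, fr) {
  rr <- rowSums(E1 * fr$radial)
  v <- E1 - fr$radial * rr
  vn <- row_norms(v)
  s1 <- rowSums(v * fr$circumferential) + rowSums(v * fr$longitudinal)
  # deterministic antipodal fold: in-plane majority non-negative, with
  # tie-breaks on the longitudinal then circumferential component; a
  # purely radial vector folds to +90
  sgn <- sign(s1)
  t1 <- rowSums(v * fr$longitudinal)
  t2 <- rowSums(v * fr$circumferential)
  sgn[sgn == 0] <- sign(t1)[sgn == 0]
  sgn[sgn == 0] <- sign(t2)[sgn == 0]
  pure <- vn < 1e-6
  sgn[pure] <- sign(rr)[pure]
  sgn[sgn == 0] <- 1
  rad2deg(asin(pmin(1, pmax(-1, sgn * rr))))
}

.e3_angles <- function(E3, fr, reference = c("tangential", "radial_longitudinal")) {
  reference <- match.arg(reference)
  rr <- rowSums(E3 * fr$radial)
  ll <- rowSums(E3 * fr$longitudinal)
  cc <- rowSums(E3 * fr$circumferential)
  if (reference == "tangential") {
    # fold so the longitudinal component is non-negative (ties:
    # circumferential, then radial); angle to plane A = asin(radial comp)
    sgn <- sign(ll)
    sgn[sgn == 0] <- sign(cc)[sgn == 0]
    sgn[sgn == 0] <- sign(rr)[sgn == 0]
    sgn[sgn == 0] <- 1
    rad2deg(asin(pmin(1, pmax(-1, sgn * rr))))
  } else {
    # fold so the radial component is non-negative (ties: longitudinal,
    # then circumferential); angle to plane B = asin(circumferential comp)
    sgn <- sign(rr)
    sgn[sgn == 0] <- sign(ll)[sgn == 0]
    sgn[sgn == 0] <- sign(cc)[sgn == 0]
    sgn[sgn == 0] <- 1
    rad2deg(asin(pmin(1, pmax(-1, sgn * cc))))
  }
}

.frame_as_list <- function(frame) {
  stopifnot(inherits(frame, "local_frame"))
  list(circumferential = matrix(frame$circumferential, 1),
       longitudinal = matrix(frame$longitudinal, 1),
       radial = matrix(frame$radial_outward, 1))
}

#' Helical angle of the primary eigenvector
#'
#' The primary eigenvector is projected onto the epicardial tangential
#' plane (plane A); the helical angle is the signed angle of that
#' projection against the local circumferential direction, positive when
#' the fibre ascends towards the base while running counterclockwise as
#' viewed from the base, folded into `[-90, 90]`. The result is invariant
#' under sign flips of the eigenvector. Vectors within `degenerate_deg`
#' of the radial direction have an undefined projection and return `NA`.
#'
#' @param e1 unit 3-vector (sign-arbitrary).
#' @param frame a [local_frame()].
#' @param degenerate_deg degeneracy threshold (default 2 degrees).
#' @return Angle in degrees.
#' @export
helical_angle <- function(e1, frame, degenerate_deg = 2) {
  .helical_angles(matrix(unitize(e1), 1), .frame_as_list(frame), degenerate_deg)
}

#' Intrusion angle of the primary eigenvector
#'
#' Arcsine of the radial component: the tilt of the fibre out of the
#' epicardial tangential plane, positive when the fibre tilts outward
#' after a deterministic antipodal folding (the in-plane projection is
#' folded to a non-negative circumferential-plus-longitudinal sum).
#'
#' @inheritParams helical_angle
#' @return Angle in degrees in `[-90, 90]`.
#' @export
intrusion_angle <- function(e1, frame) {
  .intrusion_angles(matrix(unitize(e1), 1), .frame_as_list(frame))
}

#' E3 angle of the tertiary eigenvector
#'
#' Angle between the tertiary eigenvector (the normal of the flattened
#' cardiomyocyte aggregates) and a reference plane: the epicardial
#' tangential plane (default) or the radial-longitudinal plane (plane B).
#' The sign comes from the radial (tangential reference) or
#' circumferential (plane-B reference) component after antipodal folding.
#'
#' @param e3 unit 3-vector (sign-arbitrary).
#' @param frame a [local_frame()].
#' @param reference `"tangential"` or `"radial_longitudinal"`.
#' @return Angle in degrees in `[-90, 90]`.
#' @export
e3_angle <- function(e3, frame, reference = c("tangential", "radial_longitudinal")) {
  .e3_angles(matrix(unitize(e3), 1), .frame_as_list(frame), reference)
}

#' Voxel-wise angle maps over the slices of interest
#'
#' Computes helical, intrusion and E3 angles for every analysable
#' myocardial voxel of the three slices of interest, against that voxel's
#' per-sector local frame, together with transmural depth and zone /
#' region / level labels. Voxels with FA below the analysis floor,
#' invalid or flagged tensor fits, invalid frames, or an undefined
#' transmural depth carry no angles.
#'
#' @param tensors a [fit_tensor()] result.
#' @param frames a [build_frames()] result.
#' @param zone_map integer 3-D zone label array.
#' @param e3_reference reference plane for the E3 angle.
#' @param fa_floor analysis FA floor (default 0.15).
#' @return data.frame of class `angle_maps`: one row per analysed voxel
#'   with columns `index`, `level`, `zone`, `region`, `excluded`,
#'   `sector`, `depth_pct`, `fa`, `helical`, `intrusion`, `e3`.
#' @export
compute_angle_maps <- function(tensors, frames, zone_map,
                               e3_reference = c("tangential", "radial_longitudinal"),
                               fa_floor = 0.15) {
  stopifnot(inherits(tensors, "tensor_field"), inherits(frames, "sector_frames"))
  e3_reference <- match.arg(e3_reference)
  dm <- frames$dims
  zdef <- zone_definitions()
  nvox <- prod(dm)
  # tensor lookup by linear voxel index
  tmap <- integer(nvox)
  tmap[tensors$index] <- seq_along(tensors$index)

  out <- list()
  for (lev in names(frames$slices)) {
    sl <- frames$slices[[lev]]
    in_slice <- which(zone_map[, , sl] > 0, arr.ind = TRUE)
    if (!nrow(in_slice)) next
    lin <- in_slice[, 1] + (in_slice[, 2] - 1L) * dm[1] + (sl - 1L) * dm[1] * dm[2]
    ti <- tmap[lin]
    keep <- ti > 0L
    in_slice <- in_slice[keep, , drop = FALSE]; lin <- lin[keep]; ti <- ti[keep]
    if (!length(ti)) next
    ok_t <- tensors$valid[ti] & !tensors$clamped[ti] & !tensors$degenerate[ti] &
      tensors$fa[ti] >= fa_floor
    zone <- zone_map[cbind(in_slice, sl)]
    reg <- zdef$region[zone]
    reg2 <- ifelse(reg == "rv", "rv", "lv")
    co <- .slice_mm(in_slice, dm[1:2], frames$voxel_size[1:2])
    ctr <- frames$centres[[lev]]
    rel <- cbind(co[, 1] - ctr[1], co[, 2] - ctr[2])
    th <- atan2(rel[, 2], rel[, 1]) %% (2 * pi)
    r <- sqrt(rowSums(rel^2))
    k <- 1L + pmin(frames$n_lv - 1L, as.integer(floor(th / (2 * pi) * frames$n_lv)))

    res <- data.frame(index = lin, level = lev, zone = zone, region = reg,
                      excluded = zdef$excluded[zone], sector = k,
                      depth_pct = NA_real_, fa = tensors$fa[ti],
                      helical = NA_real_, intrusion = NA_real_, e3 = NA_real_)
    for (rg in unique(reg2)) {
      tab <- .sector_rows(frames, lev, rg)
      sel <- which(reg2 == rg)
      row <- match(k[sel], tab$sector)
      good <- !is.na(row) & tab$valid[row] & ok_t[sel]
      srow <- row[good]; svox <- sel[good]
      if (!length(svox)) next
      span <- tab$r_epi[srow] - tab$r_endo[srow]
      res$depth_pct[svox] <- pmin(100, pmax(0, 100 * (r[svox] - tab$r_endo[srow]) /
                                              pmax(span, 1e-9)))
      fr <- list(circumferential = cbind(tab$cx, tab$cy, tab$cz)[srow, , drop = FALSE],
                 longitudinal = cbind(tab$lx, tab$ly, tab$lz)[srow, , drop = FALSE],
                 radial = cbind(tab$nx, tab$ny, tab$nz)[srow, , drop = FALSE])
      E1 <- tensors$e1[ti[svox], , drop = FALSE]
      E3 <- tensors$e3[ti[svox], , drop = FALSE]
      res$helical[svox] <- .helical_angles(E1, fr)
      res$intrusion[svox] <- .intrusion_angles(E1, fr)
      res$e3[svox] <- .e3_angles(E3, fr, e3_reference)
    }
    out[[lev]] <- res
  }
  maps <- do.call(rbind, out)
  rownames(maps) <- NULL
  class(maps) <- c("angle_maps", "data.frame")
  maps
}

#' Pool angle maps into histograms and transmural profiles
#'
#' Excluded zones and voxels without angles are removed; the remaining
#' voxels are pooled per region (LV free wall, septum, RV free wall) into
#' density-normalized histograms, and helical and intrusion angles are
#' additionally binned into ten 10% transmural-depth intervals with
#' per-bin median and interquartile range. E3 angles are pooled but not
#' depth-binned: their heterogeneous spatial distribution does not
#' support a transmural reading.
#'
#' @param maps an [compute_angle_maps()] result.
#' @param binwidth_deg histogram bin width (default 10 degrees).
#' @param min_count minimum voxels per depth bin for a median (default 10).
#' @return List of class `angle_summary` with data.frames `histograms`
#'   (`region`, `angle_type`, `bin_lo`, `bin_hi`, `count`, `density`; the
#'   densities of each histogram sum to 1) and `profile` (`region`,
#'   `angle_type`, `depth_bin` 1-10, `bin_lo`, `bin_hi`, `n`,
#'   `median_deg`, `iqr_lo`, `iqr_hi`).
#' @export
pool_and_bin <- function(maps, binwidth_deg = 10, min_count = 10) {
  dat <- maps[!maps$excluded & !is.na(maps$depth_pct), , drop = FALSE]
  regions <- c("lv", "septum", "rv")
  br <- seq(-90, 90, by = binwidth_deg)
  hist_rows <- list(); prof_rows <- list()
  for (reg in regions) {
    d <- dat[dat$region == reg, , drop = FALSE]
    if (!nrow(d)) {
      warning(sprintf("region %s is empty", reg))
      next
    }
    for (at in c("helical", "intrusion", "e3")) {
      v <- d[[at]]
      v <- v[!is.na(v)]
      if (!length(v)) next
      cnt <- tabulate(findInterval(v, br, rightmost.closed = TRUE,
                                   all.inside = TRUE), nbins = length(br) - 1L)
      hist_rows[[length(hist_rows) + 1L]] <- data.frame(
        region = reg, angle_type = at, bin_lo = br[-length(br)], bin_hi = br[-1],
        count = cnt, density = cnt / sum(cnt))
      if (at == "e3") next
      db <- pmin(10L, 1L + as.integer(floor(d$depth_pct / 10)))
      for (bb in 1:10) {
        vv <- d[[at]][db == bb]
        vv <- vv[!is.na(vv)]
        n <- length(vv)
        q <- if (n >= min_count) quantile(vv, c(0.25, 0.5, 0.75), names = FALSE)
        else c(NA_real_, NA_real_, NA_real_)
        prof_rows[[length(prof_rows) + 1L]] <- data.frame(
          region = reg, angle_type = at, depth_bin = bb,
          bin_lo = (bb - 1) * 10, bin_hi = bb * 10, n = n,
          median_deg = q[2], iqr_lo = q[1], iqr_hi = q[3])
      }
    }
  }
  structure(list(histograms = do.call(rbind, hist_rows),
                 profile = do.call(rbind, prof_rows)),
            class = "angle_summary")
}

#' Regional median over a transmural window
#'
#' Median of one angle type over the analysed voxels of a region whose
#' transmural depth falls in `[depth_lo, depth_hi)` percent (the upper
#' bound is inclusive at 100). Excluded zones are never counted.
#'
#' @param maps an [compute_angle_maps()] result.
#' @param region `"lv"`, `"septum"`, `"rv"`, or `"all"` for the entire
#'   analysed myocardium.
#' @param depth_lo,depth_hi depth window in percent.
#' @param angle_type `"helical"`, `"intrusion"` or `"e3"`.
#' @return List with `median_deg` and `n`.
#' @export
region_median <- function(maps, region, depth_lo = 0, depth_hi = 100,
                          angle_type = "helical") {
  dat <- maps[!maps$excluded & !is.na(maps$depth_pct), , drop = FALSE]
  if (region != "all") dat <- dat[dat$region == region, , drop = FALSE]
  hi_ok <- if (depth_hi >= 100) dat$depth_pct <= 100 else dat$depth_pct < depth_hi
  v <- dat[[angle_type]][dat$depth_pct >= depth_lo & hi_ok]
  v <- v[!is.na(v)]
  list(median_deg = if (length(v)) median(v) else NA_real_, n = length(v))
}
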