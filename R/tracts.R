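#' FACT tractography configuration
#'
#' Fibre assignment by continuous tracking: streamlines follow each
#' voxel's primary eigenvector to the voxel boundary without
#' interpolation, terminating on low fractional anisotropy, an abrupt
#' direction change (inner product of successive step directions below
#' threshold), mask exit, or the length cap.
#'
#' @param fa_threshold minimum FA to enter a voxel (default 0.15).
#' @param inner_product_threshold minimum absolute inner product between
#'   successive step directions (default 0.75).
#' @param max_length_mm total track length cap in mm (default 40, i.e.
#'   4 cm).
#' @return Object of class `tract_config`.
#' @export
tract_config <- function(fa_threshold = 0.15, inner_product_threshold = 0.75,
                         max_length_mm = 40) {
  if (fa_threshold <= 0 || fa_threshold > 1 ||
      inner_product_threshold <= 0 || inner_product_threshold > 1)
    stop("thresholds must lie in (0, 1]")
  if (max_length_mm <= 0) stop("max_length_mm must be positive")
  structure(list(fa_threshold = fa_threshold,
                 inner_product_threshold = inner_product_threshold,
                 max_length_mm = max_length_mm),
            class = "tract_config")
}

# dense lookup arrays for the e1 / fa fields of a tensor_field
.field_arrays <- function(tensors, mask = NULL) {
  dm <- tensors$dims
  nv <- prod(dm)
  fa <- array(0, dm); ok <- array(FALSE, dm)
  ex <- ey <- ez <- array(0, dm)
  fa[tensors$index] <- tensors$fa
  ok[tensors$index] <- tensors$valid
  ex[tensors$index] <- tensors$e1[, 1]
  ey[tensors$index] <- tensors$e1[, 2]
  ez[tensors$index] <- tensors$e1[, 3]
  if (!is.null(mask)) ok <- ok & mask
  list(dims = dm, fa = fa, ok = ok, ex = ex, ey = ey, ez = ez)
}

# one FACT half-track from the centre of `seed` along initial direction
# `d0`; returns the polyline (excluding the seed centre) and the
# termination reason
.fact_half <- function(fld, seed, d0, cfg, vs, budget_mm) {
  p <- (seed - 0.5) * vs
  v <- seed
  d <- d0
  pts <- list(); len <- 0
  reason <- "mask"
  max_steps <- ceiling(budget_mm / min(vs)) * 4L + 16L
  for (step in seq_len(max_steps)) {
    if (sum(abs(d)) < 1e-12) { reason <- "angle"; break }
    # parametric distance to each voxel face along d
    tt <- rep(Inf, 3)
    for (ax in 1:3) {
      if (d[ax] > 1e-12) tt[ax] <- (v[ax] * vs[ax] - p[ax]) / d[ax]
      else if (d[ax] < -1e-12) tt[ax] <- ((v[ax] - 1) * vs[ax] - p[ax]) / d[ax]
    }
    tmin <- max(min(tt), 1e-9)
    if (len + tmin >= budget_mm) {
      # truncate the final segment at the cap
      p <- p + d * (budget_mm - len)
      pts[[length(pts) + 1L]] <- p
      len <- budget_mm
      reason <- "length"
      break
    }
    p <- p + d * tmin
    len <- len + tmin
    pts[[length(pts) + 1L]] <- p
    # voxel entered next
    vn <- v
    ax <- which.min(tt)
    vn[ax] <- vn[ax] + if (d[ax] > 0) 1L else -1L
    if (any(vn < 1L) || any(vn > fld$dims)) { reason <- "mask"; break }
    if (!fld$ok[vn[1], vn[2], vn[3]]) { reason <- "mask"; break }
    if (fld$fa[vn[1], vn[2], vn[3]] < cfg$fa_threshold) { reason <- "fa"; break }
    e1n <- c(fld$ex[vn[1], vn[2], vn[3]], fld$ey[vn[1], vn[2], vn[3]],
             fld$ez[vn[1], vn[2], vn[3]])
    ip <- sum(d * e1n)
    if (abs(ip) < cfg$inner_product_threshold) { reason <- "angle"; break }
    d <- if (ip >= 0) e1n else -e1n   # continue the previous direction
    v <- vn
  }
  list(points = if (length(pts)) do.call(rbind, pts) else matrix(numeric(0), 0, 3),
       length_mm = len, reason = reason)
}

#' FACT streamline from a seed voxel
#'
#' Tracks bidirectionally from the seed-voxel centre through the primary
#' eigenvector field. Within each voxel the path follows that voxel's e1
#' (sign chosen to continue the previous direction) to the voxel
#' boundary. Each end terminates on FA below threshold, inner product of
#' successive directions below threshold, mask exit, or the total length
#' cap (shared between the two ends). Point coordinates are in mm with
#' the origin at the corner of voxel (1,1,1).
#'
#' @param tensors a [fit_tensor()] result.
#' @param seed integer voxel index triple `(i, j, k)`.
#' @param mask optional logical array restricting tracking.
#' @param config a [tract_config()].
#' @param voxel_size voxel dimensions, mm.
#' @return Object of class `track`: `points` (m x 3 mm), `seed`,
#'   `length_mm`, `termination_reason` (named `backward` / `forward`; a
#'   seed below the FA threshold yields a single-point track with reason
#'   `"fa"` at both ends).
#' @export
fact_track <- function(tensors, seed, mask = NULL, config = tract_config(),
                       voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(tensors, "tensor_field"), inherits(config, "tract_config"))
  seed <- as.integer(seed)
  fld <- .field_arrays(tensors, mask)
  centre <- (seed - 0.5) * voxel_size
  bad <- !fld$ok[seed[1], seed[2], seed[3]] ||
    fld$fa[seed[1], seed[2], seed[3]] < config$fa_threshold
  if (bad) {
    return(structure(list(points = matrix(centre, 1, 3), seed = seed,
                          length_mm = 0,
                          termination_reason = c(backward = "fa", forward = "fa")),
                     class = "track"))
  }
  e1 <- c(fld$ex[seed[1], seed[2], seed[3]], fld$ey[seed[1], seed[2], seed[3]],
          fld$ez[seed[1], seed[2], seed[3]])
  half_budget <- config$max_length_mm / 2
  fwd <- .fact_half(fld, seed, e1, config, voxel_size, half_budget)
  bwd <- .fact_half(fld, seed, -e1, config, voxel_size, half_budget)
  pts <- rbind(bwd$points[rev(seq_len(nrow(bwd$points))), , drop = FALSE],
               matrix(centre, 1, 3),
               fwd$points)
  structure(list(points = pts, seed = seed,
                 length_mm = bwd$length_mm + fwd$length_mm,
                 termination_reason = c(backward = bwd$reason,
                                        forward = fwd$reason)),
            class = "track")
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("track: %d points, %.1f mm, terminated %s / %s\n",
              nrow(x$points), x$length_mm,
              x$termination_reason[["backward"]], x$termination_reason[["forward"]]))
  invisible(x)
}

#' Track a set of seeds
#'
#' @param tensors a [fit_tensor()] result.
#' @param seeds n x 3 integer matrix of seed voxels.
#' @inheritParams fact_track
#' @return List of `track` objects.
#' @export
track_many <- function(tensors, seeds, mask = NULL, config = tract_config(),
                       voxel_size = c(1, 1, 1)) {
  seeds <- matrix(as.integer(seeds), ncol = 3)
  lapply(seq_len(nrow(seeds)), function(i)
    fact_track(tensors, seeds[i, ], mask, config, voxel_size))
}

#' Write tracks as TSV polylines
#'
#' Columns: track id, point index, x, y, z (mm).
#'
#' @param tracks list of `track` objects.
#' @param path output file.
#' @export
write_tracks <- function(tracks, path) {
  rows <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    p <- tracks[[i]]$points
    data.frame(track = i, point = seq_len(nrow(p)),
               x = p[, 1], y = p[, 2], z = p[, 3])
  }))
  write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Seed sets at the sampled right-ventricular locations
#'
#' Returns four named, deterministic seed sets at the equatorial level:
#' the RV free wall at its rightmost, posterior and anterior aspects, and
#' the septal myocardium facing the RV at the same level. Empty regions
#' yield empty sets with a warning.
#'
#' @param zone_map integer 3-D zone label array.
#' @param frames a [build_frames()] result (provides the equatorial slice
#'   and cavity centre).
#' @param n_per seeds per set (default 25).
#' @param rng_seed integer seed for the deterministic subsample.
#' @return Named list of n x 3 integer seed-voxel matrices.
#' @export
seed_regions <- function(zone_map, frames, n_per = 25L, rng_seed = 1L) {
  sl <- frames$slices[["equatorial"]]
  ctr <- frames$centres[["equatorial"]]
  zdef <- zone_definitions()
  rv_zones <- zdef$zone[zdef$region == "rv"]
  sep_zones <- zdef$zone[zdef$region == "septum" & !zdef$excluded]
  z2 <- zone_map[, , sl]
  rv_idx <- which(matrix(z2 %in% rv_zones, nrow(z2)), arr.ind = TRUE)
  sets <- list()
  if (nrow(rv_idx)) {
    co <- .slice_mm(rv_idx, frames$dims[1:2], frames$voxel_size[1:2])
    th <- atan2(co[, 2] - ctr[2], co[, 1] - ctr[1])
    mid <- atan2(mean(sin(th)), mean(cos(th)))
    rel <- wrap_pi(th - mid)
    band <- deg2rad(20)
    sets$rv_rightmost <- rv_idx[abs(rel) <= band, , drop = FALSE]
    sets$rv_anterior <- rv_idx[rel >= max(rel) - band, , drop = FALSE]
    sets$rv_posterior <- rv_idx[rel <= min(rel) + band, , drop = FALSE]
  } else {
    warning("RV free wall empty at the equatorial level")
    sets$rv_rightmost <- sets$rv_anterior <- sets$rv_posterior <-
      matrix(integer(0), 0, 2)
  }
  sep_idx <- which(matrix(z2 %in% sep_zones, nrow(z2)), arr.ind = TRUE)
  if (!nrow(sep_idx)) warning("septum empty at the equatorial level")
  sets$septal_rv <- sep_idx
  set.seed(rng_seed)
  lapply(sets, function(m) {
    if (nrow(m) > n_per) m <- m[sort(sample.int(nrow(m), n_per)), , drop = FALSE]
    if (!nrow(m)) return(matrix(integer(0), 0, 3))
    cbind(m, sl)
  })
}
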