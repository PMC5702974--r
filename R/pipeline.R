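#' Configure a two-group phantom recovery study
#'
#' A study generates `n` phantom subjects per group from a base spec, each
#' with its own seed controlling a small isotropic geometry jitter, with
#' per-group ground-truth helical profiles; runs the full analysis on
#' every subject; and compares the groups. A run is fully determined by
#' `(config, seed)`.
#'
#' @param n_control,n_dilated subjects per group.
#' @param base_spec the common [phantom_spec()]; per-group profiles
#'   override its `helix_profile`.
#' @param profiles named list of per-group helix profiles (defaults: the
#'   reference control / dilated medians, piecewise-constant per third).
#' @param geometry_jitter half-width of the uniform per-subject scaling
#'   of radii and wall thicknesses (default 0.03, i.e. +/-3%).
#' @param noise_sigma Rician noise level passed to every subject.
#' @param n_sectors circumferential sectors for the frame construction.
#' @return Object of class `study_config`.
#' @export
study_config <- function(n_control = 7L, n_dilated = 7L,
                         base_spec = phantom_spec(),
                         profiles = list(control = reference_helix_profiles("control"),
                                         dilated = reference_helix_profiles("dilated")),
                         geometry_jitter = 0.03,
                         noise_sigma = base_spec$noise_sigma,
                         n_sectors = 64L) {
  stopifnot(n_control >= 1, n_dilated >= 1,
            geometry_jitter >= 0, geometry_jitter < 0.2)
  structure(list(n_control = as.integer(n_control),
                 n_dilated = as.integer(n_dilated),
                 base_spec = base_spec, profiles = profiles,
                 geometry_jitter = geometry_jitter,
                 noise_sigma = noise_sigma, n_sectors = as.integer(n_sectors)),
            class = "study_config")
}

# per-subject spec: isotropic geometry scaling drawn from the subject
# seed, group profile substituted
.subject_spec <- function(config, group, subject_seed) {
  base <- config$base_spec
  set.seed(subject_seed)
  s <- if (config$geometry_jitter > 0)
    runif(1, 1 - config$geometry_jitter, 1 + config$geometry_jitter) else 1
  phantom_spec(lv_outer_radii = base$lv_outer_radii * s,
               lv_wall_thickness = base$lv_wall_thickness * s,
               lv_apex_thickness = base$lv_apex_thickness * s,
               rv_wall_thickness = base$rv_wall_thickness * s,
               rv_cavity_gap = base$rv_cavity_gap * s,
               rv_crescent_extent = base$rv_crescent_extent,
               base_truncation_fraction = base$base_truncation_fraction,
               voxel_size = base$voxel_size, dims = base$dims,
               helix_profile = config$profiles[[group]],
               intrusion_offset = base$intrusion_offset,
               e3_profile = base$e3_profile,
               eigenvalues = base$eigenvalues, s0 = base$s0,
               noise_sigma = config$noise_sigma, rng_seed = subject_seed)
}

#' Analyse one subject
#'
#' The single-subject pipeline: tensor fit, frame construction, angle
#' maps, pooled summaries and the wall-thickness table.
#'
#' @param dwi 4-D signal array.
#' @param scheme a [gradient_scheme()].
#' @param zone_map integer 3-D zone label array.
#' @param voxel_size voxel dimensions, mm.
#' @param n_sectors circumferential sectors (default 64).
#' @param e3_reference reference plane for the E3 angle.
#' @return List of class `subject_analysis`: `tensors`, `frames`, `maps`,
#'   `summary`, `thickness`.
#' @export
analyse_subject <- function(dwi, scheme, zone_map, voxel_size,
                            n_sectors = 64L, e3_reference = "tangential") {
  mask <- array(zone_map > 0, dim(zone_map))
  tensors <- fit_tensor(dwi, scheme, mask)
  frames <- build_frames(zone_map, voxel_size, n_lv = n_sectors)
  maps <- compute_angle_maps(tensors, frames, zone_map,
                             e3_reference = e3_reference)
  summary <- suppressWarnings(pool_and_bin(maps))
  thickness <- wall_thickness_table(frames, zone_map)
  structure(list(tensors = tensors, frames = frames, maps = maps,
                 summary = summary, thickness = thickness),
            class = "subject_analysis")
}

#' Run a full two-group recovery study
#'
#' Generates every subject's phantom, runs the per-subject analysis,
#' writes per-subject artefacts (angle tables, transmural profiles, wall
#' thicknesses), runs the group comparison, and writes the comparison
#' tables and a manifest of parameters, seeds and file checksums. Any
#' stage failure halts with the stage name and offending subject id.
#'
#' @param config a [study_config()].
#' @param out_dir output directory.
#' @param seed master seed; per-subject seeds are derived from it.
#' @param write_volumes also write per-subject NIfTI volumes and gradient
#'   tables (off by default: the tables are the analysis artefacts).
#' @return List of class `study_result` with `comparison`, `subjects`
#'   (per-subject angle maps and thickness tables), `config`, `manifest`.
#' @export
run_study <- function(config, out_dir, seed = 1L, write_volumes = FALSE) {
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  groups <- list(control = config$n_control, dilated = config$n_dilated)
  scheme <- default_scheme()
  subjects <- list()
  files <- character()
  sub_id <- 0L
  for (group in names(groups)) {
    for (i in seq_len(groups[[group]])) {
      sub_id <- sub_id + 1L
      id <- sprintf("%s_%02d", group, i)
      subject_seed <- (as.integer(seed) * 1000L + sub_id) %% .Machine$integer.max
      stage <- "phantom"
      res <- tryCatch({
        spec <- .subject_spec(config, group, subject_seed)
        ph <- build_phantom(spec, scheme)
        stage <- "analysis"
        an <- analyse_subject(ph$dwi, scheme, ph$geometry$zone_map,
                              spec$voxel_size, config$n_sectors)
        sdir <- file.path(out_dir, id)
        dir.create(sdir, showWarnings = FALSE)
        stage <- "write"
        write.table(an$maps, file.path(sdir, "angles.tsv"), sep = "\t",
                    row.names = FALSE, quote = FALSE)
        write.table(an$summary$profile, file.path(sdir, "profile.tsv"),
                    sep = "\t", row.names = FALSE, quote = FALSE)
        write.table(an$thickness, file.path(sdir, "thickness.tsv"),
                    sep = "\t", row.names = FALSE, quote = FALSE)
        if (write_volumes) write_phantom(ph, file.path(sdir, "volumes"))
        files <- c(files, file.path(sdir, c("angles.tsv", "profile.tsv",
                                            "thickness.tsv")))
        list(group = group, id = id, seed = subject_seed, maps = an$maps,
             thickness = an$thickness)
      }, error = function(e) {
        stop(sprintf("stage '%s' failed for subject %s: %s", stage, id,
                     conditionMessage(e)), call. = FALSE)
      })
      subjects[[id]] <- res
    }
  }
  grp <- vapply(subjects, function(s) s$group, "")
  maps_ctl <- lapply(subjects[grp == "control"], function(s) s$maps)
  maps_dil <- lapply(subjects[grp == "dilated"], function(s) s$maps)
  thick <- function(ss) list(
    lv_wall_mm = vapply(ss, function(s)
      median(s$thickness$thickness_mm[s$thickness$region == "lv"], na.rm = TRUE), 1),
    rv_wall_mm = vapply(ss, function(s)
      median(s$thickness$thickness_mm[s$thickness$region == "rv"], na.rm = TRUE), 1))
  # group A = dilated, group B = control: `diff` is dilated minus control
  comparison <- compare_study(maps_dil, maps_ctl,
                              morphometrics_a = thick(subjects[grp == "dilated"]),
                              morphometrics_b = thick(subjects[grp == "control"]),
                              rng_seed = seed)
  files <- c(files, write_comparison(comparison, file.path(out_dir, "comparison")))
  manifest <- list(
    package_version = as.character(utils::packageVersion("myoarch")),
    seed = seed,
    subjects = lapply(subjects, function(s) list(group = s$group, seed = s$seed)),
    parameters = list(
      n_control = config$n_control, n_dilated = config$n_dilated,
      geometry_jitter = config$geometry_jitter,
      noise_sigma = config$noise_sigma, n_sectors = config$n_sectors,
      dims = config$base_spec$dims, voxel_size = config$base_spec$voxel_size,
      eigenvalues = config$base_spec$eigenvalues, s0 = config$base_spec$s0),
    files = lapply(setNames(nm = unname(files)), function(f)
      unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(list(comparison = comparison, subjects = subjects,
                 config = config, manifest = manifest,
                 out_dir = out_dir), class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("study result: %d subjects in %s\n", length(x$subjects), x$out_dir))
  print(x$comparison)
  invisible(x)
}
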