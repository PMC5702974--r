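.group_comparison <- function(test_name, statistic, p_value, n_per_group,
                              grouping = NA_character_, method = NA_character_) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = unname(p_value), n_per_group = n_per_group,
                 grouping = grouping, method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.4g (n = %s)\n", x$test_name,
              x$statistic, x$p_value, paste(x$n_per_group, collapse = " vs ")))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum of the absolute difference between the two
#' empirical CDFs; the p-value is exact (enumeration over splits) when
#' both samples have at most 10 observations and there are no ties,
#' asymptotic otherwise.
#'
#' @param sample_a,sample_b numeric vectors, non-empty.
#' @return A `group_comparison` with the D statistic and p-value.
#' @export
ks_two_sample <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) stop("empty sample")
  exact <- length(sample_a) <= 10 && length(sample_b) <= 10 &&
    !anyDuplicated(c(sample_a, sample_b))
  res <- suppressWarnings(ks.test(sample_a, sample_b, exact = exact))
  .group_comparison("two-sample Kolmogorov-Smirnov", res$statistic, res$p.value,
                    c(length(sample_a), length(sample_b)),
                    method = if (exact) "exact" else "asymptotic")
}

#' Mann-Whitney U test (Wilcoxon rank-sum)
#'
#' Two-sided. The U statistic is reported; the p-value is exact for at
#' most 8 observations per group without ties, and uses the tie-corrected
#' normal approximation with continuity correction otherwise.
#'
#' @param sample_a,sample_b numeric vectors, non-empty.
#' @return A `group_comparison` with the U statistic and p-value.
#' @export
mann_whitney <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) stop("empty sample")
  exact <- length(sample_a) <= 8 && length(sample_b) <= 8 &&
    !anyDuplicated(c(sample_a, sample_b))
  res <- suppressWarnings(wilcox.test(sample_a, sample_b, exact = exact,
                                      correct = TRUE))
  .group_comparison("Mann-Whitney U", res$statistic, res$p.value,
                    c(length(sample_a), length(sample_b)),
                    method = if (exact) "exact" else "normal approximation")
}

#' Shapiro-Wilk normality screen
#'
#' @param sample numeric vector with 3 to 5000 observations.
#' @return A `group_comparison` with the W statistic and p-value.
#' @export
normality_screen <- function(sample) {
  n <- length(sample)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  res <- shapiro.test(sample)
  .group_comparison("Shapiro-Wilk", res$statistic, res$p.value, n)
}

# per-subject median table: region x angle type x depth bin
.subject_bin_medians <- function(maps) {
  dat <- maps[!maps$excluded & !is.na(maps$depth_pct), , drop = FALSE]
  dat <- dat[dat$region %in% c("lv", "septum", "rv"), , drop = FALSE]
  rows <- list()
  for (at in c("helical", "intrusion")) {
    v <- dat[[at]]
    ok <- !is.na(v)
    db <- pmin(10L, 1L + as.integer(floor(dat$depth_pct / 10)))
    ag <- aggregate(v[ok], by = list(region = dat$region[ok], bin = db[ok]),
                    FUN = median)
    ag$angle_type <- at
    rows[[at]] <- ag
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "x"] <- "median_deg"
  rownames(out) <- NULL
  out
}

# per-subject transmural-third medians, regions plus the pooled entire
# heart
.subject_third_medians <- function(maps) {
  dat <- maps[!maps$excluded & !is.na(maps$depth_pct) & !is.na(maps$helical), ,
              drop = FALSE]
  dat <- dat[dat$region %in% c("lv", "septum", "rv"), , drop = FALSE]
  third <- cut(dat$depth_pct, c(-Inf, 100 / 3, 200 / 3, Inf),
               labels = c("endo", "mid", "epi"))
  rows <- expand.grid(region = c("lv", "septum", "rv", "all"),
                      third = c("endo", "mid", "epi"),
                      stringsAsFactors = FALSE)
  rows$median_deg <- mapply(function(rg, th) {
    sel <- third == th & (rg == "all" | dat$region == rg)
    if (!any(sel)) NA_real_ else median(dat$helical[sel])
  }, rows$region, rows$third)
  rows
}

#' Between-group comparison of angle distributions
#'
#' Implements the study-level statistics: two-sample Kolmogorov-Smirnov
#' on the pooled per-region angle distributions (each subject subsampled
#' to the common minimum voxel count so every subject carries equal
#' weight; set `subject_weight = FALSE` for raw pooling), Mann-Whitney U
#' per 10% transmural-depth bin on the per-subject bin medians (helical
#' and intrusion only: E3 angles are heterogeneously distributed through
#' the wall and transmural testing of them is refused by design), and a
#' transmural-thirds summary (median, IQR, difference of group medians,
#' Mann-Whitney p) per region and for the entire heart. Optional
#' morphometric vectors (one value per subject) are compared with the
#' Wilcoxon rank-sum test.
#'
#' @param maps_a,maps_b lists of [compute_angle_maps()] results (one per
#'   subject); at least 2 subjects per group.
#' @param morphometrics_a,morphometrics_b optional named lists of numeric
#'   per-subject vectors (e.g. wall thicknesses).
#' @param subject_weight equalize subject weights in the pooled KS test.
#' @param test_e3_by_depth must remain `FALSE`; requesting transmural E3
#'   testing is an error.
#' @param alpha significance level (default 0.05).
#' @param rng_seed seed for the equal-weight subsampling.
#' @return List of class `study_comparison` with data.frames `ks`
#'   (region x angle type), `by_bin` (per depth bin), `thirds` (the
#'   summary-table shape: region x third with group medians, IQRs,
#'   difference and p), and `morphometrics` (possibly empty).
#' @export
compare_study <- function(maps_a, maps_b,
                          morphometrics_a = NULL, morphometrics_b = NULL,
                          subject_weight = TRUE, test_e3_by_depth = FALSE,
                          alpha = 0.05, rng_seed = 1L) {
  if (isTRUE(test_e3_by_depth))
    stop("transmural testing of E3 angles is refused by design")
  if (length(maps_a) < 2 || length(maps_b) < 2)
    stop("each group needs at least 2 subjects")

  pool <- function(maps_list, at, reg) {
    per <- lapply(maps_list, function(m) {
      d <- m[!m$excluded & m$region == reg & !is.na(m[[at]]), at]
      d[!is.na(d)]
    })
    if (subject_weight) {
      nmin <- min(vapply(per, length, 1L))
      if (nmin > 0)
        per <- lapply(per, function(v) v[sort(sample.int(length(v), nmin))])
    }
    unlist(per)
  }

  set.seed(rng_seed)
  ks_rows <- list()
  for (reg in c("lv", "septum", "rv")) for (at in c("helical", "intrusion", "e3")) {
    va <- pool(maps_a, at, reg); vb <- pool(maps_b, at, reg)
    if (!length(va) || !length(vb)) next
    r <- ks_two_sample(va, vb)
    ks_rows[[length(ks_rows) + 1L]] <- data.frame(
      region = reg, angle_type = at, D = r$statistic, p = r$p_value,
      n_a = length(va), n_b = length(vb))
  }

  bm_a <- lapply(maps_a, .subject_bin_medians)
  bm_b <- lapply(maps_b, .subject_bin_medians)
  bin_rows <- list()
  for (reg in c("lv", "septum", "rv")) for (at in c("helical", "intrusion")) {
    for (bb in 1:10) {
      ga <- vapply(bm_a, function(t) {
        v <- t$median_deg[t$region == reg & t$angle_type == at & t$bin == bb]
        if (length(v)) v[1] else NA_real_
      }, 1)
      gb <- vapply(bm_b, function(t) {
        v <- t$median_deg[t$region == reg & t$angle_type == at & t$bin == bb]
        if (length(v)) v[1] else NA_real_
      }, 1)
      ga <- ga[!is.na(ga)]; gb <- gb[!is.na(gb)]
      if (length(ga) < 2 || length(gb) < 2) next
      r <- mann_whitney(ga, gb)
      bin_rows[[length(bin_rows) + 1L]] <- data.frame(
        region = reg, angle_type = at, depth_bin = bb,
        median_a = median(ga), median_b = median(gb),
        U = r$statistic, p = r$p_value,
        significant = r$p_value < alpha)
    }
  }

  tm_a <- lapply(maps_a, .subject_third_medians)
  tm_b <- lapply(maps_b, .subject_third_medians)
  third_rows <- list()
  for (reg in c("lv", "septum", "rv", "all")) for (th in c("endo", "mid", "epi")) {
    ga <- vapply(tm_a, function(t)
      t$median_deg[t$region == reg & t$third == th], 1)
    gb <- vapply(tm_b, function(t)
      t$median_deg[t$region == reg & t$third == th], 1)
    ga <- ga[!is.na(ga)]; gb <- gb[!is.na(gb)]
    if (length(ga) < 2 || length(gb) < 2) next
    r <- mann_whitney(ga, gb)
    qa <- quantile(ga, c(0.25, 0.75), names = FALSE)
    qb <- quantile(gb, c(0.25, 0.75), names = FALSE)
    third_rows[[length(third_rows) + 1L]] <- data.frame(
      region = reg, third = th,
      median_a = median(ga), iqr_a_lo = qa[1], iqr_a_hi = qa[2],
      median_b = median(gb), iqr_b_lo = qb[1], iqr_b_hi = qb[2],
      diff = median(ga) - median(gb), p = r$p_value,
      significant = r$p_value < alpha)
  }

  morph_rows <- list()
  if (!is.null(morphometrics_a)) {
    for (nm in names(morphometrics_a)) {
      va <- morphometrics_a[[nm]]; vb <- morphometrics_b[[nm]]
      r <- mann_whitney(va, vb)   # Wilcoxon rank-sum
      morph_rows[[length(morph_rows) + 1L]] <- data.frame(
        measure = nm, median_a = median(va), median_b = median(vb),
        diff = median(va) - median(vb), p = r$p_value,
        significant = r$p_value < alpha)
    }
  }

  structure(list(ks = do.call(rbind, ks_rows),
                 by_bin = do.call(rbind, bin_rows),
                 thirds = do.call(rbind, third_rows),
                 morphometrics = do.call(rbind, morph_rows),
                 alpha = alpha,
                 n_subjects = c(a = length(maps_a), b = length(maps_b))),
            class = "study_comparison")
}

#' @export
print.study_comparison <- function(x, ...) {
  cat(sprintf("study comparison: %d vs %d subjects, alpha %.2f\n",
              x$n_subjects[["a"]], x$n_subjects[["b"]], x$alpha))
  cat("\nHelical angle by transmural third (group A vs B):\n")
  th <- x$thirds
  for (i in seq_len(nrow(th))) {
    cat(sprintf("  %-7s %-5s A %6.1f (%.1f;%.1f)  B %6.1f (%.1f;%.1f)  diff %6.1f  p %s\n",
                th$region[i], th$third[i],
                th$median_a[i], th$iqr_a_lo[i], th$iqr_a_hi[i],
                th$median_b[i], th$iqr_b_lo[i], th$iqr_b_hi[i],
                th$diff[i],
                ifelse(th$p[i] < x$alpha, format.pval(th$p[i], digits = 2), "NS")))
  }
  invisible(x)
}

#' Write the comparison tables
#'
#' @param comparison a [compare_study()] result.
#' @param dir output directory.
#' @return Invisibly, the written file paths.
#' @export
write_comparison <- function(comparison, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (nm in c("ks", "by_bin", "thirds", "morphometrics")) {
    t <- comparison[[nm]]
    if (is.null(t)) next
    p <- file.path(dir, paste0(nm, ".tsv"))
    write.table(t, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths[nm] <- p
  }
  p <- file.path(dir, "summary.md")
  con <- file(p, "w")
  sink(con); print(comparison); sink()
  close(con)
  paths["summary"] <- p
  invisible(paths)
}
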