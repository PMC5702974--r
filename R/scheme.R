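#' Diffusion gradient scheme
#'
#' A gradient scheme couples diffusion-encoding directions with their
#' b-values (s/mm^2). All non-zero-b directions must be unit vectors and the
#' scheme must contain at least one b = 0 measurement plus at least six
#' distinct, non-collinear diffusion directions, the minimum for a tensor
#' fit.
#'
#' @param directions numeric matrix, one row per measurement, 3 columns.
#'   Rows with `bvalues == 0` may be zero vectors.
#' @param bvalues numeric vector of b-values in s/mm^2, one per row.
#' @return An object of class `gradient_scheme` with elements `directions`
#'   (n x 3 matrix) and `bvalues`.
#' @examples
#' sch <- default_scheme()
#' nrow(sch$directions)  # 31 measurements: 30 DWI + 1 b=0
#' @export
gradient_scheme <- function(directions, bvalues) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L)
    stop("directions must have 3 columns")
  bvalues <- as.numeric(bvalues)
  if (length(bvalues) != nrow(directions))
    stop("one b-value per direction required")
  dwi <- bvalues > 0
  if (!any(!dwi))
    stop("scheme must contain at least one b = 0 measurement")
  nrm <- row_norms(directions[dwi, , drop = FALSE])
  if (any(abs(nrm - 1) > 1e-6))
    stop("non-unit gradient direction in scheme")
  # at least 6 distinct non-collinear diffusion directions: the 6 x 6
  # quadratic-form design must have full rank
  dd <- directions[dwi, , drop = FALSE]
  G <- cbind(dd[, 1]^2, dd[, 2]^2, dd[, 3]^2,
             2 * dd[, 1] * dd[, 2], 2 * dd[, 1] * dd[, 3],
             2 * dd[, 2] * dd[, 3])
  if (qr(G)$rank < 6L)
    stop("need at least 6 non-collinear diffusion directions")
  structure(list(directions = directions, bvalues = bvalues),
            class = "gradient_scheme")
}

# 30-direction electrostatic-repulsion layout (antipodally symmetric
# Coulomb-energy minimum), canonical upper hemisphere.
.dirs30 <- matrix(c(
  -0.0894252, -0.0903894, 0.9918835,
  0.1321007, 0.3247171, 0.9365406,
  0.3406340, -0.1832581, 0.9221632,
  -0.3702192, 0.2646706, 0.8904422,
  -0.0700319, -0.5386018, 0.8396450,
  -0.4921450, -0.2560819, 0.8319948,
  0.5744064, 0.2313908, 0.7851851,
  -0.1797087, 0.6530291, 0.7357023,
  0.3752346, -0.6192785, 0.6897051,
  0.3657407, 0.6446155, 0.6713454,
  -0.7401832, 0.0986503, 0.6651293,
  0.7126796, -0.2408157, 0.6588593,
  -0.4839550, -0.6464194, 0.5898554,
  -0.6281255, 0.5455577, 0.5548200,
  0.0123220, -0.8648207, 0.5019296,
  -0.8302602, -0.3177646, 0.4579232,
  0.8867135, 0.1312688, 0.4432919,
  0.0415727, 0.8984938, 0.4370133,
  0.7486191, 0.5487522, 0.3720758,
  0.7162204, -0.5969115, 0.3615592,
  -0.4057885, 0.8687421, 0.2839418,
  -0.9416646, 0.1892450, 0.2783058,
  -0.3783856, -0.8951374, 0.2356976,
  0.4509607, 0.8646297, 0.2214724,
  0.4126632, -0.8861005, 0.2110332,
  0.9535434, -0.2432121, 0.1777719,
  -0.7592064, -0.6406942, 0.1145275,
  -0.7745446, 0.6232559, 0.1078553,
  -0.9737194, -0.2274142, 0.0123778,
  0.0144211, -0.9998215, 0.0122099), ncol = 3, byrow = TRUE)

#' Built-in 30-direction acquisition scheme
#'
#' Thirty isotropically distributed directions (electrostatic-repulsion
#' layout over the antipodally-identified sphere) at the given b-value,
#' preceded by one b = 0 measurement. This emulates the common ex-vivo
#' DT-CMR protocol of 30 DWI directions at b = 1000 s/mm^2 plus one
#' unweighted image.
#'
#' @param bvalue diffusion weighting in s/mm^2 (default 1000).
#' @return A `gradient_scheme` with 31 measurements (first is b = 0).
#' @export
default_scheme <- function(bvalue = 1000) {
  dirs <- rbind(c(0, 0, 0), row_unitize(.dirs30))
  gradient_scheme(dirs, c(0, rep(bvalue, nrow(.dirs30))))
}

#' Read / write FSL-style gradient tables
#'
#' `bvecs` holds three whitespace-separated rows (x, y, z components, one
#' column per measurement); `bvals` holds one row of b-values.
#'
#' @param bvec,bval paths to the two text files.
#' @return `read_scheme()` returns a `gradient_scheme`.
#' @export
read_scheme <- function(bvec, bval) {
  v <- as.matrix(read.table(bvec))
  if (nrow(v) != 3L) stop("bvec file must have 3 rows")
  b <- as.numeric(read.table(bval)[1, ])
  dirs <- t(v)
  nz <- b > 0
  dirs[nz, ] <- row_unitize(dirs[nz, , drop = FALSE])
  gradient_scheme(dirs, b)
}

#' @param scheme a `gradient_scheme`.
#' @rdname read_scheme
#' @export
write_scheme <- function(scheme, bvec, bval) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  write.table(format(t(scheme$directions), digits = 8),
              bvec, row.names = FALSE, col.names = FALSE, quote = FALSE)
  write.table(t(scheme$bvalues), bval,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(c(bvec = bvec, bval = bval))
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("gradient scheme: %d measurements (%d with b = 0), b max %g s/mm^2\n",
              length(x$bvalues), sum(x$bvalues == 0), max(x$bvalues)))
  invisible(x)
}
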