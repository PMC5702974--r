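#' Fit diffusion tensors by ordinary least squares on log-signals
#'
#' Solves, per voxel, the log-linear Stejskal-Tanner system
#' `log S = log s0 - b g' D g` for the six tensor components and `log s0`.
#' Measurements with non-positive signal are excluded for that voxel; a
#' voxel with fewer than 7 usable measurements, or a degenerate design, is
#' flagged invalid rather than silently filled.
#'
#' @param dwi 4-D signal array; the 4th dimension matches the scheme.
#' @param scheme a [gradient_scheme()].
#' @param mask logical array of voxels to fit (default: voxels with
#'   positive b = 0 signal).
#' @return An object of class `tensor_field`: `index` (linear voxel
#'   indices), `d6` (n x 6 tensor components xx, yy, zz, xy, xz, yz,
#'   mm^2/s), `evals` (n x 3, descending, negatives clamped to 0), `e1`,
#'   `e2`, `e3` (n x 3 unit rows, sign-arbitrary), `fa`, `s0_estimate`,
#'   and logical flags `valid`, `clamped`, `degenerate`.
#' @export
fit_tensor <- function(dwi, scheme, mask = NULL) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  dm <- dim(dwi)
  if (length(dm) != 4L || dm[4] != length(scheme$bvalues))
    stop("dwi 4th dimension must match the scheme length")
  dims <- dm[1:3]
  nvox <- prod(dims)
  if (is.null(mask)) {
    b0 <- which(scheme$bvalues == 0)[1]
    mask <- array(dwi[, , , b0] > 0, dims)
  }
  idx <- which(as.vector(mask))
  if (!length(idx)) stop("empty mask")
  k <- dm[4]
  # signals as k x n matrix
  S <- matrix(0, k, length(idx))
  for (j in seq_len(k)) S[j, ] <- dwi[idx + (j - 1) * nvox]

  g <- scheme$directions; b <- scheme$bvalues
  X <- cbind(1,
             -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])

  n <- length(idx)
  beta <- matrix(NA_real_, 7, n)
  ok_sig <- S > 0
  full <- colSums(ok_sig) == k
  if (any(full)) {
    XtX <- crossprod(X)
    beta[, full] <- solve(XtX, crossprod(X, log(S[, full, drop = FALSE])))
  }
  valid <- full
  part <- which(!full & colSums(ok_sig) >= 7L)
  for (j in part) {
    use <- ok_sig[, j]
    Xi <- X[use, , drop = FALSE]
    qr_ <- qr(Xi)
    if (qr_$rank < 7L) next
    beta[, j] <- qr.coef(qr_, log(S[use, j]))
    valid[j] <- TRUE
  }

  d6 <- t(beta[2:7, , drop = FALSE])
  d6[!valid, ] <- 0
  es <- eig3_batch(d6)
  evals <- es$values
  clamped <- evals[, 3] < 0 | evals[, 2] < 0 | evals[, 1] < 0
  evals[evals < 0] <- 0
  degenerate <- (evals[, 1] - evals[, 2]) < 1e-6 * pmax(evals[, 1], .Machine$double.eps)
  fa <- .fa_from_evals(evals)
  valid <- valid & !is.na(fa)

  structure(list(index = idx, dims = dims, d6 = d6,
                 evals = evals,
                 e1 = es$vectors[, 1:3, drop = FALSE],
                 e2 = es$vectors[, 4:6, drop = FALSE],
                 e3 = es$vectors[, 7:9, drop = FALSE],
                 fa = fa, s0_estimate = exp(beta[1, ]),
                 valid = valid, clamped = clamped & valid,
                 degenerate = degenerate & valid),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("tensor field: %d voxels (%d valid, %d clamped, %d degenerate)\n",
              length(x$index), sum(x$valid), sum(x$clamped), sum(x$degenerate)))
  cat(sprintf("  median FA %.3f, median MD %.2e mm^2/s\n",
              median(x$fa[x$valid], na.rm = TRUE),
              median(rowMeans(x$evals)[x$valid], na.rm = TRUE)))
  invisible(x)
}

.fa_from_evals <- function(evals) {
  ss <- rowSums(evals^2)
  mb <- rowMeans(evals)
  fa <- sqrt(1.5 * rowSums((evals - mb)^2) / ss)
  fa[ss <= 0] <- NA_real_
  pmin(fa, 1)
}

#' Eigensystem of a single diffusion tensor
#'
#' @param tensor symmetric 3x3 matrix.
#' @return List with `values` (descending; negatives clamped to 0 with
#'   `clamped = TRUE`), `vectors` (columns e1, e2, e3, orthonormal,
#'   sign-arbitrary), and flags `clamped`, `degenerate` (set when
#'   `(l1 - l2)/l1 < 1e-6`).
#' @export
eigensystem <- function(tensor) {
  tensor <- as.matrix(tensor)
  if (!isTRUE(all.equal(tensor, t(tensor), tolerance = 1e-8)))
    stop("tensor must be symmetric")
  e <- eigen(tensor, symmetric = TRUE)
  clamped <- any(e$values < 0)
  vals <- pmax(e$values, 0)
  degenerate <- (vals[1] - vals[2]) < 1e-6 * max(vals[1], .Machine$double.eps)
  list(values = vals, vectors = e$vectors, clamped = clamped,
       degenerate = degenerate)
}

#' Fractional anisotropy
#'
#' `FA = sqrt(3/2) * ||lambda - mean|| / ||lambda||`, in `[0, 1]`.
#'
#' @param l1,l2,l3 eigenvalues (non-negative, not all zero); vectors are
#'   accepted elementwise.
#' @return FA values; all-zero triples are an error for scalars and `NA`
#'   elementwise.
#' @export
fractional_anisotropy <- function(l1, l2, l3) {
  ev <- cbind(l1, l2, l3)
  if (any(ev < 0)) stop("eigenvalues must be non-negative")
  fa <- .fa_from_evals(ev)
  if (length(l1) == 1L && is.na(fa)) stop("FA undefined for all-zero eigenvalues")
  as.vector(fa)
}
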