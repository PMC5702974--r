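# Shared fixtures: phantoms are generated in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# coarse desk-scale spec: same heart geometry as the default, coarser grid
coarse_spec <- function(...) {
  args <- list(...)
  if (is.null(args$dims)) args$dims <- c(64L, 64L, 40L)
  if (is.null(args$voxel_size)) args$voxel_size <- c(0.6, 0.6, 1.0)
  do.call(phantom_spec, args)
}

coarse_phantom <- function() cached("coarse_phantom", build_phantom(coarse_spec()))

coarse_analysis <- function() cached("coarse_analysis", {
  ph <- coarse_phantom()
  analyse_subject(ph$dwi, ph$scheme, ph$geometry$zone_map, ph$spec$voxel_size)
})

# synthetic tensor field from explicit e1/e3 assignments (unit tests for
# tracking and angle plumbing)
synthetic_tensor_field <- function(dims, e1, e3, fa = 0.67, index = NULL) {
  if (is.null(index)) index <- seq_len(prod(dims))
  n <- length(index)
  if (is.null(dim(e1))) e1 <- matrix(rep(e1, each = n), ncol = 3)
  if (is.null(dim(e3))) e3 <- matrix(rep(e3, each = n), ncol = 3)
  structure(list(index = index, dims = dims, e1 = e1, e3 = e3,
                 evals = matrix(rep(c(1.7e-3, 0.7e-3, 0.3e-3), each = n), ncol = 3),
                 fa = rep(fa, length.out = n), valid = rep(TRUE, n),
                 clamped = rep(FALSE, n), degenerate = rep(FALSE, n)),
            class = "tensor_field")
}

# random unit vectors
runit <- function(n) {
  m <- matrix(rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}
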