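#' Create a particle-mesh grid
#'
#' Regular grid over an orthorhombic periodic box.  Grid spacings are
#' h_d = L_d / n_d; reciprocal-space operations use angular wavenumbers
#' k = 2 pi m / L with m in FFT frequency order.  For even grid dimensions
#' the Nyquist mode of odd-order spectral derivatives is zeroed.
#'
#' @param dims length-3 integer vector of grid points per axis (>= 4).
#' @param box length-3 box edge lengths (nm).
#' @param precompute_gradients cache the per-axis i*k arrays used by
#'   spectral derivatives (default).  Disable for very large meshes used
#'   only for energies (they are built on demand if a gradient is asked
#'   for).
#' @return An object of class `hhpf_mesh` with fields `dims`, `box`,
#'   `h` (spacings), `cell_volume`, `kvec` (list of per-axis angular
#'   wavenumbers) and cached spectral arrays.
#' @export
mesh <- function(dims, box, precompute_gradients = TRUE) {
  dims <- as.integer(round(dims))
  if (length(dims) == 1L) dims <- rep(dims, 3L)
  box <- as.numeric(box)
  if (length(box) == 1L) box <- rep(box, 3L)
  if (length(dims) != 3L || any(dims < 4L))
    stop("mesh dims must be three integers >= 4")
  if (length(box) != 3L || any(box <= 0)) stop("invalid box")
  h <- box / dims
  kvec <- lapply(1:3, function(d) {
    m <- c(0:(dims[d] %/% 2), -((dims[d] - 1) %/% 2):-1)
    m <- m[seq_len(dims[d])]
    2 * pi * m / box[d]
  })
  # |k|^2 array and per-axis i*k arrays with the Nyquist derivative zeroed
  kx <- kvec[[1]]; ky <- kvec[[2]]; kz <- kvec[[3]]
  k2 <- outer(kx^2, ky^2, "+")
  k2 <- outer(k2, kz^2, "+")
  ikd <- if (precompute_gradients) .mesh_ik_build(dims, kvec) else NULL
  structure(list(dims = dims, box = box, h = h,
                 cell_volume = prod(h), kvec = kvec, k2 = k2, ik = ikd),
            class = "hhpf_mesh")
}

.mesh_ik_build <- function(dims, kvec) {
  lapply(1:3, function(d) {
    k <- kvec[[d]]
    if (dims[d] %% 2L == 0L) k[dims[d] %/% 2 + 1L] <- 0
    arr <- array(0, dims)
    if (d == 1L) arr <- array(rep(k, times = dims[2] * dims[3]), dims)
    if (d == 2L) arr <- array(rep(rep(k, each = dims[1]), times = dims[3]), dims)
    if (d == 3L) arr <- array(rep(k, each = dims[1] * dims[2]), dims)
    arr * 1i
  })
}

# i*k arrays, building them on demand for meshes created without the cache
.mesh_ik <- function(msh) {
  msh$ik %||% .mesh_ik_build(msh$dims, msh$kvec)
}

#' @export
print.hhpf_mesh <- function(x, ...) {
  cat("mesh:", paste(x$dims, collapse = " x "), "points, h =",
      paste(signif(x$h, 4), collapse = " x "), "nm\n")
  invisible(x)
}

#' Density filter specification
#'
#' The grid-independent window that smears CIC densities in reciprocal
#' space.  The Gaussian filter has transfer function
#' H(k) = exp(-sigma^2 |k|^2 / 2), i.e. a real-space Gaussian of standard
#' deviation sigma; sigma is the physical coarse-graining length,
#' independent of the grid spacing.  `identity` disables filtering
#' (recovering the conventional grid-defined particle-field model).
#' A custom filter is a function of |k| (or of k^2 via `transfer_k2`)
#' returning the transfer function; it must equal 1 at k = 0 so that
#' filtering conserves the number of particles.
#'
#' @param kind one of "gaussian", "identity", "custom".
#' @param sigma filter width (nm) for the Gaussian filter.
#' @param transfer for `kind = "custom"`: function of |k| returning H(|k|).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("gaussian", "identity", "custom"),
                        sigma = NULL, transfer = NULL) {
  kind <- match.arg(kind)
  if (kind == "gaussian") {
    if (is.null(sigma) || sigma < 0) stop("gaussian filter needs sigma >= 0")
  }
  if (kind == "custom") {
    if (!is.function(transfer)) stop("custom filter needs a transfer function")
    if (abs(transfer(0) - 1) > 1e-12)
      stop("filter transfer function must equal 1 at k = 0")
  }
  structure(list(kind = kind, sigma = sigma, transfer = transfer),
            class = "filter_spec")
}

#' Gaussian filter shorthand
#' @param sigma filter width (nm).
#' @return a `filter_spec`.
#' @export
gaussian_filter <- function(sigma) filter_spec("gaussian", sigma = sigma)

# CIC (trilinear) assignment transfer function prod_d sinc^2(k_d h_d / 2);
# dividing a painted spectrum by this deconvolves the assignment window
# (standard particle-mesh compensation).
.cic_transfer <- function(msh) {
  s1 <- function(d) {
    x <- msh$kvec[[d]] * msh$h[d] / 2
    w <- rep(1, length(x))
    nz <- x != 0
    w[nz] <- (sin(x[nz]) / x[nz])^2
    w
  }
  w <- outer(s1(1), s1(2))
  outer(w, s1(3))
}

# transfer function evaluated on the mesh's |k|^2 array
.filter_transfer <- function(filter, msh) {
  switch(filter$kind,
    gaussian = exp(-0.5 * filter$sigma^2 * msh$k2),
    identity = array(1, msh$dims),
    custom = {
      H <- filter$transfer(sqrt(msh$k2))
      array(H, msh$dims)
    })
}
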