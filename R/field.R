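#' @useDynLib hhpfmd, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.ifft <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' Paint particle number densities onto the mesh (cloud-in-cell)
#'
#' Each particle distributes unit weight over the 8 surrounding grid
#' vertices by trilinear interpolation, with periodic wrap-around; the
#' result is divided by the cell volume so that
#' `sum(phi_k) * h^3 = N_k` holds exactly (partition of unity).
#'
#' @param system a `particle_system`.
#' @param msh a mesh from [mesh()] over the same box.
#' @return An object of class `species_fields` with element `phi`: a list of
#'   K grids (number density, nm^-3), one per species.
#' @export
paint_cic <- function(system, msh) {
  if (max(abs(msh$box - system$box)) > 1e-12)
    stop("mesh box does not match system box")
  k <- length(system$species_names)
  v <- .cic_paint_cpp(system$positions, system$species, k, msh$dims,
                      msh$box, rep(1, system$n))
  ncell <- prod(msh$dims)
  phi <- lapply(seq_len(k), function(s)
    array(v[((s - 1) * ncell + 1):(s * ncell)], msh$dims))
  names(phi) <- system$species_names
  structure(list(phi = phi, phi_tilde = NULL, V = NULL, gradV = NULL,
                 mesh = msh), class = "species_fields")
}

#' Filter a density grid in reciprocal space
#'
#' phi_tilde = IFFT( FFT(phi) * H(k) ).  The Gaussian transfer function is
#' H(k) = exp(-sigma^2 |k|^2 / 2); H(0) = 1 for any admissible filter, so
#' the total integral of the density is preserved.  Filtering twice with
#' width sigma equals filtering once with sigma * sqrt(2) (Gaussian
#' semigroup property).
#'
#' @param phi a 3-d density array matching the mesh dims.
#' @param filter a `filter_spec`.
#' @param msh the mesh.
#' @return the filtered (real) array.
#' @export
filter_density <- function(phi, filter, msh) {
  if (!all(dim(phi) == msh$dims)) stop("grid dims do not match mesh")
  H <- .filter_transfer(filter, msh)
  Re(.ifft(stats::fft(phi) * H))
}

# dw/dphit_k on grids for the default chi/kappa functional
.dw_default <- function(model, phit) {
  k <- length(phit)
  tot <- Reduce(`+`, phit)
  lapply(seq_len(k), function(s) {
    acc <- model$kappa_inv * (tot - model$phi0)
    for (l in seq_len(k)) if (model$chi[s, l] != 0)
      acc <- acc + model$chi[s, l] * phit[[l]]
    acc / model$phi0
  })
}

# w on grids for the default chi/kappa functional
.w_default <- function(model, phit) {
  k <- length(phit)
  tot <- Reduce(`+`, phit)
  acc <- model$kappa_inv * (tot - model$phi0)^2
  for (s in seq_len(k)) for (l in seq_len(k)) if (model$chi[s, l] != 0)
    acc <- acc + model$chi[s, l] * phit[[s]] * phit[[l]]
  acc / (2 * model$phi0)
}

#' External potential from the filtered densities
#'
#' V_k = H * (dw / dphit_k): the per-point functional derivative of the
#' interaction energy density, convolved once more with the filter.  The
#' second convolution makes the particle-mesh forces exact gradients of the
#' discretised energy functional (the filter enters the energy through the
#' filtered density, so it reappears in the chain rule of the derivative
#' with respect to particle positions).
#'
#' @param fields a `species_fields` with `phi_tilde` set, or a list of
#'   filtered density grids.
#' @param model an `interaction_model`.
#' @param filter a `filter_spec` (defaults to the model's Gaussian filter).
#' @param msh the mesh.
#' @return list of K potential grids (kJ/mol).
#' @export
external_potential <- function(fields, model, filter = NULL, msh = NULL) {
  if (inherits(fields, "species_fields")) {
    msh <- msh %||% fields$mesh
    phit <- fields$phi_tilde
  } else phit <- fields
  if (is.null(phit)) stop("phi_tilde not computed")
  if (is.null(filter)) filter <- gaussian_filter(model$sigma)
  H <- .filter_transfer(filter, msh)
  dw <- if (is.null(model$w)) .dw_default(model, phit)
        else .eval_functional(model, phit, "dw")
  lapply(dw, function(d) Re(.ifft(stats::fft(d) * H)))
}

#' Spectral gradient of a grid field
#'
#' Component d of the gradient is IFFT( i k_d FFT(V) ); for even grid
#' dimensions the Nyquist mode of the derivative is zeroed per axis (the
#' odd-derivative convention).  Exact for resolved Fourier modes.
#'
#' @param V a real grid.
#' @param msh the mesh.
#' @return list of 3 gradient grids.
#' @export
spectral_gradient <- function(V, msh) {
  Vh <- stats::fft(V)
  ik <- .mesh_ik(msh)
  lapply(1:3, function(d) Re(.ifft(ik[[d]] * Vh)))
}

#' Interpolate grid forces back onto particles
#'
#' F_i = -sum_vertices P(r_vertex - r_i) gradV_species(i)(vertex), with the
#' same (weight-normalized, sum-to-one) CIC stencil used for painting:
#' identical kernel both ways.  This is the classic particle-mesh readout
#' of a spectrally differentiated potential; see [field_forces()] for the
#' exact-gradient readout the integrator uses.
#'
#' @param system a `particle_system`.
#' @param gradV list over species of lists of 3 gradient grids.
#' @param msh the mesh.
#' @return N x 3 force matrix (kJ/mol/nm).
#' @export
interpolate_forces <- function(system, gradV, msh) {
  k <- length(system$species_names)
  if (length(gradV) != k) stop("gradV must have one entry per species")
  field <- unlist(lapply(gradV, function(g) c(g[[1]], g[[2]], g[[3]])),
                  use.names = FALSE)
  g <- .cic_gather_cpp(system$positions, system$species, k, field,
                       msh$dims, msh$box)
  -g
}

#' Exact-gradient force readout from potential grids
#'
#' F_i = -d/dr_i of the CIC interpolant of V_species(i): the trilinear
#' weights are differentiated analytically, so the force is the exact
#' negative gradient of the discrete energy functional with respect to
#' the particle position (to round-off), at any grid resolution.  The
#' spectral-derivative readout ([spectral_gradient()] +
#' [interpolate_forces()]) agrees with this up to interpolation error
#' that vanishes with grid refinement.
#'
#' @param system a `particle_system`.
#' @param V list over species of external-potential grids.
#' @param msh the mesh.
#' @return N x 3 force matrix (kJ/mol/nm).
#' @export
readout_forces <- function(system, V, msh) {
  k <- length(system$species_names)
  if (length(V) != k) stop("V must have one entry per species")
  field <- unlist(V, use.names = FALSE)
  g <- .cic_gather_grad_cpp(system$positions, system$species, k, field,
                            msh$dims, msh$box)
  -g
}

#' Interaction energy functional on the mesh
#'
#' W = h^3 sum_ijk w(phit_1 .. phit_K), midpoint quadrature of the energy
#' density over the grid.
#'
#' @param fields `species_fields` with `phi_tilde`, or a list of filtered
#'   density grids.
#' @param model an `interaction_model`.
#' @param msh the mesh (optional when `fields` carries one).
#' @return energy (kJ/mol).
#' @export
field_energy <- function(fields, model, msh = NULL) {
  if (inherits(fields, "species_fields")) {
    msh <- msh %||% fields$mesh
    phit <- fields$phi_tilde
  } else phit <- fields
  if (is.null(phit)) stop("phi_tilde not computed")
  w <- if (is.null(model$w)) .w_default(model, phit)
       else .eval_functional(model, phit, "w")
  msh$cell_volume * sum(w)
}

#' Full particle-field force evaluation
#'
#' One-call pipeline: CIC painting, reciprocal-space filtering, functional
#' derivative, second filter convolution, and exact-gradient CIC force
#' readout (see [readout_forces()]), so that the returned forces are the
#' exact negative gradients of the returned energy with respect to the
#' particle positions.  This is the evaluation the rRESPA integrator
#' performs once per outer step.
#'
#' @param system a `particle_system`.
#' @param model an `interaction_model`.
#' @param msh the mesh.
#' @param filter optional `filter_spec`; defaults to the model's Gaussian.
#' @param Hhat optional precomputed transfer array (internal cache).
#' @param readout force readout: `"spectral"` (default) differentiates the
#'   external potential in reciprocal space and interpolates the gradient
#'   back with the CIC stencil — the conventional particle-mesh force,
#'   continuous in the particle positions; `"exact"` differentiates the
#'   CIC interpolant of V analytically, giving the exact negative gradient
#'   of the discrete energy at any resolution (the two agree under grid
#'   refinement).
#' @param compute_fields also return the full `species_fields` (phi,
#'   phi_tilde, V, gradV) for diagnostics.
#' @return list with `forces` (N x 3), `energy` (kJ/mol) and optionally
#'   `fields`.
#' @export
field_forces <- function(system, model, msh, filter = NULL, Hhat = NULL,
                         readout = c("spectral", "exact"),
                         compute_fields = FALSE) {
  readout <- match.arg(readout)
  if (is.null(filter)) filter <- gaussian_filter(model$sigma)
  if (is.null(Hhat)) Hhat <- .filter_transfer(filter, msh)
  k <- length(system$species_names)
  ncell <- prod(msh$dims)
  v <- .cic_paint_cpp(system$positions, system$species, k, msh$dims,
                      msh$box, rep(1, system$n))
  phi <- lapply(seq_len(k), function(s)
    array(v[((s - 1) * ncell + 1):(s * ncell)], msh$dims))
  phit <- lapply(phi, function(p) Re(.ifft(stats::fft(p) * Hhat)))
  dw <- if (is.null(model$w)) .dw_default(model, phit)
        else .eval_functional(model, phit, "dw")
  need_grad <- readout == "spectral" || compute_fields
  gradV <- if (need_grad) vector("list", k) else NULL
  Vlist <- vector("list", k)
  for (s in seq_len(k)) {
    ghat <- stats::fft(dw[[s]]) * Hhat
    if (readout == "exact" || compute_fields) Vlist[[s]] <- Re(.ifft(ghat))
    if (need_grad) {
      ik <- .mesh_ik(msh)
      gradV[[s]] <- lapply(1:3, function(d) Re(.ifft(ik[[d]] * ghat)))
    }
  }
  forces <- if (readout == "exact") readout_forces(system, Vlist, msh)
            else interpolate_forces(system, gradV, msh)
  w <- if (is.null(model$w)) .w_default(model, phit)
       else .eval_functional(model, phit, "w")
  energy <- msh$cell_volume * sum(w)
  out <- list(forces = forces, energy = energy)
  if (compute_fields) {
    names(phi) <- names(phit) <- names(Vlist) <- names(gradV) <-
      system$species_names
    out$fields <- structure(list(phi = phi, phi_tilde = phit, V = Vlist,
                                 gradV = gradV, mesh = msh),
                            class = "species_fields")
  }
  out
}

#' Two-particle field-potential energy curve
#'
#' Energy of a pair of particles interacting only through the density
#' functional, as a function of their separation: W(d) - W(infinity),
#' averaged over random sub-grid offsets and orientations of the pair.
#' The separation-independent single-particle (self) energies are removed
#' per configuration, which for the quadratic chi/kappa functional equals
#' referencing to infinite separation.  In the grid-converged Gaussian
#' filtered limit the curve is proportional to exp(-d^2 / (4 sigma^2))
#' (the correlation of two sigma-Gaussian clouds); in unfiltered mode
#' (`filter_spec("identity")`) it is the conventional grid-defined
#' particle-field pair energy with finite range ~2h.
#'
#' @param model an `interaction_model` (a single-species model is used;
#'   the pair couples through chi[1,1] + kappa_inv).
#' @param msh the mesh.
#' @param separations numeric vector of pair distances (nm), each < box/2.
#' @param filter a `filter_spec`; defaults to the model's Gaussian.
#' @param n_offsets number of randomized offsets/orientations averaged.
#' @param orientations "random" directions or "axis" (cycled x/y/z).
#' @param compensate divide the painted spectra by the CIC assignment
#'   transfer function (standard particle-mesh deconvolution), so the
#'   curve is free of the O((h/sigma)^2) assignment-width bias and
#'   reaches the Gaussian-core limit on any adequately resolved grid.
#' @return data.frame with `separation` and `energy` (kJ/mol).
#' @export
pair_potential_scan <- function(model, msh, separations, filter = NULL,
                                n_offsets = 32,
                                orientations = c("random", "axis"),
                                compensate = FALSE) {
  orientations <- match.arg(orientations)
  if (any(separations > min(msh$box) / 2))
    stop("separation exceeds half the box; enlarge the box")
  if (is.null(filter)) filter <- gaussian_filter(model$sigma)
  H <- .filter_transfer(filter, msh)
  if (compensate) H <- H / .cic_transfer(msh)
  box <- msh$box
  coef <- (model$chi[1, 1] + model$kappa_inv) / model$phi0
  ncell <- prod(msh$dims)
  # cross energy of two unit CIC clouds via Parseval:
  #   coef * (h^3 / ncell) * sum_k Re(rho1_hat * conj(rho2_hat)) H(k)^2
  cross_energy <- function(p1, p2) {
    r1 <- array(.cic_paint_cpp(rbind(p1), 1L, 1L, msh$dims, box, 1), msh$dims)
    r2 <- array(.cic_paint_cpp(rbind(p2), 1L, 1L, msh$dims, box, 1), msh$dims)
    a <- Re(stats::fft(r1) * Conj(stats::fft(r2))) * H^2
    coef * msh$cell_volume * sum(a) / ncell
  }
  energy <- vapply(separations, function(d) {
    acc <- 0
    for (o in seq_len(n_offsets)) {
      orig <- stats::runif(3) * box
      u <- if (orientations == "random") {
        z <- stats::rnorm(3)
        z / sqrt(sum(z^2))
      } else {
        z <- c(0, 0, 0)
        z[(o - 1) %% 3 + 1] <- 1
        z
      }
      acc <- acc + cross_energy(orig, orig + d * u)
    }
    acc / n_offsets
  }, numeric(1))
  data.frame(separation = separations, energy = energy)
}
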