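#' Bonded (intramolecular) forces and energy
#'
#' Evaluates harmonic bonds 1/2 k_b (r - r0)^2, harmonic angles
#' 1/2 k_a (theta - theta0)^2, proper dihedrals c (1 + cos(n phi - phase))
#' and combined bending-torsional backbone terms, with minimum-image
#' displacements and exact analytic gradients.  Dihedrals use the IUPAC
#' sign convention (cis = 0, right-handed positive).  Near-collinear
#' angles (|sin theta| < 1e-8) use a capped safe derivative and are
#' counted in `n_degenerate`; dihedrals with a collinear inner bond are
#' skipped and counted likewise.
#'
#' @param system a `particle_system`.
#' @param top a `topology`.
#' @return list with `forces` (N x 3, kJ/mol/nm), `energy` (kJ/mol) and
#'   `n_degenerate` (count of degenerate-geometry fallbacks).
#' @export
bonded_forces <- function(system, top) {
  packed <- .pack_topology(top)
  out <- .bonded_forces_cpp(system$positions, system$box, packed)
  if (out$n_degenerate > 0)
    warning(out$n_degenerate, " degenerate bonded geometries encountered")
  out
}

#' Combined bending-torsional forces only
#'
#' Convenience wrapper evaluating just the backbone bend-torsion terms
#' U = 1/2 k(phi) (gamma - gamma0(phi))^2 + Vp(phi), where gamma is the
#' bending angle of the first triplet of the quadruple and phi its
#' dihedral; k, Vp and gamma0 are cosine series in phi.
#'
#' @param system a `particle_system`.
#' @param bend_torsions a `bend_torsions` list (see [topology()]).
#' @return list with `forces`, `energy`, `n_degenerate`.
#' @export
combined_bend_torsion_forces <- function(system, bend_torsions) {
  top <- topology(bend_torsions = bend_torsions)
  bonded_forces(system, top)
}

# ---------------------------------------------------------------------------
# Dipole reconstruction
# ---------------------------------------------------------------------------

# Core ghost-placement map for one backbone, written so that it also works
# on complex inputs: the Jacobian of ghost positions with respect to the
# backbone coordinates is then available by complex-step differentiation to
# machine precision.
#
# For segment j (between backbone sites j and j+1) the dipole direction is
# the in-plane unit vector perpendicular to the segment, constructed from
# the neighbouring site (j-1, or j+2 for the first segment).  The direction
# therefore depends on the local bending angle gamma of the C-alpha triplet.
.ghosts_for_backbone <- function(coords, q, delta) {
  nb <- nrow(coords)
  nseg <- nb - 1L
  out <- matrix(0i, 2L * nseg, 3L)
  csqrt <- function(x) sqrt(x)  # principal branch; fine for near-real input
  for (j in seq_len(nseg)) {
    a <- coords[j + 1L, ] - coords[j, ]
    la <- csqrt(sum(a * a))
    ahat <- a / la
    ref <- if (j > 1L) coords[j - 1L, ] - coords[j, ]
           else coords[j + 2L, ] - coords[j + 1L, ]
    p <- ref - sum(ref * ahat) * ahat
    lp2 <- sum(p * p)
    if (Mod(lp2) < 1e-16) {
      # collinear triplet: direction undefined; fall back to a fixed
      # perpendicular (normalized bisector convention degenerates here)
      w <- c(1, 0, 0)
      if (Mod(ahat[1])^2 > 0.9) w <- c(0, 1, 0)
      p <- w - sum(w * ahat) * ahat
      lp2 <- sum(p * p)
      attr(out, "collinear") <- TRUE
    }
    u <- p / csqrt(lp2)
    mid <- (coords[j, ] + coords[j + 1L, ]) / 2
    out[2L * j - 1L, ] <- mid + delta * u
    out[2L * j, ]      <- mid - delta * u
  }
  out
}

#' Reconstruct backbone dipoles as ghost charge pairs
#'
#' For each consecutive C-alpha--C-alpha segment of a peptide backbone, a
#' pair of ghost charges +q / -q is placed at the segment midpoint
#' +/- delta * u, where the unit vector u lies in the plane of the local
#' C-alpha triplet, perpendicular to the segment (so it rotates with the
#' backbone and depends on the local bending angle).  Ghost charges are
#' bookkeeping only: they are never propagated by the integrator; forces
#' acting on them are transferred back to the parent backbone sites through
#' the placement Jacobian (see [project_dipole_forces()]), which is computed
#' to machine precision by complex-step differentiation of the placement
#' map.
#'
#' @param system a `particle_system`.
#' @param spec a dipole spec: list with `backbone` (ordered indices,
#'   length >= 3), `q` (e) and `delta` (nm).
#' @return object of class `dipole_set`: list with `ghosts` (data.frame
#'   x, y, z, q), `parents` (index vector of backbone sites), `jacobian`
#'   (d ghost coords / d parent coords, (6 nseg) x (3 nb)) and `spec`.
#' @export
reconstruct_dipoles <- function(system, spec) {
  bb <- spec$backbone
  if (length(bb) < 3) stop("dipole reconstruction needs >= 3 backbone sites")
  coords <- .unwrap_chain(system$positions[bb, , drop = FALSE], system$box)
  g <- .ghosts_for_backbone(coords + 0i, spec$q, spec$delta)
  if (isTRUE(attr(g, "collinear")))
    warning("collinear backbone triplet: dipole direction fell back to a fixed perpendicular")
  nseg <- length(bb) - 1L
  ng <- 2L * nseg
  charges <- rep(c(spec$q, -spec$q), nseg)
  # complex-step Jacobian: dg/dx to machine precision
  hstep <- 1e-20
  J <- matrix(0, ng * 3L, length(bb) * 3L)
  for (p in seq_along(bb)) for (ax in 1:3) {
    cc <- coords + 0i
    cc[p, ax] <- cc[p, ax] + hstep * 1i
    gp <- .ghosts_for_backbone(cc, spec$q, spec$delta)
    J[, (p - 1L) * 3L + ax] <- as.vector(Im(gp)) / hstep
  }
  ghosts <- data.frame(x = Re(g[, 1]), y = Re(g[, 2]), z = Re(g[, 3]),
                       q = charges)
  structure(list(ghosts = ghosts, parents = bb, jacobian = J, spec = spec),
            class = "dipole_set")
}

# unwrap a chain so consecutive sites are minimum-image continuous
.unwrap_chain <- function(coords, box) {
  for (r in 2:nrow(coords)) {
    d <- coords[r, ] - coords[r - 1L, ]
    coords[r, ] <- coords[r, ] - box * round(d / box)
  }
  coords
}

#' Project ghost-charge forces onto the backbone
#'
#' Chain-rule transfer F_parent = J^T F_ghost of the electrostatic forces
#' acting on the reconstructed dipole charges onto the parent C-alpha
#' sites, so the ghost positions never need to be propagated.  The
#' projection conserves total force (the Jacobian columns sum to the
#' identity under rigid translation) and total torque.
#'
#' @param ghost_forces (2 nseg) x 3 matrix of forces on the ghost charges.
#' @param dipoles a `dipole_set` from [reconstruct_dipoles()].
#' @param n total number of particles (to size the output).
#' @return N x 3 force matrix with the projected forces on the backbone
#'   rows and zero elsewhere.
#' @export
project_dipole_forces <- function(ghost_forces, dipoles, n) {
  # ghost coordinate vector ordering: as.vector of (ng x 3) matrix
  fg <- as.vector(as.matrix(ghost_forces))
  fp <- drop(crossprod(dipoles$jacobian, fg))  # length 3 * nb, per-parent xyz
  out <- matrix(0, n, 3)
  nb <- length(dipoles$parents)
  fp <- matrix(fp, nb, 3, byrow = TRUE)
  out[dipoles$parents, ] <- out[dipoles$parents, ] + fp
  out
}
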