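#' Molecular topology
#'
#' Container for the intramolecular interaction terms of a system: harmonic
#' bonds, harmonic angles, cosine-series proper dihedrals, combined
#' bending-torsional backbone terms, and dipole reconstruction specs for
#' peptide backbones.
#'
#' @param bonds data.frame with columns `i, j, r0, k` (indices 1-based,
#'   `r0` in nm, `k` in kJ/mol/nm^2).
#' @param angles data.frame with columns `i, j, k, theta0, ka` (`theta0`
#'   radians, `ka` kJ/mol/rad^2); `j` is the apex.
#' @param dihedrals data.frame with columns `i, j, k, l, n, c, phase`:
#'   one row per harmonic, U = c (1 + cos(n phi - phase)).
#' @param bend_torsions list with elements `idx` (m x 4 index matrix) and
#'   cosine-series coefficient matrices `k_coef`, `vp_coef`, `g0_coef`
#'   (m rows; column p is the coefficient of cos((p-1) phi)).  The term is
#'   U = 1/2 k(phi) (gamma - gamma0(phi))^2 + Vp(phi), with gamma the bend
#'   angle of (i, j, k) and phi the dihedral of (i, j, k, l).
#' @param dipoles list of dipole specs, each a list with `backbone`
#'   (ordered C-alpha indices, length >= 3), `q` (ghost charge magnitude, e)
#'   and `delta` (half distance between the two ghost charges, nm).
#' @return An object of class `topology`.
#' @export
topology <- function(bonds = NULL, angles = NULL, dihedrals = NULL,
                     bend_torsions = NULL, dipoles = NULL) {
  empty <- function(cols) {
    df <- as.data.frame(matrix(numeric(0), 0, length(cols)))
    names(df) <- cols
    df
  }
  if (is.null(bonds)) bonds <- empty(c("i", "j", "r0", "k"))
  if (is.null(angles)) angles <- empty(c("i", "j", "k", "theta0", "ka"))
  if (is.null(dihedrals)) dihedrals <- empty(c("i", "j", "k", "l", "n", "c", "phase"))
  if (is.null(bend_torsions))
    bend_torsions <- list(idx = matrix(numeric(0), 0, 4),
                          k_coef = matrix(numeric(0), 0, 1),
                          vp_coef = matrix(numeric(0), 0, 1),
                          g0_coef = matrix(numeric(0), 0, 1))
  if (is.null(dipoles)) dipoles <- list()
  bt_n <- nrow(bend_torsions$idx)
  for (nm in c("k_coef", "vp_coef", "g0_coef")) {
    bend_torsions[[nm]] <- as.matrix(bend_torsions[[nm]])
    if (nrow(bend_torsions[[nm]]) != bt_n)
      stop("bend_torsions$", nm, " must have one row per term")
  }
  structure(list(bonds = as.data.frame(bonds),
                 angles = as.data.frame(angles),
                 dihedrals = as.data.frame(dihedrals),
                 bend_torsions = bend_torsions,
                 dipoles = dipoles),
            class = "topology")
}

#' Validate a topology against a particle system
#'
#' Checks index ranges, distinctness of term indices and same-molecule
#' membership for every term; errors name the offending term.
#'
#' @param top a `topology`.
#' @param system a `particle_system`.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validate_topology <- function(top, system) {
  n <- system$n
  mol <- system$molecule_id
  chk <- function(idx, what) {
    idx <- as.matrix(idx)
    if (nrow(idx) == 0) return(invisible(NULL))
    for (r in seq_len(nrow(idx))) {
      ix <- as.integer(idx[r, ])
      if (any(ix < 1L | ix > n))
        stop(sprintf("%s term %d: particle index out of range (N = %d): %s",
                     what, r, n, paste(ix, collapse = ",")))
      if (anyDuplicated(ix))
        stop(sprintf("%s term %d: repeated particle index", what, r))
      if (length(unique(mol[ix])) != 1L)
        stop(sprintf("%s term %d: particles belong to different molecules", what, r))
    }
  }
  chk(top$bonds[, c("i", "j"), drop = FALSE], "bond")
  chk(top$angles[, c("i", "j", "k"), drop = FALSE], "angle")
  chk(top$dihedrals[, c("i", "j", "k", "l"), drop = FALSE], "dihedral")
  chk(top$bend_torsions$idx, "bend-torsion")
  for (s in seq_along(top$dipoles)) {
    d <- top$dipoles[[s]]
    if (length(d$backbone) < 3)
      stop(sprintf("dipole spec %d: need at least 3 consecutive backbone sites", s))
    if (any(d$backbone < 1 | d$backbone > n))
      stop(sprintf("dipole spec %d: backbone index out of range", s))
    if (is.null(d$q) || d$q <= 0 || is.null(d$delta) || d$delta <= 0)
      stop(sprintf("dipole spec %d: q and delta must be positive", s))
  }
  invisible(TRUE)
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", nrow(x$bonds), "bonds,", nrow(x$angles), "angles,",
      nrow(x$dihedrals), "dihedral harmonics,",
      nrow(x$bend_torsions$idx), "bend-torsion terms,",
      length(x$dipoles), "dipole specs\n")
  invisible(x)
}

# pack a topology into the flat matrices the C++ kernels expect
.pack_topology <- function(top) {
  as_m <- function(df) {
    m <- as.matrix(df)
    storage.mode(m) <- "double"
    m
  }
  bt <- top$bend_torsions
  idx <- as.matrix(bt$idx)
  storage.mode(idx) <- "double"
  mk <- as.matrix(bt$k_coef); storage.mode(mk) <- "double"
  mv <- as.matrix(bt$vp_coef); storage.mode(mv) <- "double"
  mg <- as.matrix(bt$g0_coef); storage.mode(mg) <- "double"
  if (nrow(idx) == 0) {
    mk <- matrix(numeric(0), 0, 1)
    mv <- matrix(numeric(0), 0, 1)
    mg <- matrix(numeric(0), 0, 1)
  }
  list(bonds = as_m(top$bonds), angles = as_m(top$angles),
       dihedrals = as_m(top$dihedrals),
       cbt_idx = idx, cbt_k = mk, cbt_vp = mv, cbt_g0 = mg)
}
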