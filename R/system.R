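#' Create a particle system
#'
#' The central state object of the simulator: positions, velocities, masses,
#' charges, species assignment and molecule membership of N coarse-grained
#' particles in an orthorhombic periodic box.  Positions are wrapped into the
#' half-open interval `[0, L)` per dimension on construction.
#'
#' @param positions N x 3 matrix of positions (nm).
#' @param species integer vector (1..K) or character vector of species names.
#' @param box length-3 numeric, box edge lengths (nm); all must be > 0.
#' @param velocities N x 3 matrix (nm/ps); defaults to zero.
#' @param masses per-particle masses (g/mol); recycled if length 1.
#' @param charges per-particle charges (e); recycled if length 1.
#' @param molecule_id integer vector assigning particles to molecules;
#'   particles of one molecule must be index-contiguous.  Defaults to one
#'   molecule per particle.
#' @param species_names character vector of unique species labels; required
#'   when `species` is given as integers and more than `max(species)` names
#'   are wanted.
#' @return An object of class `particle_system`.
#' @export
particle_system <- function(positions, species, box, velocities = NULL,
                            masses = 72, charges = 0, molecule_id = NULL,
                            species_names = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be an N x 3 matrix")
  storage.mode(positions) <- "double"
  n <- nrow(positions)
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("invalid box: three positive edge lengths are required")
  if (is.character(species)) {
    if (is.null(species_names)) species_names <- unique(species)
    species <- match(species, species_names)
    if (anyNA(species)) stop("species name not found in species_names")
  }
  species <- as.integer(species)
  if (length(species) != n) stop("species must have one entry per particle")
  if (is.null(species_names))
    species_names <- paste0("S", seq_len(max(species, 1L)))
  if (anyDuplicated(species_names)) stop("species names must be unique")
  if (any(species < 1L | species > length(species_names)))
    stop("species index out of range")
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  velocities <- as.matrix(velocities)
  storage.mode(velocities) <- "double"
  if (!all(dim(velocities) == c(n, 3L))) stop("velocities must be N x 3")
  masses <- rep_len(as.numeric(masses), n)
  if (any(masses <= 0)) stop("masses must be positive")
  charges <- rep_len(as.numeric(charges), n)
  if (is.null(molecule_id)) molecule_id <- seq_len(n)
  molecule_id <- as.integer(molecule_id)
  if (length(molecule_id) != n) stop("molecule_id must have one entry per particle")
  if (n > 1 && any(diff(molecule_id) < 0L))
    stop("particles of one molecule must be index-contiguous")
  sys <- structure(list(
    n = n,
    positions = wrap_positions(positions, box),
    velocities = velocities,
    species = species,
    species_names = species_names,
    masses = masses,
    charges = charges,
    molecule_id = molecule_id,
    box = box
  ), class = "particle_system")
  sys
}

#' Wrap coordinates into the periodic box
#'
#' Idempotent wrapping into `[0, L)` per dimension.
#'
#' @param positions N x 3 matrix (nm).
#' @param box length-3 box (nm).
#' @return wrapped N x 3 matrix.
#' @export
wrap_positions <- function(positions, box) {
  for (d in 1:3) {
    x <- positions[, d] %% box[d]
    # x %% L can return L itself for tiny negative x
    x[x >= box[d]] <- 0
    positions[, d] <- x
  }
  positions
}

#' Mean number density of a system
#'
#' phi0 = N / V, the average particle number density entering the
#' incompressibility term of the interaction functional.
#'
#' @param system a `particle_system`.
#' @return number density (nm^-3).  For an empty system, 0 with a warning.
#' @export
compute_phi0 <- function(system) {
  v <- prod(system$box)
  if (!is.finite(v) || v <= 0) stop("invalid box: volume must be positive")
  if (system$n == 0L) {
    warning("empty system: phi0 = 0")
    return(0)
  }
  system$n / v
}

#' Kinetic energy and instantaneous temperature
#'
#' KE = 1/2 sum m_i v_i^2; T = 2 KE / (dof R) with dof = 3N - 3 when the
#' centre-of-mass degrees of freedom are removed (`remove_com = TRUE`), else
#' dof = 3N.
#'
#' @param system a `particle_system`.
#' @param remove_com logical; subtract the three centre-of-mass degrees of
#'   freedom from the temperature denominator.
#' @return list with `energy` (kJ/mol) and `temperature` (K).
#' @export
kinetic_temperature <- function(system, remove_com = TRUE) {
  ke <- 0.5 * sum(system$masses * rowSums(system$velocities^2))
  dof <- if (remove_com) 3 * system$n - 3 else 3 * system$n
  if (dof <= 0)
    stop("not enough degrees of freedom for a temperature (need N >= 2 with remove_com)")
  list(energy = ke, temperature = 2 * ke / (dof * .RGAS))
}

#' Total linear momentum
#'
#' @param system a `particle_system`.
#' @return length-3 vector, sum of m_i v_i ((g/mol) nm/ps).
#' @export
net_momentum <- function(system) {
  colSums(system$masses * system$velocities)
}

#' Remove centre-of-mass momentum
#'
#' Subtracts the mass-weighted mean velocity, leaving the system with zero
#' net momentum.  Kinetic energy never increases under this operation.
#'
#' @param system a `particle_system`.
#' @return the system with adjusted velocities.
#' @export
remove_com_momentum <- function(system) {
  vcom <- net_momentum(system) / sum(system$masses)
  system$velocities <- sweep(system$velocities, 2, vcom)
  system
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Each velocity component of particle i is N(0, R T / m_i).  Uses the
#' current R random number generator state.
#'
#' @param system a `particle_system`.
#' @param temperature target temperature (K).
#' @param remove_com subtract the centre-of-mass drift afterwards (default).
#' @return the system with new velocities.
#' @export
maxwell_velocities <- function(system, temperature, remove_com = TRUE) {
  sd <- sqrt(.RGAS * temperature / system$masses)
  system$velocities <- matrix(stats::rnorm(3 * system$n, 0, rep(sd, 3)),
                              system$n, 3)
  if (remove_com && system$n > 1) system <- remove_com_momentum(system)
  system
}

#' @export
print.particle_system <- function(x, ...) {
  cat("particle_system:", x$n, "particles,",
      length(x$species_names), "species in box",
      paste(signif(x$box, 4), collapse = " x "), "nm\n")
  tab <- table(factor(x$species_names[x$species], levels = x$species_names))
  cat("  species counts:",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
  qt <- sum(x$charges)
  if (any(x$charges != 0)) cat("  total charge:", signif(qt, 6), "e\n")
  invisible(x)
}

#' @export
summary.particle_system <- function(object, ...) {
  kt <- if (object$n >= 2) kinetic_temperature(object) else
    list(energy = 0, temperature = NA_real_)
  out <- list(
    n = object$n,
    box = object$box,
    phi0 = if (object$n > 0) object$n / prod(object$box) else 0,
    kinetic_energy = kt$energy,
    temperature = kt$temperature,
    net_momentum = net_momentum(object),
    total_charge = sum(object$charges)
  )
  class(out) <- "summary.particle_system"
  out
}

#' @export
print.summary.particle_system <- function(x, ...) {
  cat("N =", x$n, " box =", paste(signif(x$box, 4), collapse = " x "),
      " phi0 =", signif(x$phi0, 5), "nm^-3\n")
  cat("KE =", signif(x$kinetic_energy, 6), "kJ/mol  T =",
      signif(x$temperature, 5), "K\n")
  cat("net momentum:", paste(signif(x$net_momentum, 3), collapse = " "), "\n")
  invisible(x)
}
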