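#' Fixture manifest
#'
#' Deterministic record of a generated test system: name, per-species
#' counts, topology term counts, box and seed.  Regenerating a fixture
#' with the same seed reproduces the system bitwise.
#'
#' @param system a `particle_system`.
#' @param top a `topology`.
#' @param name fixture name.
#' @param seed the seed used (NA for deterministic builders).
#' @param notes free-text provenance notes.
#' @return object of class `fixture_manifest`.
#' @export
fixture_manifest <- function(system, top, name, seed = NA_integer_,
                             notes = "") {
  counts <- table(factor(system$species_names[system$species],
                         levels = system$species_names))
  structure(list(name = name,
                 n_particles = system$n,
                 species_counts = as.list(as.integer(counts)) |>
                   stats::setNames(names(counts)),
                 n_bonds = nrow(top$bonds),
                 n_angles = nrow(top$angles),
                 n_dihedrals = nrow(top$dihedrals),
                 n_bend_torsions = nrow(top$bend_torsions$idx),
                 n_dipole_specs = length(top$dipoles),
                 box = system$box,
                 seed = seed,
                 notes = notes),
            class = "fixture_manifest")
}

#' @export
print.fixture_manifest <- function(x, ...) {
  cat("fixture", x$name, "-", x$n_particles, "particles, box",
      paste(signif(x$box, 4), collapse = " x "), "nm, seed", x$seed, "\n")
  invisible(x)
}

#' Two-particle probe system
#'
#' Two particles placed symmetrically about the box centre along the
#' x-axis, zero velocities: the fixture for pair-potential scans and
#' force-symmetry checks.
#'
#' @param species_pair length-2 vector of species (names or indices).
#' @param box box edge(s) (nm).
#' @param separation pair distance (nm), must be < box/2.
#' @param mass bead mass (g/mol).
#' @param species_names species label set (default from `species_pair`).
#' @return list with `system`, `topology` (empty) and `manifest`.
#' @export
build_two_particle <- function(species_pair = c("A", "A"), box = 5,
                               separation = 1, mass = 72,
                               species_names = NULL) {
  box <- rep(as.numeric(box), length.out = 3)
  if (separation > min(box) / 2)
    stop("separation exceeds half the smallest box edge")
  ctr <- box / 2
  pos <- rbind(ctr - c(separation / 2, 0, 0), ctr + c(separation / 2, 0, 0))
  if (is.null(species_names) && is.character(species_pair))
    species_names <- unique(species_pair)
  sys <- particle_system(pos, species_pair, box, masses = mass,
                         species_names = species_names)
  top <- topology()
  list(system = sys, topology = top,
       manifest = fixture_manifest(sys, top, "two_particle",
                                   notes = sprintf("separation %g nm",
                                                   separation)))
}

#' Charged pair probe
#'
#' As [build_two_particle()] with charges on the two beads; used by the
#' electrostatics oracles.
#'
#' @param q1,q2 charges (e).
#' @param separation pair distance (nm).
#' @param box box edge(s) (nm).
#' @param mass bead mass.
#' @return list with `system`, `topology`, `manifest`.
#' @export
build_charged_pair <- function(q1 = 1, q2 = -1, separation = 1, box = 5,
                               mass = 72) {
  fx <- build_two_particle(c("A", "A"), box, separation, mass)
  fx$system$charges <- c(q1, q2)
  fx$manifest <- fixture_manifest(fx$system, fx$topology, "charged_pair",
                                  notes = sprintf("q = (%g, %g)", q1, q2))
  fx
}

#' Homopolymer melt fixture
#'
#' Random-walk homopolymer chains of fixed bond length, bonds only,
#' velocities drawn from the Maxwell-Boltzmann distribution at the target
#' temperature.  Seed-deterministic.
#'
#' @param n_chains number of chains.
#' @param chain_length beads per chain (default 10).
#' @param box box edge(s) (nm).
#' @param bond_length initial and equilibrium bond length r0 (nm).
#' @param bond_k bond force constant (kJ/mol/nm^2).
#' @param mass bead mass (g/mol).
#' @param temperature Maxwell-Boltzmann initialisation temperature (K).
#' @param seed RNG seed.
#' @return list with `system`, `topology`, `manifest`.
#' @export
build_homopolymer_melt <- function(n_chains = 10, chain_length = 10,
                                   box = 4, bond_length = 0.5,
                                   bond_k = 1250, mass = 72,
                                   temperature = 323, seed = 1) {
  set.seed(seed)
  box <- rep(as.numeric(box), length.out = 3)
  n <- n_chains * chain_length
  pos <- matrix(0, n, 3)
  for (c in seq_len(n_chains)) {
    start <- stats::runif(3) * box
    at <- start
    for (b in seq_len(chain_length)) {
      i <- (c - 1) * chain_length + b
      pos[i, ] <- at
      step <- stats::rnorm(3)
      at <- at + bond_length * step / sqrt(sum(step^2))
    }
  }
  mol <- rep(seq_len(n_chains), each = chain_length)
  sys <- particle_system(pos, rep(1L, n), box, masses = mass,
                         molecule_id = mol, species_names = "HP")
  sys <- maxwell_velocities(sys, temperature)
  i1 <- unlist(lapply(seq_len(n_chains), function(c)
    (c - 1) * chain_length + seq_len(chain_length - 1)))
  bonds <- data.frame(i = i1, j = i1 + 1L, r0 = bond_length, k = bond_k)
  top <- topology(bonds = bonds)
  list(system = sys, topology = top,
       manifest = fixture_manifest(sys, top, "homopolymer_melt", seed,
                                   sprintf("%d chains x %d beads",
                                           n_chains, chain_length)))
}

# 10-bead coarse-grained lipid template (head N, P; glycerol G x2; two
# 3-bead C tails), shape-compatible with a 4-to-1 mapped phospholipid.
# Parameters are representative placeholders, not a published set.
.lipid_template <- function(bond_r0 = 0.47, bond_k = 1250,
                            theta0 = pi, ka = 25) {
  species <- c("N", "P", "G", "G", "C", "C", "C", "C", "C", "C")
  bonds <- data.frame(
    i = c(1, 2, 3, 3, 5, 6, 4, 8, 9),
    j = c(2, 3, 4, 5, 6, 7, 8, 9, 10),
    r0 = bond_r0, k = bond_k)
  angles <- data.frame(
    i  = c(1, 2, 2, 3, 5, 3, 4, 8),
    j  = c(2, 3, 3, 5, 6, 4, 8, 9),
    k  = c(3, 4, 5, 6, 7, 8, 9, 10),
    theta0 = theta0, ka = ka)
  list(species = species, bonds = bonds, angles = angles)
}

#' Default lipid/water interaction matrix
#'
#' Representative chi matrix (kJ/mol) for the 5 species of the lipid/water
#' fixtures (N, P, G, C, W) with the qualitative structure of
#' coarse-grained phospholipid parametrizations: strongly repulsive
#' tail-water (C-W), mildly attractive head-water, weakly repulsive
#' head-tail.  A documented placeholder, not a published parameter set.
#'
#' @return 5 x 5 symmetric matrix with dimnames.
#' @export
default_lipid_chi <- function() {
  sp <- c("N", "P", "G", "C", "W")
  chi <- matrix(0, 5, 5, dimnames = list(sp, sp))
  set2 <- function(a, b, v) {
    chi[a, b] <<- v
    chi[b, a] <<- v
  }
  set2("N", "P", -1.5)
  set2("N", "G", 6.6)
  set2("N", "C", 13.5)
  set2("N", "W", -3.8)
  set2("P", "G", 4.5)
  set2("P", "C", 14.7)
  set2("P", "W", -1.5)
  set2("G", "C", 8.5)
  set2("G", "W", 4.5)
  set2("C", "W", 33.75)
  chi
}

#' Lipid/water box fixture
#'
#' `n_lipids` 10-bead coarse-grained lipids (N, P, G x 2, two 3-bead C
#' tails) plus water beads, either scattered at random (`random`) or as a
#' preassembled symmetric bilayer with its midplane normal to z
#' (`bilayer`).  Seed-deterministic; velocities Maxwell-Boltzmann at the
#' target temperature.  The accompanying chi matrix default is
#' [default_lipid_chi()] (a placeholder with the qualitative hydrophobic /
#' hydrophilic structure).
#'
#' @param n_lipids number of lipids.
#' @param waters_per_lipid water beads per lipid.
#' @param box box edges (nm), length 1 or 3.
#' @param arrangement "random" or "bilayer".
#' @param temperature Maxwell-Boltzmann initialisation temperature (K).
#' @param mass bead mass (g/mol).
#' @param seed RNG seed.
#' @param max_retries placement retries per molecule before giving up.
#' @return list with `system`, `topology`, `chi`, `manifest`.
#' @export
build_lipid_water_box <- function(n_lipids = 32, waters_per_lipid = 16,
                                  box = c(4, 4, 6),
                                  arrangement = c("random", "bilayer"),
                                  temperature = 323, mass = 72, seed = 1,
                                  max_retries = 200) {
  arrangement <- match.arg(arrangement)
  set.seed(seed)
  box <- rep(as.numeric(box), length.out = 3)
  tmpl <- .lipid_template()
  nb <- length(tmpl$species)
  n_w <- round(n_lipids * waters_per_lipid)
  n <- n_lipids * nb + n_w
  sp_names <- c("N", "P", "G", "C", "W")
  pos <- matrix(0, n, 3)
  species <- integer(n)
  mol <- integer(n)
  # straight lipid conformation along a direction u: head bead 1 first;
  # a small transverse jitter avoids exactly collinear angle triplets
  lipid_coords <- function(origin, u) {
    spacing <- 0.47
    zline <- sweep(outer(0:6, u) * spacing, 2, origin, "+")
    out <- matrix(0, nb, 3)
    # N P G1 G2 along u; tail A continues off G1, tail B off G2 sideways
    perp <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- perp - sum(perp * u) * u
    perp <- perp / sqrt(sum(perp^2))
    out[1, ] <- zline[1, ]
    out[2, ] <- zline[2, ]
    out[3, ] <- zline[3, ]
    out[4, ] <- zline[3, ] + 0.33 * perp + 0.33 * spacing * u
    out[5, ] <- zline[4, ]                     # tail A1 (off G1)
    out[6, ] <- zline[5, ]
    out[7, ] <- zline[6, ]
    out[8, ] <- out[4, ] + spacing * u         # tail B1 (off G2)
    out[9, ] <- out[8, ] + spacing * u
    out[10, ] <- out[9, ] + spacing * u
    out + matrix(stats::runif(3 * nb, -0.02, 0.02), nb, 3)
  }
  centers <- matrix(NA_real_, n_lipids, 3)
  if (arrangement == "bilayer") {
    per_leaf <- ceiling(n_lipids / 2)
    ngrid <- ceiling(sqrt(per_leaf))
    gx <- box[1] / ngrid
    gy <- box[2] / ngrid
    zmid <- box[3] / 2
    for (m in seq_len(n_lipids)) {
      leaf <- if (m <= per_leaf) 1 else 2
      idx <- if (leaf == 1) m - 1 else m - per_leaf - 1
      cx <- (idx %% ngrid + 0.5) * gx + stats::runif(1, -0.05, 0.05)
      cy <- (idx %/% ngrid + 0.5) * gy + stats::runif(1, -0.05, 0.05)
      u <- if (leaf == 1) c(0, 0, 1) else c(0, 0, -1)  # head -> tail
      origin <- c(cx, cy, zmid - u[3] * 1.9)
      crd <- lipid_coords(origin, u)
      rows <- (m - 1) * nb + seq_len(nb)
      pos[rows, ] <- crd
      centers[m, ] <- colMeans(crd)
    }
  } else {
    min_sep <- 0.8
    for (m in seq_len(n_lipids)) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        ctr <- stats::runif(3) * box
        if (m > 1) {
          d <- sweep(centers[seq_len(m - 1), , drop = FALSE], 2, ctr)
          d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
          if (min(sqrt(rowSums(d^2))) < min_sep) next
        }
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        crd <- lipid_coords(ctr - 1.5 * u, u)
        rows <- (m - 1) * nb + seq_len(nb)
        pos[rows, ] <- crd
        centers[m, ] <- ctr
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place lipid ", m, " after ", max_retries,
             " retries; use a larger box")
    }
  }
  species[seq_len(n_lipids * nb)] <-
    rep(match(tmpl$species, sp_names), n_lipids)
  mol[seq_len(n_lipids * nb)] <- rep(seq_len(n_lipids), each = nb)
  # waters: random, kept out of the bilayer slab for the preassembled case
  wrow <- n_lipids * nb
  zmid <- box[3] / 2
  for (w in seq_len(n_w)) {
    repeat {
      p <- stats::runif(3) * box
      if (arrangement == "bilayer" && abs(p[3] - zmid) < 1.6) next
      break
    }
    pos[wrow + w, ] <- p
    species[wrow + w] <- match("W", sp_names)
    mol[wrow + w] <- n_lipids + w
  }
  sys <- particle_system(pos, species, box, masses = mass,
                         molecule_id = mol, species_names = sp_names)
  sys <- maxwell_velocities(sys, temperature)
  shift <- function(df, m) {
    df$i <- df$i + (m - 1) * nb
    df$j <- df$j + (m - 1) * nb
    if (!is.null(df$k)) df$k <- df$k + (m - 1) * nb
    df
  }
  bonds <- do.call(rbind, lapply(seq_len(n_lipids), function(m)
    shift(tmpl$bonds, m)))
  angles <- do.call(rbind, lapply(seq_len(n_lipids), function(m)
    shift(tmpl$angles, m)))
  top <- topology(bonds = bonds, angles = angles)
  list(system = sys, topology = top, chi = default_lipid_chi(),
       manifest = fixture_manifest(sys, top, "lipid_water_box", seed,
                                   paste0(arrangement, " arrangement, ",
                                          n_lipids, " lipids + ", n_w,
                                          " waters")))
}
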