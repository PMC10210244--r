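# shared helpers for the test suite

# central finite-difference gradient of a scalar function of one particle
# coordinate; returns the FD force component (-dE/dx)
fd_force <- function(system, i, ax, energy_fun, eps = 1e-5) {
  sp <- system; sp$positions[i, ax] <- sp$positions[i, ax] + eps
  sm <- system; sm$positions[i, ax] <- sm$positions[i, ax] - eps
  -(energy_fun(sp) - energy_fun(sm)) / (2 * eps)
}

# minimum-image distance between two position matrices
periodic_dist <- function(a, b, box) {
  d <- abs(a - b)
  d <- pmin(d, rep(box, each = nrow(d)) - d)
  sqrt(rowSums(d^2))
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# a small random two-species system for force oracles
random_two_species_system <- function(n = 12, box = c(3, 3, 3), seed = 42) {
  set.seed(seed)
  particle_system(matrix(stats::runif(3 * n), n, 3) %*% diag(box),
                  sample(1:2, n, TRUE), box,
                  species_names = c("A", "B"))
}

# a compact bonded molecule exercising every term type
bonded_test_molecule <- function() {
  pos <- matrix(c(0, 0, 0, 0.5, 0.1, 0, 0.9, 0.5, 0.2, 1.2, 0.2, 0.6,
                  1.5, 0.6, 0.9, 1.1, 1.0, 1.2), 6, 3, byrow = TRUE) + 1
  sys <- particle_system(pos, rep(1, 6), c(4, 4, 4), molecule_id = rep(1, 6))
  top <- topology(
    bonds = data.frame(i = 1:5, j = 2:6, r0 = 0.45, k = 900),
    angles = data.frame(i = 1:4, j = 2:5, k = 3:6, theta0 = 2.0, ka = 30),
    dihedrals = data.frame(i = 1:3, j = 2:4, k = 3:5, l = 4:6,
                           n = c(1, 2, 3), c = c(4, 2, 1),
                           phase = c(0, 0.4, 1.0)),
    bend_torsions = list(
      idx = matrix(c(1, 2, 3, 4, 2, 3, 4, 5), 2, 4, byrow = TRUE),
      k_coef = matrix(c(20, 3, 1, 15, -2, 0.5), 2, 3, byrow = TRUE),
      vp_coef = matrix(c(2, 1, 0.3, 1, 0.5, -0.2), 2, 3, byrow = TRUE),
      g0_coef = matrix(c(1.9, 0.1, 0.05, 2.0, -0.1, 0.02), 2, 3, byrow = TRUE)))
  list(system = sys, topology = top)
}
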