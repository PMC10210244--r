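test_that("harmonic bonds reproduce closed forms", {
  box <- c(4, 4, 4)
  pos <- rbind(c(1, 1, 1), c(1.45, 1, 1))
  sys <- particle_system(pos, c(1, 1), box, molecule_id = c(1, 1))
  top <- topology(bonds = data.frame(i = 1, j = 2, r0 = 0.45, k = 1000))
  bf <- bonded_forces(sys, top)
  expect_equal(bf$energy, 0, tolerance = 1e-12)
  expect_equal(max(abs(bf$forces)), 0, tolerance = 1e-10)
  # stretched by 0.1 nm at k_b = 1000: E = 5 kJ/mol, |F| = 100 on each
  sys$positions[2, 1] <- 1.55
  bf <- bonded_forces(sys, top)
  expect_equal(bf$energy, 5)
  expect_equal(bf$forces[1, 1], 100)
  expect_equal(bf$forces[2, 1], -100)
  # minimum image: the same bond through the periodic boundary
  sys$positions[1, ] <- c(0.1, 1, 1)
  sys$positions[2, ] <- c(3.75, 1, 1)   # distance 0.35 through the wall
  bf <- bonded_forces(sys, top)
  expect_equal(bf$energy, 0.5 * 1000 * 0.1^2)
})

test_that("all bonded terms are exact gradients with zero net force and torque", {
  fx <- bonded_test_molecule()
  bf <- bonded_forces(fx$system, fx$topology)
  efun <- function(s) bonded_forces(s, fx$topology)$energy
  for (i in 1:6) for (ax in 1:3) {
    fd <- fd_force(fx$system, i, ax, efun, eps = 1e-6)
    expect_equal(bf$forces[i, ax], fd, tolerance = 1e-6 * max(1, abs(fd)))
  }
  expect_equal(max(abs(colSums(bf$forces))), 0, tolerance = 1e-10)
  r <- fx$system$positions
  f <- bf$forces
  torque <- colSums(cbind(r[, 2] * f[, 3] - r[, 3] * f[, 2],
                          r[, 3] * f[, 1] - r[, 1] * f[, 3],
                          r[, 1] * f[, 2] - r[, 2] * f[, 1]))
  expect_equal(max(abs(torque)), 0, tolerance = 1e-10)
})

test_that("bonded energies are invariant under rigid motions and re-wrapping", {
  fx <- bonded_test_molecule()
  e0 <- bonded_forces(fx$system, fx$topology)$energy
  # translation across the periodic boundary
  sh <- fx$system
  sh$positions <- wrap_positions(sweep(sh$positions, 2, c(3.1, -2.7, 1.9), "+"),
                                 sh$box)
  expect_equal(bonded_forces(sh, fx$topology)$energy, e0, tolerance = 1e-10)
  # rotation
  th <- 0.83
  rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  ro <- fx$system
  ctr <- colMeans(ro$positions)
  ro$positions <- wrap_positions(sweep(sweep(ro$positions, 2, ctr) %*% t(rz),
                                       2, ctr, "+"), ro$box)
  expect_equal(bonded_forces(ro, fx$topology)$energy, e0, tolerance = 1e-9)
})

test_that("combined bend-torsion reduces to its degenerate limits", {
  fx <- bonded_test_molecule()
  sys <- fx$system
  # k(phi) = k, Vp = 0, gamma0 = const: exactly a harmonic angle term
  bt <- list(idx = matrix(c(1, 2, 3, 4), 1, 4),
             k_coef = matrix(25, 1, 1),
             vp_coef = matrix(0, 1, 1),
             g0_coef = matrix(1.8, 1, 1))
  cbt <- combined_bend_torsion_forces(sys, bt)
  ang <- bonded_forces(sys, topology(angles = data.frame(
    i = 1, j = 2, k = 3, theta0 = 1.8, ka = 25)))
  expect_equal(cbt$energy, ang$energy, tolerance = 1e-12)
  expect_equal(cbt$forces, ang$forces, tolerance = 1e-10)
  # gamma == gamma0(phi) everywhere: energy reduces to Vp(phi) and forces
  # are purely torsional (no force along the bend gradient)
  u <- sys$positions[1, ] - sys$positions[2, ]
  v <- sys$positions[3, ] - sys$positions[2, ]
  gamma <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  b1 <- sys$positions[2, ] - sys$positions[1, ]
  b2 <- sys$positions[3, ] - sys$positions[2, ]
  b3 <- sys$positions[4, ] - sys$positions[3, ]
  crossp <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  n1 <- crossp(b1, b2)
  n2 <- crossp(b2, b3)
  phi <- atan2(sum(crossp(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
  bt2 <- list(idx = matrix(c(1, 2, 3, 4), 1, 4),
              k_coef = matrix(40, 1, 1),
              vp_coef = matrix(c(3, 1.5), 1, 2),
              g0_coef = matrix(gamma, 1, 1))
  cbt2 <- combined_bend_torsion_forces(sys, bt2)
  expect_equal(cbt2$energy, 3 + 1.5 * cos(phi), tolerance = 1e-10)
})

test_that("dipole reconstruction places, rotates and projects correctly", {
  box <- c(4, 4, 4)
  nb <- 5
  bb <- matrix(c(1.0, 1.0, 1.0, 1.4, 1.2, 1.05, 1.8, 1.1, 1.3,
                 2.2, 1.3, 1.5, 2.6, 1.2, 1.8), nb, 3, byrow = TRUE)
  pos <- rbind(bb, c(3.0, 2.5, 2.5))
  sys <- particle_system(pos, rep(1, nb + 1), box,
                         charges = c(rep(0, nb), 1),
                         molecule_id = c(rep(1, nb), 2))
  spec <- list(backbone = 1:nb, q = 0.25, delta = 0.06)
  ds <- reconstruct_dipoles(sys, spec)
  # charges per dipole sum to zero
  expect_equal(sum(ds$ghosts$q), 0)
  expect_equal(max(abs(tapply(ds$ghosts$q, rep(1:(nb - 1), each = 2),
                              sum))), 0)
  # ghosts equidistant (delta) from segment midpoints
  mid <- (bb[1:4, ] + bb[2:5, ]) / 2
  gp <- as.matrix(ds$ghosts[, 1:3])
  expect_equal(sqrt(rowSums((gp - mid[rep(1:4, each = 2), ])^2)),
               rep(0.06, 8), tolerance = 1e-12)
  # rigid rotation of the backbone rotates all ghosts identically
  th <- 0.7
  rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  ctr <- colMeans(bb)
  sys2 <- sys
  sys2$positions[1:nb, ] <- sweep(sweep(bb, 2, ctr) %*% t(rz), 2, ctr, "+")
  ds2 <- reconstruct_dipoles(sys2, spec)
  expect_equal(unname(as.matrix(ds2$ghosts[, 1:3])),
               sweep(sweep(gp, 2, ctr) %*% t(rz), 2, ctr, "+"),
               tolerance = 1e-10)
  # zero ghost forces project to zero
  z <- project_dipole_forces(matrix(0, 8, 3), ds, sys$n)
  expect_equal(max(abs(z)), 0)
  # translations pass through: total projected force equals total ghost force
  set.seed(2)
  gfor <- matrix(rnorm(24), 8, 3)
  pf <- project_dipole_forces(gfor, ds, sys$n)
  expect_equal(colSums(pf), colSums(gfor), tolerance = 1e-9)
})

test_that("dipole-projected electrostatic forces match the energy gradient", {
  box <- c(4, 4, 4)
  nb <- 5
  bb <- matrix(c(1.0, 1.0, 1.0, 1.4, 1.2, 1.05, 1.8, 1.1, 1.3,
                 2.2, 1.3, 1.5, 2.6, 1.2, 1.8), nb, 3, byrow = TRUE)
  pos <- rbind(bb, c(3.03, 2.52, 2.51))  # off-vertex: the CIC
  # interpolant is differentiable away from cell boundaries
  sys <- particle_system(pos, rep(1, nb + 1), box,
                         charges = c(rep(0, nb), 1),
                         molecule_id = c(rep(1, nb), 2))
  spec <- list(backbone = 1:nb, q = 0.25, delta = 0.06)
  msh <- mesh(rep(32, 3), box)
  cfg <- electrostatics_config(epsilon_r = 1)
  gf <- gaussian_filter(0.5)
  wfun <- function(s) {
    d <- reconstruct_dipoles(s, spec)
    electrostatics_eval(s, cfg, gf, msh, ghosts = d$ghosts)$energy
  }
  ds <- reconstruct_dipoles(sys, spec)
  ee <- electrostatics_eval(sys, cfg, gf, msh, ghosts = ds$ghosts,
                            readout = "exact")
  ftot <- ee$forces + project_dipole_forces(ee$ghost_forces, ds, sys$n)
  for (i in c(1, 3, 5, 6)) for (ax in 1:3) {
    fd <- fd_force(sys, i, ax, wfun)
    expect_equal(ftot[i, ax], fd, tolerance = 1e-6 * max(1, abs(fd)))
  }
})

test_that("degenerate geometries take the safe fallback paths", {
  box <- c(4, 4, 4)
  # collinear angle triplet
  pos <- rbind(c(1, 1, 1), c(1.5, 1, 1), c(2, 1, 1))
  sys <- particle_system(pos, rep(1, 3), box, molecule_id = rep(1, 3))
  top <- topology(angles = data.frame(i = 1, j = 2, k = 3, theta0 = 2.0,
                                      ka = 30))
  expect_warning(bf <- bonded_forces(sys, top), "degenerate")
  expect_true(all(is.finite(bf$forces)))
  # collinear inner bond of a dihedral: term skipped
  pos4 <- rbind(c(1, 1, 1), c(1.5, 1, 1), c(2, 1, 1), c(2.5, 1.4, 1))
  sys4 <- particle_system(pos4, rep(1, 4), box, molecule_id = rep(1, 4))
  top4 <- topology(dihedrals = data.frame(i = 1, j = 2, k = 3, l = 4,
                                          n = 1, c = 5, phase = 0))
  expect_warning(bf4 <- bonded_forces(sys4, top4), "degenerate")
  expect_equal(bf4$energy, 0)
  # collinear backbone triplet: dipole direction falls back with a warning
  bb <- rbind(c(1, 1, 1), c(1.5, 1, 1), c(2, 1, 1))
  sysb <- particle_system(bb, rep(1, 3), box, molecule_id = rep(1, 3))
  expect_warning(reconstruct_dipoles(sysb, list(backbone = 1:3, q = 0.2,
                                                delta = 0.05)),
                 "collinear")
  # topology validation catches bad indices
  expect_error(validate_topology(
    topology(bonds = data.frame(i = 1, j = 9, r0 = 0.4, k = 100)), sys),
    "out of range")
})
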