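test_that("CIC painting distributes unit weight with trilinear stencils", {
  box <- c(2, 2, 2)
  msh <- mesh(c(8, 8, 8), box)
  h <- msh$h[1]
  # particle exactly on a vertex: all weight on that vertex
  sys <- particle_system(matrix(c(2 * h, 3 * h, 5 * h), 1, 3), 1L, box,
                         species_names = "A")
  f <- paint_cic(sys, msh)
  phi <- f$phi[[1]]
  expect_equal(phi[3, 4, 6], 1 / msh$cell_volume)
  expect_equal(sum(phi > 0), 1)
  # particle at a cell centre: 1/8 on each surrounding vertex
  sys$positions[1, ] <- c(2.5 * h, 3.5 * h, 5.5 * h)
  phi <- paint_cic(sys, msh)$phi[[1]]
  expect_equal(sum(phi > 0), 8)
  expect_equal(max(phi), min(phi[phi > 0]))
  expect_equal(max(phi), 1 / (8 * msh$cell_volume))
  # partition of unity: sum phi h^3 = N_k for arbitrary configurations
  set.seed(5)
  n <- 40
  sys2 <- particle_system(matrix(runif(3 * n), n, 3) %*% diag(box),
                          sample(1:3, n, TRUE), box,
                          species_names = c("A", "B", "C"))
  f2 <- paint_cic(sys2, msh)
  counts <- tabulate(sys2$species, 3)
  for (s in 1:3)
    expect_equal(sum(f2$phi[[s]]) * msh$cell_volume, counts[s],
                 tolerance = 1e-12)
})

test_that("reciprocal-space filtering preserves mass and obeys the Gaussian semigroup", {
  box <- c(2, 2.5, 3)
  msh <- mesh(c(12, 16, 20), box)
  set.seed(8)
  phi <- array(runif(prod(msh$dims)), msh$dims)
  # sigma -> 0 is the identity
  expect_equal(filter_density(phi, gaussian_filter(0), msh), phi,
               tolerance = 1e-12)
  # uniform fields are unchanged (H(0) = 1)
  u <- array(3.7, msh$dims)
  expect_equal(filter_density(u, gaussian_filter(0.4), msh), u,
               tolerance = 1e-12)
  # total integral preserved
  ft <- filter_density(phi, gaussian_filter(0.3), msh)
  expect_equal(sum(ft), sum(phi), tolerance = 1e-10)
  # semigroup: twice with sigma == once with sigma * sqrt(2)
  f2 <- filter_density(filter_density(phi, gaussian_filter(0.25), msh),
                       gaussian_filter(0.25), msh)
  f1 <- filter_density(phi, gaussian_filter(0.25 * sqrt(2)), msh)
  expect_equal(f2, f1, tolerance = 1e-12)
  expect_error(filter_density(array(0, c(4, 4, 4)), gaussian_filter(0.3), msh),
               "dims")
  # custom filters must conserve density
  expect_error(filter_spec("custom", transfer = function(k) 0.5 * exp(-k^2)),
               "k = 0")
})

test_that("external potential matches closed forms and the functional derivative", {
  box <- c(3, 3, 3)
  msh <- mesh(c(16, 16, 16), box)
  phi0 <- 2.0
  m1 <- interaction_model(matrix(0, 1, 1), kappa_inv = 3, sigma = 0.4,
                          phi0 = phi0, species = "A")
  # phi_tilde == phi0 everywhere -> V == 0
  V <- external_potential(list(array(phi0, msh$dims)), m1, msh = msh)
  expect_equal(max(abs(V[[1]])), 0, tolerance = 1e-12)
  # uniform offset: V = delta kappa_inv / phi0
  V2 <- external_potential(list(array(phi0 + 0.5, msh$dims)), m1, msh = msh)
  expect_equal(V2[[1]], array(0.5 * 3 / phi0, msh$dims), tolerance = 1e-10)
  # brute-force functional derivative: perturb phi_tilde at one grid point
  m2 <- interaction_model(matrix(c(0, 5, 5, 0), 2, 2), kappa_inv = 2.4,
                          sigma = 0.4, phi0 = phi0, species = c("A", "B"))
  set.seed(2)
  phit <- list(array(runif(prod(msh$dims)), msh$dims),
               array(runif(prod(msh$dims)), msh$dims))
  # dW/dphit_k at a point, before the second filter convolution, equals
  # h^3 * dw/dphit_k; use the identity filter to isolate that layer
  Vd <- external_potential(phit, m2, filter = filter_spec("identity"),
                           msh = msh)
  W0 <- field_energy(phit, m2, msh)
  for (pt in list(c(3, 5, 7), c(10, 2, 14))) {
    dphi <- 1e-6
    pp <- phit
    pp[[1]][pt[1], pt[2], pt[3]] <- pp[[1]][pt[1], pt[2], pt[3]] + dphi
    pm <- phit
    pm[[1]][pt[1], pt[2], pt[3]] <- pm[[1]][pt[1], pt[2], pt[3]] - dphi
    fd <- (field_energy(pp, m2, msh) - field_energy(pm, m2, msh)) /
      (2 * dphi * msh$cell_volume)
    expect_equal(fd, Vd[[1]][pt[1], pt[2], pt[3]], tolerance = 1e-5)
  }
})

test_that("spectral gradient is exact for resolved modes and matches finite differences", {
  box <- c(2, 2.5, 3)
  msh <- mesh(c(16, 20, 24), box)
  # constant field
  g0 <- spectral_gradient(array(4, msh$dims), msh)
  expect_equal(max(abs(g0[[1]])) + max(abs(g0[[2]])) + max(abs(g0[[3]])), 0,
               tolerance = 1e-12)
  # single sine mode along x
  xv <- (0:15) / 16 * box[1]
  V <- array(0, msh$dims)
  for (i in 1:16) V[i, , ] <- sin(2 * pi * xv[i] / box[1])
  g <- spectral_gradient(V, msh)
  ex <- array(0, msh$dims)
  for (i in 1:16) ex[i, , ] <- (2 * pi / box[1]) * cos(2 * pi * xv[i] / box[1])
  expect_equal(g[[1]], ex, tolerance = 1e-12)
  expect_equal(max(abs(g[[2]])), 0, tolerance = 1e-12)
  # random band-limited field vs high-order centred differences on the grid
  set.seed(9)
  Vb <- filter_density(array(rnorm(prod(msh$dims)), msh$dims),
                       gaussian_filter(0.5), msh)
  gb <- spectral_gradient(Vb, msh)[[1]]
  h <- msh$h[1]
  idx <- function(s) ((0:15 + s) %% 16) + 1
  fd4 <- (-Vb[idx(2), , ] + 8 * Vb[idx(1), , ] - 8 * Vb[idx(-1), , ] +
            Vb[idx(-2), , ]) / (12 * h)
  expect_lt(max(abs(gb - fd4)) / max(abs(gb)), 5e-3)
})

test_that("force readout: uniform potential gives zero force; isolated particle feels none", {
  box <- c(3, 3, 3)
  msh <- mesh(c(16, 16, 16), box)
  sys <- particle_system(matrix(c(1.234, 0.77, 2.1), 1, 3), 1L, box,
                         species_names = "A")
  Vu <- list(array(5.5, msh$dims))
  gradU <- list(spectral_gradient(Vu[[1]], msh))
  expect_equal(max(abs(interpolate_forces(sys, gradU, msh))), 0,
               tolerance = 1e-10)
  expect_equal(max(abs(readout_forces(sys, Vu, msh))), 0, tolerance = 1e-10)
  # single particle with kappa-only functional: the spectral readout
  # feels no self-force (odd gradient field read out at its own centre);
  # the exact-gradient readout's residual self-force is pure assignment
  # aliasing and shrinks under refinement
  m <- interaction_model(matrix(0, 1, 1), kappa_inv = 2, sigma = 0.5,
                         phi0 = 1, species = "A")
  ff <- field_forces(sys, m, msh, readout = "spectral")
  expect_lt(max(abs(ff$forces)), 1e-12)
  f_ex <- sapply(c(16, 48), function(n) {
    max(abs(field_forces(sys, m, mesh(rep(n, 3), box),
                         readout = "exact")$forces))
  })
  expect_lt(f_ex[2], f_ex[1])
})

test_that("two-particle field forces are equal and opposite, tightening with sigma/h", {
  m <- interaction_model(matrix(0, 1, 1), kappa_inv = 2, sigma = 0.45,
                         phi0 = 1, species = "A")
  asym <- sapply(c(12, 24), function(n) {
    msh <- mesh(rep(n, 3), c(3, 3, 3))
    fx <- build_two_particle(box = 3, separation = 0.53)
    # off-grid placement
    fx$system$positions <- fx$system$positions + 0.013
    ff <- field_forces(fx$system, m, msh, readout = "spectral")
    sum(abs(ff$forces[1, ] + ff$forces[2, ])) / sum(abs(ff$forces[1, ]))
  })
  expect_lt(asym[2], asym[1])
  expect_lt(asym[2], 1e-3)
})

test_that("field energy closed forms hold for homogeneous systems", {
  box <- c(2, 3, 4)
  msh <- mesh(c(8, 12, 16), box)
  phi0 <- 3
  m <- interaction_model(matrix(0, 1, 1), kappa_inv = 5, sigma = 0.4,
                         phi0 = phi0, species = "A")
  expect_equal(field_energy(list(array(phi0, msh$dims)), m, msh), 0,
               tolerance = 1e-10)
  delta <- 0.7
  expect_equal(field_energy(list(array(phi0 + delta, msh$dims)), m, msh),
               prod(box) * 5 * delta^2 / (2 * phi0), tolerance = 1e-10)
})

test_that("custom symbolic functionals reproduce the built-in chi/kappa model", {
  sys <- random_two_species_system()
  msh <- mesh(c(16, 16, 16), sys$box)
  phi0 <- compute_phi0(sys)
  chi <- matrix(c(0, 5, 5, 0), 2, 2)
  m1 <- interaction_model(chi, kappa_inv = 2.4, sigma = 0.5, phi0 = phi0,
                          species = c("A", "B"))
  m2 <- interaction_model(chi, kappa_inv = 2.4, sigma = 0.5, phi0 = phi0,
                          species = c("A", "B"),
                          w = quote((2 * 5 * phi_A * phi_B +
                                       2.4 * (phi_A + phi_B - phi0)^2) /
                                      (2 * phi0)))
  f1 <- field_forces(sys, m1, msh)
  f2 <- field_forces(sys, m2, msh)
  expect_equal(f1$energy, f2$energy, tolerance = 1e-12)
  expect_equal(f1$forces, f2$forces, tolerance = 1e-12)
  # non-differentiable functionals are rejected
  expect_error(interaction_model(chi, kappa_inv = 2.4, sigma = 0.5,
                                 phi0 = phi0, species = c("A", "B"),
                                 w = quote(besselJ(phi_A, 0) + phi_B)),
               "differentiable")
})

test_that("pair potential scan decays to zero and refines toward the Gaussian core", {
  m <- interaction_model(matrix(0, 1, 1), kappa_inv = 2, sigma = 0.3,
                         phi0 = 1, species = "A")
  seps <- c(0.3, 0.9, 2.4)  # 1, 3 and 8 sigma
  set.seed(1)
  curves <- lapply(c(32, 64), function(n) {
    msh <- mesh(rep(n, 3), rep(6, 3))
    pair_potential_scan(m, msh, seps, n_offsets = 8, compensate = TRUE)
  })
  gc <- 2 * (4 * pi * 0.3^2)^-1.5 * exp(-seps^2 / (4 * 0.3^2))
  err <- sapply(curves, function(cu) max(abs(cu$energy - gc)))
  expect_lt(err[2], err[1])        # monotone refinement
  # separation of 8 sigma: interaction has vanished
  expect_lt(abs(curves[[2]]$energy[3]), 1e-6 * max(abs(curves[[2]]$energy)))
  expect_error(pair_potential_scan(m, mesh(rep(16, 3), rep(6, 3)), 4),
               "half the box")
})

test_that("field energy becomes translation invariant under grid refinement", {
  # sub-grid shifts change the energy only through assignment aliasing,
  # which decays as sigma/h grows
  m <- interaction_model(matrix(0, 1, 1), kappa_inv = 2, sigma = 0.5,
                         phi0 = 1, species = "A")
  fx <- build_two_particle(box = 3, separation = 0.5)
  set.seed(11)
  dev <- sapply(c(16, 48), function(n) {
    msh <- mesh(rep(n, 3), c(3, 3, 3))
    e0 <- field_forces(fx$system, m, msh)$energy
    d <- 0
    for (rep in 1:4) {
      sh <- fx$system
      sh$positions <- wrap_positions(sweep(sh$positions, 2,
                                           runif(3) * msh$h, "+"), sh$box)
      d <- max(d, abs(field_forces(sh, m, msh)$energy - e0) / abs(e0))
    }
    d
  })
  expect_lt(dev[2], dev[1])
  expect_lt(dev[2], 5e-4)   # sigma/h = 8
})
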