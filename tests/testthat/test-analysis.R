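test_that("sigma calibration recovers a known width and scales with the reference spacing", {
  # self-consistency: reference = the Gaussian-core curve at sigma* = 0.25
  h_ref <- 0.5875
  seps <- seq(0, 3 * h_ref, length.out = 25)
  gcref <- data.frame(
    separation = seps,
    energy = (4 * pi * 0.25^2)^-1.5 * exp(-seps^2 / (4 * 0.25^2)))
  cal <- calibrate_sigma(reference = gcref, conv_n = 48)
  expect_lt(abs(cal$sigma - 0.25), 1e-3)
  # fitted sigma scales linearly when the reference spacing is doubled
  cal1 <- calibrate_sigma(h_ref = h_ref, n_offsets = 16, conv_n = 48,
                          seed = 7)
  cal2 <- calibrate_sigma(h_ref = 2 * h_ref, n_offsets = 16, conv_n = 48,
                          sigma_range = c(0.2, 0.9), seed = 7)
  expect_lt(abs(cal2$sigma / cal1$sigma - 2), 0.02)
  # a non-bracketed minimum is reported at the boundary
  expect_error(calibrate_sigma(reference = gcref, conv_n = 48,
                               sigma_range = c(0.3, 0.45)),
               "boundary")
})

test_that("density profiles conserve counts and detect bilayer structure", {
  # uniform ideal gas: flat within counting noise
  set.seed(14)
  n <- 4000
  box <- c(3, 3, 6)
  sys <- particle_system(matrix(runif(3 * n), n, 3) %*% diag(box),
                         rep(1, n), box, species_names = "W")
  pr <- density_profile(sys, bins = 20)
  expect_equal(sum(pr$W) * attr(pr, "bin_width") * box[1] * box[2], n,
               tolerance = 1e-9)
  expect_lt(sd(pr$W) / mean(pr$W), 0.15)
  # preassembled bilayer: tails peak at the midplane, heads flank
  fb <- build_lipid_water_box(n_lipids = 64, waters_per_lipid = 8,
                              box = c(4.6, 4.6, 6), arrangement = "bilayer",
                              seed = 3)
  prb <- density_profile(fb$system, bins = 30)
  zmid <- fb$system$box[3] / 2
  ctail <- prb$z[which.max(prb$C)]
  expect_lt(abs(ctail - zmid), 1.0)
  # head density peaks away from the midplane
  expect_gt(abs(prb$z[which.max(prb$N)] - zmid), 1.0)
  # symmetrized profile is exactly mirror-symmetric
  prs <- density_profile(fb$system, bins = 30, symmetrize = TRUE)
  expect_equal(prs$C, rev(prs$C), tolerance = 1e-12)
})

test_that("energy drift fits recover synthetic slopes", {
  led <- data.frame(time = seq(0, 1000, by = 1), total = 1000)
  dr0 <- energy_drift(led)
  expect_equal(dr0$percent_per_ns, 0, tolerance = 1e-12)
  # synthetic ramp of 1 % of the mean per ns
  led$total <- 1000 + 10 * led$time / 1000
  dr1 <- energy_drift(led, n_particles = 50)
  expect_equal(dr1$percent_per_ns, 10 / 1005 * 100, tolerance = 1e-6)
  expect_equal(dr1$abs_per_particle_per_ns, 10 / 50, tolerance = 1e-9)
  expect_error(energy_drift(led[1:20, ]), "frames")
})

test_that("periodic density-based clustering identifies aggregates", {
  box <- c(6, 6, 6)
  set.seed(21)
  # two tight blobs, one split across the periodic boundary
  blob1 <- sweep(matrix(rnorm(45, sd = 0.15), 15, 3), 2, c(1, 1, 1), "+")
  blob2 <- sweep(matrix(rnorm(45, sd = 0.15), 15, 3), 2, c(5.9, 3, 3), "+")
  pts <- wrap_positions(rbind(blob1, blob2), box)
  cl <- cluster_aggregates(pts, box, cutoff = 0.6, min_samples = 4)
  expect_equal(cl$n_clusters, 2)
  expect_equal(sort(cl$sizes), c(15, 15))
  expect_equal(cl$nbar_over_n, 0.5)
  # all points mutually close: one cluster, nbar/n = 1
  tight <- matrix(rnorm(30, sd = 0.05), 10, 3) + 2
  cl1 <- cluster_aggregates(tight, box, cutoff = 1, min_samples = 4)
  expect_equal(cl1$n_clusters, 1)
  expect_equal(cl1$nbar_over_n, 1)
  # sparse gas: all noise at min_samples = 4
  sparse <- matrix(runif(60), 20, 3) %*% diag(box)
  cls <- cluster_aggregates(sparse, box, cutoff = 0.3, min_samples = 4)
  expect_equal(cls$n_clusters, 0)
  expect_true(all(cls$labels == 0))
  # invariance under permutation and rigid periodic translation
  prm <- sample(30)
  clp <- cluster_aggregates(pts[prm, ], box, cutoff = 0.6, min_samples = 4)
  expect_equal(sort(clp$sizes), sort(cl$sizes))
  sh <- wrap_positions(sweep(pts, 2, c(2.3, -1.1, 4.4), "+"), box)
  clsh <- cluster_aggregates(sh, box, cutoff = 0.6, min_samples = 4)
  expect_equal(sort(clsh$sizes), sort(cl$sizes))
  expect_equal(clsh$nbar_over_n, cl$nbar_over_n)
})

test_that("bilayer detection accepts slabs and rejects dispersed or porous states", {
  # preassembled bilayer: detected
  fb <- build_lipid_water_box(n_lipids = 64, waters_per_lipid = 8,
                              box = c(4.6, 4.6, 6), arrangement = "bilayer",
                              seed = 3)
  det <- bilayer_reached(fb$system)
  expect_true(det$bilayer)
  # randomized box at t = 0: not a bilayer
  fr <- build_lipid_water_box(n_lipids = 32, waters_per_lipid = 8,
                              box = c(4, 4, 5), arrangement = "random",
                              seed = 4)
  expect_false(bilayer_reached(fr$system)$bilayer)
  # carve a cylindrical pore out of the bilayer: the column test fails
  sysp <- fb$system
  ctr <- fb$system$box[1:2] / 2
  xy <- sysp$positions[, 1:2]
  inpore <- sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2) < 1.3
  tails <- sysp$species == match("C", sysp$species_names)
  keep <- !(inpore & tails)
  sysp$positions <- sysp$positions[keep, , drop = FALSE]
  sysp$velocities <- sysp$velocities[keep, , drop = FALSE]
  sysp$species <- sysp$species[keep]
  sysp$masses <- sysp$masses[keep]
  sysp$charges <- sysp$charges[keep]
  sysp$molecule_id <- sysp$molecule_id[keep]
  sysp$n <- sum(keep)
  detp <- bilayer_reached(sysp, column_grid = 6)
  expect_false(detp$bilayer)
  expect_false(detp$diagnostics$spanning)
})
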