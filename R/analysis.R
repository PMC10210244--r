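#' Calibrate the filter width against an unfiltered reference
#'
#' Finds the Gaussian filter width sigma whose grid-converged two-particle
#' energy curve (a Gaussian-core interaction, the correlation of two
#' sigma-Gaussian clouds) best matches the pair energy of the conventional
#' unfiltered grid-defined particle-field model at reference grid spacing
#' `h_ref`.  The reference curve is the offset- and orientation-averaged
#' two-particle scan; the converged trial curve is evaluated through the
#' exact reciprocal-space (Parseval) form of the scan in its grid-converged
#' limit, where the pair spectrum reduces to a plane-wave cross term, so
#' each sigma evaluation is a cheap lattice sum.
#'
#' The least-squares objective uses uniform weights over the separations
#' by default; because the choice of objective is not canonical, the
#' result of refitting with relative-error weights and with force curves
#' is reported alongside (`sensitivity`).
#'
#' @param reference optional reference curve (data.frame separation,
#'   energy).  By default the unfiltered scan at `h_ref` is computed.
#' @param h_ref reference grid spacing (nm); the conventional value is
#'   0.5875.
#' @param separations scan distances; default 25 points spanning
#'   `[0, 3 h_ref]`.
#' @param sigma_range search interval for sigma (nm).
#' @param mode fit on "energy" curves (default), "force" curves (their
#'   numerical derivative), or "both".
#' @param weights "uniform" (default) or "relative" (errors scaled by the
#'   reference magnitude).
#' @param n_offsets offsets/orientations averaged on the reference side.
#' @param n_ref reference grid points per axis (box = n_ref * h_ref).
#' @param conv_n grid points per axis of the converged trial mesh.
#' @param seed RNG seed for the offset averaging.
#' @return list with `sigma` (best fit, nm), `se` (curvature-based
#'   uncertainty), `objective`, `mode`, `curves` (reference and fitted
#'   trial curve) and `sensitivity` (fits under the alternative objective
#'   choices).
#' @export
calibrate_sigma <- function(reference = NULL, h_ref = 0.5875,
                            separations = NULL,
                            sigma_range = c(0.1, 0.45),
                            mode = c("energy", "force", "both"),
                            weights = c("uniform", "relative"),
                            n_offsets = 32, n_ref = 8, conv_n = 64,
                            seed = 1) {
  mode <- match.arg(mode)
  weights <- match.arg(weights)
  if (is.null(separations))
    separations <- seq(0, 3 * h_ref, length.out = 25)
  box <- n_ref * h_ref
  model <- interaction_model(chi = matrix(0, 1, 1), kappa_inv = 1,
                             sigma = 0.3, phi0 = 1, species = "A")
  set.seed(seed)
  if (is.null(reference)) {
    msh_ref <- mesh(rep(n_ref, 3), rep(box, 3))
    reference <- pair_potential_scan(model, msh_ref, separations,
                                     filter = filter_spec("identity"),
                                     n_offsets = n_offsets)
  }
  # converged-side trial curve: in the grid-converged limit the pair cross
  # spectrum is the plane-wave term cos(k . d), so the sigma-dependent
  # energy is an exact reciprocal-space lattice sum (the periodic
  # Gaussian-core interaction) with no assignment-width bias
  msh_c <- mesh(rep(conv_n, 3), rep(box, 3))
  ncell <- prod(msh_c$dims)
  k2v <- as.vector(msh_c$k2)
  kxv <- as.vector(array(rep(msh_c$kvec[[1]], times = conv_n^2), msh_c$dims))
  # unit-amplitude point clouds carry a 1/h^3 density normalization each
  spectra <- lapply(separations,
                    function(d) cos(kxv * d) / msh_c$cell_volume^2)
  coef <- (model$chi[1, 1] + model$kappa_inv) / model$phi0
  trial_curve <- function(sg) {
    H2 <- exp(-sg^2 * k2v)
    vapply(spectra, function(a)
      coef * msh_c$cell_volume * sum(a * H2) / ncell, numeric(1))
  }
  dgrid <- reference$separation
  refE <- reference$energy
  fit_once <- function(mode, weights) {
    obj <- function(sg) {
      tE <- trial_curve(sg)
      res <- switch(mode,
        energy = tE - refE,
        force = .num_deriv(dgrid, tE) - .num_deriv(dgrid, refE),
        both = c(tE - refE,
                 .num_deriv(dgrid, tE) - .num_deriv(dgrid, refE)))
      w <- switch(weights,
        uniform = rep(1, length(res)),
        relative = 1 / pmax(abs(switch(mode,
          energy = refE,
          force = .num_deriv(dgrid, refE),
          both = c(refE, .num_deriv(dgrid, refE)))), 1e-3 * max(abs(refE))))
      sum((w * res)^2)
    }
    opt <- stats::optimize(obj, sigma_range, tol = 1e-6)
    if (min(abs(opt$minimum - sigma_range)) < 1e-4)
      stop(sprintf("sigma fit hit the search boundary at %.4f; widen sigma_range",
                   opt$minimum))
    # curvature-based uncertainty from a local quadratic
    eps <- 1e-3
    d2 <- (obj(opt$minimum + eps) - 2 * opt$objective +
             obj(opt$minimum - eps)) / eps^2
    npts <- length(dgrid)
    se <- if (d2 > 0) sqrt(2 * opt$objective / ((npts - 1) * d2)) else NA_real_
    list(sigma = opt$minimum, se = se, objective = opt$objective)
  }
  main <- fit_once(mode, weights)
  sens <- list(
    relative_weights = fit_once(mode, "relative")$sigma,
    force_mode = fit_once("force", weights)$sigma,
    both_mode = fit_once("both", weights)$sigma
  )
  list(sigma = main$sigma, se = main$se, objective = main$objective,
       mode = mode, weights = weights,
       curves = data.frame(separation = dgrid, reference = refE,
                           fitted = trial_curve(main$sigma)),
       sensitivity = sens)
}

.num_deriv <- function(x, y) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  d
}

#' Species density profile along a box axis
#'
#' Time-averaged binned number densities per species; optional
#' symmetrization mirrors the profile about the box midplane and averages
#' the two halves.
#'
#' @param frames a list of frames (each with `positions`), an `hhpf_run`
#'   with a stored trajectory, or a single `particle_system`.
#' @param system a `particle_system` providing species/box metadata (not
#'   needed when `frames` is a system or run carrying one).
#' @param axis 1, 2 or 3 (or "x", "y", "z").
#' @param bins number of bins.
#' @param symmetrize mirror-average about the box midplane.
#' @return object of class `density_profile`: data.frame with `z`
#'   (bin centers, nm) and one number-density column per species
#'   (nm^-3), plus attributes `axis`, `bin_width`.
#' @export
density_profile <- function(frames, system = NULL, axis = 3, bins = 50,
                            symmetrize = FALSE) {
  if (is.character(axis)) axis <- match(axis, c("x", "y", "z"))
  if (inherits(frames, "hhpf_run")) {
    system <- system %||% frames$system
    frames <- frames$trajectory %||% list(list(positions = frames$system$positions))
  } else if (inherits(frames, "particle_system")) {
    system <- frames
    frames <- list(list(positions = frames$positions))
  }
  if (is.null(system)) stop("a particle_system is needed for species/box metadata")
  if (length(frames) == 0) stop("no frames to analyse")
  box <- system$box
  L <- box[axis]
  area <- prod(box[-axis])
  edges <- seq(0, L, length.out = bins + 1)
  width <- L / bins
  k <- length(system$species_names)
  acc <- matrix(0, bins, k)
  for (f in frames) {
    z <- f$positions[, axis] %% L
    b <- pmin(pmax(floor(z / width) + 1L, 1L), bins)
    for (s in seq_len(k)) {
      sel <- system$species == s
      if (any(sel)) acc[, s] <- acc[, s] + tabulate(b[sel], bins)
    }
  }
  dens <- acc / (length(frames) * area * width)
  if (symmetrize) dens <- (dens + dens[bins:1, , drop = FALSE]) / 2
  out <- data.frame(z = (edges[-1] + edges[-(bins + 1)]) / 2)
  for (s in seq_len(k)) out[[system$species_names[s]]] <- dens[, s]
  attr(out, "axis") <- axis
  attr(out, "bin_width") <- width
  attr(out, "symmetrized") <- symmetrize
  class(out) <- c("density_profile", "data.frame")
  out
}

#' Total-energy drift of a run
#'
#' Ordinary least-squares slope of the total energy over time, normalized
#' as percent of the mean absolute total energy per nanosecond; also
#' reported as absolute drift per particle per nanosecond.
#'
#' @param ledger an energy ledger (data.frame with `time`, `total`) or an
#'   `hhpf_run`.
#' @param window optional time window c(t0, t1) (ps) to fit over.
#' @param n_particles needed for the per-particle normalization when a
#'   bare ledger is given.
#' @param min_frames minimum frames required in the window.
#' @return object of class `drift_report`: list with
#'   `percent_per_ns`, `abs_per_particle_per_ns` (kJ/mol), `slope`
#'   (kJ/mol/ps), `se_percent_per_ns`, `window`, `n_frames`.
#' @export
energy_drift <- function(ledger, window = NULL, n_particles = NULL,
                         min_frames = 100) {
  if (inherits(ledger, "hhpf_run")) {
    n_particles <- n_particles %||% ledger$system$n
    ledger <- ledger$ledger
  }
  l <- ledger
  if (!is.null(window)) l <- l[l$time >= window[1] & l$time <= window[2], ]
  if (nrow(l) < min_frames)
    stop("need at least ", min_frames, " frames in the fit window (have ",
         nrow(l), ")")
  fit <- stats::lm(total ~ time, data = l)
  slope <- stats::coef(fit)[["time"]]           # kJ/mol per ps
  se <- suppressWarnings(summary(fit)$coefficients["time", "Std. Error"])
  scale <- mean(abs(l$total))
  pct_ns <- 100 * slope * 1000 / scale
  out <- list(percent_per_ns = pct_ns,
              se_percent_per_ns = 100 * se * 1000 / scale,
              abs_per_particle_per_ns = if (!is.null(n_particles))
                slope * 1000 / n_particles else NA_real_,
              slope = slope,
              window = range(l$time), n_frames = nrow(l),
              mean_total = mean(l$total))
  class(out) <- "drift_report"
  out
}

#' @export
print.drift_report <- function(x, ...) {
  cat(sprintf("energy drift: %.3g %%/ns (se %.2g) over %.4g..%.4g ps (%d frames)\n",
              x$percent_per_ns, x$se_percent_per_ns, x$window[1],
              x$window[2], x$n_frames))
  invisible(x)
}

#' Density-based clustering with periodic boundaries
#'
#' DBSCAN-style clustering under the minimum-image metric: points with at
#' least `min_samples` neighbours (including themselves) within `cutoff`
#' are core points; clusters are the connected components of core points,
#' plus border points attached to a core neighbour.  Returns the cluster
#' labels (0 = noise) and the aggregate statistic N-bar/N = (mean cluster
#' size) / (number of clustered points... see `nbar_over_n` definition
#' below).
#'
#' @param positions M x 3 matrix (or a `particle_system`).
#' @param box periodic box (taken from the system when given).
#' @param cutoff neighbour distance (nm), > 0.
#' @param min_samples core-point threshold (neighbour count including
#'   self).
#' @param subset optional index vector restricting the analysis (e.g. the
#'   solute particles).
#' @return list with `labels` (integer, 0 for noise), `n_clusters`,
#'   `sizes`, and `nbar_over_n` = mean cluster size divided by the total
#'   number of analysed points.
#' @export
cluster_aggregates <- function(positions, box = NULL, cutoff,
                               min_samples = 4, subset = NULL) {
  if (inherits(positions, "particle_system")) {
    box <- positions$box
    positions <- positions$positions
  }
  if (is.null(box)) stop("box required")
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (!is.null(subset)) positions <- positions[subset, , drop = FALSE]
  m <- nrow(positions)
  if (m == 0) return(list(labels = integer(0), n_clusters = 0L,
                          sizes = integer(0), nbar_over_n = NA_real_))
  # minimum-image squared distances
  d2 <- matrix(0, m, m)
  for (ax in 1:3) {
    dd <- outer(positions[, ax], positions[, ax], "-")
    dd <- dd - box[ax] * round(dd / box[ax])
    d2 <- d2 + dd^2
  }
  adj <- d2 <= cutoff^2
  ncount <- rowSums(adj)
  core <- ncount >= min_samples
  labels <- integer(m)
  cl <- 0L
  for (i in seq_len(m)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue) > 0) {
      j <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[j, ])
      for (v in nb) {
        if (labels[v] == 0L) {
          labels[v] <- cl
          if (core[v]) queue <- c(queue, v)
        }
      }
    }
  }
  sizes <- if (cl > 0) tabulate(labels[labels > 0], cl) else integer(0)
  nbar <- if (cl > 0) mean(sizes) / m else 0
  list(labels = labels, n_clusters = cl, sizes = sizes, nbar_over_n = nbar)
}

#' Detect a spanning bilayer conformation
#'
#' A frame counts as a bilayer when (a) the lipid tail beads form a single
#' slab along z that spans the full xy cross-section — every xy column of
#' a coarse grid contains at least one tail bead inside the slab (no
#' pore) — and (b) head beads are present on both faces of the slab
#' (two leaflets).  The slab is located after recentering the tail cloud
#' by its circular mean, so a bilayer crossing the periodic boundary is
#' handled.  All thresholds are configurable and returned in the
#' diagnostics.
#'
#' @param system a `particle_system` (a single frame).
#' @param tail_species species name(s) of the tail beads (default "C").
#' @param head_species species name(s) of head beads (default N and P).
#' @param column_grid number of xy columns per axis (default 4).
#' @param slab_quantile tail z-quantile pair defining the slab (default
#'   c(0.02, 0.98)).
#' @param max_thickness_frac maximum slab thickness as a fraction of the
#'   box height for a valid bilayer (default 0.6).
#' @param min_heads_per_face minimum head beads required on each face.
#' @return list with `bilayer` (logical) and `diagnostics`.
#' @export
bilayer_reached <- function(system, tail_species = "C",
                            head_species = c("N", "P"),
                            column_grid = 4,
                            slab_quantile = c(0.02, 0.98),
                            max_thickness_frac = 0.6,
                            min_heads_per_face = 3) {
  spn <- system$species_names
  tails <- system$species %in% match(tail_species, spn)
  heads <- system$species %in% match(head_species, spn)
  if (!any(tails)) stop("no tail beads found for species ",
                        paste(tail_species, collapse = ","))
  box <- system$box
  zt <- system$positions[tails, 3]
  # recenter by circular mean of the tail cloud
  ang <- zt / box[3] * 2 * pi
  zc <- atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi) * box[3]
  recenter <- function(z) (z - zc + box[3] / 2) %% box[3]
  ztr <- recenter(zt)
  qs <- stats::quantile(ztr, slab_quantile, names = FALSE)
  thickness <- qs[2] - qs[1]
  ok_thick <- thickness < max_thickness_frac * box[3]
  # pore test: every xy column must contain a tail bead inside the slab
  xy <- system$positions[tails, 1:2, drop = FALSE]
  inslab <- ztr >= qs[1] & ztr <= qs[2]
  cx <- pmin(floor(xy[, 1] / box[1] * column_grid) + 1L, column_grid)
  cy <- pmin(floor(xy[, 2] / box[2] * column_grid) + 1L, column_grid)
  colhit <- matrix(FALSE, column_grid, column_grid)
  colhit[cbind(cx[inslab], cy[inslab])] <- TRUE
  ok_span <- all(colhit)
  # leaflet test: heads above and below the slab centre
  ok_heads <- TRUE
  nh_lo <- nh_hi <- NA_integer_
  if (any(heads)) {
    zh <- recenter(system$positions[heads, 3])
    mid <- (qs[1] + qs[2]) / 2
    nh_lo <- sum(zh < mid)
    nh_hi <- sum(zh >= mid)
    ok_heads <- nh_lo >= min_heads_per_face && nh_hi >= min_heads_per_face
  }
  list(bilayer = ok_thick && ok_span && ok_heads,
       diagnostics = list(thickness = thickness, slab = qs,
                          spanning = ok_span, columns_hit = sum(colhit),
                          n_heads_low = nh_lo, n_heads_high = nh_hi,
                          thickness_ok = ok_thick))
}
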