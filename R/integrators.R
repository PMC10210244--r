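#' rRESPA / run configuration
#'
#' Integration contract for [run_hhpf()].  The outer (field) time step is
#' `field_update_time = n_inner * inner_dt` identically; intramolecular
#' forces are integrated by velocity-Verlet in increments of `inner_dt`,
#' and the slowly varying field forces are applied as impulses of half the
#' outer step before and after the inner loop (symmetric Trotter split).
#' In the limit `n_inner = 1` the scheme reduces exactly to velocity-Verlet
#' under the summed force.
#'
#' @param inner_dt inner time step (ps); default 0.01.
#' @param n_inner number of inner steps per field update (>= 1).
#' @param field_update_time alternative to `n_inner`: outer step (ps);
#'   must be an integer multiple of `inner_dt`.
#' @param n_outer number of outer steps to integrate.
#' @param ensemble "nve" (no thermostat) or "nvt" (CSVR).
#' @param target_T target temperature (K) for the thermostat and velocity
#'   initialisation.
#' @param tau thermostat coupling time (ps); default 0.1.
#' @param seed integer seed; every stochastic element of a run (thermostat
#'   noise) draws from the run's RNG stream seeded here.
#' @param electrostatics optional `electrostatics_config`.
#' @param output_every record the energy ledger every this many outer steps.
#' @param store_trajectory store positions/velocities every this many outer
#'   steps (0 = never).
#' @param sigma_schedule optional data.frame with columns `time` (ps) and
#'   `sigma` (nm): the filter width is linearly interpolated between the
#'   scheduled points (constant outside), enabling on-the-fly coarse-grain
#'   annealing.
#' @param precision "double" (default) or "single"; single-precision mode
#'   rounds positions and velocities to 32-bit floats after every outer
#'   step (energies are always accumulated in double).
#' @param force_readout `"spectral"` (default, the conventional
#'   particle-mesh force: reciprocal-space gradient interpolated back with
#'   the CIC stencil, continuous in the positions) or `"exact"` (analytic
#'   gradient of the discrete energy functional); see [field_forces()].
#' @param remove_com remove centre-of-mass momentum at the start.
#' @return object of class `rrespa_config`.
#' @export
run_config <- function(inner_dt = 0.01, n_inner = NULL,
                       field_update_time = NULL, n_outer = 100,
                       ensemble = c("nve", "nvt"), target_T = 323,
                       tau = 0.1, seed = 1L, electrostatics = NULL,
                       output_every = 1L, store_trajectory = 0L,
                       sigma_schedule = NULL,
                       precision = c("double", "single"),
                       force_readout = c("spectral", "exact"),
                       remove_com = TRUE) {
  ensemble <- match.arg(ensemble)
  precision <- match.arg(precision)
  force_readout <- match.arg(force_readout)
  if (is.null(n_inner)) {
    if (is.null(field_update_time)) stop("give n_inner or field_update_time")
    n_inner <- round(field_update_time / inner_dt)
    if (abs(n_inner * inner_dt - field_update_time) > 1e-9)
      stop("field_update_time must be an integer multiple of inner_dt")
  }
  n_inner <- as.integer(n_inner)
  if (inner_dt <= 0 || n_inner < 1L) stop("need inner_dt > 0 and n_inner >= 1")
  if (ensemble == "nvt" && tau <= 0) stop("thermostat coupling time tau must be > 0")
  if (!is.null(sigma_schedule)) {
    sigma_schedule <- as.data.frame(sigma_schedule)
    if (!all(c("time", "sigma") %in% names(sigma_schedule)))
      stop("sigma_schedule needs columns time and sigma")
    if (is.unsorted(sigma_schedule$time))
      stop("sigma_schedule times must be non-decreasing")
  }
  structure(list(inner_dt = inner_dt, n_inner = n_inner,
                 field_update_time = n_inner * inner_dt,
                 n_outer = as.integer(n_outer), ensemble = ensemble,
                 target_T = target_T, tau = tau, seed = as.integer(seed),
                 electrostatics = electrostatics,
                 output_every = as.integer(output_every),
                 store_trajectory = as.integer(store_trajectory),
                 sigma_schedule = sigma_schedule, precision = precision,
                 force_readout = force_readout,
                 remove_com = isTRUE(remove_com)),
            class = "rrespa_config")
}

#' One velocity-Verlet step
#'
#' Standard kick-drift-kick under a force provider, with periodic
#' re-wrapping after the drift.  Deterministic given its inputs; reversing
#' the velocities and stepping again retraces the trajectory to round-off.
#'
#' @param system a `particle_system`.
#' @param force_provider function(system) returning a list with at least
#'   `forces` (N x 3) — or a bare N x 3 matrix.
#' @param dt time step (ps).
#' @param forces optional forces at the current positions (skips one
#'   provider call).
#' @return list with `system` (updated), `forces` (at the new positions)
#'   and `provider` (the provider's full return value at the new positions).
#' @export
velocity_verlet_step <- function(system, force_provider, dt, forces = NULL) {
  getF <- function(out) if (is.list(out)) out$forces else out
  if (is.null(forces)) forces <- getF(force_provider(system))
  if (!all(is.finite(forces)))
    stop("non-finite force encountered; integration aborted")
  half <- 0.5 * dt
  system$velocities <- system$velocities + half * forces / system$masses
  system$positions <- wrap_positions(system$positions + dt * system$velocities,
                                     system$box)
  out <- force_provider(system)
  fnew <- getF(out)
  if (!all(is.finite(fnew)))
    stop("non-finite force encountered; integration aborted")
  system$velocities <- system$velocities + half * fnew / system$masses
  list(system = system, forces = fnew, provider = out)
}

#' One rRESPA outer step
#'
#' Half field-force impulse (Delta t / 2 on the velocities), `n_inner`
#' velocity-Verlet steps of the inner step under the bonded provider only,
#' one field recomputation at the new positions, and the closing half
#' impulse.  Exactly one field evaluation per outer step: the opening
#' impulse reuses the field forces computed at the end of the previous
#' step, since the inner reference system does not move the field between
#' the closing and opening impulses.  For `n_inner = 1` the step is
#' delegated to [velocity_verlet_step()] under the summed
#' field-plus-bonded force, to which the scheme is then identical.
#'
#' @param system a `particle_system`.
#' @param bonded_provider function(system) -> list(forces, energy).
#' @param field_provider function(system) -> list(forces, energy).
#' @param config an `rrespa_config` (only `inner_dt` and `n_inner` used).
#' @param field_cache optional field provider output at the current
#'   positions (from the previous step).
#' @return list with `system`, `field` (provider output at the new
#'   positions) and `bonded` (provider output at the new positions).
#' @export
rrespa_step <- function(system, bonded_provider, field_provider, config,
                        field_cache = NULL) {
  dt <- config$inner_dt
  n <- config$n_inner
  if (n == 1L) {
    combined <- function(sys) {
      fb <- bonded_provider(sys)
      ff <- field_provider(sys)
      list(forces = ff$forces + fb$forces, bonded = fb, field = ff)
    }
    f0 <- if (is.null(field_cache)) NULL else {
      fb0 <- bonded_provider(system)
      field_cache$forces + fb0$forces
    }
    st <- velocity_verlet_step(system, combined, dt, forces = f0)
    return(list(system = st$system, field = st$provider$field,
                bonded = st$provider$bonded))
  }
  ff <- if (is.null(field_cache)) field_provider(system) else field_cache
  half_outer <- 0.5 * n * dt
  system$velocities <- system$velocities + half_outer * ff$forces / system$masses
  fb <- bonded_provider(system)
  for (s in seq_len(n)) {
    st <- velocity_verlet_step(system, bonded_provider, dt, forces = fb$forces)
    system <- st$system
    fb <- st$provider
  }
  ff <- field_provider(system)
  system$velocities <- system$velocities + half_outer * ff$forces / system$masses
  list(system = system, field = ff, bonded = fb)
}

#' CSVR (canonical sampling through velocity rescaling) thermostat step
#'
#' Global stochastic rescaling of all velocities so that the kinetic
#' energy samples its canonical (chi-squared with dof degrees of freedom)
#' distribution, with relaxation time `tau`.  Preserves zero net momentum
#' when it is zero, and reduces to NVE as tau -> infinity.  Draws from the
#' current R RNG stream (one normal and one chi-squared variate per call),
#' so runs are deterministic given the run seed and call sequence.
#'
#' @param system a `particle_system`.
#' @param target_T target temperature (K).
#' @param tau coupling time (ps), > 0.
#' @param dt time elapsed since the previous thermostat application (ps).
#' @param remove_com if TRUE, dof = 3N - 3, else 3N.
#' @return the system with rescaled velocities; the applied scale factor is
#'   available as attribute `"alpha"`.
#' @export
csvr_thermostat_step <- function(system, target_T, tau, dt,
                                 remove_com = TRUE) {
  if (tau <= 0) stop("thermostat coupling time tau must be > 0")
  dof <- if (remove_com) 3 * system$n - 3 else 3 * system$n
  if (dof < 1) stop("not enough degrees of freedom to thermostat")
  ke <- 0.5 * sum(system$masses * rowSums(system$velocities^2))
  if (ke <= 0) {
    warning("zero kinetic energy; thermostat step skipped")
    return(system)
  }
  kebar <- 0.5 * dof * .RGAS * target_T
  c1 <- exp(-dt / tau)
  r1 <- stats::rnorm(1)
  s <- if (dof > 1) stats::rchisq(1, df = dof - 1) else 0
  kenew <- ke * c1 + kebar * (1 - c1) * (r1^2 + s) / dof +
    2 * r1 * sqrt(ke * kebar * c1 * (1 - c1) / dof)
  alpha <- sqrt(max(kenew, 0) / ke)
  system$velocities <- system$velocities * alpha
  attr(system, "alpha") <- alpha
  system
}

# round a numeric object through 32-bit floats (single-precision mode)
.to_single <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.vector(x), raw(), size = 4L), "numeric",
               size = 4L, n = length(x))
  dim(y) <- d
  y
}

# sigma at time t under an optional schedule
.sigma_at <- function(model, schedule, t) {
  if (is.null(schedule)) return(model$sigma)
  stats::approx(schedule$time, schedule$sigma, xout = t, rule = 2)$y
}

#' Run an HhPF molecular dynamics simulation
#'
#' The main driver: rRESPA multiple-time-step integration of a particle
#' system under bonded forces (inner loop, compiled kernel) and
#' particle-field plus optional electrostatic and reconstructed-dipole
#' forces (outer impulses), with an optional CSVR thermostat, energy
#' ledger, and optional trajectory storage.
#'
#' @param system a `particle_system`.
#' @param top a `topology` (may be empty).
#' @param model an `interaction_model`, or NULL for no field forces.
#' @param msh a mesh over the system box (required when `model` is given).
#' @param config an `rrespa_config` from [run_config()].
#' @return object of class `hhpf_run`: final `system`, the energy `ledger`
#'   (data.frame: time, kinetic, field, electrostatic, bonded, total,
#'   temperature), `trajectory` (list of frames or NULL), and the echoed
#'   `config`.
#' @export
run_hhpf <- function(system, top = topology(), model = NULL, msh = NULL,
                     config = run_config()) {
  if (!is.null(model) && is.null(msh)) stop("a mesh is required with a field model")
  set.seed(config$seed)
  if (config$remove_com) system <- remove_com_momentum(system)
  validate_topology(top, system)
  packed <- .pack_topology(top)
  invmass <- 1 / system$masses
  dt <- config$inner_dt
  n_in <- config$n_inner
  t_outer <- config$field_update_time
  elec <- config$electrostatics
  elec_on <- !is.null(elec) && isTRUE(elec$enabled)
  has_dip <- length(top$dipoles) > 0
  # filter caches
  cur_sigma <- if (!is.null(model)) .sigma_at(model, config$sigma_schedule, 0) else NA
  Hhat <- NULL
  Hel <- NULL
  make_filters <- function(sg) {
    Hhat <<- .filter_transfer(gaussian_filter(sg), msh)
    sel <- if (elec_on && !is.null(elec$sigma_el)) elec$sigma_el else sg
    if (elec_on) Hel <<- .filter_transfer(gaussian_filter(sel), msh)
  }
  if (!is.null(model)) make_filters(cur_sigma)

  slow_eval <- function(sys) {
    if (is.null(model))
      return(list(forces = matrix(0, sys$n, 3), field_energy = 0,
                  elec_energy = 0))
    mdl <- model
    mdl$sigma <- cur_sigma
    fe <- field_forces(sys, mdl, msh, Hhat = Hhat,
                       readout = config$force_readout)
    f <- fe$forces
    we <- 0
    if (elec_on) {
      ghosts <- NULL
      dsets <- NULL
      if (has_dip) {
        dsets <- lapply(top$dipoles, function(sp) reconstruct_dipoles(sys, sp))
        ghosts <- do.call(rbind, lapply(dsets, `[[`, "ghosts"))
      }
      ee <- .electrostatics_eval(sys, elec, NULL, msh, ghosts = ghosts,
                                 Hhat = Hel, readout = config$force_readout)
      we <- ee$energy
      f <- f + ee$forces
      if (has_dip) {
        off <- 0L
        for (ds in dsets) {
          ng <- nrow(ds$ghosts)
          f <- f + project_dipole_forces(
            ee$ghost_forces[off + seq_len(ng), , drop = FALSE], ds, sys$n)
          off <- off + ng
        }
      }
    }
    list(forces = f, field_energy = fe$energy, elec_energy = we)
  }

  bonded_eval <- function(sys) {
    out <- .bonded_forces_cpp(sys$positions, sys$box, packed)
    list(forces = out$forces, energy = out$energy)
  }

  # initial slow forces and bonded forces
  slow <- slow_eval(system)
  bf <- bonded_eval(system)
  nrec <- config$n_outer %/% config$output_every + 1L
  ledger <- data.frame(time = numeric(nrec), kinetic = numeric(nrec),
                       field = numeric(nrec), electrostatic = numeric(nrec),
                       bonded = numeric(nrec), total = numeric(nrec),
                       temperature = numeric(nrec))
  irec <- 0L
  record <- function(tnow) {
    irec <<- irec + 1L
    kt <- kinetic_temperature(system, remove_com = config$remove_com)
    ledger[irec, ] <<- c(tnow, kt$energy, slow$field_energy,
                         slow$elec_energy, bf$energy,
                         kt$energy + slow$field_energy + slow$elec_energy +
                           bf$energy, kt$temperature)
  }
  traj <- if (config$store_trajectory > 0) vector("list",
            config$n_outer %/% config$store_trajectory + 1L) else NULL
  itraj <- 0L
  snap <- function(tnow) {
    itraj <<- itraj + 1L
    traj[[itraj]] <<- list(time = tnow, step = round(tnow / t_outer),
                           positions = system$positions,
                           velocities = system$velocities)
  }
  record(0)
  if (!is.null(traj)) snap(0)

  half_outer <- 0.5 * t_outer
  for (step in seq_len(config$n_outer)) {
    tnow <- step * t_outer
    if (!is.null(model) && !is.null(config$sigma_schedule)) {
      # the filter width used for this step's field update, at the time
      # of the recomputation (end of the outer step)
      sg <- .sigma_at(model, config$sigma_schedule, tnow)
      if (abs(sg - cur_sigma) > 1e-12) {
        cur_sigma <- sg
        make_filters(sg)
      }
    }
    if (n_in == 1L) {
      # exact velocity-Verlet limit under the summed force
      combined <- function(sys) {
        fb <- bonded_eval(sys)
        fs <- slow_eval(sys)
        list(forces = fs$forces + fb$forces, bonded = fb, slow = fs)
      }
      st <- velocity_verlet_step(system, combined, dt,
                                 forces = slow$forces + bf$forces)
      system <- st$system
      bf <- st$provider$bonded
      slow <- st$provider$slow
    } else {
      system$velocities <- system$velocities +
        half_outer * slow$forces * invmass
      inner <- .inner_verlet_cpp(system$positions, system$velocities,
                                 invmass, system$box, dt, n_in, packed,
                                 bf$forces)
      system$positions <- inner$pos
      system$velocities <- inner$vel
      bf <- list(forces = inner$forces, energy = inner$energy)
      slow <- slow_eval(system)
      system$velocities <- system$velocities +
        half_outer * slow$forces * invmass
    }
    if (config$ensemble == "nvt")
      system <- csvr_thermostat_step(system, config$target_T, config$tau,
                                     t_outer, config$remove_com)
    if (config$precision == "single") {
      system$positions <- wrap_positions(.to_single(system$positions),
                                         system$box)
      system$velocities <- .to_single(system$velocities)
    }
    if (step %% config$output_every == 0L) record(tnow)
    if (!is.null(traj) && step %% config$store_trajectory == 0L) snap(tnow)
  }
  ledger <- ledger[seq_len(irec), ]
  structure(list(system = system, ledger = ledger,
                 trajectory = if (!is.null(traj)) traj[seq_len(itraj)],
                 config = config,
                 model = model, mesh = msh, final_sigma = cur_sigma),
            class = "hhpf_run")
}

#' @export
print.hhpf_run <- function(x, ...) {
  l <- x$ledger
  cat("hhpf_run:", x$config$n_outer, "outer steps of",
      x$config$field_update_time, "ps (", x$config$n_inner, "x",
      x$config$inner_dt, "ps inner ),", x$config$ensemble, "\n")
  cat(sprintf("  t = %.4g ps, total energy %.6g kJ/mol, T = %.4g K\n",
              l$time[nrow(l)], l$total[nrow(l)], l$temperature[nrow(l)]))
  invisible(x)
}

#' @export
summary.hhpf_run <- function(object, ...) {
  l <- object$ledger
  out <- list(
    n_frames = nrow(l),
    time_span = range(l$time),
    mean_total = mean(l$total),
    sd_total = stats::sd(l$total),
    mean_T = mean(l$temperature),
    energy_components = colMeans(l[, c("kinetic", "field", "electrostatic",
                                       "bonded")])
  )
  class(out) <- "summary.hhpf_run"
  out
}

#' @export
print.summary.hhpf_run <- function(x, ...) {
  cat(sprintf("frames: %d over %.4g..%.4g ps\n", x$n_frames,
              x$time_span[1], x$time_span[2]))
  cat(sprintf("total energy: %.6g +/- %.3g kJ/mol; mean T = %.4g K\n",
              x$mean_total, x$sd_total, x$mean_T))
  cat("mean components (kJ/mol):",
      paste(names(x$energy_components),
            signif(x$energy_components, 6), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Plot energy traces of a run
#'
#' @param x an `hhpf_run`.
#' @param which components to draw.
#' @param ... passed to matplot.
#' @export
plot.hhpf_run <- function(x, which = c("total", "kinetic", "field",
                                       "electrostatic", "bonded"), ...) {
  l <- x$ledger
  which <- match.arg(which, several.ok = TRUE)
  graphics::matplot(l$time, as.matrix(l[, which, drop = FALSE]), type = "l",
                    lty = 1, xlab = "time (ps)", ylab = "energy (kJ/mol)", ...)
  graphics::legend("topright", legend = which, lty = 1,
                   col = seq_along(which), bty = "n")
  invisible(x)
}
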