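#' Write a structure + topology file
#'
#' Serializes a particle system and its topology to a single hierarchical
#' JSON container (text, human-diffable) with `particles` and `topology`
#' groups, mirroring the dataset layout of HDF5-based MD ecosystems.
#'
#' @param system a `particle_system`.
#' @param top a `topology`.
#' @param path output file path.
#' @return invisibly `path`.
#' @export
write_structure <- function(system, top, path) {
  obj <- list(
    format = "hhpf-structure",
    version = 1L,
    box = system$box,
    particles = list(
      n = system$n,
      species_names = system$species_names,
      species = system$species,
      mass = system$masses,
      charge = system$charges,
      molecule = system$molecule_id,
      position = system$positions,
      velocity = system$velocities
    ),
    topology = list(
      bonds = top$bonds,
      angles = top$angles,
      dihedrals = top$dihedrals,
      bend_torsions = list(
        idx = top$bend_torsions$idx,
        k_coef = top$bend_torsions$k_coef,
        vp_coef = top$bend_torsions$vp_coef,
        g0_coef = top$bend_torsions$g0_coef
      ),
      dipoles = top$dipoles
    )
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", matrix = "rowmajor")
  invisible(path)
}

#' Read a structure + topology file
#'
#' Reads and validates a container written by [write_structure()]; all
#' dataset lengths, index ranges and topology invariants are checked with
#' path-precise error messages.
#'
#' @param path file path.
#' @return list with `system` (a `particle_system`) and `topology`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "hhpf-structure"))
    stop(path, ": not an hhpf structure file (missing format tag)")
  p <- obj$particles
  need <- c("n", "species_names", "species", "mass", "charge", "molecule",
            "position")
  for (k in need) if (is.null(p[[k]]))
    stop(path, ": missing dataset particles/", k)
  n <- as.integer(p$n)
  for (k in c("species", "mass", "charge", "molecule"))
    if (length(p[[k]]) != n)
      stop(sprintf("%s: particles/%s has length %d, expected %d",
                   path, k, length(p[[k]]), n))
  pos <- matrix(unlist(p$position), n, 3, byrow = FALSE)
  if (is.matrix(p$position)) pos <- p$position
  vel <- if (!is.null(p$velocity)) {
    v <- p$velocity
    if (!is.matrix(v)) v <- matrix(unlist(v), n, 3)
    v
  } else NULL
  sys <- particle_system(pos, as.integer(p$species), as.numeric(obj$box),
                         velocities = vel, masses = as.numeric(p$mass),
                         charges = as.numeric(p$charge),
                         molecule_id = as.integer(p$molecule),
                         species_names = as.character(p$species_names))
  tp <- obj$topology
  as_df <- function(x, cols) {
    if (is.null(x) || (is.data.frame(x) && nrow(x) == 0) || length(x) == 0)
      return(NULL)
    if (!is.data.frame(x) && all(lengths(x) == 0)) return(NULL)
    df <- as.data.frame(x)
    if (!all(cols %in% names(df)))
      stop(path, ": topology table missing columns ",
           paste(setdiff(cols, names(df)), collapse = ", "))
    df
  }
  bt <- NULL
  if (!is.null(tp$bend_torsions) && length(tp$bend_torsions$idx) > 0) {
    bt <- list(idx = matrix(unlist(tp$bend_torsions$idx), ncol = 4),
               k_coef = as.matrix(tp$bend_torsions$k_coef),
               vp_coef = as.matrix(tp$bend_torsions$vp_coef),
               g0_coef = as.matrix(tp$bend_torsions$g0_coef))
    if (is.matrix(tp$bend_torsions$idx)) bt$idx <- tp$bend_torsions$idx
  }
  dip <- NULL
  if (!is.null(tp$dipoles) && length(tp$dipoles) > 0) {
    dip <- lapply(seq_len(if (is.data.frame(tp$dipoles)) nrow(tp$dipoles)
                          else length(tp$dipoles)), function(i) {
      d <- if (is.data.frame(tp$dipoles)) as.list(tp$dipoles[i, ])
           else tp$dipoles[[i]]
      list(backbone = as.integer(unlist(d$backbone)),
           q = as.numeric(d$q), delta = as.numeric(d$delta))
    })
  }
  top <- topology(bonds = as_df(tp$bonds, c("i", "j", "r0", "k")),
                  angles = as_df(tp$angles, c("i", "j", "k", "theta0", "ka")),
                  dihedrals = as_df(tp$dihedrals,
                                    c("i", "j", "k", "l", "n", "c", "phase")),
                  bend_torsions = bt, dipoles = dip)
  validate_topology(top, sys)
  list(system = sys, topology = top)
}

#' Read a run configuration file
#'
#' YAML run configuration.  Unknown keys are an error (nothing is silently
#' ignored); missing required keys are reported together.  The
#' incompressibility parameter accepts the shorthand `"7.45 RT"`, resolved
#' with the configured target temperature.  A `sigma_schedule` list of
#' `[time, sigma]` pairs enables on-the-fly filter-width annealing.
#'
#' @param path YAML file path.
#' @return list with `config` (an `rrespa_config`), `model_args` (chi,
#'   kappa_inv, sigma, phi0 if given), `mesh_dims`, and the full effective
#'   configuration echo in `echo`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- c("mesh_dims", "sigma", "sigma_schedule", "chi", "kappa_inv",
             "phi0", "ensemble", "target_T", "inner_dt", "n_inner",
             "field_update_time", "n_outer", "electrostatics",
             "output_every", "store_trajectory", "seed", "precision",
             "tau")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  required <- c("mesh_dims", "sigma", "n_outer")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0)
    stop("missing required configuration keys: ",
         paste(missing, collapse = ", "))
  target_T <- raw$target_T %||% 323
  kappa_inv <- raw$kappa_inv %||% "7.45 RT"
  if (is.character(kappa_inv)) {
    m <- regmatches(kappa_inv,
                    regexec("^\\s*([0-9.eE+-]+)\\s*RT\\s*$", kappa_inv))[[1]]
    if (length(m) != 2)
      stop("kappa_inv must be a number or of the form '<x> RT'")
    kappa_inv <- as.numeric(m[2]) * .RGAS * target_T
  }
  chi <- NULL
  if (!is.null(raw$chi)) {
    # chi given as a list of [species_a, species_b, value] triplets
    tr <- raw$chi
    sp <- unique(unlist(lapply(tr, function(x) c(x[[1]], x[[2]]))))
    chi <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
    for (x in tr) {
      chi[x[[1]], x[[2]]] <- as.numeric(x[[3]])
      chi[x[[2]], x[[1]]] <- as.numeric(x[[3]])
    }
  }
  seed <- raw$seed
  if (is.null(seed)) {
    seed <- as.integer(Sys.time()) %% .Machine$integer.max
    message("no seed given; generated seed ", seed)
  }
  schedule <- NULL
  if (!is.null(raw$sigma_schedule)) {
    schedule <- do.call(rbind, lapply(raw$sigma_schedule, function(x)
      data.frame(time = as.numeric(x[[1]]), sigma = as.numeric(x[[2]]))))
  }
  elec <- NULL
  if (!is.null(raw$electrostatics)) {
    e <- raw$electrostatics
    elec <- electrostatics_config(enabled = e$enabled %||% TRUE,
                                  epsilon_r = e$epsilon_r %||% 1,
                                  sigma_el = e$sigma_el)
  }
  cfg <- run_config(
    inner_dt = raw$inner_dt %||% 0.01,
    n_inner = raw$n_inner,
    field_update_time = if (is.null(raw$n_inner)) raw$field_update_time %||% 0.2,
    n_outer = raw$n_outer,
    ensemble = raw$ensemble %||% "nve",
    target_T = target_T,
    tau = raw$tau %||% 0.1,
    seed = seed,
    electrostatics = elec,
    output_every = raw$output_every %||% 1L,
    store_trajectory = raw$store_trajectory %||% 0L,
    sigma_schedule = schedule,
    precision = raw$precision %||% "double"
  )
  echo <- list(mesh_dims = raw$mesh_dims, sigma = raw$sigma,
               sigma_schedule = schedule, chi = chi, kappa_inv = kappa_inv,
               phi0 = raw$phi0, config = unclass(cfg))
  list(config = cfg,
       model_args = list(chi = chi, kappa_inv = kappa_inv,
                         sigma = as.numeric(raw$sigma), phi0 = raw$phi0),
       mesh_dims = as.integer(unlist(raw$mesh_dims)),
       echo = echo)
}

#' Write a trajectory in the H5MD layout
#'
#' Serializes a finished run to a single JSON file following the H5MD
#' logical layout: an `h5md` metadata group (version, creator), a
#' `particles/all` group with `position`/`velocity` elements each holding
#' parallel `step`, `time` and `value` datasets plus the box edges, and an
#' `observables` group with one element per energy ledger column.  Units
#' are recorded as `units` attributes alongside each value dataset.
#'
#' @param run an `hhpf_run` (must have been run with
#'   `store_trajectory > 0` for position/velocity frames; the observables
#'   are always present).
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_h5md <- function(run, path) {
  ok <- tryCatch({
    con <- file(path, open = "w")
    close(con)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write to ", path)
  frames <- run$trajectory %||% list()
  steps <- vapply(frames, function(f) as.numeric(f$step), numeric(1))
  times <- vapply(frames, function(f) f$time, numeric(1))
  l <- run$ledger
  obs_element <- function(col, units) list(
    step = round(l$time / run$config$field_update_time),
    time = l$time,
    value = l[[col]],
    units = units
  )
  obj <- list(
    h5md = list(version = c(1L, 1L),
                creator = list(name = "hhpfmd",
                               version = as.character(
                                 utils::packageVersion("hhpfmd")))),
    particles = list(all = list(
      box = list(edges = run$system$box, units = "nm",
                 boundary = rep("periodic", 3)),
      position = list(step = steps, time = times,
                      value = lapply(frames, function(f) f$positions),
                      units = "nm"),
      velocity = list(step = steps, time = times,
                      value = lapply(frames, function(f) f$velocities),
                      units = "nm ps-1")
    )),
    observables = list(
      total_energy = obs_element("total", "kJ mol-1"),
      kinetic_energy = obs_element("kinetic", "kJ mol-1"),
      field_energy = obs_element("field", "kJ mol-1"),
      electrostatic_energy = obs_element("electrostatic", "kJ mol-1"),
      bonded_energy = obs_element("bonded", "kJ mol-1"),
      temperature = obs_element("temperature", "K")
    ),
    parameters = list(seed = run$config$seed,
                      inner_dt = run$config$inner_dt,
                      n_inner = run$config$n_inner,
                      ensemble = run$config$ensemble)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a trajectory file written by [write_h5md()]
#'
#' @param path file path.
#' @return the parsed container (list), with position/velocity frames as
#'   matrices.
#' @export
read_h5md <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix <- function(el) {
    v <- el$value
    if (is.array(v) && length(dim(v)) == 3) {
      # frames of equal shape simplify to a [frame, particle, axis] array
      el$value <- lapply(seq_len(dim(v)[1]), function(i) {
        m <- v[i, , , drop = TRUE]
        dim(m) <- dim(v)[2:3]
        storage.mode(m) <- "double"
        m
      })
    } else if (is.list(v)) {
      el$value <- lapply(v, function(m) {
        m <- as.matrix(m)
        storage.mode(m) <- "double"
        m
      })
    }
    el
  }
  obj$particles$all$position <- fix(obj$particles$all$position)
  obj$particles$all$velocity <- fix(obj$particles$all$velocity)
  obj
}

#' Validate the H5MD-style layout of a trajectory container
#'
#' Checks the group/dataset names and shape rules of the layout: h5md
#' metadata with a 2-component version, particles/all with box edges and
#' step/time/value triplets of equal length, and observables elements each
#' with parallel step/time/value.
#'
#' @param x a parsed container (from [read_h5md()]) or a path.
#' @return invisibly TRUE; errors describe the first violation.
#' @export
validate_h5md <- function(x) {
  if (is.character(x)) x <- read_h5md(x)
  if (is.null(x$h5md$version) || length(x$h5md$version) != 2)
    stop("h5md/version must have 2 components")
  if (is.null(x$h5md$creator$name)) stop("h5md/creator/name missing")
  pa <- x$particles$all
  if (is.null(pa)) stop("particles/all group missing")
  if (length(pa$box$edges) != 3) stop("particles/all/box/edges must be length 3")
  for (el in c("position", "velocity")) {
    e <- pa[[el]]
    if (is.null(e)) stop("particles/all/", el, " missing")
    nv <- if (is.list(e$value)) length(e$value) else 0L
    if (length(e$step) != length(e$time) || length(e$time) != nv)
      stop("particles/all/", el, ": step/time/value lengths differ")
  }
  if (is.null(x$observables)) stop("observables group missing")
  for (nm in names(x$observables)) {
    e <- x$observables[[nm]]
    if (length(e$step) != length(e$time) ||
        length(e$time) != length(e$value))
      stop("observables/", nm, ": step/time/value lengths differ")
  }
  invisible(TRUE)
}
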