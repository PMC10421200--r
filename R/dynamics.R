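# Desk-scale molecular dynamics: steepest-descent minimisation,
# velocity-Verlet NVT/NVE with velocity-rescale or Langevin thermostats,
# and RMSD validation against a reference structure.

#' Molecular-dynamics run configuration
#'
#' @param timestep Integration timestep, fs.
#' @param nsteps Number of steps.
#' @param temperature Target temperature, K.
#' @param thermostat "velocity-rescale", "langevin" or "none".
#' @param tau_t Velocity-rescale coupling time, ps.
#' @param friction Langevin friction, ps^-1.
#' @param seed Random seed (recorded in trajectory provenance).
#' @param stride Frame-output stride (steps).
#' @param log_stride Energy-log stride (steps).
#' @param frozen Logical vector (or integer indices) of frozen atoms.
#' @param skin Neighbour-list skin, A.
#' @param nlist_every Neighbour-list rebuild interval, steps.
#' @return Object of class `run_config`.
#' @export
run_config <- function(timestep = 1, nsteps = 1000, temperature = 300,
                       thermostat = c("velocity-rescale", "langevin", "none"),
                       tau_t = 1, friction = 10, seed = 1,
                       stride = 100, log_stride = 100,
                       frozen = NULL, skin = 2, nlist_every = 10) {
  thermostat <- match.arg(thermostat)
  if (timestep <= 0) stop("timestep must be > 0")
  if (temperature < 0) stop("temperature must be >= 0")
  structure(list(timestep = timestep, nsteps = as.integer(nsteps),
                 temperature = temperature, thermostat = thermostat,
                 tau_t = tau_t, friction = friction, seed = as.integer(seed),
                 stride = as.integer(stride), log_stride = as.integer(log_stride),
                 frozen = frozen, skin = skin,
                 nlist_every = as.integer(nlist_every)),
            class = "run_config")
}

#' Trajectory container
#'
#' @param frames List of n x 3 position matrices (A).
#' @param times Frame times, ps (strictly increasing).
#' @param species Atom labels.
#' @param box,periodic Box vectors (A) and periodicity flags.
#' @param elog Optional energy log (data.frame).
#' @param provenance Optional list (seed, config).
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(frames, times, species, box, periodic,
                       elog = NULL, provenance = NULL) {
  if (length(frames) != length(times)) stop("frames/times length mismatch")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  nat <- vapply(frames, nrow, integer(1))
  if (length(unique(nat)) > 1) stop("atom count varies across frames")
  structure(list(frames = frames, times = times, species = species,
                 box = box, periodic = periodic, elog = elog,
                 provenance = provenance),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, t = %.4g .. %.4g ps\n",
              length(x$frames), nrow(x$frames[[1]]),
              min(x$times), max(x$times)))
  if (!is.null(x$provenance$seed))
    cat("  seed:", x$provenance$seed, "\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param x A `trajectory`.
#' @return Integer.
#' @export
n_frames <- function(x) length(x$frames)

.mobility_matrix <- function(n, frozen, mobile = NULL) {
  if (!is.null(mobile)) {
    stopifnot(nrow(mobile) == n, ncol(mobile) == 3)
    return(matrix(as.numeric(mobile), n, 3))
  }
  m <- matrix(1, n, 3)
  if (!is.null(frozen)) {
    if (is.logical(frozen)) frozen <- which(frozen)
    m[frozen, ] <- 0
  }
  m
}

.mb_velocities <- function(n, mass, temperature) {
  sd <- sqrt(.kB * temperature / mass)
  matrix(rnorm(3 * n), n, 3) * sd
}

#' Steepest-descent energy minimisation
#'
#' Adaptive-step steepest descent; the energy sequence is non-increasing
#' and the run terminates when the largest mobile force component falls
#' below `force_tol` or after `max_steps` trial steps.
#'
#' @param structure A `nanostructure` with derived topology.
#' @param ff A [forcefield()].
#' @param max_steps Maximum steps (default 4500).
#' @param force_tol Convergence threshold on the max force component,
#'   kJ/mol/A.
#' @param frozen Frozen-atom selection as in [run_config()].
#' @param init_step Initial trial displacement, A.
#' @return The structure with minimised positions; attributes `energy`,
#'   `energy_trace`, `steps`, `max_force`.
#' @export
minimize <- function(structure, ff, max_steps = 4500, force_tol = 10,
                     frozen = NULL, init_step = 0.05) {
  ffl <- .build_engine_ff(structure, ff)
  mob <- .mobility_matrix(n_atoms(structure), frozen)
  res <- cpp_minimize(structure$xyz, structure$box,
                      as.integer(structure$periodic), ffl, .null_ext(),
                      .engine_masses(structure, ff), mob,
                      as.integer(max_steps), force_tol, init_step,
                      2.0, 10L)
  out <- structure
  out$xyz <- res$positions
  attr(out, "energy") <- res$energy
  attr(out, "energy_trace") <- res$energy_trace
  attr(out, "steps") <- res$steps
  attr(out, "max_force") <- res$max_force
  out
}

.null_metad <- function() list(on = FALSE)

.run_engine <- function(structure, ff, config, ext = NULL, metad = NULL,
                        mobile = NULL, velocities = NULL, use_ff = TRUE) {
  n <- n_atoms(structure)
  ffl <- .build_engine_ff(structure, ff, use_ff = use_ff)
  mass <- .engine_masses(structure, ff)
  mob <- .mobility_matrix(n, config$frozen, mobile)
  set.seed(config$seed)
  if (is.null(velocities)) {
    velocities <- .mb_velocities(n, mass, config$temperature) * mob
  }
  thermo <- match(config$thermostat, c("none", "velocity-rescale", "langevin")) - 1L
  runl <- list(dt_fs = config$timestep, nsteps = config$nsteps,
               thermostat = thermo, temperature = config$temperature,
               tau_t_ps = config$tau_t, gamma_ps = config$friction,
               stride = config$stride, log_stride = config$log_stride,
               skin = config$skin, nlist_every = config$nlist_every)
  res <- cpp_run_md(structure$xyz, velocities, mass, structure$box,
                    as.integer(structure$periodic), mob, ffl,
                    if (is.null(ext)) .null_ext() else ext,
                    if (is.null(metad)) .null_metad() else metad,
                    runl)
  # engine packs each frame row-wise as (x1,y1,z1,x2,...)
  frames <- lapply(seq_len(nrow(res$frames)), function(k)
    matrix(res$frames[k, ], ncol = 3, byrow = TRUE))
  elog <- as.data.frame(res$elog)
  names(elog) <- c("step", "time", "E_pot", "E_kin", "T", "E_bias")
  traj <- trajectory(frames, res$frame_times, structure$species,
                     structure$box, structure$periodic, elog = elog,
                     provenance = list(seed = config$seed,
                                       config = unclass(config)))
  list(trajectory = traj, engine = res)
}

#' Run molecular dynamics
#'
#' Velocity-Verlet integration with the configured thermostat.  Initial
#' velocities are Maxwell-Boltzmann at the target temperature, drawn from
#' the configured seed; identical seed and configuration reproduce the
#' trajectory bit for bit.
#'
#' @param structure A `nanostructure` with derived topology.
#' @param ff A [forcefield()].
#' @param config A [run_config()].
#' @param velocities Optional n x 3 initial velocities (A per internal
#'   time unit); overrides Maxwell-Boltzmann initialisation.
#' @return A `trajectory` (with `$elog` energy log).
#' @export
run_md <- function(structure, ff, config, velocities = NULL) {
  .run_engine(structure, ff, config, velocities = velocities)$trajectory
}

# ---- RMSD ---------------------------------------------------------------

.kabsch <- function(P, Q) {
  # optimal rotation R (for row-vector points, P %*% R) mapping P onto Q
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Per-frame RMSD from a reference structure
#'
#' Translation is always removed (both frames centred); with
#' `superpose = TRUE` the optimal rigid rotation (Kabsch) is applied too.
#'
#' @param trajectory A `trajectory`.
#' @param reference A `nanostructure` (matching atom count).
#' @param superpose Remove rigid rotation as well as translation.
#' @param atoms Optional subset of atom indices.
#' @return data.frame with columns `time` (ps) and `rmsd` (A).
#' @export
rmsd_series <- function(trajectory, reference, superpose = TRUE,
                        atoms = NULL) {
  ref <- reference$xyz
  if (nrow(ref) != nrow(trajectory$frames[[1]]))
    stop("atom-count mismatch between trajectory and reference")
  if (!is.null(atoms)) ref <- ref[atoms, , drop = FALSE]
  refc <- scale(ref, scale = FALSE)
  vals <- vapply(trajectory$frames, function(fr) {
    if (!is.null(atoms)) fr <- fr[atoms, , drop = FALSE]
    frc <- scale(fr, scale = FALSE)
    if (superpose) frc <- frc %*% .kabsch(frc, refc)
    sqrt(mean(rowSums((frc - refc)^2)))
  }, numeric(1))
  data.frame(time = trajectory$times, rmsd = vals)
}
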