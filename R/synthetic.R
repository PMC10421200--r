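# Synthetic inputs with known answers: toy sorbate-over-surface systems
# whose exact PMF is prescribed analytically, orientation ensembles, and
# layered fluids with a prescribed density profile.  Every generator is
# deterministic under a fixed seed; one user seed fans out to independent
# per-generator streams so adding a generator never perturbs existing
# fixtures.

.sub_seed <- function(seed, id) {
  as.integer((as.numeric(seed) * 48271 + id) %% 2147483647)
}

# map a user-facing potential spec (nm units) to the engine's (kind, params
# in A) representation
.canon_potential <- function(potential) {
  kind <- potential$kind
  if (kind == "square-well") {
    edge <- if (is.null(potential$edge)) 0.01 else potential$edge
    core_k <- if (is.null(potential$core_k)) 1e6 else potential$core_k
    list(kind = 1L, params = c(potential$depth, potential$s_on * 10,
                               potential$s_off * 10, edge * 10,
                               core_k / 100))
  } else if (kind == "harmonic") {
    list(kind = 2L, params = c(potential$k / 100, potential$s0 * 10))
  } else if (kind == "double-well") {
    list(kind = 3L, params = c(potential$barrier, potential$center * 10,
                               potential$half_width * 10))
  } else if (kind == "wall-9-3") {
    list(kind = 4L, params = c(potential$epsilon, potential$sigma * 10))
  } else stop("unknown potential kind: ", kind)
}

# R mirror of the compiled external potentials (s in A, params in A)
.ext_energy <- function(kind, p, sA) {
  if (kind == 1L) {
    sa <- 1 / (1 + exp(-(sA - p[2]) / p[4]))
    sb <- 1 / (1 + exp(-(p[3] - sA) / p[4]))
    -p[1] * sa * sb + 0.5 * p[5] * pmax(0, p[2] - sA)^2
  } else if (kind == 2L) {
    0.5 * p[1] * (sA - p[2])^2
  } else if (kind == 3L) {
    x <- sA - p[2]
    p[1] * (x^2 - p[3]^2)^2 / p[3]^4
  } else if (kind == 4L) {
    r3 <- (p[2] / sA)^3
    p[1] * (2 / 15 * r3^3 - r3)
  } else rep(0, length(sA))
}

#' Toy sorbate-over-surface system with an analytically known PMF
#'
#' One frozen surface atom at the origin and a single sorbate particle
#' (or a rigid two-site dimer) constrained to the z axis, moving in a
#' prescribed external potential along its surface separation.  Because
#' the potential is the only s-dependent energy, the exact PMF equals the
#' constructed potential up to an additive constant, which makes the
#' system an end-to-end oracle for the metadynamics and free-energy
#' estimators.
#'
#' @param potential Spec list.  Kinds: `square-well` (depth kJ/mol,
#'   s_on/s_off nm, logistic `edge` width nm (default 0.01) and a
#'   quadratic contact core below s_on with `core_k` kJ/mol/nm^2,
#'   default 1e6), `harmonic` (k kJ/mol/nm^2, s0 nm),
#'   `double-well` (barrier kJ/mol,
#'   center nm, half_width nm: minima at center +- half_width),
#'   `wall-9-3` (epsilon kJ/mol, sigma nm).
#' @param seed Seed recorded in the system and used by the runner.
#' @param two_site Build a rigid two-site dimer instead of one particle.
#' @param site_separation Dimer site separation, nm.
#' @param mass Sorbate site mass, g/mol.
#' @param z0 Initial sorbate height, nm.
#' @return Object of class `toy_surface_system` with fields `structure`,
#'   `ff`, `sorbate`, `surface`, `mobile`, `potential`, `exact_pmf`
#'   (function of s in nm, kJ/mol), `seed`.
#' @export
make_toy_surface_system <- function(potential, seed = 1, two_site = FALSE,
                                    site_separation = 0.2, mass = 100,
                                    z0 = 0.8) {
  canon <- .canon_potential(potential)
  L <- 200  # box side, A (open boundaries)
  if (two_site) {
    sep <- site_separation * 10
    xyz <- rbind(c(L / 2, L / 2, 0),
                 c(L / 2, L / 2, z0 * 10 - sep / 2),
                 c(L / 2, L / 2, z0 * 10 + sep / 2))
    species <- c("SURF", "X", "X")
    bonds <- matrix(c(2L, 3L), 1, 2)
    sorbate <- c(2L, 3L)
  } else {
    xyz <- rbind(c(L / 2, L / 2, 0), c(L / 2, L / 2, z0 * 10))
    species <- c("SURF", "X")
    bonds <- matrix(integer(0), 0, 2)
    sorbate <- 2L
  }
  st <- nanostructure(species, xyz, box = rep(L, 3),
                      periodic = c(FALSE, FALSE, FALSE),
                      charge = rep(0, length(species)), bonds = bonds)
  # surface atom offset: the external potential acts on the COM separation
  ff <- forcefield(
    species = data.frame(name = c("SURF", "X"), q = 0,
                         sigma = c(1, 1), epsilon = c(0, 0),
                         mass = c(1e6, mass)),
    bonds = data.frame(a = "X", b = "X", kb = 100, r0 = site_separation * 10),
    angles = data.frame(end = character(0), apex = character(0),
                        k = numeric(0), theta0 = numeric(0)),
    cutoff = 0.3, coulomb = "off")
  mobile <- matrix(0, nrow(xyz), 3)
  mobile[sorbate, 3] <- 1   # sorbate moves along z only
  exact_pmf <- function(s_nm) .ext_energy(canon$kind, canon$params, s_nm * 10)
  structure(list(structure = st, ff = ff, sorbate = sorbate, surface = 1L,
                 mobile = mobile, potential = canon,
                 potential_spec = potential,
                 exact_pmf = exact_pmf, seed = as.integer(seed)),
            class = "toy_surface_system")
}

#' @export
print.toy_surface_system <- function(x, ...) {
  cat(sprintf("toy_surface_system: %s potential, %d sorbate site(s), seed %d\n",
              x$potential_spec$kind, length(x$sorbate), x$seed))
  invisible(x)
}

.toy_ext <- function(system) {
  list(kind = system$potential$kind, params = system$potential$params,
       group = as.integer(system$sorbate - 1L),
       surf = as.integer(system$surface - 1L),
       beta = 20)
}

#' Run metadynamics on a toy surface system with its recorded seed
#'
#' Convenience wrapper: [run_metadynamics()] with the system's force
#' field and a [run_config()] seeded from the system.
#'
#' @param system A [make_toy_surface_system()].
#' @param nsteps Number of 1-fs steps.
#' @param metad A [metad_config()].
#' @param temperature Temperature, K.
#' @param friction Langevin friction, ps^-1.
#' @return A `metad_result`.
#' @export
run_toy_metadynamics <- function(system, nsteps = 2e6,
                                 metad = metad_config(),
                                 temperature = 300, friction = 10) {
  run <- run_config(timestep = 1, nsteps = nsteps,
                    temperature = temperature, thermostat = "langevin",
                    friction = friction, seed = system$seed,
                    stride = max(1, nsteps %/% 200),
                    log_stride = max(1, nsteps %/% 500))
  res <- run_metadynamics(system, ff = system$ff, run = run, metad = metad)
  res
}

#' Random unit vectors: isotropic or axially biased
#'
#' Isotropic sampling is uniform on the sphere; axial-biased sampling
#' draws the polar angle from a Gaussian around `mu` (reflected into
#' \[0, 180\] deg) with spread `1/sqrt(concentration)` rad, and the
#' azimuth uniformly.
#'
#' @param kind "isotropic" or "axial-biased".
#' @param n Number of vectors.
#' @param seed Seed (fanned out; see package vignette).
#' @param mu Polar-angle mode for axial bias, degrees.
#' @param concentration Axial concentration parameter (> 0); larger is
#'   tighter.
#' @return n x 3 matrix of unit vectors; attribute `seed`.
#' @export
sample_orientations <- function(kind = c("isotropic", "axial-biased"), n,
                                seed = 1, mu = 65, concentration = 50) {
  kind <- match.arg(kind)
  if (n <= 0) stop("n must be > 0")
  set.seed(.sub_seed(seed, 101L))
  phi <- runif(n, 0, 2 * pi)
  if (kind == "isotropic") {
    z <- runif(n, -1, 1)
  } else {
    sd_deg <- 180 / pi / sqrt(concentration)
    th <- rnorm(n, mu, sd_deg)
    th <- abs(th) %% 360
    th <- ifelse(th > 180, 360 - th, th)   # reflect into [0, 180]
    z <- cos(th * pi / 180)
  }
  r <- sqrt(pmax(0, 1 - z^2))
  out <- cbind(r * cos(phi), r * sin(phi), z)
  attr(out, "seed") <- seed
  out
}

#' Layered-fluid trajectory with a prescribed density profile
#'
#' Places `n_particles` per frame by inverse-transform sampling of the
#' target rho(z) along z and uniformly in x, y — a test bed for the
#' density-profile analysis.
#'
#' @param profile Target rho(z): a non-negative (un-normalised) function
#'   of z in nm, or "uniform", or a list
#'   `list(kind = "two-gaussian", centers, sd, weights)` (nm).
#' @param n_particles Particles per frame.
#' @param n_frames Frames.
#' @param box Box, A (z extent sets the profile domain).
#' @param seed Seed.
#' @return A `trajectory` of species "OW" with 1-ps frame spacing;
#'   provenance records the seed.
#' @export
layered_fluid_trajectory <- function(profile, n_particles = 1000,
                                     n_frames = 10, box = c(30, 30, 60),
                                     seed = 1) {
  zmax <- box[3] / 10   # nm
  f <- if (is.function(profile)) {
    profile
  } else if (identical(profile, "uniform")) {
    function(z) rep(1, length(z))
  } else if (is.list(profile) && identical(profile$kind, "two-gaussian")) {
    function(z) {
      w <- if (is.null(profile$weights)) c(1, 1) else profile$weights
      w[1] * exp(-(z - profile$centers[1])^2 / (2 * profile$sd[1]^2)) +
        w[2] * exp(-(z - profile$centers[2])^2 / (2 * profile$sd[2]^2))
    }
  } else stop("unknown profile spec")
  zg <- seq(0, zmax, length.out = 4096)
  dens <- f(zg)
  if (any(dens < 0)) stop("rho must be >= 0")
  cdf <- cumsum(dens)
  if (cdf[length(cdf)] <= 0) stop("zero-mass profile")
  cdf <- cdf / cdf[length(cdf)]
  # make cdf strictly increasing for interpolation
  keep <- c(TRUE, diff(cdf) > 0)
  set.seed(.sub_seed(seed, 202L))
  frames <- lapply(seq_len(n_frames), function(k) {
    z <- approx(cdf[keep], zg[keep], xout = runif(n_particles),
                rule = 2)$y * 10
    cbind(runif(n_particles, 0, box[1]), runif(n_particles, 0, box[2]), z)
  })
  trajectory(frames, seq_len(n_frames), species = rep("OW", n_particles),
             box = box, periodic = c(TRUE, TRUE, FALSE),
             provenance = list(seed = seed))
}
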