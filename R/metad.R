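# Metadynamics on the surface-separation-distance (SSD) collective
# variable: CV evaluation, Gaussian bias bookkeeping, the one-sided
# quartic wall, unbiased mean-force accumulation and PMF recovery by
# integration of the mean force.
#
# User-facing CV quantities are in nm (forces in kJ/mol/nm); structure
# coordinates remain in Angstrom and are converted at the boundary.

#' Surface separation distance (SSD)
#'
#' Distance from the sorbate's centre of mass to the nearest surface atom:
#' the hard minimum, or the smooth soft-min
#' `s = -(1/beta) log sum_i exp(-beta d_i)` whose gradient is continuous
#' in the atomic coordinates.  The soft minimum is always <= the hard
#' minimum and converges to it as `beta` grows.
#'
#' @param sorbate Matrix (n x 3) of sorbate positions, nm.
#' @param surface Matrix (m x 3) of surface-atom positions, nm.
#' @param mode "hard" or "soft".
#' @param beta Soft-min sharpness, nm^-1 (default 200).
#' @param masses Sorbate masses for the COM (default: equal).
#' @param box,periodic Optional box (nm) and periodicity for minimum-image
#'   distances.
#' @return List with `s` (nm) and `gradient` (n x 3, d s / d sorbate
#'   coordinates, dimensionless).
#' @export
ssd <- function(sorbate, surface, mode = c("soft", "hard"), beta = 200,
                masses = NULL, box = NULL, periodic = NULL) {
  mode <- match.arg(mode)
  sorbate <- rbind(sorbate)
  surface <- rbind(surface)
  if (nrow(sorbate) == 0 || nrow(surface) == 0) stop("empty position set")
  if (is.null(masses)) masses <- rep(1, nrow(sorbate))
  if (is.null(box)) box <- c(0, 0, 0)
  if (is.null(periodic)) periodic <- c(FALSE, FALSE, FALSE)
  com <- colSums(sorbate * masses) / sum(masses)
  res <- cpp_ssd(com, surface, box, as.integer(periodic),
                 if (mode == "hard") -1 else beta)
  w <- masses / sum(masses)
  grad <- outer(w, res$grad)
  list(s = res$s, gradient = grad)
}

#' Metadynamics bias energy and derivative
#'
#' `U(s) = sum_k omega_k exp(-(s - s_k)^2 / (2 sigma_k^2))` over the
#' deposited hills, with its analytic derivative.
#'
#' @param s CV value(s), nm.
#' @param hills data.frame with columns s, sigma, height (as written by
#'   [write_hills()]).
#' @return List with `energy` (kJ/mol) and `dUds` (kJ/mol/nm), vectorised
#'   over `s`.
#' @export
bias_energy_force <- function(s, hills) {
  if (is.null(hills) || nrow(hills) == 0)
    return(list(energy = rep(0, length(s)), dUds = rep(0, length(s))))
  u <- numeric(length(s)); d <- numeric(length(s))
  for (k in seq_len(nrow(hills))) {
    x <- s - hills$s[k]
    g <- hills$height[k] * exp(-x^2 / (2 * hills$sigma[k]^2))
    u <- u + g
    d <- d - x / hills$sigma[k]^2 * g
  }
  list(energy = u, dUds = d)
}

#' Quartic upper-wall energy and derivative
#'
#' `U(s) = kappa (s - a)^4` for `s > a`, zero otherwise (one-sided by
#' default; `two_sided = TRUE` applies the quartic on both sides).  The
#' wall constant is in kJ/mol/A^4, matching the published protocol
#' (a = 1.5 nm, kappa = 40 kJ/mol/A^4 gives 40 kJ/mol at s = 1.6 nm).
#'
#' @param s CV value(s), nm.
#' @param a Wall position, nm.
#' @param kappa Wall constant, kJ/mol/A^4 (>= 0).
#' @param two_sided Apply on both sides of `a`.
#' @return List with `energy` (kJ/mol) and `dUds` (kJ/mol/nm).
#' @export
wall_energy_force <- function(s, a, kappa, two_sided = FALSE) {
  if (kappa < 0) stop("kappa must be >= 0")
  x <- (s - a) * 10                      # nm -> A
  active <- if (two_sided) x != 0 else x > 0
  u <- ifelse(active, kappa * x^4, 0)
  d <- ifelse(active, 4 * kappa * x^3 * 10, 0)   # per nm
  list(energy = u, dUds = d)
}

#' Metadynamics configuration
#'
#' Defaults follow the published protocol: Gaussian height 0.01 kJ/mol and
#' width 0.05 nm deposited every 1 ps, upper wall at 1.5 nm with
#' kappa = 40 kJ/mol/A^4.
#'
#' @param omega Gaussian height, kJ/mol.
#' @param sigma Gaussian width, nm.
#' @param tau Deposition period, ps.
#' @param wall_a Wall position, nm.
#' @param wall_kappa Wall constant, kJ/mol/A^4.
#' @param two_sided_wall Quartic on both sides of `wall_a`.
#' @param cv "com" (sorbate centre of mass) or "site" (single sorbate
#'   atom, `site` giving its index within the sorbate group).
#' @param site Sorbate atom index for `cv = "site"`.
#' @param beta Soft-min sharpness for dynamics, nm^-1.
#' @param bin_width Mean-force bin width, nm (default sigma / 2).
#' @param bin_range CV range binned, nm (default c(0, wall_a + 4 sigma)).
#' @param burnin_frac Fraction of the run excluded from force averaging
#'   (default 1/6).
#' @param n_blocks Number of post-burn-in blocks for error estimation.
#' @param cv_stride CV log stride, steps.
#' @return Object of class `metad_config`.
#' @export
metad_config <- function(omega = 0.01, sigma = 0.05, tau = 1,
                         wall_a = 1.5, wall_kappa = 40,
                         two_sided_wall = FALSE,
                         cv = c("com", "site"), site = 1L,
                         beta = 200, bin_width = sigma / 2,
                         bin_range = NULL, burnin_frac = 1 / 6,
                         n_blocks = 5, cv_stride = 10) {
  cv <- match.arg(cv)
  if (tau <= 0) stop("tau must be > 0")
  if (sigma <= 0) stop("sigma must be > 0")
  if (omega < 0) stop("omega must be >= 0")
  if (is.null(bin_range)) bin_range <- c(0, wall_a + 4 * sigma)
  structure(list(omega = omega, sigma = sigma, tau = tau,
                 wall_a = wall_a, wall_kappa = wall_kappa,
                 two_sided_wall = two_sided_wall, cv = cv,
                 site = as.integer(site), beta = beta,
                 bin_width = bin_width, bin_range = bin_range,
                 burnin_frac = burnin_frac, n_blocks = as.integer(n_blocks),
                 cv_stride = as.integer(cv_stride)),
            class = "metad_config")
}

#' Binned unbiased mean-force profile
#'
#' @param s Bin centres, nm.
#' @param count Per-bin sample counts.
#' @param force Per-bin mean unbiased force along the CV, kJ/mol/nm.
#' @param blocks Optional list with matrices `sum` and `count`
#'   (nbins x nblocks) for block-error analysis.
#' @return Object of class `mean_force_profile`.
#' @export
mean_force_profile <- function(s, count, force, blocks = NULL) {
  stopifnot(length(s) == length(count), length(s) == length(force))
  if (any(count < 0)) stop("negative bin count")
  structure(list(s = s, count = count, force = force, blocks = blocks),
            class = "mean_force_profile")
}

#' @export
print.mean_force_profile <- function(x, ...) {
  occ <- x$count > 0
  cat(sprintf("mean_force_profile: %d bins (%d occupied), s = %.3f .. %.3f nm\n",
              length(x$s), sum(occ), min(x$s[occ]), max(x$s[occ])))
  cat(sprintf("  samples: %g\n", sum(x$count)))
  invisible(x)
}

#' Run metadynamics
#'
#' Integrates the system with the configured thermostat while depositing
#' Gaussian bias along the SSD every `tau` ps, confining the CV with the
#' quartic upper wall, and accumulating the instantaneous unbiased force
#' along the CV, `F_s = (grad s . F_sys) / |grad s|^2`, into bins (bias
#' and wall forces are excluded from `F_sys`).
#'
#' @param system A [make_toy_surface_system()] object, or a
#'   `nanostructure` (then `sorbate` and `surface` index vectors are
#'   required and `ff` supplies the forces).
#' @param ff A [forcefield()], or NULL for toy systems whose only
#'   CV-dependent energy is their external potential.
#' @param run A [run_config()].
#' @param metad A [metad_config()].
#' @param sorbate,surface Atom index vectors (full-structure systems).
#' @return Object of class `metad_result`: list with `trajectory`,
#'   `hills` (time ps, s nm, sigma nm, height kJ/mol), `cv` (time, s,
#'   unbiased force kJ/mol/nm, bias energy), `profile`
#'   (a [mean_force_profile()]), and the configurations.
#' @export
run_metadynamics <- function(system, ff = NULL, run, metad = metad_config(),
                             sorbate = NULL, surface = NULL) {
  if (inherits(system, "toy_surface_system")) {
    structure <- system$structure
    sorbate <- system$sorbate
    surface <- system$surface
    ext <- .toy_ext(system)
    mobile <- system$mobile
    if (is.null(ff)) ff <- system$ff
    use_ff <- TRUE
  } else {
    structure <- system
    if (is.null(sorbate) || is.null(surface))
      stop("sorbate and surface index vectors are required")
    ext <- NULL
    mobile <- NULL
    use_ff <- !is.null(ff)
  }
  group <- if (metad$cv == "com") sorbate else sorbate[metad$site]
  dt_ps <- run$timestep / 1000
  tau_steps <- max(1L, as.integer(round(metad$tau / dt_ps)))
  nbins <- as.integer(ceiling(diff(metad$bin_range) / metad$bin_width))
  burnin <- as.integer(floor(run$nsteps * metad$burnin_frac))
  block_steps <- as.integer(ceiling((run$nsteps - burnin) / metad$n_blocks))
  metadl <- list(on = TRUE,
                 group = as.integer(group - 1L),
                 surf = as.integer(surface - 1L),
                 beta = metad$beta / 10,                 # nm^-1 -> A^-1
                 omega = metad$omega,
                 sigma_g = metad$sigma * 10,             # nm -> A
                 tau_steps = tau_steps,
                 wall_a = metad$wall_a * 10,
                 wall_kappa = metad$wall_kappa,          # already per A^4
                 wall_two_sided = metad$two_sided_wall,
                 bin_lo = metad$bin_range[1] * 10,
                 bin_w = metad$bin_width * 10,
                 nbins = nbins,
                 burnin_steps = burnin,
                 block_steps = block_steps,
                 cv_stride = metad$cv_stride)
  res <- .run_engine(structure, ff, run, ext = ext, metad = metadl,
                     mobile = mobile, use_ff = use_ff)
  eng <- res$engine$metad
  hills <- data.frame(time = as.numeric(eng$hill_t),
                      s = as.numeric(eng$hill_s) / 10,
                      sigma = rep(metad$sigma, length(eng$hill_t)),
                      height = rep(metad$omega, length(eng$hill_t)))
  cv <- data.frame(time = eng$cv_t, s = eng$cv_s / 10,
                   force = eng$cv_f * 10,                # kJ/mol/A -> kJ/mol/nm
                   bias = eng$cv_ebias)
  cnt <- rowSums(eng$fbin_cnt)
  fsum <- rowSums(eng$fbin_sum)
  centers <- (metad$bin_range[1] + (seq_len(nbins) - 0.5) * metad$bin_width)
  force <- ifelse(cnt > 0, fsum / pmax(cnt, 1) * 10, NA_real_)
  profile <- mean_force_profile(centers, cnt, force,
                                blocks = list(sum = eng$fbin_sum * 10,
                                              count = eng$fbin_cnt))
  structure(list(trajectory = res$trajectory, hills = hills, cv = cv,
                 profile = profile, run = run, metad = metad),
            class = "metad_result")
}

#' @export
print.metad_result <- function(x, ...) {
  cat(sprintf("metad_result: %d hills, %d CV samples\n",
              nrow(x$hills), nrow(x$cv)))
  print(x$profile)
  invisible(x)
}

#' Integrate a mean-force profile into a PMF
#'
#' `W(s) = int_s^{s_n} <F(s')> ds'` by the trapezoid rule from the bulk
#' edge inward.  The zero of W is set to the mean over a bulk window (by
#' default the outer quarter of the occupied range, excluding the two
#' outermost bins, which can be perturbed by the confining wall); with
#' `bulk_fraction = 0` the largest occupied bin is used instead.
#' Interior gaps of at most `max_gap` consecutive empty bins are bridged
#' by linear interpolation of the mean force (and flagged); larger gaps
#' signal unconverged sampling.
#'
#' @param profile A [mean_force_profile()].
#' @param temperature Temperature recorded on the PMF, K.
#' @param max_gap Largest bridgeable run of empty interior bins.
#' @param bulk_fraction Outer fraction of the occupied range averaged for
#'   the zero reference.
#' @return A [pmf_curve()] with attribute `bridged` (indices of
#'   interpolated bins).
#' @export
integrate_pmf <- function(profile, temperature = 300, max_gap = 2,
                          bulk_fraction = 0.25) {
  occ <- which(profile$count > 0 & is.finite(profile$force))
  if (length(occ) < 2) stop("need at least 2 occupied bins")
  lo <- min(occ); hi <- max(occ)
  s <- profile$s[lo:hi]
  f <- profile$force[lo:hi]
  empty <- !(seq(lo, hi) %in% occ)
  if (any(empty)) {
    runs <- rle(empty)
    if (any(runs$lengths[runs$values] > max_gap))
      stop("unconverged sampling: interior gap of more than ", max_gap,
           " empty bins")
    f[empty] <- approx(s[!empty], f[!empty], xout = s[empty])$y
  }
  n <- length(s)
  W <- numeric(n)
  for (i in seq(n - 1, 1)) {
    W[i] <- W[i + 1] + 0.5 * (f[i] + f[i + 1]) * (s[i + 1] - s[i])
  }
  if (bulk_fraction > 0 && n >= 8) {
    iw <- seq(max(1, floor(n * (1 - bulk_fraction))), n - 2)
    W <- W - mean(W[iw])
  }
  out <- pmf_curve(s, W, temperature = temperature, reference = "bulk-zero")
  attr(out, "bridged") <- which(empty)
  out
}
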