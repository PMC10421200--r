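# Interfacial-structure analysis: density profiles (planar, radial,
# nearest-surface-atom), water dipole / OH orientation distributions,
# first-shell detection and pairwise radial distribution functions.
#
# Trajectories and reference coordinates are in Angstrom (engine units);
# binned axes and reported distances are in nm, densities in nm^-3.

.sel_indices <- function(traj, selection) {
  if (is.character(selection)) which(traj$species %in% selection)
  else as.integer(selection)
}

.as_traj <- function(x) {
  if (inherits(x, "trajectory")) return(x)
  if (inherits(x, "nanostructure"))
    return(trajectory(list(x$xyz), 0, x$species, x$box, x$periodic))
  stop("need a trajectory or nanostructure")
}

#' Time-averaged density profile
#'
#' Number density of a selection along one of three axes: `planar-z`
#' (slab geometry, normalised by cross-section x bin width), `radial`
#' (normalised by spherical-shell volume around `center`), or
#' `nearest-surface` (distance to the closest atom of `reference`,
#' normalised by Monte-Carlo-estimated accessible bin volumes inside the
#' box, so that the profile integrates back to the particle count).
#'
#' @param trajectory A `trajectory` (or single `nanostructure`).
#' @param selection Species labels or atom indices.
#' @param mode "planar-z", "radial" or "nearest-surface".
#' @param reference Centre (length-3, A) for radial mode; surface-atom
#'   position matrix (A) or `nanostructure` for nearest-surface mode.
#' @param bin Bin width, nm.
#' @param range Length-2 binned range, nm (mode-appropriate default).
#' @param mc_points Monte-Carlo points for nearest-surface volumes.
#' @param mc_seed Seed for the volume estimate.
#' @return Object of class `density_profile`: bin centres `s` (nm),
#'   `density` (nm^-3), `bin_volume` (nm^3), per-frame mean count.
#' @export
density_profile <- function(trajectory, selection, mode = c("planar-z",
                            "radial", "nearest-surface"), reference = NULL,
                            bin = 0.02, range = NULL,
                            mc_points = 50000, mc_seed = 1) {
  mode <- match.arg(mode)
  traj <- .as_traj(trajectory)
  sel <- .sel_indices(traj, selection)
  if (length(sel) == 0) stop("empty selection")
  box <- traj$box
  if (inherits(reference, "nanostructure")) reference <- reference$xyz
  binA <- bin * 10
  values <- switch(mode,
    "planar-z" = unlist(lapply(traj$frames, function(fr) fr[sel, 3])),
    "radial" = {
      ctr <- if (is.null(reference)) c(0, 0, 0) else reference
      unlist(lapply(traj$frames, function(fr) {
        d <- sweep(fr[sel, , drop = FALSE], 2, ctr)
        sqrt(rowSums(d^2))
      }))
    },
    "nearest-surface" = {
      if (is.null(reference)) stop("nearest-surface mode needs reference atoms")
      unlist(lapply(traj$frames, function(fr)
        cpp_pair_distances_min(fr[sel, , drop = FALSE], reference,
                               box, as.integer(traj$periodic))))
    })
  if (is.null(range)) {
    range <- switch(mode,
      "planar-z" = c(0, box[3] / 10),
      c(0, max(values) / 10 + bin))
  }
  rngA <- range * 10
  nb <- ceiling(diff(rngA) / binA)
  edges <- rngA[1] + (0:nb) * binA
  centers <- (edges[-1] + edges[-(nb + 1)]) / 2
  cnt <- tabulate(findInterval(values, edges, rightmost.closed = TRUE,
                               all.inside = FALSE), nbins = nb + 1)[1:nb]
  cnt[is.na(cnt)] <- 0
  nfr <- length(traj$frames)
  mean_cnt <- cnt / nfr
  volA3 <- switch(mode,
    "planar-z" = rep(box[1] * box[2] * binA, nb),
    "radial" = 4 * pi / 3 * (edges[-1]^3 - edges[-(nb + 1)]^3),
    "nearest-surface" = {
      set.seed(mc_seed)
      pts <- cbind(runif(mc_points, 0, box[1]), runif(mc_points, 0, box[2]),
                   runif(mc_points, 0, box[3]))
      d <- cpp_pair_distances_min(pts, reference, box,
                                  as.integer(traj$periodic))
      h <- tabulate(findInterval(d, edges, rightmost.closed = TRUE),
                    nbins = nb + 1)[1:nb]
      h[is.na(h)] <- 0
      h / mc_points * prod(box)
    })
  dens <- ifelse(volA3 > 0, mean_cnt / volA3 * 1000, 0)  # A^-3 -> nm^-3
  structure(list(mode = mode, s = centers / 10, density = dens,
                 bin_volume = volA3 / 1000, mean_count = mean_cnt,
                 n_frames = nfr, bin = bin),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("density_profile (%s): %d bins, s = %.3f .. %.3f nm\n",
              x$mode, length(x$s), min(x$s), max(x$s)))
  cat(sprintf("  mean selected count/frame: %.2f\n", sum(x$mean_count)))
  invisible(x)
}

#' @export
plot.density_profile <- function(x, ...) {
  graphics::plot(x$s, x$density, type = "l", xlab = "s (nm)",
                 ylab = expression(rho ~ (nm^-3)), ...)
  invisible(x)
}

#' Water orientation angles in a shell
#'
#' For each water molecule whose oxygen lies in the distance shell, the
#' dipole direction (from O through the H-H midpoint) and the two OH bond
#' directions are compared with the reference direction: the surface
#' normal (+z) for slabs, or the outward radial direction for particles.
#' theta is the dipole angle, alpha the OH angles.
#'
#' @param trajectory A `trajectory`.
#' @param water Integer matrix (n x 3): O, H, H atom indices per molecule.
#' @param reference "normal" (slab, +z) or "radial".
#' @param origin Surface plane z (A) for "normal"; centre (length-3, A)
#'   for "radial".  Distances are measured from it.
#' @param shell Length-2 shell range, nm (default: everything).
#' @return data.frame with theta, alpha1, alpha2 (degrees) and distance
#'   (nm), one row per in-shell water per frame.
#' @export
orientation_angles <- function(trajectory, water, reference = c("normal",
                               "radial"), origin = 0, shell = c(0, Inf)) {
  reference <- match.arg(reference)
  traj <- .as_traj(trajectory)
  water <- rbind(water)
  if (ncol(water) != 3) stop("water must be an n x 3 index matrix (O, H, H)")
  ang <- function(v, ref) {
    cosang <- rowSums(v * ref) / sqrt(rowSums(v^2) * rowSums(ref^2))
    acos(pmax(-1, pmin(1, cosang))) * 180 / pi
  }
  out <- lapply(traj$frames, function(fr) {
    O <- fr[water[, 1], , drop = FALSE]
    H1 <- fr[water[, 2], , drop = FALSE]
    H2 <- fr[water[, 3], , drop = FALSE]
    if (reference == "normal") {
      dist <- (O[, 3] - origin) / 10
      ref <- matrix(rep(c(0, 0, 1), each = nrow(O)), ncol = 3)
    } else {
      d <- sweep(O, 2, origin)
      r <- sqrt(rowSums(d^2))
      dist <- r / 10
      ref <- d / r
    }
    keep <- dist >= shell[1] & dist <= shell[2]
    if (!any(keep)) return(NULL)
    O <- O[keep, , drop = FALSE]; H1 <- H1[keep, , drop = FALSE]
    H2 <- H2[keep, , drop = FALSE]; ref <- ref[keep, , drop = FALSE]
    dip <- (H1 + H2) / 2 - O
    data.frame(theta = ang(dip, ref),
               alpha1 = ang(H1 - O, ref),
               alpha2 = ang(H2 - O, ref),
               distance = dist[keep])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(theta = numeric(0), alpha1 = numeric(0),
                      alpha2 = numeric(0), distance = numeric(0))
  out
}

#' Angle histogram as a probability density over \[0, 180\] degrees
#'
#' Raw mode reports the sampled angle density (an isotropic ensemble then
#' follows the sin-theta solid-angle shape, peaking at 90 deg);
#' sin-corrected mode divides each bin by sin(theta at bin centre) before
#' normalising, so an isotropic ensemble is flat.
#'
#' @param angles Numeric vector of angles in degrees (e.g. the `theta`
#'   column of [orientation_angles()]).
#' @param weighting "raw" or "sin-corrected".
#' @param bin Bin width, degrees.
#' @return data.frame with `angle` (bin centres, deg) and `density`
#'   (deg^-1, integrating to 1 over the domain).
#' @export
orientation_histogram <- function(angles, weighting = c("raw",
                                  "sin-corrected"), bin = 5) {
  weighting <- match.arg(weighting)
  if (length(angles) == 0) stop("empty input")
  nb <- ceiling(180 / bin)
  edges <- (0:nb) * bin
  centers <- (edges[-1] + edges[-(nb + 1)]) / 2
  cnt <- tabulate(findInterval(pmin(angles, 180 - 1e-9), edges,
                               rightmost.closed = TRUE), nbins = nb)
  dens <- as.numeric(cnt)
  if (weighting == "sin-corrected")
    dens <- dens / sin(centers * pi / 180)
  dens <- dens / (sum(dens) * bin)
  data.frame(angle = centers, density = dens)
}

#' Radial distribution function between two groups
#'
#' `g(r)` with ideal-gas normalisation in the frame's box.  With
#' `com = TRUE` the first group is collapsed to its centre of mass in
#' each frame (the convention for sorbent-to-polymer RDFs).
#'
#' @param trajectory A `trajectory` (or `nanostructure`).
#' @param group_a,group_b Species labels or atom indices.
#' @param bin Bin width, nm.
#' @param r_max Maximum distance, nm; must not exceed half the smallest
#'   periodic box length.
#' @param com Collapse group_a to one point per frame.
#' @return data.frame with `r` (nm) and `g`.
#' @export
pair_rdf <- function(trajectory, group_a, group_b, bin = 0.002,
                     r_max = 1, com = FALSE) {
  traj <- .as_traj(trajectory)
  ia <- .sel_indices(traj, group_a)
  ib <- .sel_indices(traj, group_b)
  if (length(ia) == 0 || length(ib) == 0) stop("empty group")
  box <- traj$box
  per <- traj$periodic
  rmaxA <- r_max * 10
  if (any(per) && rmaxA > min(box[per]) / 2)
    stop("r_max exceeds half the smallest periodic box length")
  binA <- bin * 10
  nb <- ceiling(rmaxA / binA)
  edges <- (0:nb) * binA
  centers <- (edges[-1] + edges[-(nb + 1)]) / 2
  same <- !com && length(ia) == length(ib) && all(sort(ia) == sort(ib))
  total <- numeric(nb)
  for (fr in traj$frames) {
    A <- fr[ia, , drop = FALSE]
    if (com) A <- matrix(colMeans(A), 1, 3)
    B <- fr[ib, , drop = FALSE]
    d <- cpp_all_pair_dists(A, B, box, as.integer(per), rmaxA, same)
    h <- tabulate(findInterval(d, edges, rightmost.closed = TRUE), nbins = nb)
    total <- total + h
  }
  vol <- prod(box)
  shell <- 4 * pi / 3 * (edges[-1]^3 - edges[-(nb + 1)]^3)
  na <- if (com) 1 else length(ia)
  npairs <- if (same) na * (na - 1) / 2 else na * length(ib)
  ideal <- npairs / vol * shell * length(traj$frames)
  data.frame(r = centers / 10, g = ifelse(ideal > 0, total / ideal, 0))
}

#' First minimum of a profile after its first maximum
#'
#' Applies a centred moving-average smoothing (window in bins) and
#' returns the location of the first local minimum following the first
#' local maximum; used to delimit the first solvation shell.
#'
#' @param profile A `density_profile`, an RDF data.frame (r, g), or a
#'   two-column matrix (x, y).
#' @param window Smoothing window in bins (odd; 1 disables smoothing).
#' @return Location of the first minimum (same x units as the input).
#' @export
first_minimum <- function(profile, window = 3) {
  if (inherits(profile, "density_profile")) {
    x <- profile$s; y <- profile$density
  } else {
    m <- as.matrix(profile)
    x <- m[, 1]; y <- m[, 2]
  }
  if (window > 1) {
    k <- rep(1 / window, window)
    ys <- stats::filter(y, k, sides = 2)
    inner <- !is.na(ys)
    x <- x[inner]; y <- as.numeric(ys[inner])
  }
  n <- length(y)
  imax <- NA
  for (i in 2:(n - 1)) {
    if (y[i] > y[i - 1] && y[i] >= y[i + 1]) { imax <- i; break }
  }
  if (is.na(imax)) {
    if (y[1] > y[2]) imax <- 1
    else stop("monotone profile: no interior maximum")
  }
  for (i in seq(max(imax + 1, 2), n - 1)) {
    if (y[i] < y[i - 1] && y[i] <= y[i + 1]) return(x[i])
  }
  stop("monotone profile beyond the first maximum: no minimum found")
}
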