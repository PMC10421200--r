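make_gas_traj <- function(n = 2000, frames = 5, box = c(30, 30, 60),
                          seed = 2) {
  set.seed(seed)
  fr <- lapply(seq_len(frames), function(k)
    cbind(runif(n, 0, box[1]), runif(n, 0, box[2]), runif(n, 0, box[3])))
  trajectory(fr, seq_len(frames), rep("OW", n), box,
             c(TRUE, TRUE, TRUE))
}

test_that("planar density of an ideal gas is flat at N/V", {
  tr <- make_gas_traj()
  dp <- density_profile(tr, "OW", mode = "planar-z", bin = 0.05)
  nv <- 2000 / prod(tr$box / 10)        # nm^-3
  expect_lt(max(abs(dp$density - nv)) / nv, 0.45)   # counting noise, max over bins
  expect_equal(mean(dp$density), nv, tolerance = 0.02)
})

test_that("radial density of a uniform sphere is flat after shell normalisation", {
  set.seed(3)
  n <- 30000
  # uniform points in a ball of radius 12 A by rejection
  p <- matrix(runif(3 * n * 3, -12, 12), ncol = 3)
  p <- p[rowSums(p^2) < 144, ][seq_len(8000), ]
  tr <- trajectory(list(p), 0, rep("OW", nrow(p)), c(40, 40, 40),
                   c(FALSE, FALSE, FALSE))
  dp <- density_profile(tr, "OW", mode = "radial", reference = c(0, 0, 0),
                        bin = 0.1, range = c(0, 1.2))
  inner <- dp$s > 0.3 & dp$s < 1.1   # skip small-shell noise
  expect_lt(sd(dp$density[inner]) / mean(dp$density[inner]), 0.15)
})

test_that("density profiles conserve particle number to 0.1 percent", {
  tr <- make_gas_traj(n = 3000, frames = 3)
  dp <- density_profile(tr, "OW", mode = "planar-z", bin = 0.05)
  expect_equal(sum(dp$density * dp$bin_volume), 3000, tolerance = 1e-3)

  slab <- build_slab_110(lattice_spec(5.41), 2, 2, 4)
  dn <- density_profile(tr, "OW", mode = "nearest-surface",
                        reference = slab, bin = 0.05, range = c(0, 7),
                        mc_points = 200000)
  expect_equal(sum(dp$density * dp$bin_volume), 3000, tolerance = 1e-3)
  expect_equal(sum(dn$mean_count), 3000, tolerance = 1e-3)
})

test_that("layered-fluid generator round-trips through the profile analysis", {
  target <- list(kind = "two-gaussian", centers = c(1.5, 4.0),
                 sd = c(0.3, 0.3))
  tr <- layered_fluid_trajectory(target, n_particles = 4000, n_frames = 10,
                                 box = c(30, 30, 60), seed = 8)
  dp <- density_profile(tr, "OW", mode = "planar-z", bin = 0.1)
  # recovered peak positions within one bin of the targets
  pk1 <- dp$s[dp$s < 2.5][which.max(dp$density[dp$s < 2.5])]
  pk2 <- dp$s[dp$s > 2.5][which.max(dp$density[dp$s > 2.5])]
  expect_lt(abs(pk1 - 1.5), 0.1 + 1e-9)
  expect_lt(abs(pk2 - 4.0), 0.1 + 1e-9)
})

test_that("orientation angles have their geometric closed forms", {
  # one water with dipole along +z
  hoh <- 104.52 * pi / 180
  O <- c(0, 0, 0)
  H1 <- c(sin(hoh / 2), 0, cos(hoh / 2))
  H2 <- c(-sin(hoh / 2), 0, cos(hoh / 2))
  fr <- rbind(O, H1, H2)
  tr <- trajectory(list(fr), 0, c("OW", "HW", "HW"), c(20, 20, 20),
                   rep(FALSE, 3))
  ang <- orientation_angles(tr, water = cbind(1, 2, 3),
                            reference = "normal", origin = -5)
  expect_equal(ang$theta, 0, tolerance = 1e-9)
  expect_equal(ang$alpha1, 104.52 / 2, tolerance = 1e-9)
  expect_equal(ang$alpha2, 104.52 / 2, tolerance = 1e-9)
})

test_that("isotropic orientations give sin-shaped raw and flat corrected histograms", {
  v <- sample_orientations("isotropic", 200000, seed = 6)
  theta <- acos(pmax(-1, pmin(1, v[, 3]))) * 180 / pi
  expect_lt(abs(mean(cos(theta * pi / 180))), 3 / sqrt(length(theta)) + 0.005)

  raw <- orientation_histogram(theta, "raw", bin = 5)
  # raw density proportional to sin(theta), maximum at 90 degrees
  expect_equal(raw$angle[which.max(raw$density)], 92.5, tolerance = 3)
  shape <- sin(raw$angle * pi / 180) * pi / 180 / 2   # analytic density
  expect_lt(max(abs(raw$density - shape)), 0.1 * max(shape))

  cor <- orientation_histogram(theta, "sin-corrected", bin = 5)
  inner <- cor$angle > 10 & cor$angle < 170
  expect_lt(sd(cor$density[inner]) / mean(cor$density[inner]), 0.1)

  # all mass in one bin integrates to one
  one <- orientation_histogram(rep(42, 100), "raw", bin = 5)
  expect_equal(sum(one$density) * 5, 1)
  expect_equal(sum(one$density > 0), 1)
  expect_error(orientation_histogram(numeric(0)), "empty")
})

test_that("orientation histograms are invariant under rigid rotation with the reference", {
  set.seed(14)
  n <- 500
  O <- cbind(runif(n, 5, 15), runif(n, 5, 15), runif(n, 5, 15))
  d <- sample_orientations("axial-biased", n, seed = 3, mu = 65)
  hoh <- 104.52 * pi / 180
  # build waters with dipole along d (arbitrary perpendicular for the H plane)
  perp <- cbind(-d[, 2], d[, 1], 0)
  perp <- perp / sqrt(rowSums(perp^2))
  H1 <- O + cos(hoh / 2) * d + sin(hoh / 2) * perp
  H2 <- O + cos(hoh / 2) * d - sin(hoh / 2) * perp
  fr <- rbind(O, H1, H2)
  w <- cbind(1:n, n + 1:n, 2 * n + 1:n)
  tr <- trajectory(list(fr), 0, rep(c("OW", "HW", "HW"), each = n),
                   c(40, 40, 40), rep(FALSE, 3))
  a1 <- orientation_angles(tr, w, reference = "normal", origin = 0)
  # rotate everything by 90 deg about x: the reference becomes +y, which we
  # emulate by rotating coordinates and keeping the +z reference
  R <- rbind(c(1, 0, 0), c(0, 0, -1), c(0, 1, 0))
  tr2 <- trajectory(list(fr %*% t(R)), 0, tr$species, c(40, 40, 40),
                    rep(FALSE, 3))
  # reference direction rotates with the frame: z -> Rz, so compare against
  # angles measured w.r.t. the rotated normal via the radial trick:
  a2 <- orientation_angles(tr2, w, reference = "radial",
                           origin = c(0, 1e8, 0))
  # outward radial direction from the distant centre is (0,-1,0), which is
  # exactly the rotated surface normal R z
  expect_equal(sort(a1$theta), sort(a2$theta), tolerance = 1e-3)
  expect_equal(sort(c(a1$alpha1, a1$alpha2)), sort(c(a2$alpha1, a2$alpha2)),
               tolerance = 1e-3)
})

test_that("pair RDF matches ideal-gas and lattice oracles", {
  tr <- make_gas_traj(n = 1500, frames = 4, box = c(25, 25, 25), seed = 10)
  rdf <- pair_rdf(tr, "OW", "OW", bin = 0.02, r_max = 1.2)
  outer <- rdf$r > 0.3
  expect_lt(abs(mean(rdf$g[outer]) - 1), 0.05)
  expect_lt(sd(rdf$g[outer]), 0.2)

  # two fixed particles at distance d: single peak at d
  fr <- rbind(c(5, 5, 5), c(5, 5, 11.5))
  tr2 <- trajectory(list(fr), 0, c("A", "B"), c(30, 30, 30), rep(FALSE, 3))
  rdf2 <- pair_rdf(tr2, 1, 2, bin = 0.01, r_max = 1.2)
  expect_equal(rdf2$r[which.max(rdf2$g)], 0.655, tolerance = 0.011)

  # perfect ZnS lattice: unlike-pair shells at a*sqrt(3)/4 and a*sqrt(11)/4
  cell <- build_unit_cell(lattice_spec(5.41))
  big <- build_slab_110(lattice_spec(5.41), 2, 2, 8)   # thicker block
  rdf3 <- pair_rdf(big, which(big$species == "Zn"), which(big$species == "S"),
                   bin = 0.005, r_max = 0.52)
  peaks <- rdf3$r[rdf3$g > 0.5 * max(rdf3$g)]
  expect_lt(abs(min(peaks) - 0.23426), 0.005 + 1e-9)
  expect_true(any(abs(rdf3$r[rdf3$g > 1] - 0.4486) < 0.0075))
  expect_error(pair_rdf(tr, "OW", "OW", r_max = 2), "half")
})

test_that("first minimum is found after the first maximum", {
  x <- seq(0, 6, 0.05)
  y <- exp(-(x - 1.5)^2 / 0.18) + 0.8 * exp(-(x - 3.5)^2 / 0.5) + 0.01
  fm <- first_minimum(cbind(x, y))
  # analytic trough of the two-Gaussian mixture, found numerically
  tr <- optimize(function(z) exp(-(z - 1.5)^2 / 0.18) +
                   0.8 * exp(-(z - 3.5)^2 / 0.5), c(1.6, 3.4))$minimum
  expect_lt(abs(fm - tr), 0.05 + 1e-9)
  # smoothing window 1 on noiseless input gives the same answer
  expect_equal(first_minimum(cbind(x, y), window = 1), fm, tolerance = 0.051)
  expect_error(first_minimum(cbind(x, exp(-x))), "monotone")
})
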