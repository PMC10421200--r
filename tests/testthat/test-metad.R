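test_that("SSD hard and soft minima match closed forms", {
  # one surface atom at the origin, sorbate COM 3 nm above
  h <- ssd(rbind(c(0, 0, 3)), rbind(c(0, 0, 0)), mode = "hard")
  expect_equal(h$s, 3)
  expect_equal(h$gradient, rbind(c(0, 0, 1)))

  # two surface atoms at distances {3, 4} nm, beta = 10 /nm
  surf <- rbind(c(0, 0, 0), c(0, 0, 7))
  sft <- ssd(rbind(c(0, 0, 3)), surf, mode = "soft", beta = 10)
  expect_equal(sft$s, 3 - log(1 + exp(-10)) / 10, tolerance = 1e-12)

  expect_error(ssd(matrix(0, 0, 3), surf), "empty")
})

test_that("soft minimum is a lower bound on the hard minimum and tight at default beta", {
  set.seed(5)
  for (k in 1:20) {
    surf <- matrix(runif(30, 0, 2), ncol = 3)
    p <- matrix(runif(3, 2.5, 4), ncol = 3)
    d <- sort(sqrt(colSums((t(surf) - as.numeric(p))^2)))
    sh <- ssd(p, surf, mode = "hard")$s
    ss <- ssd(p, surf, mode = "soft", beta = 200)$s
    expect_lte(ss, sh + 1e-12)
    # worst-case bound log(n)/beta always; tight when distances are separated
    expect_lt(sh - ss, log(nrow(surf)) / 200 + 1e-12)
    if (d[2] - d[1] > 0.04) expect_lt(sh - ss, 1e-3)
  }
})

test_that("SSD gradient matches central finite differences", {
  set.seed(9)
  surf <- matrix(runif(15, 0, 1), ncol = 3)
  sorb <- rbind(c(0.2, 0.3, 2.0), c(0.4, 0.1, 2.4))
  masses <- c(2, 1)
  g <- ssd(sorb, surf, mode = "soft", beta = 50, masses = masses)$gradient
  h <- 1e-6
  for (i in 1:2) for (cc in 1:3) {
    sp <- sorb; sp[i, cc] <- sp[i, cc] + h
    sm <- sorb; sm[i, cc] <- sm[i, cc] - h
    num <- (ssd(sp, surf, "soft", 50, masses)$s -
            ssd(sm, surf, "soft", 50, masses)$s) / (2 * h)
    expect_equal(g[i, cc], num, tolerance = 1e-6)
  }
})

test_that("bias energy is the analytic sum of deposited Gaussians", {
  expect_equal(bias_energy_force(0.5, NULL)$energy, 0)
  one <- data.frame(time = 1, s = 0.5, sigma = 0.05, height = 0.01)
  at_center <- bias_energy_force(0.5, one)
  expect_equal(at_center$energy, 0.01)
  expect_equal(at_center$dUds, 0)
  two <- rbind(one, one)
  expect_equal(bias_energy_force(c(0.4, 0.55), two)$energy,
               2 * bias_energy_force(c(0.4, 0.55), one)$energy)
})

test_that("quartic wall is one-sided, continuous and differentiable at contact", {
  expect_equal(wall_energy_force(1.2, 1.5, 40)$energy, 0)
  expect_equal(wall_energy_force(1.5, 1.5, 40)$dUds, 0)
  # published constants: 1 A beyond a 1.5-nm wall with kappa 40 kJ/mol/A^4
  expect_equal(wall_energy_force(1.6, 1.5, 40)$energy, 40, tolerance = 1e-10)
  # smooth contact: energy and first derivative vanish as s -> a+
  eps <- 1e-4
  expect_lt(wall_energy_force(1.5 + eps, 1.5, 40)$energy, 1e-10)
  expect_lt(wall_energy_force(1.5 + eps, 1.5, 40)$dUds, 1e-5)
  # two-sided variant activates below the wall too
  expect_gt(wall_energy_force(1.4, 1.5, 40, two_sided = TRUE)$energy, 0)
  expect_error(wall_energy_force(1, 1.5, -1), "kappa")
})

test_that("metadynamics bookkeeping: hill count, zero-bias limit, file round-trip", {
  sys <- make_toy_surface_system(list(kind = "harmonic", k = 300, s0 = 0.7),
                                 seed = 21)
  res <- run_toy_metadynamics(sys, nsteps = 5000, metad = metad_config())
  # one hill per tau = 1 ps = 1000 steps
  expect_equal(nrow(res$hills), floor(5000 / 1000))

  # omega = 0: bias energy identically zero along the run
  res0 <- run_toy_metadynamics(sys, nsteps = 5000,
                               metad = metad_config(omega = 0))
  expect_true(all(res0$cv$bias == 0))
  expect_equal(nrow(res0$hills), 0)

  # hills file round-trip reproduces the bias energy exactly
  f <- tempfile()
  write_hills(res$hills, f)
  back <- read_hills(f)
  sgrid <- seq(0.2, 1.2, 0.05)
  expect_equal(bias_energy_force(sgrid, back)$energy,
               bias_energy_force(sgrid, res$hills)$energy, tolerance = 1e-6)
})

test_that("binned mean force matches the analytic gradient of a known potential", {
  k <- 300
  sys <- make_toy_surface_system(list(kind = "harmonic", k = k, s0 = 0.7),
                                 seed = 13)
  res <- run_toy_metadynamics(sys, nsteps = 4e5, metad = metad_config())
  p <- res$profile
  good <- which(p$count > 3000)
  expect_gt(length(good), 5)
  # per-bin standard error from the block decomposition
  for (i in good) {
    bs <- p$blocks$sum[i, ] / pmax(p$blocks$count[i, ], 1)
    bs <- bs[p$blocks$count[i, ] > 100]
    if (length(bs) < 3) next
    se <- sd(bs) / sqrt(length(bs))
    expect_lt(abs(p$force[i] - (-k * (p$s[i] - 0.7))), 3 * se + 3)
  }
})

test_that("PMF integration of exact mean forces recovers closed forms", {
  # all-zero force: W identically zero
  s <- seq(0.05, 1.55, 0.025)
  prof <- mean_force_profile(s, rep(100, length(s)), rep(0, length(s)))
  expect_true(all(integrate_pmf(prof, bulk_fraction = 0)$W == 0))

  # harmonic: F = -k(s - s0) integrates back to k/2 (s-s0)^2 + const
  k <- 200
  f <- -k * (s - 0.8)
  prof2 <- mean_force_profile(s, rep(100, length(s)), f)
  pmf <- integrate_pmf(prof2, bulk_fraction = 0)
  wex <- 0.5 * k * (s - 0.8)^2
  wex <- wex - wex[length(s)]
  expect_equal(pmf$W, wex, tolerance = 1e-10)  # trapezoid exact for linear F

  # Richardson check: doubling resolution changes W by less than the
  # coarse-grid trapezoid error bound for a curved force
  s1 <- seq(0.1, 1.1, 0.05)
  s2 <- seq(0.1, 1.1, 0.025)
  fc <- function(x) -exp(-x) * 50
  w1 <- integrate_pmf(mean_force_profile(s1, rep(10, length(s1)), fc(s1)),
                      bulk_fraction = 0)
  w2 <- integrate_pmf(mean_force_profile(s2, rep(10, length(s2)), fc(s2)),
                      bulk_fraction = 0)
  wi <- approx(w2$s, w2$W, xout = w1$s)$y
  h <- 0.05
  bound <- 50 * h^2 / 12 * (1.1 - 0.1)   # (b-a) h^2 max|f''|/12
  expect_lt(max(abs(w1$W - wi)), bound)
})

test_that("empty interior bins are bridged up to the gap limit, then rejected", {
  s <- seq(0.1, 1.0, 0.05)
  cnt <- rep(50, length(s))
  f <- -100 * (s - 0.6)
  cnt[8:9] <- 0
  f[8:9] <- NA
  prof <- mean_force_profile(s, cnt, f)
  pmf <- integrate_pmf(prof, bulk_fraction = 0)
  expect_equal(attr(pmf, "bridged"), c(8, 9))
  # linear interpolation across the gap is exact for a linear force
  wex <- 50 * (s - 0.6)^2
  expect_equal(pmf$W, wex - wex[length(s)], tolerance = 1e-10)

  cnt[8:10] <- 0
  f[8:10] <- NA
  expect_error(integrate_pmf(mean_force_profile(s, cnt, f)), "unconverged")
})

test_that("metadynamics runs are reproducible under a fixed seed", {
  sys <- make_toy_surface_system(list(kind = "double-well", barrier = 4,
                                      center = 0.6, half_width = 0.2),
                                 seed = 31)
  r1 <- run_toy_metadynamics(sys, nsteps = 20000)
  r2 <- run_toy_metadynamics(sys, nsteps = 20000)
  expect_identical(r1$cv, r2$cv)
  expect_identical(r1$hills, r2$hills)
  expect_identical(r1$profile$force, r2$profile$force)
})
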