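test_that("Boltzmann inversion inverts exactly sampled densities", {
  s <- seq(0.1, 1.5, 0.02)
  # uniform density: W identically zero
  p0 <- pmf_from_density(rep(500, length(s)), s, 300, bulk_window = c(1, 1.5))
  expect_true(all(p0$W == 0))

  # rho proportional to exp(-U/kBT): W = U - U(bulk) to machine precision
  U <- 3 * sin(4 * s) * exp(-s)
  rho <- exp(-U / kT300)
  p1 <- pmf_from_density(rho, s, 300, bulk_window = c(1.4, 1.5))
  ub <- mean(rho[s >= 1.4])
  expect_equal(p1$W, U + kT300 * log(ub), tolerance = 1e-10)

  # normalisation invariance
  p7 <- pmf_from_density(7 * rho, s, 300, bulk_window = c(1.4, 1.5))
  expect_equal(p7$W, p1$W, tolerance = 1e-12)

  # empty bins flagged as NA, never infinite
  cnt <- rep(100, length(s)); cnt[5] <- 0
  p2 <- pmf_from_density(cnt, s, 300, bulk_window = c(1, 1.5))
  expect_true(is.na(p2$W[5]))
  expect_true(all(is.finite(p2$W[-5])))
  expect_error(pmf_from_density(cnt, s, 300, bulk_window = c(2, 3)),
               "bulk")
})

test_that("binding-region detection classifies the constructed geometries", {
  # square well -5 kJ/mol on [0.3, 0.6): direct binding, rc 0.3, delta 0.3
  pmf <- square_well_pmf(depth = 5, lo = 0.3, hi = 0.6)
  reg <- find_binding_region(pmf)
  expect_equal(reg$mode, "direct")
  expect_equal(reg$rc, 0.3)
  expect_equal(reg$delta, 0.3)

  # single smooth minimum at 0.55 nm, depth -3: water-mediated
  s <- seq(0.3, 1.2, 0.005)
  W <- -3 * exp(-(s - 0.55)^2 / (2 * 0.05^2))
  reg2 <- find_binding_region(pmf_curve(s, W))
  expect_equal(reg2$mode, "water-mediated")
  expect_equal(reg2$minima$position[which.min(reg2$minima$depth)], 0.55,
               tolerance = 0.01)

  # flat PMF: no binding
  reg3 <- find_binding_region(pmf_curve(s, rep(0, length(s))))
  expect_equal(reg3$mode, "none")
  expect_true(is.na(reg3$delta))

  # monotone decreasing toward contact with no crossing back: mode none
  reg4 <- find_binding_region(pmf_curve(s, 5 * (1.2 - s)))
  expect_equal(reg4$mode, "none")
})

test_that("layer-averaged adsorption free energy has its closed forms", {
  # constant W = -5 across the whole layer [0.3, 0.6]: dG = -5 exactly
  pmf <- square_well_pmf(depth = 5, lo = 0.3, hi = 0.6, closed = TRUE)
  reg <- structure(list(rc = 0.3, delta = 0.3, mode = "direct"),
                   class = "binding_region")
  ans <- adsorption_free_energy(pmf, reg)
  expect_equal(ans$dG, -5, tolerance = 1e-9)

  # flat PMF: dG = 0 with mode none, never an error
  flat <- pmf_curve(seq(0.3, 1, 0.005), rep(0, 141))
  ans0 <- adsorption_free_energy(flat)
  expect_equal(ans0$dG, 0)
  expect_equal(ans0$region$mode, "none")

  # two-level layer: half at -kBT log 2, half at 0 -> dG = -kBT log 1.5
  s <- seq(0.3, 1.2, 0.0005)
  W <- ifelse(s < 0.45, -kT300 * log(2), ifelse(s < 0.6, -1e-9, 0))
  pmf2 <- pmf_curve(s, W, temperature = 300)
  reg2 <- list(rc = 0.3, delta = 0.3, mode = "direct")
  ans2 <- adsorption_free_energy(pmf2, structure(reg2, class = "binding_region"))
  expect_equal(ans2$dG, -kT300 * log(1.5), tolerance = 1e-2)
})

test_that("standard-state shift is the analytic concentration term and invertible", {
  pmf <- square_well_pmf()
  ans <- adsorption_free_energy(pmf, find_binding_region(pmf))
  same <- standard_state_shift(ans, 1, 1)
  expect_equal(same$dG, ans$dG)
  shifted <- standard_state_shift(ans, 10, 1, temperature = 300)
  expect_equal(shifted$dG - ans$dG, 8.314462618e-3 * 300 * log(10),
               tolerance = 1e-10)
  expect_equal(shifted$dG - ans$dG, 5.743, tolerance = 1e-3)
  back <- standard_state_shift(shifted, 1, 10, temperature = 300)
  expect_equal(back$dG, ans$dG, tolerance = 1e-12)
  expect_error(standard_state_shift(ans, -1, 1), "concentration")
})

test_that("block error follows the standard-error law on iid samples", {
  # constant series: zero error
  const <- data.frame(time = seq(0, 99), x = rep(3, 100))
  be <- block_error(const, 10, function(b) mean(b$x))
  expect_equal(be$error, 0)
  expect_equal(be$n_blocks, 9)

  # iid Gaussian, estimator = mean: error ~ sigma/sqrt(N)
  set.seed(4)
  n <- 20000; sigma <- 2
  samp <- data.frame(time = seq_len(n) - 1, x = rnorm(n, 0, sigma))
  be2 <- block_error(samp, 1000, function(b) mean(b$x))
  expect_lt(abs(be2$error - sigma / sqrt(n)) / (sigma / sqrt(n)), 0.9)

  # fewer than two complete blocks is an error
  expect_error(block_error(const, 60, function(b) mean(b$x)), "insufficient")
})

test_that("dG is monotone under pointwise deepening of the PMF", {
  set.seed(12)
  s <- seq(0.25, 1.2, 0.01)
  for (k in 1:10) {
    base <- -runif(1, 1, 6) * exp(-(s - runif(1, 0.35, 0.6))^2 / 0.01)
    pmf1 <- pmf_curve(s, base)
    pmf2 <- pmf_curve(s, base - runif(length(s), 0, 0.5) *
                           (s < 0.7))   # deepen only the bound region
    r1 <- find_binding_region(pmf1)
    if (r1$mode == "none") next
    d1 <- adsorption_free_energy(pmf1, r1)$dG
    d2 <- adsorption_free_energy(pmf2, r1)$dG
    expect_lte(d2, d1 + 1e-12)
  }
})

test_that("dG is stable under grid refinement on smooth fixtures", {
  for (ds in c(0.01, 0.005)) {
    s <- seq(0.25, 1.2, ds)
    W <- -4 * exp(-(s - 0.45)^2 / (2 * 0.07^2))
    pmf <- pmf_curve(s, W)
    d <- adsorption_free_energy(pmf, find_binding_region(pmf))$dG
    if (ds == 0.01) d_coarse <- d else d_fine <- d
  }
  expect_lt(abs(d_coarse - d_fine), 0.05)
})
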