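test_that("total pair potential is the sum of its closed-form terms", {
  # pure Coulomb between +2e and -2e at 10 A: kC * 4 / 10
  b0 <- buckingham_params(A = 0, rho = 1, C6 = 0)
  expect_equal(pair_total_potential(10, b0, 2, -2), -555.74, tolerance = 1e-6)
  # pure exponential when charges and dispersion vanish
  b <- buckingham_params(A = 1000, rho = 0.3, C6 = 0)
  r <- c(2, 2.5, 3)
  expect_equal(pair_total_potential(r, b, 0, 0), 1000 * exp(-r / 0.3))
  # additivity of the three terms
  b2 <- buckingham_params(A = 1234, rho = 0.25, C6 = 500)
  expect_equal(pair_total_potential(r, b2, 2, -2),
               1234 * exp(-r / 0.25) - 500 / r^6 - 4 * 1389.35 / r)
  expect_error(pair_total_potential(0, b2, 1, 1), "singular")
})

test_that("harmonic bond fit recovers itself and matches the grid oracle", {
  # self-fit
  f <- function(r) 7 + 0.5 * 350 * (r - 2.31)^2
  fit <- fit_harmonic_bond(f, 2.0, 2.5)
  expect_equal(fit$kb, 350, tolerance = 1e-6)
  expect_equal(fit$r0, 2.31, tolerance = 1e-6)
  expect_lt(fit$residual, 1e-8)

  # Coulomb-plus-repulsion pair curve over the bond window vs the
  # independent normal-equations oracle (coded in the test helper, not lm)
  g <- function(r) -4 * 1389.35 / r + 5e5 * exp(-r / 0.25)
  fit2 <- fit_harmonic_bond(g, 2.0, 2.5)
  or <- quad_fit_oracle(g, 2.0, 2.5)
  expect_equal(fit2$kb, unname(or$k), tolerance = 1e-6)
  expect_equal(fit2$r0, unname(or$x0), tolerance = 1e-6)

  # a concave window (e.g. bare attractive Coulomb) is rejected
  expect_error(fit_harmonic_bond(function(r) -4 * 1389.35 / r, 2, 2.5),
               "curvature")
})

test_that("harmonic angle fit matches the second-order expansion of a cosine form", {
  th0 <- 109.47
  kprime <- 40
  f <- function(th_deg) kprime * (cos(th_deg * pi / 180) - cos(th0 * pi / 180))^2
  fit <- fit_harmonic_angle(f, th0 + c(-2, 2))
  expect_equal(fit$theta0, th0, tolerance = 1e-3)
  expect_equal(fit$k_theta, 2 * kprime * sin(th0 * pi / 180)^2,
               tolerance = 1e-2)
  or <- quad_fit_oracle(function(td) f(td * 1), th0 - 2, th0 + 2)
  # oracle works in degrees; convert curvature to rad^-2
  expect_equal(fit$k_theta, unname(or$k) * (180 / pi)^2, tolerance = 1e-6)
  # self-fit
  h <- function(th_deg) 0.5 * 274.022 * (th_deg * pi / 180 - th0 * pi / 180)^2
  fit2 <- fit_harmonic_angle(h, c(95, 125))
  expect_equal(fit2$k_theta, 274.022, tolerance = 1e-6)
  expect_equal(fit2$theta0, th0, tolerance = 1e-6)
})

test_that("Lorentz-Berthelot mixing and special-pair overrides", {
  zn <- list(species = "Zn", sigma = 3.816, epsilon = 0.022)
  s <- list(species = "S", sigma = 4.27, epsilon = 1.087)
  m <- lorentz_berthelot(zn, s)
  expect_equal(m$sigma, 4.043)
  expect_equal(m$epsilon, 0.15464, tolerance = 1e-4)
  # idempotence
  m2 <- lorentz_berthelot(zn, zn)
  expect_equal(m2$sigma, zn$sigma)
  expect_equal(m2$epsilon, zn$epsilon)
  # override takes precedence, symmetric in the key
  sp <- default_zns_forcefield()$special_pairs
  oc <- list(species = "OC", sigma = 3.0, epsilon = 0.88)
  ov <- lorentz_berthelot(zn, oc, sp)
  expect_true(ov$special)
  expect_equal(ov$sigma, 1.75)
  expect_equal(ov$epsilon, 86.00)
  expect_equal(lorentz_berthelot(oc, zn, sp)$sigma, 1.75)
})

test_that("packaged ZnS parameter set carries the published constants", {
  ff <- default_zns_forcefield()
  expect_equal(ff$bonds$kb * 100, 92000)   # default reading kJ/mol/nm^2
  expect_equal(ff$bonds$r0, 1.6)
  expect_equal(default_zns_forcefield(kb_units = "kJ/mol/A2")$bonds$kb, 92000)
  expect_equal(ff$angles$k, rep(274.022, 2))
  expect_equal(ff$angles$theta0, rep(109.47, 2))
  sp <- ff$species
  expect_equal(sp$q[sp$name == "Zn"], 2)
  expect_equal(sp$q[sp$name == "S"], -2)
  expect_equal(ff$cutoff, 1.4)
})

test_that("energy evaluation honours exclusions and closed forms", {
  # bonded dimer at r0: zero bond energy/forces, non-bonded fully excluded
  td <- toy_dimer(r = 2.0, kb = 500, r0 = 2.0)
  td$ff$species$q <- c(2, -2)   # would interact strongly if not excluded
  td$structure$charge <- c(2, -2)
  ev <- evaluate_energy_forces(td$structure, td$ff)
  expect_equal(ev$energy, 0, tolerance = 1e-12)
  expect_equal(max(abs(ev$forces)), 0, tolerance = 1e-10)
  expect_equal(unname(ev$breakdown[c("lj", "coulomb")]), c(0, 0))

  # two non-bonded +-2e charges 1 nm apart, plain Coulomb: -555.74 kJ/mol
  cp <- charged_pair(r = 10, coulomb = "plain", cutoff = 5)
  ev2 <- evaluate_energy_forces(cp$structure, cp$ff)
  expect_equal(ev2$energy, -555.74, tolerance = 1e-4)
  expect_equal(unname(ev2$breakdown["coulomb"]), -555.74, tolerance = 1e-4)
})

test_that("forces are the exact negative gradient of the implemented energy", {
  set.seed(42)
  slab <- derive_topology(build_slab_110(lattice_spec(5.41), 2, 2, 4), 2.9)
  slab$xyz <- slab$xyz + matrix(rnorm(length(slab$xyz), 0, 0.05), ncol = 3)
  ff <- default_zns_forcefield(cutoff = 0.5)
  ev <- evaluate_energy_forces(slab, ff)
  h <- 1e-5
  for (i in sample(n_atoms(slab), 4)) {
    for (cc in 1:3) {
      xp <- slab; xp$xyz[i, cc] <- xp$xyz[i, cc] + h
      xm <- slab; xm$xyz[i, cc] <- xm$xyz[i, cc] - h
      fnum <- -(evaluate_energy_forces(xp, ff)$energy -
                evaluate_energy_forces(xm, ff)$energy) / (2 * h)
      expect_equal(ev$forces[i, cc], fnum,
                   tolerance = 1e-4 * max(1, abs(fnum)))
    }
  }
  # translational invariance: zero net force
  expect_lt(max(abs(colSums(ev$forces))), 1e-8)
})

test_that("energy is invariant under rigid rotation of a non-periodic system", {
  np <- derive_topology(build_nanoparticle(lattice_spec(5.41), 14), 2.9)
  ff <- default_zns_forcefield(cutoff = 1.0)
  e0 <- evaluate_energy_forces(np, ff)$energy
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- np
  rot$xyz <- np$xyz %*% t(R)
  e1 <- evaluate_energy_forces(rot, ff)$energy
  expect_equal(e1, e0, tolerance = 1e-8 * abs(e0))
})

test_that("unparameterized species and overlapping atoms are rejected", {
  st <- nanostructure(c("Zn", "Xx"), rbind(c(0, 0, 0), c(0, 0, 3)),
                      box = c(30, 30, 30))
  expect_error(evaluate_energy_forces(st, default_zns_forcefield(cutoff = 0.5)),
               "unparameterized")
  cp <- charged_pair(r = 1e-8)
  expect_error(evaluate_energy_forces(cp$structure, cp$ff), "overlap")
})

test_that("force-field table files round-trip losslessly", {
  ff <- default_zns_forcefield()
  f <- tempfile(fileext = ".yml")
  write_forcefield(ff, f)
  ff2 <- read_forcefield(f)
  expect_equal(ff2$species, ff$species)
  expect_equal(ff2$bonds, ff$bonds)
  expect_equal(ff2$angles, ff$angles)
  expect_equal(ff2$special_pairs, ff$special_pairs)
  expect_equal(ff2$cutoff, ff$cutoff)
  expect_equal(ff2$exclusion, ff$exclusion)
  expect_equal(ff2$coulomb, ff$coulomb)
})
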