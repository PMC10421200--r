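test_that("steepest descent converges a displaced bonded dimer to its minimum", {
  td <- toy_dimer(r = 2.3, kb = 500, r0 = 2.0)
  mn <- minimize(td$structure, td$ff, max_steps = 2000, force_tol = 1e-6,
                 init_step = 0.05)
  r_final <- sqrt(sum((mn$xyz[2, ] - mn$xyz[1, ])^2))
  expect_lt(abs(r_final - 2.0), 1e-4)
  # line-search contract: energy sequence non-increasing
  expect_true(all(diff(attr(mn, "energy_trace")) <= 1e-12))
})

test_that("a jittered cell minimises below the force tolerance", {
  set.seed(1)
  cell <- derive_topology(build_unit_cell(lattice_spec(5.41)), 2.9)
  cell$xyz <- cell$xyz + matrix(rnorm(24, 0, 0.1), ncol = 3)
  ff <- default_zns_forcefield(cutoff = 0.25)
  mn <- minimize(cell, ff, max_steps = 4500, force_tol = 1)
  expect_lt(attr(mn, "max_force"), 1)
  expect_lte(attr(mn, "energy"), evaluate_energy_forces(cell, ff)$energy)
})

test_that("thermostat-free integration conserves energy (NVE limit)", {
  td <- toy_dimer(r = 2.2, kb = 100, r0 = 2.0)
  cfg <- run_config(timestep = 0.5, nsteps = 10000, temperature = 0,
                    thermostat = "none", seed = 1, stride = 5000,
                    log_stride = 100)
  tr <- run_md(td$structure, td$ff, cfg)
  etot <- tr$elog$E_pot + tr$elog$E_kin
  # symplectic integrator: bounded oscillation, no secular drift
  expect_lt(max(abs(etot - etot[1])) / max(abs(etot[1]), kT300), 1e-4)
  half <- length(etot) %/% 2
  expect_lt(abs(mean(etot[seq_len(half)]) - mean(etot[-seq_len(half)])) /
              abs(etot[1]), 1e-5)
})

test_that("Langevin dynamics reproduces the target temperature", {
  td <- toy_dimer(r = 2.0, kb = 100, r0 = 2.0)
  cfg <- run_config(timestep = 1, nsteps = 200000, temperature = 300,
                    thermostat = "langevin", friction = 10, seed = 3,
                    stride = 1e5, log_stride = 50)
  tr <- run_md(td$structure, td$ff, cfg)
  temps <- tr$elog$T[tr$elog$step > 20000]
  # 6 DOF: instantaneous T fluctuates ~ sqrt(2/ndof); average over log
  se <- sd(temps) / sqrt(length(temps) / 20)   # crude correlation allowance
  expect_lt(abs(mean(temps) - 300), 3 * se + 15)
})

test_that("identical seeds give bit-identical trajectories", {
  td <- toy_dimer()
  cfg <- run_config(timestep = 1, nsteps = 2000, temperature = 300,
                    thermostat = "langevin", seed = 7, stride = 200)
  t1 <- run_md(td$structure, td$ff, cfg)
  t2 <- run_md(td$structure, td$ff, cfg)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$elog, t2$elog)
  # different seed diverges
  cfg$seed <- 8L
  t3 <- run_md(td$structure, td$ff, cfg)
  expect_false(identical(t1$frames, t3$frames))
})

test_that("frozen atoms do not move", {
  td <- toy_dimer()
  cfg <- run_config(timestep = 1, nsteps = 1000, temperature = 300,
                    thermostat = "langevin", seed = 2, stride = 100,
                    frozen = 1)
  tr <- run_md(td$structure, td$ff, cfg)
  first_atom <- t(vapply(tr$frames, function(f) f[1, ], numeric(3)))
  expect_true(all(first_atom[, 1] == first_atom[1, 1]))
  expect_true(all(abs(sweep(first_atom, 2, first_atom[1, ])) == 0))
})

test_that("RMSD series has its closed-form values", {
  slab <- build_slab_110(lattice_spec(5.41), 2, 2, 2)
  n <- n_atoms(slab)
  # repeated reference: all zeros
  tr <- trajectory(list(slab$xyz, slab$xyz), c(0, 1), slab$species,
                   slab$box, slab$periodic)
  expect_equal(rmsd_series(tr, slab)$rmsd, c(0, 0), tolerance = 1e-12)
  # rigid translation is removed by superposition (and by centring alone)
  shifted <- slab$xyz + matrix(rep(c(1, -2, 3), each = n), ncol = 3)
  tr2 <- trajectory(list(shifted), 0, slab$species, slab$box, slab$periodic)
  expect_equal(rmsd_series(tr2, slab, superpose = TRUE)$rmsd, 0,
               tolerance = 1e-10)
  # one atom displaced by d, no superposition beyond centring:
  # closed form sqrt(d^2/N) after removing the induced COM shift
  d <- 0.9
  disp <- slab$xyz
  disp[5, 3] <- disp[5, 3] + d
  tr3 <- trajectory(list(disp), 0, slab$species, slab$box, slab$periodic)
  got <- rmsd_series(tr3, slab, superpose = FALSE)$rmsd
  expect_equal(got, sqrt(d^2 / n * (1 - 1 / n)), tolerance = 1e-10)
})

test_that("optimal-superposition RMSD agrees with the bio3d reference", {
  set.seed(11)
  slab <- build_slab_110(lattice_spec(5.41), 2, 2, 2)
  jit <- slab$xyz + matrix(rnorm(length(slab$xyz), 0, 0.3), ncol = 3)
  th <- 0.4
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rotated <- jit %*% t(R) + 5
  tr <- trajectory(list(rotated), 0, slab$species, slab$box, slab$periodic)
  mine <- rmsd_series(tr, slab, superpose = TRUE)$rmsd
  ref <- bio3d::rmsd(as.vector(t(slab$xyz)), as.vector(t(rotated)),
                     fit = TRUE)
  expect_equal(mine, ref, tolerance = 1e-3)
})

test_that("trajectory invariants are enforced", {
  expect_error(trajectory(list(matrix(0, 2, 3)), c(0, 1), c("A", "A"),
                          rep(10, 3), rep(FALSE, 3)), "mismatch")
  expect_error(trajectory(list(matrix(0, 2, 3), matrix(0, 2, 3)), c(1, 1),
                          c("A", "A"), rep(10, 3), rep(FALSE, 3)),
               "increasing")
  expect_error(trajectory(list(matrix(0, 2, 3), matrix(0, 3, 3)), c(0, 1),
                          c("A", "A"), rep(10, 3), rep(FALSE, 3)),
               "atom count")
})
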