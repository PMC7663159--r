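# synthetic energy model: closed forms, force consistency, invariances,
# analytic fixtures

test_that("harmonic bond energies are exact", {
  topo <- finalize_topology(
    toy_topology(bonds = data.frame(i = 1L, j = 2L, k = 500, r0 = 1)))
  at_min <- rbind(c(0, 0, 0), c(1, 0, 0))
  ef <- energy_and_forces(topo, at_min)
  expect_equal(ef$energy, 0)
  expect_equal(max(abs(ef$forces)), 0)
  stretched <- rbind(c(0, 0, 0), c(1.2, 0, 0))
  expect_equal(energy_and_forces(topo, stretched)$energy,
               0.5 * 500 * 0.2^2, tolerance = 1e-10)
})

test_that("forces equal the negative finite-difference gradient everywhere", {
  fx <- random_toy()
  expect_lt(max_fd_force_error(fx$topology, fx$conf$pos), 1e-5)
  # and in a squeezed geometry where LJ/Coulomb switching is active
  expect_lt(max_fd_force_error(fx$topology, fx$conf$pos * 0.7), 1e-5)
})

test_that("energy is invariant under rigid translation and rotation", {
  fx <- random_toy(seed = 11, restraint = FALSE)
  e0 <- energy_and_forces(fx$topology, fx$conf$pos)$energy
  for (rep in 1:3) {
    moved <- rigid_motion(fx$conf$pos, angle = 0.3 * rep,
                          axis = c(rep, 1, 2), shift = c(-rep, 4, 0.5))
    expect_equal(energy_and_forces(fx$topology, moved)$energy, e0,
                 tolerance = 1e-9)
  }
})

test_that("coincident interacting atoms are rejected", {
  topo <- finalize_topology(toy_topology(
    lj = data.frame(i = 1L, j = 2L, eps = 1, sigma = 3, wca = FALSE)))
  expect_error(energy_and_forces(topo, rbind(c(0, 0, 0), c(0, 0, 0))),
               "singular")
})

test_that("harmonic dimer fixture has the advertised closed forms", {
  fx <- make_harmonic_dimer(500, 1.0, masses = c(14.007, 1.008))
  expect_equal(reduced_mass(fx$conf$mass[1], fx$conf$mass[2]), 0.94033,
               tolerance = 1e-5)
  expect_equal(energy_and_forces(fx$topology, fx$conf)$energy, 0)
  p <- fx$conf$pos; p[2, 1] <- 1.2
  expect_equal(energy_and_forces(fx$topology, p)$energy, 10.0,
               tolerance = 1e-12)
})

test_that("bistable Hg fixture: degenerate symmetric wells, depth-split minima", {
  fs <- make_bistable_hg_pair(12, 12)
  ms <- bistable_minima(fs)
  expect_lt(abs(ms$delta), 1e-6)

  # spec'd asymmetry: minimum split equals the depth difference
  fb <- make_bistable_hg_pair(100, 90)
  mb <- bistable_minima(fb)
  expect_equal(mb$delta, 10, tolerance = 0.5)
  expect_true(mb$E_NO < mb$E_NN)

  fb2 <- make_bistable_hg_pair(17, 7)
  mb2 <- bistable_minima(fb2)
  expect_equal(mb2$delta, 10, tolerance = 0.5)
  # quadrature reference behaves like a Boltzmann factor of that split
  r <- bistable_occupancy_ref(fb2, 300, n = 101)
  expect_lt(r$ratio, 0.12)
  expect_gt(r$ratio, exp(-mb2$delta / (0.0083144621 * 300)) / 2)
})

test_that("Langevin sampling of the bistable well is canonical (occupancy ratio)", {
  # moderate-length run; the acceptance suite runs the long version
  fx <- make_bistable_hg_pair(12, 12)
  conf <- maxwell_boltzmann(fx$conf, 300, seed = 3)
  res <- run_nvt(fx$topology, conf, steps = 150000, dt = 4,
                 thermostat = langevin_thermostat(0.01),
                 temperature = 300, stride = 50, seed = 7)
  smap <- parse_site_labels(fx$conf$label, fx$conf$element)
  pt <- pattern_timeseries(res$frames, smap, dist_cutoff = 3.0,
                          debounce = 1)
  n_no <- sum(pt$labels == "NO"); n_nn <- sum(pt$labels == "NN")
  expect_gt(pt$transitions, 10)          # both basins visited
  p <- n_no / (n_no + n_nn)
  # binomial-style bound with the visit count as the effective sample size
  r <- rle(pt$labels[pt$labels %in% c("NO", "NN")])
  neff <- length(r$lengths)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / neff) + 0.02)
})

test_that("topology serialization round-trips and solvent particles attach", {
  fx <- random_toy()
  f <- tempfile(fileext = ".yml")
  write_topology(fx$topology, f)
  t2 <- read_topology(f)
  expect_equal(t2$bonds, fx$topology$bonds)
  expect_equal(t2$hbonds$depth, fx$topology$hbonds$depth)
  expect_equal(energy_and_forces(t2, fx$conf$pos)$energy,
               energy_and_forces(fx$topology, fx$conf$pos)$energy)
  unlink(f)

  ws <- add_solvent(fx$topology, fx$conf, n = 12, seed = 3)
  expect_equal(n_atoms(ws$conf), n_atoms(fx$conf) + 12L)
  ef <- energy_and_forces(ws$topology, ws$conf)
  expect_true(is.finite(ef$energy))
  # solvent placement respects the exclusion shell
  solpos <- ws$conf$pos[11:22, , drop = FALSE]
  for (k in seq_len(12)) {
    d2 <- rowSums(sweep(fx$conf$pos, 2, solpos[k, ])^2)
    expect_gte(min(d2), 2.8^2)
  }
  # deterministic under the seed
  ws2 <- add_solvent(fx$topology, fx$conf, n = 12, seed = 3)
  expect_identical(ws$conf$pos, ws2$conf$pos)
})
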