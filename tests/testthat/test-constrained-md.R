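# constrained velocity-Verlet engine: SHAKE/RATTLE, thermostats,
# annealing, zip-up

test_that("constrained stationary dimer has zero multiplier; stretched gives k*delta", {
  fx <- make_harmonic_dimer(500, 1.0)
  spec <- dd_spec(cbind(1, 2), fx$conf$mass)
  res0 <- run_nvt(fx$topology, fx$conf, steps = 50, dt = 0.5,
                  thermostat = NULL, spec = spec, target = 1.0)
  expect_lt(max(abs(res0$trace$lambda)), 1e-9)

  conf <- project_to_constraint(fx$conf, spec, 1.2)
  res <- run_nvt(fx$topology, conf, steps = 500, dt = 0.5,
                 thermostat = NULL, spec = spec, target = 1.2)
  # static force balance at T -> 0: |<F>| = k * 0.2
  expect_equal(mean(res$trace$lambda), 100, tolerance = 1e-6)
})

test_that("constraint and velocity condition hold at every step of an NVE run", {
  ch <- chain10()
  target <- dynamic_distance(ch$spec, ch$conf)
  conf <- maxwell_boltzmann(ch$conf, 80, seed = 12)
  conf <- project_to_constraint(conf, ch$spec, target)
  res <- run_nvt(ch$topology, conf, steps = 1000, dt = 0.5,
                 thermostat = NULL, spec = ch$spec, target = target)
  expect_lte(max(abs(res$trace$D - target)), 1e-8)
  # RATTLE: dD/dt = 0 after the final step
  g <- dynamic_distance_gradient(ch$spec, res$conf$pos)
  expect_lte(abs(sum(g * res$conf$vel)), 1e-10)
  # energy conserved under the constraint
  drift <- unname(coef(stats::lm(res$trace$E_conserved ~
                                   res$trace$time))[2]) * 1000
  expect_lt(abs(drift), 1e-4)
})

test_that("unconstrained NVE conserves energy at dt = 0.5 fs", {
  fx <- make_harmonic_dimer(500, 1.0)
  conf <- maxwell_boltzmann(fx$conf, 300, seed = 42)
  res <- run_nvt(fx$topology, conf, steps = 20000, dt = 0.5,
                 thermostat = NULL)
  drift <- unname(coef(stats::lm(res$trace$E_conserved ~
                                   res$trace$time))[2]) * 1000
  expect_lt(abs(drift), 1e-4)   # kJ/mol per ps
})

test_that("Nose-Hoover chain equilibrates the dimer to the target temperature", {
  fx <- make_harmonic_dimer(500, 1.0)
  conf <- maxwell_boltzmann(fx$conf, 300, seed = 1)
  res <- run_nvt(fx$topology, conf, steps = 60000, dt = 0.5,
                 thermostat = nose_hoover_chain(3, 1000),
                 temperature = 300)
  Ts <- res$trace$temperature[10001:60000]
  blocks <- split(Ts, cut(seq_along(Ts), 10, labels = FALSE))
  bm <- vapply(blocks, mean, numeric(1))
  se <- stats::sd(bm) / sqrt(length(bm))
  expect_lt(abs(mean(Ts) - 300), 3 * se + 15)
  # conserved quantity of the extended system drifts very slowly
  drift <- unname(coef(stats::lm(res$trace$E_conserved ~
                                   res$trace$time))[2]) * 1000
  expect_lt(abs(drift), 1e-3)
})

test_that("seeded runs are bit-reproducible", {
  fx <- make_harmonic_dimer(300, 1.2)
  conf <- maxwell_boltzmann(fx$conf, 250, seed = 5)
  r1 <- run_nvt(fx$topology, conf, steps = 500, dt = 0.5,
                thermostat = langevin_thermostat(0.01),
                temperature = 250, seed = 31)
  r2 <- run_nvt(fx$topology, conf, steps = 500, dt = 0.5,
                thermostat = langevin_thermostat(0.01),
                temperature = 250, seed = 31)
  expect_identical(r1$conf$pos, r2$conf$pos)
  expect_identical(r1$trace$E_pot, r2$trace$E_pot)
})

test_that("annealing schedule follows start_T * factor^rescales", {
  expect_equal(anneal_schedule(300, 0.99, 30000, 100), 300 * 0.99^300)
  expect_equal(anneal_schedule(300, 0.99, 0, 100), 300)
  expect_equal(anneal_schedule(300, 1.0, 12345, 100), 300)

  ch <- chain10()
  conf <- maxwell_boltzmann(ch$conf, 300, seed = 2)
  r <- anneal(ch$topology, conf, start_T = 300, factor = 0.99,
              steps = 400, rescale_every = 100, dt = 0.5)
  expect_equal(r$final_T, 300 * 0.99^4)
  r0 <- anneal(ch$topology, conf, start_T = 300, factor = 0.99,
               steps = 0)
  expect_identical(r0$conf, conf)
  expect_equal(r0$final_T, 300)
  expect_error(anneal(ch$topology, conf, factor = 1.01), "factor")
})

test_that("zip-up ramps the target linearly and hits the endpoint", {
  sched <- zip_schedule(1.88, 1.56, 10000)
  expect_equal(sched(0), 1.88)
  expect_equal(sched(5000), 1.72)
  expect_equal(sched(10000), 1.56)

  # short ramp on the ten-atom chain (the full duplex protocol runs in
  # the acceptance suite)
  ch <- chain10()
  d0 <- dynamic_distance(ch$spec, ch$conf)
  conf <- maxwell_boltzmann(ch$conf, 100, seed = 9)
  z <- zip_up(ch$topology, conf, ch$spec, D_start = d0,
              D_end = d0 - 0.3, steps = 400, dt = 0.5,
              thermostat = nose_hoover_chain(), temperature = 100,
              seed = 4)
  expect_equal(z$trace$D[400], d0 - 0.3, tolerance = 1e-8)

  expect_error(zip_up(ch$topology, conf, ch$spec, D_start = 1,
                      D_end = 2, steps = 10), "D_start >= D_end")
  expect_error(zip_up(ch$topology, conf, ch$spec, D_start = d0 + 1,
                      D_end = d0, steps = 10), "ramp undefined")
})

test_that("step API enforces the entry constraint and records multipliers", {
  fx <- make_harmonic_dimer(500, 1.0)
  spec <- dd_spec(cbind(1, 2), fx$conf$mass)
  cs <- constraint_state(1.2)
  expect_error(step_constrained(fx$topology, fx$conf, spec, cs),
               "project_to_constraint")
  conf <- project_to_constraint(fx$conf, spec, 1.2)
  st <- step_constrained(fx$topology, conf, spec, cs)
  st <- step_constrained(fx$topology, st$conf, spec, st$cstate)
  expect_length(st$cstate$lambda_trace, 2L)
  expect_equal(dynamic_distance(spec, st$conf), 1.2, tolerance = 1e-8)

  expect_error(run_nvt(fx$topology, fx$conf, steps = 0), ">= 1")
})

test_that("a numerically exploding run aborts with the last good frame", {
  # wildly unstable: stiff spring integrated far beyond its period
  topo <- finalize_topology(
    toy_topology(bonds = data.frame(i = 1L, j = 2L, k = 1e6, r0 = 1)))
  conf <- configuration(rbind(c(0, 0, 0), c(1.3, 0, 0)),
                        masses = c(1.008, 1.008), elements = c("H", "H"))
  expect_warning(res <- run_nvt(topo, conf, steps = 200, dt = 10,
                                thermostat = NULL),
                 "aborted at step")
  expect_false(is.null(res$aborted))
  expect_lt(nrow(res$trace), 200L)
  expect_true(all(is.finite(res$conf$pos)))
})
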