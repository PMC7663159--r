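# mean force estimation, trapezoidal integration, schedules, the dimer
# oracle, and a short TI consistency run

test_that("mean constraint force: constant, alternating, and AR(1) traces", {
  cst <- mean_constraint_force(rep(3.7, 100))
  expect_equal(cst$mean, 3.7)
  expect_identical(cst$stderr, 0)
  expect_true(cst$constant)

  alt <- mean_constraint_force(rep(c(2, -2), 500),
                               equilibration_fraction = 0)
  expect_lt(abs(alt$mean), 1e-12)

  # AR(1) with known mean, phi = 0.9
  set.seed(77)
  n <- 20000; mu <- 5; phi <- 0.9
  x <- numeric(n); x[1] <- mu
  eps <- rnorm(n, sd = 1)
  for (t in 2:n) x[t] <- mu + phi * (x[t - 1] - mu) + eps[t]
  st <- mean_constraint_force(x)
  expect_lt(abs(st$mean - mu), 3 * st$stderr)
  # running average converges to the mean
  expect_equal(st$running[length(st$running)], st$mean)

  expect_error(mean_constraint_force(1:5), "too short")
})

test_that("trapezoidal TI: rectangle, exact linear case, reversal, additivity", {
  D <- seq(3.0, 5.8, 0.2)
  prof <- ti_integrate(D, rep(40, length(D)))
  expect_equal(prof$delta_A[length(D)], 2.8 * 40)
  expect_equal(prof$delta_A[1], 0)

  # linear force: trapezoid is exact
  a <- 1.0; b <- 2.5; F0 <- -10; F1 <- 30
  Dg <- seq(a, b, length.out = 7)
  Fg <- F0 + (F1 - F0) * (Dg - a) / (b - a)
  prof2 <- ti_integrate(Dg, Fg)
  expect_equal(prof2$delta_A[7], (F0 + F1) * (b - a) / 2,
               tolerance = 1e-12)

  # reversing the window order negates the end-to-end difference
  prof3 <- ti_integrate(rev(Dg), rev(Fg))
  expect_equal(prof3$delta_A[7], -prof2$delta_A[7], tolerance = 1e-12)

  # additivity of consecutive sub-lists
  s1 <- ti_integrate(Dg[1:4], Fg[1:4])
  s2 <- ti_integrate(Dg[4:7], Fg[4:7])
  expect_equal(s1$delta_A[4] + s2$delta_A[4], prof2$delta_A[7],
               tolerance = 1e-12)

  expect_error(ti_integrate(c(1, 3, 2), c(1, 1, 1)), "monotone")
  expect_error(ti_integrate(1.5, 2), ">= 2")
})

test_that("schedule strings parse, including piecewise segments", {
  s <- parse_schedule("3.0:5.8:0.2")
  expect_length(s$points, 15L)
  p <- parse_schedule("2.5:3.5:0.1,3.5:8.5:0.5")
  expect_length(p$points, 21L)   # 11 + 10 (shared boundary not repeated)
  expect_equal(p$points[11:13], c(3.5, 4.0, 4.5))
  down <- parse_schedule("5.8:3.0:0.2")
  expect_length(down$points, 15L)
  expect_true(all(diff(down$points) < 0))
  expect_error(parse_schedule("3.0-5.8-0.2"), "malformed")
})

test_that("the closed-form dimer profile has the documented structure", {
  kT <- 0.0083144621 * 300
  or <- dimer_free_energy_oracle(500, 1.0, 300, seq(0.8, 1.4, 0.01))
  # asymmetry about r0 is the entropic 2 kT log term
  d <- 0.15
  a_plus <- dimer_free_energy_oracle(500, 1.0, 300, 1.0 + d, ref = 1.0)$A
  a_minus <- dimer_free_energy_oracle(500, 1.0, 300, 1.0 - d, ref = 1.0)$A
  expect_equal(a_minus - a_plus, 2 * kT * log((1 + d) / (1 - d)),
               tolerance = 1e-12)
  # mean_force is the derivative of A (numeric check)
  i <- 30
  num <- (or$A[i + 1] - or$A[i - 1]) / (or$r[i + 1] - or$r[i - 1])
  expect_equal(num, or$mean_force[i], tolerance = 1e-3)
  # T -> 0: profile reduces to the bare potential
  cold <- dimer_free_energy_oracle(500, 1.0, 1e-6, c(1.0, 1.3), ref = 1.0)
  expect_equal(cold$A[2], 0.5 * 500 * 0.3^2, tolerance = 1e-3)
})

test_that("a short TI run reproduces the oracle and a single window integrates to zero", {
  fx <- make_harmonic_dimer(500, 1.0)
  spec <- dd_spec(cbind(1, 2), fx$conf$mass)
  conf <- maxwell_boltzmann(fx$conf, 300, seed = 5)
  ti <- run_ti(fx$topology, conf, spec,
               window_schedule(seq(1.0, 1.4, 0.1), 4000, 0.25),
               dt = 0.5, thermostat = langevin_thermostat(0.01),
               temperature = 300, pre_steps = 500, seed = 17)
  or <- dimer_free_energy_oracle(500, 1.0, 300, ti$profile$D)
  expect_equal(ti$profile$delta_A[5], or$A[5], tolerance = 0.05 * or$A[5])
  expect_null(ti$failed)

  one <- run_ti(fx$topology, conf, spec, window_schedule(1.0, 200),
                dt = 0.5, thermostat = langevin_thermostat(0.01),
                pre_steps = 0, seed = 3)
  expect_true(all(one$profile$delta_A == 0))
})
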