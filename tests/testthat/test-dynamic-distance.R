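# the collective variable: value, gradient, invariances

test_that("single pair and equal-distance degeneracy reduce to the pair distance", {
  m <- c(14.007, 1.008)
  conf <- configuration(rbind(c(0, 0, 0), c(1.88, 0, 0)), m,
                        elements = c("N", "H"))
  spec <- dd_spec(cbind(1, 2), m)
  expect_equal(dynamic_distance(spec, conf), 1.88)

  # several pairs, mixed reduced masses, all at distance d -> D = d
  d <- 2.37
  m2 <- c(14.007, 1.008, 15.999, 14.007, 200.592, 15.999)
  pos <- rbind(c(0, 0, 0), c(d, 0, 0),
               c(0, 5, 0), c(0, 5 + d, 0),
               c(9, 0, 0), c(9, 0, d))
  spec2 <- dd_spec(rbind(c(1, 2), c(3, 4), c(5, 6)), m2)
  expect_equal(dynamic_distance(spec2, pos), d)
  # weights sum to one by construction
  expect_equal(sum(spec2$w), 1)
})

test_that("the hand-derived two-pair value is reproduced", {
  # N-H pair at 2.0 A and N-O pair at 3.0 A
  m <- c(14.007, 1.008, 14.007, 15.999)
  pos <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 5, 0), c(3, 5, 0))
  spec <- dd_spec(rbind(c(1, 2), c(3, 4)), m)
  expect_equal(spec$mu, c(reduced_mass(14.007, 1.008),
                          reduced_mass(14.007, 15.999)))
  expect_equal(spec$mu_star, sum(spec$mu))
  expect_equal(dynamic_distance(spec, pos), 2.9053, tolerance = 1e-4)
})

test_that("gradient matches unit vectors, finite differences, and is sparse", {
  m <- c(14.007, 1.008)
  pos <- rbind(c(0, 0, 0), c(1.7, 0, 0))
  spec <- dd_spec(cbind(1, 2), m)
  g <- dynamic_distance_gradient(spec, pos)
  expect_equal(g[1, ], c(-1, 0, 0))
  expect_equal(g[2, ], c(1, 0, 0))

  # random 6-pair system + 3 unconstrained atoms
  set.seed(42)
  n <- 15
  pos <- matrix(rnorm(3 * n, sd = 2), n, 3)
  masses <- runif(n, 1, 30)
  pairs <- matrix(1:12, ncol = 2, byrow = TRUE)
  spec <- dd_spec(pairs, masses)
  g <- dynamic_distance_gradient(spec, pos)
  h <- 1e-6
  err <- 0
  for (i in seq_len(n)) {
    for (c in 1:3) {
      pp <- pos; pp[i, c] <- pp[i, c] + h
      pm <- pos; pm[i, c] <- pm[i, c] - h
      fd <- (dynamic_distance(spec, pp) - dynamic_distance(spec, pm)) /
        (2 * h)
      err <- max(err, abs(fd - g[i, c]))
    }
  }
  expect_lt(err, 1e-7)
  expect_identical(g[13:15, ], matrix(0, 3, 3))
})

test_that("translation invariance, scaling, monotonicity, RMS degeneracy", {
  set.seed(3)
  n <- 8
  masses <- runif(n, 1, 20)
  pairs <- matrix(1:8, ncol = 2, byrow = TRUE)
  spec <- dd_spec(pairs, masses)
  for (rep in 1:5) {
    pos <- matrix(rnorm(3 * n, sd = 3), n, 3)
    D <- dynamic_distance(spec, pos)
    expect_equal(dynamic_distance(spec, sweep(pos, 2, c(5, -2, 9), "+")),
                 D, tolerance = 1e-13)
    # scaling all pair vectors: scale all positions about the origin
    s <- -1.7
    expect_equal(dynamic_distance(spec, s * pos), abs(s) * D)
    # stretching one pair strictly increases D
    pos2 <- pos
    dir <- pos2[2, ] - pos2[1, ]
    pos2[2, ] <- pos2[2, ] + 0.3 * dir / sqrt(sum(dir^2))
    expect_gt(dynamic_distance(spec, pos2), D)
  }
  # equal reduced masses -> root-mean-square pair distance
  meq <- rep(12, n)
  speq <- dd_spec(pairs, meq)
  pos <- matrix(rnorm(3 * n, sd = 3), n, 3)
  pd <- sqrt(rowSums((pos[pairs[, 1], ] - pos[pairs[, 2], ])^2))
  expect_equal(dynamic_distance(speq, pos), sqrt(mean(pd^2)))
})

test_that("degenerate inputs are rejected", {
  m <- c(14.007, 1.008, 15.999)
  expect_error(dd_spec(matrix(integer(0), 0, 2), m), "empty")
  expect_error(dd_spec(rbind(c(1, 2), c(2, 3)), m), "overlap")
  spec <- dd_spec(cbind(1, 2), m[1:2])
  pos0 <- rbind(c(0, 0, 0), c(0, 0, 0))
  expect_error(dynamic_distance_gradient(spec, pos0), "singular")
})
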