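# shared fixtures, built in code

# ten-atom harmonic chain with a three-pair dynamic-distance spec;
# gentle springs and heavy atoms keep energy-conservation checks clean
chain10 <- function(seed = 101, k = 80) {
  set.seed(seed)
  pos <- cbind(seq(0, 18, length.out = 10) +
                 stats::rnorm(10, sd = 0.05),
               stats::rnorm(10, sd = 0.3), stats::rnorm(10, sd = 0.3))
  masses <- rep(c(12.011, 15.999), 5)
  conf <- configuration(pos, masses, elements = rep(c("C", "O"), 5))
  r <- sqrt(rowSums((pos[1:9, ] - pos[2:10, ])^2))
  topo <- finalize_topology(toy_topology(
    bonds = data.frame(i = 1:9, j = 2:10, k = k, r0 = r)))
  spec <- dd_spec(rbind(c(1, 4), c(5, 8), c(6, 9)), masses)
  list(topology = topo, conf = conf, spec = spec)
}

# small random toy system exercising every energy term; positional
# restraints are frame-fixed, so drop them when testing rigid-motion
# invariance
random_toy <- function(seed = 7, n = 10, restraint = TRUE) {
  set.seed(seed)
  pos <- matrix(stats::rnorm(3 * n, sd = 3), n, 3)
  topo <- finalize_topology(toy_topology(
    bonds = data.frame(i = 1:5, j = 6:10,
                       k = stats::runif(5, 100, 500),
                       r0 = stats::runif(5, 1, 2)),
    hbonds = data.frame(i = 1:3, j = 8:10, depth = 20, width = 2,
                        r0 = 1.9),
    hg = data.frame(i = 4L, j = 7L, depth = 25, width = 2, r0 = 2.15),
    lj = data.frame(i = c(1, 2), j = c(4, 5), eps = 0.5, sigma = 3,
                    wca = c(TRUE, FALSE)),
    charges = c(rep(0.3, 5), rep(-0.3, 5)),
    restraints = if (restraint) {
      data.frame(i = 2L, x = 0, y = 0, z = 0, k = 5)
    } else NULL))
  conf <- configuration(pos, masses = rep(c(12.011, 15.999), 5),
                        elements = rep(c("C", "O"), 5))
  list(topology = topo, conf = conf)
}

max_fd_force_error <- function(topo, pos, h = 1e-6) {
  ef <- energy_and_forces(topo, pos)
  err <- 0
  for (i in seq_len(nrow(pos))) {
    for (c in 1:3) {
      pp <- pos; pp[i, c] <- pp[i, c] + h
      pm <- pos; pm[i, c] <- pm[i, c] - h
      fd <- -(energy_and_forces(topo, pp)$energy -
                energy_and_forces(topo, pm)$energy) / (2 * h)
      err <- max(err, abs(fd - ef$forces[i, c]))
    }
  }
  err
}

rigid_motion <- function(pos, angle = 0.7, axis = c(1, 2, -1),
                         shift = c(3, -2, 5)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  sweep(pos %*% t(R), 2, shift, "+")
}
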