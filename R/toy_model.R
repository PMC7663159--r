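#' Synthetic classical energy model
#'
#' A classical force field with the qualitative structure the
#' free-energy analysis assumes: harmonic bonds keep each coarse base
#' template near-rigid, Morse wells describe hydrogen bonds and
#' Hg--N/O coordinate bonds (so dissociation is representable), 12-6
#' Lennard-Jones (optionally purely repulsive, WCA) terms provide
#' sterics, and point charges interact through a switched Coulomb term.
#' It makes no claim to quantum-chemical accuracy; it provides smooth,
#' bounded-below energy surfaces with tunable well depths.
#'
#' Morse convention: `V(r) = De * ((1 - exp(-a (r - r0)))^2 - 1)`, i.e.
#' the bound minimum sits at `-De` and dissociated pairs approach zero.
#'
#' @param bonds data.frame `i, j, k, r0` (harmonic, kJ/mol/Å^2 and Å).
#' @param hbonds data.frame `i, j, depth, width, r0` (Morse hydrogen
#'   bonds; kJ/mol, 1/Å, Å).
#' @param hg data.frame `i, j, depth, width, r0` (Morse Hg coordination;
#'   several acceptors per Hg are allowed, which is what creates the
#'   bistable NO/NN surface).
#' @param lj data.frame `i, j, eps, sigma, wca` (logical `wca`: truncate
#'   and shift at the minimum, giving a purely repulsive core).
#' @param charges numeric per-atom partial charges (e), or NULL.
#' @param restraints data.frame `i, x, y, z, k` harmonic positional
#'   restraints.
#' @param coul_on,coul_off switching window (Å) for the Coulomb term;
#'   interactions are smoothly switched off between these radii.
#' @param dielectric uniform relative permittivity dividing the Coulomb
#'   term (implicit-solvent screening; 1 = vacuum).
#' @param charge_groups optional list of integer vectors; Coulomb
#'   interactions between atoms of the same group are excluded (used for
#'   moieties whose internal electrostatics are already absorbed into
#'   explicit bonded/Morse terms, like the mercurated pair core).
#' @return object of class `"toy_topology"`.
#' @export
toy_topology <- function(bonds = NULL, hbonds = NULL, hg = NULL,
                         lj = NULL, charges = NULL, restraints = NULL,
                         coul_on = 6, coul_off = 8, dielectric = 1,
                         charge_groups = NULL) {
  chk <- function(df, cols, positive) {
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    stopifnot(all(cols %in% names(df)))
    for (cc in positive) {
      if (any(df[[cc]] <= 0)) stop("column '", cc, "' must be > 0")
    }
    df
  }
  topo <- structure(list(
    bonds = chk(bonds, c("i", "j", "k", "r0"), c("k")),
    hbonds = chk(hbonds, c("i", "j", "depth", "width", "r0"),
                 c("depth", "width")),
    hg = chk(hg, c("i", "j", "depth", "width", "r0"), c("depth", "width")),
    lj = chk(lj, c("i", "j", "eps", "sigma"), c("eps", "sigma")),
    charges = charges,
    restraints = chk(restraints, c("i", "x", "y", "z", "k"), c("k")),
    coul_on = coul_on, coul_off = coul_off, dielectric = dielectric,
    charge_groups = charge_groups
  ), class = "toy_topology")
  topo
}

#' @export
print.toy_topology <- function(x, ...) {
  nn <- function(df) if (is.null(df)) 0L else nrow(df)
  cat(sprintf(paste0("<toy_topology> %d bonds, %d h-bond Morse, ",
                     "%d Hg Morse, %d LJ, %d restraints, charges: %s\n"),
              nn(x$bonds), nn(x$hbonds), nn(x$hg), nn(x$lj),
              nn(x$restraints),
              if (is.null(x$charges)) "none" else
                sprintf("%d atoms, total %+g e", length(x$charges),
                        sum(x$charges))))
  invisible(x)
}

## internal: merged Morse table
.morse_terms <- function(topo) {
  rbind(topo$hbonds[, c("i", "j", "depth", "width", "r0")],
        topo$hg[, c("i", "j", "depth", "width", "r0")])
}

## internal: charged pair list (precomputed once, cached on the topology)
.charge_pairs <- function(topo) {
  cp <- attr(topo, ".charge_pairs")
  if (!is.null(cp)) return(cp)
  q <- topo$charges
  if (is.null(q) || all(q == 0)) return(NULL)
  idx <- which(q != 0)
  if (length(idx) < 2L) return(NULL)
  cmb <- utils::combn(idx, 2L)
  cp <- data.frame(i = cmb[1L, ], j = cmb[2L, ],
                   qq = q[cmb[1L, ]] * q[cmb[2L, ]])
  if (!is.null(topo$charge_groups)) {
    grp <- rep(NA_integer_, max(idx))
    for (g in seq_along(topo$charge_groups)) {
      grp[topo$charge_groups[[g]]] <- g
    }
    same <- !is.na(grp[cp$i]) & !is.na(grp[cp$j]) &
      grp[cp$i] == grp[cp$j]
    cp <- cp[!same, , drop = FALSE]
  }
  cp
}

#' Attach charges and cache the charged-pair list
#'
#' Precomputes the pair list used by the Coulomb term so repeated force
#' evaluations do not rebuild it.
#' @param topo a [toy_topology()].
#' @return the topology with the cached pair list.
#' @keywords internal
#' @export
finalize_topology <- function(topo) {
  attr(topo, ".charge_pairs") <- .charge_pairs(topo)
  topo
}

#' Energy and forces of the toy model
#'
#' Forces are the exact negative gradient of the energy; consistency is
#' enforced by finite-difference tests in the package test suite.
#'
#' @param topo a [toy_topology()].
#' @param conf a [configuration()] or N x 3 position matrix.
#' @return list with `energy` (kJ/mol) and `forces` (N x 3, kJ/mol/Å).
#' @export
energy_and_forces <- function(topo, conf) {
  pos <- if (inherits(conf, "configuration")) conf$pos else as.matrix(conf)
  n <- nrow(pos)
  energy <- 0
  ti <- integer(0); tj <- integer(0); ts <- numeric(0)  # dV/dr / r per pair
  dvx <- numeric(0); dvy <- numeric(0); dvz <- numeric(0)

  add_pairs <- function(i, j) {
    dv <- pos[i, , drop = FALSE] - pos[j, , drop = FALSE]
    r <- sqrt(rowSums(dv * dv))
    list(dv = dv, r = r)
  }
  push <- function(i, j, dv, s) {
    ti <<- c(ti, i); tj <<- c(tj, j); ts <<- c(ts, s)
    dvx <<- c(dvx, dv[, 1L]); dvy <<- c(dvy, dv[, 2L]); dvz <<- c(dvz, dv[, 3L])
  }

  if (!is.null(topo$bonds)) {
    b <- topo$bonds
    p <- add_pairs(b$i, b$j)
    dr <- p$r - b$r0
    energy <- energy + sum(0.5 * b$k * dr * dr)
    push(b$i, b$j, p$dv, b$k * dr / p$r)
  }
  mo <- .morse_terms(topo)
  if (!is.null(mo) && nrow(mo)) {
    p <- add_pairs(mo$i, mo$j)
    e <- exp(-mo$width * (p$r - mo$r0))
    om <- 1 - e
    energy <- energy + sum(mo$depth * (om * om - 1))
    push(mo$i, mo$j, p$dv, 2 * mo$depth * mo$width * e * om / p$r)
  }
  if (!is.null(topo$lj)) {
    l <- topo$lj
    p <- add_pairs(l$i, l$j)
    if (any(p$r < 1e-8)) {
      stop("coincident atoms in a Lennard-Jones pair: energy is singular")
    }
    wca <- if ("wca" %in% names(l)) as.logical(l$wca) else rep(FALSE, nrow(l))
    rmin <- 2^(1 / 6) * l$sigma
    act <- !wca | (p$r < rmin)
    if (any(act)) {
      sr6 <- (l$sigma[act] / p$r[act])^6
      v <- 4 * l$eps[act] * (sr6 * sr6 - sr6) + ifelse(wca[act], l$eps[act], 0)
      energy <- energy + sum(v)
      s <- (24 * l$eps[act] * (sr6 - 2 * sr6 * sr6) / p$r[act]) / p$r[act]
      push(l$i[act], l$j[act], p$dv[act, , drop = FALSE], s)
    }
  }
  cp <- attr(topo, ".charge_pairs")
  if (is.null(cp)) cp <- .charge_pairs(topo)
  if (!is.null(cp)) {
    p <- add_pairs(cp$i, cp$j)
    if (any(p$r < 1e-8)) {
      stop("coincident charged atoms: Coulomb energy is singular")
    }
    ron <- topo$coul_on; roff <- topo$coul_off
    inr <- p$r < roff
    if (any(inr)) {
      r <- p$r[inr]; qq <- cp$qq[inr]
      sw <- rep(1, length(r)); dsw <- rep(0, length(r))
      mid <- r > ron
      if (any(mid)) {
        A <- roff^2 - r[mid]^2
        B <- roff^2 + 2 * r[mid]^2 - 3 * ron^2
        C <- (roff^2 - ron^2)^3
        sw[mid] <- A * A * B / C
        dsw[mid] <- 12 * r[mid] * A * (ron^2 - r[mid]^2) / C
      }
      eps_r <- if (is.null(topo$dielectric)) 1 else topo$dielectric
      v0 <- .KE * qq / (eps_r * r)
      energy <- energy + sum(v0 * sw)
      s <- (v0 * dsw - v0 * sw / r) / r
      push(cp$i[inr], cp$j[inr], p$dv[inr, , drop = FALSE], s)
    }
  }
  forces <- matrix(0, n, 3L)
  if (length(ti)) {
    ## force on i is -dV/dr * (ri-rj)/r = -s * dv  (s = dV/dr / r)
    fi <- cbind(-ts * dvx, -ts * dvy, -ts * dvz)
    idx <- c(ti, tj)
    fall <- rbind(fi, -fi)
    agg <- rowsum(fall, group = idx, reorder = FALSE)
    forces[as.integer(rownames(agg)), ] <-
      forces[as.integer(rownames(agg)), ] + agg
  }
  if (!is.null(topo$restraints)) {
    rs <- topo$restraints
    dv <- pos[rs$i, , drop = FALSE] - cbind(rs$x, rs$y, rs$z)
    energy <- energy + sum(0.5 * rs$k * rowSums(dv * dv))
    agg <- rowsum(-rs$k * dv, group = rs$i, reorder = FALSE)
    forces[as.integer(rownames(agg)), ] <-
      forces[as.integer(rownames(agg)), ] + agg
  }
  if (!is.finite(energy) || any(!is.finite(forces))) {
    stop("non-finite energy or forces (overlapping or escaping atoms?)")
  }
  list(energy = energy, forces = forces)
}

#' Two-particle harmonic dimer fixture
#'
#' The analytic validation system for thermodynamic integration: two
#' particles joined by a single harmonic bond.  Its exact constrained
#' free-energy profile is available in closed form
#' ([dimer_free_energy_oracle()]).
#'
#' @param k spring constant, kJ/mol/Å^2.
#' @param r0 equilibrium length, Å.
#' @param masses length-2 masses, amu; defaults to an N--H pair.
#' @return list with `topology` and `conf` (bond at its minimum, along x).
#' @examples
#' fx <- make_harmonic_dimer(500, 1.0)
#' energy_and_forces(fx$topology, fx$conf)$energy  # 0 at the minimum
#' @export
make_harmonic_dimer <- function(k, r0 = 1.0,
                                masses = c(14.007, 1.008)) {
  stopifnot(k > 0, r0 > 0, length(masses) == 2L)
  topo <- finalize_topology(
    toy_topology(bonds = data.frame(i = 1L, j = 2L, k = k, r0 = r0)))
  conf <- configuration(rbind(c(0, 0, 0), c(r0, 0, 0)),
                        masses = masses, elements = c("N", "H"),
                        labels = c("dimer-A", "dimer-B"))
  list(topology = topo, conf = conf)
}

#' Bistable dinuclear-Hg base-pair fixture
#'
#' A minimal model of the competing NO/NN coordination of the first
#' mercury ion in the T--Hg(II)2--epsilonA pair.  The mobile ion Hg1 sees
#' two competing Morse acceptors -- the thymine O4 (NO pattern) and the
#' thymine N3 (NN pattern) -- placed symmetrically, plus a weak isotropic
#' positional restraint that keeps it in the coordination pocket.  The
#' epsilonA N7 site sits beside the pocket as a geometric coordination
#' partner.  Hg2 with its epsilonA-N6/T-O2 bridge is included (held
#' fixed) so that bonding-pattern classification sees the complete pair.
#'
#' With equal depths the two minima are degenerate by symmetry; with
#' unequal depths the minimum-energy difference equals
#' `depth_NO - depth_NN` to within a fraction of a kJ/mol (the residual
#' attraction of the far acceptor).
#'
#' @param depth_NO Morse depth (kJ/mol) of the Hg1--T-O4 well.
#' @param depth_NN Morse depth (kJ/mol) of the Hg1--T-N3 well.
#' @param width Morse width, 1/Å.  The fixture default (3.0) is chosen so
#'   the far-acceptor residual is negligible while the inter-well barrier
#'   stays crossable at 300 K.
#' @param separation distance of each competing acceptor from the pocket
#'   centre, Å.
#' @param restraint_k positional restraint on Hg1, kJ/mol/Å^2.
#' @return list with `topology`, `conf` (Hg1 started in the NO basin) and
#'   `site_map` (see [duplex_site_map()] for the format).
#' @export
make_bistable_hg_pair <- function(depth_NO = 12, depth_NN = 12,
                                  width = 3.0, separation = 2.9,
                                  restraint_k = 5) {
  stopifnot(depth_NO > 0, depth_NN > 0, width > 0, separation > 2.15)
  labels <- c("Hg1", "T7-O4", "T7-N3", "eA20-N7",
              "Hg2", "eA20-N6", "T7-O2")
  elements <- c("Hg", "O", "N", "N", "Hg", "N", "O")
  pos <- rbind(
    c(0, separation - 2.15, 0),     # Hg1, NO basin
    c(0,  separation, 0),           # T-O4
    c(0, -separation, 0),           # T-N3
    c(1.7, 0, 0),                   # eA-N7 (geometric site)
    c(-5.0, 0, 0),                  # Hg2
    c(-5.0, 0,  2.15),              # eA-N6
    c(-5.0, 0, -2.15))              # T-O2
  conf <- configuration(pos, masses = atomic_mass(elements),
                        elements = elements, labels = labels,
                        fixed = c(FALSE, rep(TRUE, 6L)))
  hg <- data.frame(
    i = c(1L, 1L, 5L, 5L),
    j = c(2L, 3L, 6L, 7L),
    depth = c(depth_NO, depth_NN, 40, 40),
    width = c(width, width, 2, 2),
    r0 = 2.15)
  topo <- finalize_topology(toy_topology(
    hg = hg,
    restraints = data.frame(i = 1L, x = 0, y = 0, z = 0, k = restraint_k)))
  smap <- data.frame(index = seq_along(labels), label = labels,
                     element = elements)
  list(topology = topo, conf = conf, site_map = smap)
}

#' Locate the two minima of the bistable fixture
#'
#' Minimizes the fixture energy with respect to the mobile Hg position,
#' starting from each basin, and reports both minimum energies.
#'
#' @param fx a fixture from [make_bistable_hg_pair()].
#' @return list with `E_NO`, `E_NN`, `delta` (`E_NN - E_NO`), and the two
#'   minimizing Hg positions.
#' @export
bistable_minima <- function(fx) {
  obj <- function(x) {
    pos <- fx$conf$pos
    pos[1L, ] <- x
    energy_and_forces(fx$topology, pos)$energy
  }
  grd <- function(x) {
    pos <- fx$conf$pos
    pos[1L, ] <- x
    -energy_and_forces(fx$topology, pos)$forces[1L, ]
  }
  y0 <- fx$conf$pos[2L, 2L] - 2.15
  ## basins are separated by the y = 0 symmetry plane; minimize within
  ## each half-space so a shallow minority basin is not skipped over
  m1 <- stats::optim(c(0, y0, 0), obj, grd, method = "L-BFGS-B",
                     lower = c(-4, 1e-3, -4), upper = c(4, 4, 4),
                     control = list(factr = 10, maxit = 500))
  m2 <- stats::optim(c(0, -y0, 0), obj, grd, method = "L-BFGS-B",
                     lower = c(-4, -4, -4), upper = c(4, -1e-3, 4),
                     control = list(factr = 10, maxit = 500))
  list(E_NO = m1$value, E_NN = m2$value, delta = m2$value - m1$value,
       x_NO = m1$par, x_NN = m2$par)
}

#' Canonical basin occupancy of the bistable fixture by quadrature
#'
#' Integrates the Boltzmann weight of the mobile Hg ion on a dense 3-D
#' grid, labelling every grid point with the same geometric NO/NN
#' classification rule used on trajectories ([classify_pattern()]:
#' coordination = acceptors within `cutoff`, ties to the closer
#' acceptor).  The returned ratio is the exact canonical prediction for
#' the label occupancies that Langevin sampling of the fixture must
#' reproduce; unlike the bare `exp(-dE/kBT)` two-state estimate it
#' includes basin-shape (curvature and anharmonicity) contributions and
#' uses the identical region definition as the trajectory analysis.
#'
#' @param fx a fixture from [make_bistable_hg_pair()].
#' @param temperature K.
#' @param cutoff coordination cutoff used for labelling, Å.
#' @param lim half-width of the integration cube, Å.
#' @param n grid points per dimension (default 161; the well width is
#'   ~0.1 Å, so the default spacing ~0.056 Å resolves it).
#' @return list with `p_NO`, `p_NN`, `p_other` (grid probability of
#'   each label) and `ratio` (= p_NN / p_NO).
#' @export
bistable_occupancy_ref <- function(fx, temperature = 300, cutoff = 3.0,
                                   lim = 4.5, n = 161) {
  g <- seq(-lim, lim, length.out = n)
  grid <- as.matrix(expand.grid(x = g, y = g, z = g))
  pos <- fx$conf$pos
  lab <- fx$conf$label
  site_pos <- function(nm) pos[match(nm, lab), ]
  dist_to <- function(nm) {
    sqrt(rowSums(sweep(grid, 2L, site_pos(nm))^2))
  }
  ## Hg1 potential on the grid (terms involving atom 1 only)
  hg <- fx$topology$hg
  hg <- hg[hg$i == 1L | hg$j == 1L, ]
  e <- numeric(nrow(grid))
  for (t in seq_len(nrow(hg))) {
    other <- if (hg$i[t] == 1L) hg$j[t] else hg$i[t]
    r <- sqrt(rowSums(sweep(grid, 2L, pos[other, ])^2))
    ex <- exp(-hg$width[t] * (r - hg$r0[t]))
    e <- e + hg$depth[t] * ((1 - ex)^2 - 1)
  }
  rs <- fx$topology$restraints
  e <- e + 0.5 * rs$k[1L] * rowSums(sweep(grid, 2L,
                                          c(rs$x[1L], rs$y[1L], rs$z[1L]))^2)
  w <- exp(-(e - min(e)) / (.kB * temperature))
  ## same labelling rule as classify_pattern, vectorized over the grid
  dO4 <- dist_to(grep("-O4$", lab, value = TRUE)[1L])
  dN3 <- dist_to(grep("^T[0-9]+-N3$", lab, value = TRUE)[1L])
  dN7 <- dist_to(grep("^eA[0-9]+-N7$", lab, value = TRUE)[1L])
  n_in <- (dO4 <= cutoff) + (dN3 <= cutoff) + (dN7 <= cutoff)
  no_ok <- dN7 <= cutoff & dO4 <= cutoff
  nn_ok <- dN7 <= cutoff & dN3 <= cutoff
  label <- ifelse(n_in < 2L, "DISSOCIATED",
                  ifelse(no_ok & (!nn_ok | (dO4 + dN7 <= dN3 + dN7)),
                         "NO", ifelse(nn_ok, "NN", "OTHER")))
  zNO <- sum(w[label == "NO"]); zNN <- sum(w[label == "NN"])
  ztot <- sum(w)
  list(p_NO = zNO / ztot, p_NN = zNN / ztot,
       p_other = 1 - (zNO + zNN) / ztot, ratio = zNN / zNO)
}

#' Serialize / read a toy topology (YAML, versioned)
#'
#' The schema is a direct YAML mapping of the topology fields
#' (`bonds`, `hbonds`, `hg`, `lj`, `charges`, `restraints`, `coul_on`,
#' `coul_off`, `dielectric`, `charge_groups`) under a `schema_version`
#' key; data frames are stored column-wise.
#'
#' @param topo a [toy_topology()].
#' @param file path.
#' @return `write_topology`: the path, invisibly; `read_topology`: a
#'   finalized [toy_topology()].
#' @export
write_topology <- function(topo, file) {
  enc <- function(df) if (is.null(df)) NULL else as.list(df)
  yaml::write_yaml(list(
    schema_version = 1L,
    bonds = enc(topo$bonds), hbonds = enc(topo$hbonds),
    hg = enc(topo$hg), lj = enc(topo$lj),
    charges = topo$charges, restraints = enc(topo$restraints),
    coul_on = topo$coul_on, coul_off = topo$coul_off,
    dielectric = topo$dielectric,
    charge_groups = topo$charge_groups), file)
  invisible(file)
}

#' @rdname write_topology
#' @export
read_topology <- function(file) {
  x <- yaml::read_yaml(file)
  if (is.null(x$schema_version) || x$schema_version != 1L) {
    stop("unsupported topology schema version")
  }
  dec <- function(l) if (is.null(l)) NULL else as.data.frame(l)
  finalize_topology(toy_topology(
    bonds = dec(x$bonds), hbonds = dec(x$hbonds), hg = dec(x$hg),
    lj = dec(x$lj), charges = x$charges,
    restraints = dec(x$restraints), coul_on = x$coul_on,
    coul_off = x$coul_off,
    dielectric = if (is.null(x$dielectric)) 1 else x$dielectric,
    charge_groups = x$charge_groups))
}

#' Add coarse solvent particles
#'
#' Uniform-random (seeded) placement of neutral Lennard-Jones spheres
#' in a box around the solute, with solvent-solvent and solvent-solute
#' LJ terms -- a dipole-free coarse solvent for runs that need a bath
#' or collision partners.
#'
#' @param topo a [toy_topology()].
#' @param conf a [configuration()].
#' @param n number of solvent particles.
#' @param margin box margin beyond the solute bounding box, Å.
#' @param eps,sigma LJ parameters (kJ/mol, Å).
#' @param mass particle mass, amu (default: water-like 18.015).
#' @param exclusion minimum starting distance from any existing atom, Å.
#' @param seed placement seed.
#' @return list with the extended `topology` and `conf` (solvent atoms
#'   labelled `"SOL<k>"`, element `"O"`).
#' @export
add_solvent <- function(topo, conf, n, margin = 6, eps = 0.6,
                        sigma = 3.2, mass = 18.015, exclusion = 2.8,
                        seed = 1L) {
  stopifnot(n >= 1L)
  n0 <- n_atoms(conf)
  lo <- apply(conf$pos, 2L, min) - margin
  hi <- apply(conf$pos, 2L, max) + margin
  placed <- .with_seed(seed, {
    occ <- conf$pos
    out <- matrix(NA_real_, n, 3L)
    for (k in seq_len(n)) {
      repeat {
        p <- stats::runif(3L, lo, hi)
        if (min(rowSums(sweep(occ, 2L, p)^2)) >= exclusion^2) break
      }
      out[k, ] <- p
      occ <- rbind(occ, p)
    }
    out
  })
  sol <- seq.int(n0 + 1L, n0 + n)
  pairs_ss <- if (n > 1L) t(utils::combn(sol, 2L)) else
    matrix(integer(0), 0L, 2L)
  pairs_sx <- cbind(rep(sol, each = n0), rep(seq_len(n0), n))
  lj_new <- data.frame(i = c(pairs_ss[, 1L], pairs_sx[, 1L]),
                       j = c(pairs_ss[, 2L], pairs_sx[, 2L]),
                       eps = eps, sigma = sigma, wca = FALSE)
  topo$lj <- rbind(topo$lj, lj_new)
  if (!is.null(topo$charges)) topo$charges <- c(topo$charges, rep(0, n))
  conf2 <- configuration(rbind(conf$pos, placed),
                         masses = c(conf$mass, rep(mass, n)),
                         elements = c(conf$element, rep("O", n)),
                         labels = c(conf$label, sprintf("SOL%d", seq_len(n))),
                         velocities = rbind(conf$vel, matrix(0, n, 3L)),
                         fixed = c(conf$fixed, rep(FALSE, n)))
  list(topology = finalize_topology(topo), conf = conf2)
}
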