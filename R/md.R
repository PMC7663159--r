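#' @title Constrained molecular dynamics engine
#' @description
#' Velocity-Verlet integration with an exact holonomic constraint on the
#' dynamic-distance collective variable.  The position-level Lagrange
#' multiplier is solved each step by damped Newton iteration
#' (SHAKE-style; the system is 1x1 because the constraint is a single
#' scalar), and a velocity-level projection (RATTLE) enforces dD/dt = 0.
#' Thermostats: Nose-Hoover chains (deterministic) and Langevin
#' (stochastic); simulated annealing multiplies the thermostat target by
#' a fixed factor on a fixed step interval.
#' @name constrained_md
NULL

#' Nose-Hoover chain thermostat
#'
#' @param chain_length number of chained thermostat variables (default 3).
#' @param tau time constant, fs (default 1000 fs = 1 ps).
#' @return a thermostat description.
#' @export
nose_hoover_chain <- function(chain_length = 3L, tau = 1000) {
  stopifnot(chain_length >= 1L, tau > 0)
  structure(list(type = "nhc", chain_length = as.integer(chain_length),
                 tau = tau), class = "thermostat")
}

#' Langevin thermostat
#'
#' @param friction collision rate gamma, 1/fs (default 0.002).
#' @return a thermostat description.
#' @export
langevin_thermostat <- function(friction = 0.002) {
  stopifnot(friction > 0)
  structure(list(type = "langevin", friction = friction),
            class = "thermostat")
}

#' @export
print.thermostat <- function(x, ...) {
  cat("<thermostat>", x$type,
      if (x$type == "nhc") sprintf("(chain %d, tau %g fs)",
                                   x$chain_length, x$tau)
      else sprintf("(gamma %g 1/fs)", x$friction), "\n")
  invisible(x)
}

#' Constraint bookkeeping for single-step integration
#'
#' @param target_D constraint value, Å.
#' @param tol convergence tolerance on |D - target|, Å.
#' @param max_iter maximum Newton iterations.
#' @return a `constraint_state` list with an empty `lambda_trace`.
#' @export
constraint_state <- function(target_D, tol = 1e-8, max_iter = 50L) {
  stopifnot(target_D > 0, tol > 0, max_iter >= 1L)
  list(target_D = target_D, tol = tol, max_iter = as.integer(max_iter),
       lambda_trace = numeric(0))
}

#' Maxwell-Boltzmann velocity initialization
#'
#' Draws velocities at `temperature`, removes centre-of-mass momentum
#' (unless atoms are held fixed), and zeroes fixed atoms.
#'
#' @param conf a [configuration()].
#' @param temperature K.
#' @param seed integer seed (NULL: use current RNG state).
#' @param remove_com remove net momentum (default TRUE when no atom is
#'   fixed).
#' @return the configuration with velocities set.
#' @export
maxwell_boltzmann <- function(conf, temperature, seed = NULL,
                              remove_com = !any(conf$fixed)) {
  n <- n_atoms(conf)
  draw <- function() {
    sd <- sqrt(.kB * temperature * .F2A / conf$mass)
    matrix(stats::rnorm(3L * n), n, 3L) * sd
  }
  v <- if (is.null(seed)) draw() else .with_seed(seed, draw())
  v[conf$fixed, ] <- 0
  if (remove_com && !any(conf$fixed)) {
    p <- colSums(conf$mass * v)
    v <- v - matrix(p / sum(conf$mass), n, 3L, byrow = TRUE)
  }
  conf$vel <- v
  conf
}

## ---- internal integrator ------------------------------------------------

## SHAKE: solve for lambda such that D(pos1 + lambda * dir) = target,
## dir = dt^2 * Minv * gradD(old pos).  Damped Newton; after convergence
## one extra polish iteration drives the residual to ~1e-14.
.shake_solve <- function(spec, pos1, dir, target, tol, max_iter) {
  lambda <- 0
  pos <- pos1
  g <- dynamic_distance(spec, pos) - target
  it <- 0L
  while (abs(g) > tol) {
    it <- it + 1L
    if (it > max_iter) {
      stop(sprintf(paste0("constraint solver did not converge: |g| = %.3e",
                          " after %d iterations (target %.6f)"),
                   abs(g), max_iter, target))
    }
    gr <- dynamic_distance_gradient(spec, pos)
    dg <- sum(gr * dir)
    if (abs(dg) < 1e-300) stop("singular constraint Jacobian")
    step <- -g / dg
    ## damping: halve until the residual decreases
    repeat {
      pos_try <- pos1 + (lambda + step) * dir
      g_try <- dynamic_distance(spec, pos_try) - target
      if (abs(g_try) < abs(g) || abs(step) < 1e-16) break
      step <- step / 2
    }
    lambda <- lambda + step
    pos <- pos_try
    g <- g_try
  }
  ## polish
  gr <- dynamic_distance_gradient(spec, pos)
  dg <- sum(gr * dir)
  if (abs(dg) > 1e-300) {
    lambda <- lambda - g / dg
    pos <- pos1 + lambda * dir
  }
  list(lambda = lambda, pos = pos)
}

## RATTLE velocity projection: dD/dt = 0 exactly
.rattle_project <- function(spec, pos, vel, minv) {
  gr <- dynamic_distance_gradient(spec, pos)
  denom <- sum(minv * gr * gr)
  if (denom <= 0) return(vel)
  mu <- -sum(gr * vel) / denom
  vel + mu * minv * gr
}

.nhc_init <- function(thermo, ndof, temperature) {
  m <- thermo$chain_length
  kt <- .kB * temperature * .F2A
  list(eta = numeric(m), veta = numeric(m),
       Q = c(ndof * kt * thermo$tau^2, rep(kt * thermo$tau^2, m - 1L)))
}

## one half-step of the Nose-Hoover chain; returns scale factor + state
.nhc_halfstep <- function(st, ke2, ndof, kt, dt) {
  m <- length(st$eta)
  dt2 <- dt; dt4 <- dt / 2; dt8 <- dt / 4
  G <- numeric(m)
  G[m] <- if (m > 1L) (st$Q[m - 1L] * st$veta[m - 1L]^2 - kt) / st$Q[m] else
    (ke2 - ndof * kt) / st$Q[1L]
  st$veta[m] <- st$veta[m] + G[m] * dt4
  if (m > 1L) {
    for (k in (m - 1L):1L) {
      e <- exp(-st$veta[k + 1L] * dt8)
      G[k] <- if (k == 1L) (ke2 - ndof * kt) / st$Q[1L] else
        (st$Q[k - 1L] * st$veta[k - 1L]^2 - kt) / st$Q[k]
      st$veta[k] <- (st$veta[k] * e + G[k] * dt4) * e
    }
  }
  scale <- exp(-st$veta[1L] * dt2)
  ke2 <- ke2 * scale^2
  st$eta <- st$eta + st$veta * dt2
  if (m > 1L) {
    for (k in 1L:(m - 1L)) {
      e <- exp(-st$veta[k + 1L] * dt8)
      G[k] <- if (k == 1L) (ke2 - ndof * kt) / st$Q[1L] else
        (st$Q[k - 1L] * st$veta[k - 1L]^2 - kt) / st$Q[k]
      st$veta[k] <- (st$veta[k] * e + G[k] * dt4) * e
    }
    G[m] <- (st$Q[m - 1L] * st$veta[m - 1L]^2 - kt) / st$Q[m]
  } else {
    G[1L] <- (ke2 - ndof * kt) / st$Q[1L]
  }
  st$veta[m] <- st$veta[m] + G[m] * dt4
  list(scale = scale, state = st)
}

## main fixed-step integrator; target and target_T may be functions of
## the (1-based) step index
.md_engine <- function(topo, conf, steps, dt, thermo = NULL,
                       temperature = 300, spec = NULL, target = NULL,
                       tol = 1e-8, max_iter = 50L, stride = 0L,
                       seed = NULL, targetT_fn = NULL) {
  if (steps < 1L) stop("steps must be >= 1")
  run <- function() {
    pos <- conf$pos
    vel <- conf$vel
    mass <- conf$mass
    free <- !conf$fixed
    minv <- ifelse(free, .F2A / mass, 0)
    n <- nrow(pos)
    constrained <- !is.null(spec) && !is.null(target)
    target_fn <- if (is.function(target)) target else function(s) target
    tT_fn <- if (!is.null(targetT_fn)) targetT_fn else
      function(s) temperature
    ndof <- 3L * sum(free) - (if (constrained) 1L else 0L)
    com_removed <- !any(conf$fixed) && is.null(topo$restraints) &&
      (is.null(thermo) || thermo$type == "nhc")
    if (com_removed) ndof <- ndof - 3L
    nhc <- NULL
    if (!is.null(thermo) && thermo$type == "nhc") {
      nhc <- .nhc_init(thermo, ndof, tT_fn(1L))
    }
    lan_c1 <- if (!is.null(thermo) && thermo$type == "langevin") {
      exp(-thermo$friction * dt / 2)
    } else NULL

    ef <- energy_and_forces(topo, pos)
    frames <- list()
    tr_T <- tr_Ep <- tr_Ek <- tr_cons <- tr_D <- tr_tg <- tr_la <-
      rep(NA_real_, steps)
    ke2 <- function(v) sum(mass[free] * rowSums(v[free, , drop = FALSE]^2))
    kt_of <- function(Tt) .kB * Tt * .F2A

    apply_thermo_half <- function(Tt) {
      if (is.null(thermo)) return()
      if (thermo$type == "nhc") {
        hs <- .nhc_halfstep(nhc, ke2(vel), ndof, kt_of(Tt), dt / 2)
        nhc <<- hs$state
        vel[free, ] <<- vel[free, , drop = FALSE] * hs$scale
      } else {
        sd <- sqrt((1 - lan_c1^2) * kt_of(Tt) / mass[free])
        vel[free, ] <<- lan_c1 * vel[free, , drop = FALSE] +
          matrix(stats::rnorm(3L * sum(free)), sum(free), 3L) * sd
        if (constrained) vel <<- .rattle_project(spec, pos, vel, minv)
      }
    }

    aborted <- NULL
    for (s in seq_len(steps)) {
      Tt <- tT_fn(s)
      pos_good <- pos; vel_good <- vel
      apply_thermo_half(Tt)
      vel <- vel + (0.5 * dt * minv) * ef$forces
      pos1 <- pos + dt * vel
      lambda <- NA_real_
      if (constrained) {
        ## constraint force lambda * gradD enters the first half-kick
        ## like any other force: dq = (dt^2/2m) lambda gradD
        g0 <- dynamic_distance_gradient(spec, pos)
        dir <- (0.5 * dt * dt * minv) * g0
        sol <- .shake_solve(spec, pos1, dir, target_fn(s), tol, max_iter)
        lambda <- sol$lambda
        pos <- sol$pos
        vel <- vel + (0.5 * lambda * dt * minv) * g0
      } else {
        pos <- pos1
      }
      ef_try <- tryCatch(energy_and_forces(topo, pos),
                         error = function(e) e)
      if (inherits(ef_try, "error")) {
        ## abort with the last good frame; traces truncated to the
        ## completed steps
        pos <- pos_good; vel <- vel_good
        aborted <- sprintf("aborted at step %d: %s", s,
                           conditionMessage(ef_try))
        warning(aborted)
        steps <- s - 1L
        break
      }
      ef <- ef_try
      vel <- vel + (0.5 * dt * minv) * ef$forces
      if (constrained) vel <- .rattle_project(spec, pos, vel, minv)
      apply_thermo_half(Tt)

      k2 <- ke2(vel)
      tr_Ep[s] <- ef$energy
      tr_Ek[s] <- 0.5 * k2 * .E2KJ
      tr_T[s] <- k2 / (ndof * .kB * .F2A)
      if (!is.null(nhc)) {
        kt <- kt_of(Tt)
        tr_cons[s] <- tr_Ep[s] + tr_Ek[s] +
          (0.5 * sum(nhc$Q * nhc$veta^2) + ndof * kt * nhc$eta[1L] +
             kt * sum(nhc$eta[-1L])) * .E2KJ
      } else if (is.null(thermo)) {
        tr_cons[s] <- tr_Ep[s] + tr_Ek[s]
      }
      if (!is.null(spec)) {
        tr_D[s] <- dynamic_distance(spec, pos)
        if (constrained) {
          tr_tg[s] <- target_fn(s)
          tr_la[s] <- lambda
        }
      }
      if (stride > 0L && (s %% stride == 0L)) {
        frames[[length(frames) + 1L]] <- pos
      }
    }
    conf$pos <- pos
    conf$vel <- vel
    keep <- seq_len(steps)   # truncated when the run aborted early
    trace <- data.frame(step = keep, time = keep * dt,
                        temperature = tr_T[keep], E_pot = tr_Ep[keep],
                        E_kin = tr_Ek[keep], E_conserved = tr_cons[keep],
                        D = tr_D[keep], target = tr_tg[keep],
                        lambda = tr_la[keep])
    structure(list(conf = conf, trace = trace, frames = frames,
                   ndof = ndof, dt = dt, aborted = aborted),
              class = "md_result")
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

#' @export
print.md_result <- function(x, ...) {
  n <- nrow(x$trace)
  cat(sprintf(paste0("<md_result> %d steps (dt %g fs), final T %.1f K, ",
                     "E_pot %.3f kJ/mol%s\n"),
              n, x$dt, x$trace$temperature[n], x$trace$E_pot[n],
              if (!is.na(x$trace$D[n])) sprintf(", D %.4f A", x$trace$D[n])
              else ""))
  invisible(x)
}

#' Project a configuration exactly onto the constraint surface
#'
#' Moves atoms along the mass-weighted constraint gradient until
#' D = `target` (within `tol`) and removes the velocity component along
#' the constraint.
#'
#' @param conf a [configuration()].
#' @param spec a [dd_spec()].
#' @param target desired D, Å.
#' @param tol,max_iter solver controls.
#' @return the projected configuration.
#' @export
project_to_constraint <- function(conf, spec, target, tol = 1e-8,
                                  max_iter = 100L) {
  minv <- ifelse(conf$fixed, 0, .F2A / conf$mass)
  g0 <- dynamic_distance_gradient(spec, conf$pos)
  sol <- .shake_solve(spec, conf$pos, minv * g0, target, tol, max_iter)
  conf$pos <- sol$pos
  conf$vel <- .rattle_project(spec, conf$pos, conf$vel, minv)
  conf
}

#' Single constrained MD step
#'
#' One velocity-Verlet step with the dynamic distance held at
#' `cstate$target_D`; the solved Lagrange multiplier (kJ/mol/Å) is
#' appended to `cstate$lambda_trace`.  The incoming configuration must
#' already satisfy the constraint (see [project_to_constraint()]).
#'
#' @param topo a [toy_topology()].
#' @param conf a [configuration()].
#' @param spec a [dd_spec()].
#' @param cstate a [constraint_state()].
#' @param thermostat a thermostat or NULL (NVE).
#' @param dt time step, fs.
#' @param temperature thermostat target, K.
#' @return list with `conf` and the updated `cstate`.
#' @export
step_constrained <- function(topo, conf, spec, cstate, thermostat = NULL,
                             dt = 0.5, temperature = 300) {
  d0 <- dynamic_distance(spec, conf)
  if (abs(d0 - cstate$target_D) > max(cstate$tol, 1e-6)) {
    stop(sprintf(paste0("configuration violates the constraint: D = %.6f",
                        " vs target %.6f; project_to_constraint() first"),
                 d0, cstate$target_D))
  }
  res <- .md_engine(topo, conf, steps = 1L, dt = dt, thermo = thermostat,
                    temperature = temperature, spec = spec,
                    target = cstate$target_D, tol = cstate$tol,
                    max_iter = cstate$max_iter)
  cstate$lambda_trace <- c(cstate$lambda_trace, res$trace$lambda)
  list(conf = res$conf, cstate = cstate)
}

#' Run (optionally constrained) MD
#'
#' NVT with the chosen thermostat, or NVE when `thermostat = NULL`.
#' When a [dd_spec()] and `target` are given, the dynamic distance is
#' held at the target throughout.
#'
#' @param topo a [toy_topology()].
#' @param conf a [configuration()]; velocities as given (use
#'   [maxwell_boltzmann()] to thermalize).
#' @param steps number of MD steps (>= 1).
#' @param dt time step, fs (default 0.5).
#' @param thermostat a thermostat from [nose_hoover_chain()] /
#'   [langevin_thermostat()], or NULL for NVE.
#' @param temperature target temperature, K.
#' @param spec optional [dd_spec()] (monitored, and constrained when
#'   `target` is not NULL).
#' @param target constraint value (Å), a function(step) returning one,
#'   or NULL for unconstrained dynamics.
#' @param stride save a trajectory frame every `stride` steps (0: none).
#' @param seed RNG seed for stochastic thermostats.
#' @param tol,max_iter constraint-solver controls.
#' @return an `md_result`: final `conf`, per-step `trace` (temperature,
#'   energies, D, target, lambda), saved `frames`, and `aborted` (NULL,
#'   or a message if the run hit non-finite energies and stopped at the
#'   last good frame).
#' @export
run_nvt <- function(topo, conf, steps, dt = 0.5,
                    thermostat = nose_hoover_chain(), temperature = 300,
                    spec = NULL, target = NULL, stride = 0L, seed = NULL,
                    tol = 1e-8, max_iter = 50L) {
  if (!is.null(target) && is.null(spec)) {
    stop("a constraint target needs a dd_spec")
  }
  .md_engine(topo, conf, steps = steps, dt = dt, thermo = thermostat,
             temperature = temperature,
             spec = spec, target = if (is.null(target)) NULL else target,
             tol = tol, max_iter = max_iter, stride = stride, seed = seed)
}

#' Simulated annealing
#'
#' Multiplies the thermostat target temperature by `factor` every
#' `rescale_every` steps, starting from `start_T`; after `steps` steps
#' the target is `start_T * factor^(steps %/% rescale_every)`.
#'
#' @param topo,conf,spec,target,dt,thermostat,seed as in [run_nvt()].
#' @param start_T initial target temperature, K.
#' @param factor annealing factor in (0, 1]; 1 keeps T constant.
#' @param steps MD steps; 0 returns the configuration unchanged.
#' @param rescale_every rescale interval in steps (default 100).
#' @return an `md_result` (with an extra `final_T` element); for
#'   `steps = 0` the input configuration wrapped unchanged.
#' @export
anneal <- function(topo, conf, start_T = 300, factor = 0.99,
                   steps = 30000L, rescale_every = 100L, dt = 0.5,
                   thermostat = nose_hoover_chain(), spec = NULL,
                   target = NULL, seed = NULL) {
  if (factor > 1 || factor <= 0) {
    stop("annealing factor must be in (0, 1]")
  }
  final_T <- start_T * factor^(steps %/% rescale_every)
  if (steps == 0L) {
    return(structure(list(conf = conf, trace = NULL, frames = list(),
                          final_T = final_T, dt = dt),
                     class = "md_result"))
  }
  res <- .md_engine(topo, conf, steps = steps, dt = dt,
                    thermo = thermostat, spec = spec, target = target,
                    seed = seed,
                    targetT_fn = function(s)
                      start_T * factor^(s %/% rescale_every))
  res$final_T <- final_T
  res
}

#' Annealing temperature schedule
#'
#' @param start_T starting target, K.
#' @param factor annealing factor.
#' @param step step index (vectorized).
#' @param rescale_every rescale interval, steps.
#' @return target temperature(s), K.
#' @export
anneal_schedule <- function(start_T, factor, step, rescale_every = 100L) {
  start_T * factor^(step %/% rescale_every)
}

#' Zip up the hydrogen-bond structure
#'
#' Linearly ramps the constrained dynamic distance from `D_start` down
#' to `D_end` over `steps` MD steps, gradually imposing the predefined
#' hydrogen-bond pattern on the model without letting the strands drift
#' apart.  Only the collective D is constrained; individual pair
#' distances remain free to trade against each other.
#'
#' @param topo,conf,dt,thermostat,temperature,seed,stride as in
#'   [run_nvt()].
#' @param spec the EQUI-variant [dd_spec()] (all regular hydrogen bonds).
#' @param D_start initial dynamic distance, Å (default 1.88).  The
#'   configuration's current D must lie within 0.5 Å of it.
#' @param D_end final dynamic distance, Å (default 1.56).
#' @param steps ramp length in MD steps (default 10000).
#' @return an `md_result`; the final configuration satisfies
#'   D = `D_end` within the solver tolerance.
#' @export
zip_up <- function(topo, conf, spec, D_start = 1.88, D_end = 1.56,
                   steps = 10000L, dt = 0.5,
                   thermostat = nose_hoover_chain(), temperature = 300,
                   seed = NULL, stride = 0L) {
  if (!(D_start >= D_end && D_end > 0)) {
    stop("require D_start >= D_end > 0")
  }
  d0 <- dynamic_distance(spec, conf)
  if (abs(d0 - D_start) > 0.5) {
    stop(sprintf(paste0("initial dynamic distance %.3f Å differs from ",
                        "D_start = %.3f Å by more than 0.5 Å: ",
                        "ramp undefined"), d0, D_start))
  }
  sched <- zip_schedule(D_start, D_end, steps)
  .md_engine(topo, conf, steps = steps, dt = dt, thermo = thermostat,
             temperature = temperature, spec = spec,
             target = sched, seed = seed, stride = stride)
}

#' Linear zip-up target schedule
#'
#' @param D_start,D_end ramp endpoints, Å.
#' @param steps total steps.
#' @return function(step) giving the target at each step (step `steps`
#'   maps to `D_end`, step 0 to `D_start`).
#' @export
zip_schedule <- function(D_start = 1.88, D_end = 1.56, steps = 10000L) {
  force(D_start); force(D_end); force(steps)
  function(step) D_start + (D_end - D_start) * step / steps
}
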