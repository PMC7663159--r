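#' @title Thermodynamic integration over the dynamic distance
#' @description
#' Blue-moon style free-energy estimation: the dynamic distance is held
#' at a sequence of values (windows); at each window the mean Lagrange
#' multiplier -- the mean constraint force \eqn{\langle F(D)\rangle} --
#' is accumulated after an equilibration discard, and the free-energy
#' profile follows by trapezoidal integration,
#' \deqn{\Delta A = \int_{D_{min}}^{D_{max}} \langle F(D)\rangle\, dD .}
#' @name free_energy
NULL

#' Window schedule for thermodynamic integration
#'
#' @param points ordered D values, Å; strictly monotone.  Mixed step
#'   sizes are allowed (see [parse_schedule()] for the string form).
#' @param min_steps_per_window minimum MD steps per window (default
#'   2000, i.e. 1 ps at dt = 0.5 fs).
#' @param equilibration_fraction leading fraction of each window's
#'   multiplier trace discarded before averaging (default 0.2).
#' @return a `window_schedule` list.
#' @export
window_schedule <- function(points, min_steps_per_window = 2000L,
                            equilibration_fraction = 0.2) {
  d <- diff(points)
  if (length(points) < 1L || (length(d) && !(all(d > 0) || all(d < 0)))) {
    stop("schedule points must be strictly monotone")
  }
  stopifnot(min_steps_per_window >= 1L,
            equilibration_fraction >= 0, equilibration_fraction < 1)
  structure(list(points = points,
                 min_steps_per_window = as.integer(min_steps_per_window),
                 equilibration_fraction = equilibration_fraction),
            class = "window_schedule")
}

#' Parse a schedule string
#'
#' Format: comma-separated segments `from:to:by`, e.g. `"3.0:5.8:0.2"`
#' or the piecewise `"2.5:3.5:0.1,3.5:8.5:0.5"`.  Segment boundaries
#' shared between consecutive segments are not duplicated.
#'
#' @param s schedule string.
#' @param ... passed to [window_schedule()].
#' @return a `window_schedule`.
#' @examples
#' length(parse_schedule("3.0:5.8:0.2")$points)  # 15 windows
#' @export
parse_schedule <- function(s, ...) {
  segs <- strsplit(s, ",", fixed = TRUE)[[1]]
  pts <- numeric(0)
  for (seg in segs) {
    v <- suppressWarnings(as.numeric(strsplit(seg, ":", fixed = TRUE)[[1]]))
    if (length(v) != 3L || anyNA(v) || v[3] <= 0) {
      stop("malformed schedule segment '", seg, "' (expected from:to:by)")
    }
    p <- seq(v[1], v[2], by = if (v[2] >= v[1]) v[3] else -v[3])
    if (length(pts) && abs(pts[length(pts)] - p[1]) < 1e-12) p <- p[-1]
    pts <- c(pts, p)
  }
  window_schedule(pts, ...)
}

#' Mean constraint force from a Lagrange-multiplier trace
#'
#' Discards the leading `equilibration_fraction` of the trace, then
#' block-averages the remainder (default 5 blocks); the standard error
#' is that of the block means.  The running average of the retained
#' samples is also returned for convergence inspection.
#'
#' @param lambda_trace numeric vector of per-step multipliers,
#'   kJ/mol/Å; length > 10.
#' @param equilibration_fraction discarded leading fraction.
#' @param blocks number of blocks for the error estimate.
#' @return list with `mean`, `stderr`, `n`, `running` (running-average
#'   series) and `constant` (TRUE when every retained sample is
#'   identical, in which case `stderr` is exactly 0).
#' @export
mean_constraint_force <- function(lambda_trace,
                                  equilibration_fraction = 0.2,
                                  blocks = 5L) {
  m <- length(lambda_trace)
  if (m <= 10L) stop("multiplier trace too short (need > 10 samples)")
  keep <- lambda_trace[(floor(m * equilibration_fraction) + 1L):m]
  n <- length(keep)
  mu <- mean(keep)
  constant <- all(keep == keep[1L])
  if (constant) {
    se <- 0
  } else {
    bl <- split(keep, cut(seq_len(n), blocks, labels = FALSE))
    bm <- vapply(bl, mean, numeric(1))
    se <- stats::sd(bm) / sqrt(length(bm))
  }
  list(mean = mu, stderr = se, n = n,
       running = cumsum(keep) / seq_len(n), constant = constant)
}

#' Trapezoidal thermodynamic integration
#'
#' Cumulative trapezoid of the mean force over the window centres;
#' `delta_A` is zero at the first window.  Reversing the window order
#' negates the end-to-end free-energy difference exactly.
#'
#' @param D window centres, Å (strictly monotone).
#' @param mean_force mean constraint force per window, kJ/mol/Å.
#' @param stderr optional per-window standard errors (propagated to a
#'   profile error by independent-window quadrature).
#' @return a `free_energy_profile`: data.frame-like list with `D`,
#'   `mean_force`, `stderr`, `delta_A`, `delta_A_err`, `Dmin`, `Dmax`.
#' @export
ti_integrate <- function(D, mean_force, stderr = NULL) {
  if (length(D) < 2L) stop("need >= 2 windows to integrate")
  d <- diff(D)
  if (!(all(d > 0) || all(d < 0))) stop("window centres must be monotone")
  if (length(mean_force) != length(D)) {
    stop("mean_force and D lengths differ")
  }
  h <- diff(D)
  incr <- h * (mean_force[-length(D)] + mean_force[-1L]) / 2
  dA <- c(0, cumsum(incr))
  err <- if (!is.null(stderr)) {
    w <- numeric(length(D))
    w[1L] <- h[1L] / 2
    if (length(D) > 2L) {
      w[2:(length(D) - 1L)] <- (h[-length(h)] + h[-1L]) / 2
    }
    w[length(D)] <- h[length(h)] / 2
    sqrt(cumsum(c(0, (w[-1L] * stderr[-1L])^2)) + (w[1L] * stderr[1L])^2)
  } else rep(NA_real_, length(D))
  structure(list(D = D, mean_force = mean_force,
                 stderr = if (is.null(stderr)) rep(NA_real_, length(D))
                 else stderr,
                 delta_A = dA, delta_A_err = err,
                 Dmin = min(D), Dmax = max(D)),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  n <- length(x$D)
  cat(sprintf(paste0("<free_energy_profile> %d windows, D in [%.2f, %.2f]",
                     " Å, ΔA(end) = %.2f kJ/mol\n"),
              n, x$Dmin, x$Dmax, x$delta_A[n]))
  invisible(x)
}

#' @export
as.data.frame.free_energy_profile <- function(x, ...) {
  data.frame(D = x$D, mean_force = x$mean_force, stderr = x$stderr,
             delta_A = x$delta_A, delta_A_err = x$delta_A_err)
}

#' Run thermodynamic integration over a window schedule
#'
#' Optionally pre-equilibrates at the first window, then for each window
#' jumps the constraint target to the next D value, runs at least
#' `min_steps_per_window` steps, and collects the multiplier trace.  The
#' equilibration fraction of each window is discarded when averaging.
#'
#' @param topo a [toy_topology()].
#' @param conf a [configuration()]; its dynamic distance should be near
#'   the first schedule point (it is projected onto it exactly).
#' @param spec a [dd_spec()].
#' @param schedule a [window_schedule()] (or string for
#'   [parse_schedule()]).
#' @param dt time step, fs.
#' @param thermostat thermostat (default Nose-Hoover chain).
#' @param temperature K.
#' @param pre_steps extra equilibration steps at the first window before
#'   any averaging (default 1000, i.e. 500 fs at dt = 0.5).
#' @param seed RNG seed for stochastic thermostats.
#' @param keep_frames save the last frame of each window.
#' @return list with `profile` (a `free_energy_profile`), `windows`
#'   (per-window data.frame: D, mean force, stderr, steps), `traces`
#'   (list of per-window multiplier traces), `conf` (final
#'   configuration), `failed` (manifest of windows that did not run, if
#'   any).
#' @export
run_ti <- function(topo, conf, spec, schedule, dt = 0.5,
                   thermostat = nose_hoover_chain(), temperature = 300,
                   pre_steps = 1000L, seed = NULL, keep_frames = FALSE) {
  if (is.character(schedule)) schedule <- parse_schedule(schedule)
  pts <- schedule$points
  nw <- length(pts)
  conf <- project_to_constraint(conf, spec, pts[1L])
  if (pre_steps > 0L) {
    res <- run_nvt(topo, conf, steps = pre_steps, dt = dt,
                   thermostat = thermostat, temperature = temperature,
                   spec = spec, target = pts[1L],
                   seed = if (is.null(seed)) NULL else seed)
    conf <- res$conf
  }
  traces <- vector("list", nw)
  frames <- if (keep_frames) vector("list", nw) else NULL
  mf <- se <- rep(NA_real_, nw)
  failed <- character(0)
  for (k in seq_len(nw)) {
    res <- tryCatch(
      run_nvt(topo, conf, steps = schedule$min_steps_per_window, dt = dt,
              thermostat = thermostat, temperature = temperature,
              spec = spec, target = pts[k],
              seed = if (is.null(seed)) NULL else seed + k),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, sprintf("window %d (D = %.3f): %s", k, pts[k],
                                  conditionMessage(res)))
      break
    }
    conf <- res$conf
    traces[[k]] <- res$trace$lambda
    st <- mean_constraint_force(res$trace$lambda,
                                schedule$equilibration_fraction)
    mf[k] <- st$mean
    se[k] <- st$stderr
    if (keep_frames) frames[[k]] <- conf$pos
  }
  ok <- !is.na(mf)
  profile <- if (sum(ok) >= 2L) {
    ti_integrate(pts[ok], mf[ok], se[ok])
  } else {
    structure(list(D = pts[ok], mean_force = mf[ok], stderr = se[ok],
                   delta_A = rep(0, sum(ok)),
                   delta_A_err = rep(0, sum(ok)),
                   Dmin = if (any(ok)) min(pts[ok]) else NA_real_,
                   Dmax = if (any(ok)) max(pts[ok]) else NA_real_),
              class = "free_energy_profile")
  }
  list(profile = profile,
       windows = data.frame(D = pts, mean_force = mf, stderr = se,
                            steps = schedule$min_steps_per_window),
       traces = traces, conf = conf, frames = frames,
       failed = if (length(failed)) failed else NULL)
}

#' Closed-form constrained free energy of the harmonic dimer
#'
#' For two particles bound by a harmonic spring `U(r) = k (r - r0)^2 / 2`
#' and a rigidly constrained separation r in three dimensions, the
#' configurational density is proportional to `r^2 exp(-U(r)/kB T)`
#' (the `r^2` factor is the angular volume swept by the rotating pair),
#' so the free-energy profile is
#' \deqn{A(r) = U(r) - 2 k_B T \ln r + C .}
#' Equivalently, the mean constraint force is
#' `dA/dr = k (r - r0) - 2 kB T / r`, the second term being the
#' centrifugal contribution of the two rotational degrees of freedom.
#' This is the independent oracle against which the thermodynamic
#' integration machinery is validated; the metric (Fixman) correction
#' vanishes for a two-particle distance constraint because the
#' constraint metric is a constant.
#'
#' @param k spring constant, kJ/mol/Å².
#' @param r0 equilibrium length, Å.
#' @param temperature K.
#' @param r evaluation grid, Å.
#' @param ref reference distance at which A is zeroed (default `r[1]`).
#' @return data.frame with `r`, `A` (kJ/mol, A(ref) = 0) and
#'   `mean_force` (dA/dr).
#' @export
dimer_free_energy_oracle <- function(k, r0, temperature, r,
                                     ref = r[1L]) {
  stopifnot(k > 0, temperature > 0, all(r > 0))
  kt <- .kB * temperature
  A <- 0.5 * k * (r - r0)^2 - 2 * kt * log(r)
  A0 <- 0.5 * k * (ref - r0)^2 - 2 * kt * log(ref)
  data.frame(r = r, A = A - A0,
             mean_force = k * (r - r0) - 2 * kt / r)
}
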