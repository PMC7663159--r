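#' Dynamic-distance collective variable specification
#'
#' The dynamic distance is a single scalar collective variable defined over
#' a set of non-overlapping atom pairs (NOP):
#' \deqn{D = \sqrt{\sum_{(i,j)} \frac{\mu_{ij}}{\mu^*} |r_i - r_j|^2}}
#' where \eqn{\mu_{ij} = m_i m_j/(m_i+m_j)} is the reduced mass of pair
#' \eqn{(i,j)} and \eqn{\mu^* = \sum \mu_{ij}}.  Holding D fixed during MD
#' controls the collective hydrogen-bond/coordination structure while
#' letting individual pair distances trade against each other.
#'
#' Pairs must be non-overlapping: no atom may appear in two pairs,
#' otherwise the constraint gradient entries would not decouple pairwise.
#'
#' @param pairs two-column integer matrix of atom index pairs.
#' @param masses per-atom masses (amu) of the parent configuration, used to
#'   compute the reduced masses.
#' @param variant one of `"EQUI"`, `"DNA"`, `"ISO"`, or `"custom"`; a tag
#'   recording which pair-selection rule produced the spec.
#' @return object of class `"dd_spec"`: list with `pairs`, `mu` (per-pair
#'   reduced masses), `mu_star`, `w` (normalized weights `mu/mu_star`),
#'   `variant`.
#' @seealso [dynamic_distance()], [select_constraint_pairs()]
#' @export
dd_spec <- function(pairs, masses, variant = "custom") {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (nrow(pairs) == 0L) stop("empty pair list: a dd_spec needs >= 1 pair")
  idx <- as.vector(pairs)
  if (any(idx < 1L) || any(idx > length(masses))) {
    stop("pair indices out of range")
  }
  if (anyDuplicated(idx)) {
    dup <- unique(idx[duplicated(idx)])
    stop("pairs overlap: atom(s) ", paste(dup, collapse = ", "),
         " appear in more than one pair")
  }
  mu <- reduced_mass(masses[pairs[, 1L]], masses[pairs[, 2L]])
  mu_star <- sum(mu)
  structure(list(pairs = pairs, mu = mu, mu_star = mu_star,
                 w = mu / mu_star, variant = variant),
            class = "dd_spec")
}

#' @export
print.dd_spec <- function(x, ...) {
  cat(sprintf("<dd_spec> variant %s: %d pairs, mu* = %.5f amu\n",
              x$variant, nrow(x$pairs), x$mu_star))
  invisible(x)
}

## raw pair vectors and squared distances; shared by value and gradient
.dd_pairvec <- function(spec, pos) {
  dv <- pos[spec$pairs[, 1L], , drop = FALSE] -
    pos[spec$pairs[, 2L], , drop = FALSE]
  list(dv = dv, d2 = rowSums(dv * dv))
}

#' Evaluate the dynamic distance
#'
#' @param spec a [dd_spec()].
#' @param conf a [configuration()], or an N x 3 position matrix.
#' @return D in Å (scalar).
#' @examples
#' conf <- configuration(rbind(c(0, 0, 0), c(1.88, 0, 0)),
#'                       masses = c(14.007, 1.008), elements = c("N", "H"))
#' spec <- dd_spec(cbind(1, 2), conf$mass)
#' dynamic_distance(spec, conf)  # 1.88: single pair reduces to its distance
#' @export
dynamic_distance <- function(spec, conf) {
  pos <- if (inherits(conf, "configuration")) conf$pos else as.matrix(conf)
  pv <- .dd_pairvec(spec, pos)
  sqrt(sum(spec$w * pv$d2))
}

#' Per-pair contributions to the dynamic distance
#'
#' Returns, for each constrained pair, its plain Euclidean distance, its
#' weight \eqn{\mu_{ij}/\mu^*} and its contribution to \eqn{D^2}.
#'
#' @inheritParams dynamic_distance
#' @return data.frame with columns `i`, `j`, `dist`, `weight`, `contrib`.
#' @export
dd_contributions <- function(spec, conf) {
  pos <- if (inherits(conf, "configuration")) conf$pos else as.matrix(conf)
  pv <- .dd_pairvec(spec, pos)
  data.frame(i = spec$pairs[, 1L], j = spec$pairs[, 2L],
             dist = sqrt(pv$d2), weight = spec$w,
             contrib = spec$w * pv$d2)
}

#' Analytic gradient of the dynamic distance
#'
#' For atom i of pair (i, j):
#' \eqn{\partial D/\partial r_i = (\mu_{ij} / (\mu^* D)) (r_i - r_j)},
#' the negative for atom j, and exactly zero for atoms in no pair.
#'
#' @inheritParams dynamic_distance
#' @return N x 3 matrix (dimensionless, Å/Å).
#' @export
dynamic_distance_gradient <- function(spec, conf) {
  pos <- if (inherits(conf, "configuration")) conf$pos else as.matrix(conf)
  pv <- .dd_pairvec(spec, pos)
  D <- sqrt(sum(spec$w * pv$d2))
  if (D <= 0) stop("dynamic distance is zero: gradient is singular")
  g <- matrix(0, nrow(pos), 3L)
  gi <- (spec$w / D) * pv$dv
  g[spec$pairs[, 1L], ] <- gi
  g[spec$pairs[, 2L], ] <- -gi
  g
}
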