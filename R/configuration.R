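#' Atomic configuration
#'
#' A lightweight container for a point in phase space: positions,
#' velocities, masses and per-atom labels.  All MD and analysis routines
#' in the package operate on this object.
#'
#' @param positions N x 3 numeric matrix, Å.
#' @param masses length-N numeric, amu, strictly positive.
#' @param elements length-N character, element symbols.
#' @param labels length-N character, site/role labels (e.g. `"T7-O4"`).
#'   Defaults to the element symbols.
#' @param velocities N x 3 numeric matrix, Å/fs.  Defaults to zero.
#' @param fixed length-N logical; `TRUE` atoms are excluded from
#'   integration (infinitely heavy scaffold sites).  Defaults to all free.
#' @return an object of class `"configuration"`: a list with elements
#'   `pos`, `vel`, `mass`, `element`, `label`, `fixed`.
#' @examples
#' conf <- configuration(rbind(c(0, 0, 0), c(1, 0, 0)),
#'                       masses = c(14.007, 1.008), elements = c("N", "H"))
#' conf$mass
#' @export
configuration <- function(positions, masses, elements,
                          labels = elements,
                          velocities = NULL, fixed = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be an N x 3 matrix")
  n <- nrow(positions)
  if (length(masses) != n) stop("length(masses) must match nrow(positions)")
  if (any(!is.finite(masses)) || any(masses <= 0)) {
    stop("all masses must be finite and > 0")
  }
  if (length(elements) != n) stop("length(elements) must match positions")
  if (length(labels) != n) stop("length(labels) must match positions")
  if (is.null(velocities)) velocities <- matrix(0, n, 3L)
  velocities <- as.matrix(velocities)
  if (!all(dim(velocities) == c(n, 3L))) stop("velocities must be N x 3")
  if (is.null(fixed)) fixed <- rep(FALSE, n)
  if (length(fixed) != n) stop("length(fixed) must match positions")
  structure(list(pos = unname(positions), vel = unname(velocities),
                 mass = as.numeric(masses), element = as.character(elements),
                 label = as.character(labels), fixed = as.logical(fixed)),
            class = "configuration")
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf("<configuration> %d atoms (%d fixed), elements: %s\n",
              nrow(x$pos), sum(x$fixed),
              paste(names(sort(table(x$element), decreasing = TRUE)),
                    collapse = " ")))
  invisible(x)
}

#' Number of atoms in a configuration
#' @param conf a [configuration()].
#' @return integer atom count.
#' @export
n_atoms <- function(conf) nrow(conf$pos)

#' Look up atom indices by label
#'
#' @param conf a [configuration()].
#' @param labels character vector of site labels to resolve.
#' @return integer vector of atom indices.
#' @export
atom_index <- function(conf, labels) {
  idx <- match(labels, conf$label)
  if (anyNA(idx)) {
    stop("site label(s) not present: ",
         paste(labels[is.na(idx)], collapse = ", "))
  }
  idx
}
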