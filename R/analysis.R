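#' @title Structural trajectory analyses
#' @description
#' Observables of the dinuclear Hg(II)-mediated base pair and its
#' surroundings: classification of the Hg coordination (bonding
#' pattern), oscillation statistics, site-site distance traces (including
#' the proton-transfer monitor and the C1'...C1' pair width), the
#' out-of-plane pyramidalization angle of amino nitrogens, and the
#' "turnstile" dihedral of an amino group rotating about its C6-N6 bond.
#' @name structure_analysis
NULL

#' Build a site map from site labels
#'
#' Labels follow the `<base><resid>-<site>` convention used throughout
#' the package (e.g. `"T7-O4"`, `"eA20-N7"`); bare labels (`"Hg1"`,
#' `"Na+3"`) map to site-only entries.
#'
#' @param labels character vector of atom labels.
#' @param elements element symbols of the same length.
#' @return data.frame with `index`, `label`, `element`, `base`, `resid`,
#'   `site`.
#' @export
parse_site_labels <- function(labels, elements) {
  n <- length(labels)
  base <- rep(NA_character_, n); resid <- rep(NA_integer_, n)
  site <- labels
  hit <- regmatches(labels, regexec("^([A-Za-z]+)([0-9]+)-(.+)$", labels))
  for (k in seq_len(n)) {
    if (length(hit[[k]]) == 4L) {
      base[k] <- hit[[k]][2L]
      resid[k] <- as.integer(hit[[k]][3L])
      site[k] <- hit[[k]][4L]
    }
  }
  data.frame(index = seq_len(n), label = labels, element = elements,
             base = base, resid = resid, site = site)
}

## resolve a label or index against a site map
.resolve_site <- function(smap, x) {
  if (is.numeric(x)) return(as.integer(x))
  idx <- smap$index[match(x, smap$label)]
  if (anyNA(idx)) {
    stop("site label(s) not present: ",
         paste(x[is.na(idx)], collapse = ", "))
  }
  idx
}

.frame_positions <- function(frame) {
  if (inherits(frame, "configuration")) frame$pos else as.matrix(frame)
}

## identify the modified pair: the eA residue and its thymine partner
.modified_pair_resids <- function(smap, pos) {
  ea <- unique(smap$resid[!is.na(smap$base) & smap$base == "eA"])
  if (length(ea) != 1L) {
    stop("need exactly one eA residue in the site map (found ",
         length(ea), ")")
  }
  t_res <- unique(smap$resid[!is.na(smap$base) & smap$base == "T"])
  if (length(t_res) == 0L) stop("no thymine residues in the site map")
  if (length(t_res) > 1L && "level" %in% names(smap)) {
    ## the pairing partner shares the eA helix level
    lev_ea <- unique(smap$level[!is.na(smap$base) & smap$base == "eA"])
    cand <- unique(smap$resid[!is.na(smap$base) & smap$base == "T" &
                                smap$level %in% lev_ea])
    if (length(cand) == 1L) t_res <- cand
  }
  if (length(t_res) > 1L) {
    ## partner = thymine whose sites sit closest to the eA sites
    ea_idx <- smap$index[!is.na(smap$base) & smap$base == "eA"]
    cen_ea <- colMeans(pos[ea_idx, , drop = FALSE])
    d <- vapply(t_res, function(r) {
      ti <- smap$index[!is.na(smap$resid) & smap$resid == r]
      sum((colMeans(pos[ti, , drop = FALSE]) - cen_ea)^2)
    }, numeric(1))
    t_res <- t_res[which.min(d)]
  }
  list(eA = ea, T = t_res)
}

#' Classify the Hg bonding pattern of one frame
#'
#' Each Hg's coordination sphere is the set of base N/O acceptor sites
#' within `dist_cutoff`.  Patterns:
#' \describe{
#' \item{NO}{Hg1 bridges eA-N7/T-O4 and Hg2 bridges eA-N6/T-O2 (the
#'   pattern of the isolated-pair minimum).}
#' \item{NN}{Hg1 bridges eA-N7/T-N3 (the stacked-pair minimum).}
#' \item{CROSS_TT}{an Hg bridges the N3 atoms of two different
#'   thymines (inter-planar T-Hg-T pair).}
#' \item{A_EA}{an Hg bridges an adenine N1 and an eA nitrogen
#'   (A-Hg-eA pair).}
#' \item{DISSOCIATED}{either Hg has fewer than two base acceptors in
#'   the cutoff.}
#' \item{OTHER}{anything else.}
#' }
#' When several patterns match, the one with the smaller summed
#' coordinate-bond distance wins.
#'
#' @param frame a [configuration()] or N x 3 position matrix.
#' @param site_map a site map ([duplex_site_map()] /
#'   [parse_site_labels()]).
#' @param dist_cutoff coordination cutoff, Å (default 2.6, between the
#'   2.12-2.20 Å coordinate-bond medians and the 2.8 Å broken-bond
#'   mark).
#' @return a `bonding_pattern`: list with `label`, `coordination`
#'   (per-Hg data.frame of in-cutoff sites and distances) and
#'   `candidates` (matched patterns with scores).
#' @export
classify_pattern <- function(frame, site_map, dist_cutoff = 2.6) {
  pos <- .frame_positions(frame)
  smap <- site_map
  hg_idx <- smap$index[smap$element == "Hg"]
  if (length(hg_idx) < 1L) stop("no Hg sites in the site map")
  names(hg_idx) <- smap$site[match(hg_idx, smap$index)]
  mp <- .modified_pair_resids(smap, pos)
  need <- c(sprintf("eA%d-N7", mp$eA), sprintf("eA%d-N6", mp$eA),
            sprintf("T%d-O4", mp$T), sprintf("T%d-O2", mp$T),
            sprintf("T%d-N3", mp$T))
  missing <- setdiff(need, smap$label)
  if (length(missing)) {
    stop("site map lacks required sites: ",
         paste(missing, collapse = ", "))
  }
  acc <- smap[smap$element %in% c("N", "O") & !is.na(smap$base), ]
  coord <- lapply(hg_idx, function(h) {
    dv <- sweep(pos[acc$index, , drop = FALSE], 2L, pos[h, ])
    d <- sqrt(rowSums(dv * dv))
    k <- d <= dist_cutoff
    data.frame(label = acc$label[k], base = acc$base[k],
               resid = acc$resid[k], site = acc$site[k], dist = d[k])
  })
  dissoc <- any(vapply(coord, nrow, integer(1)) < 2L)
  dist_to <- function(h, lab) {
    cc <- coord[[h]]
    i <- match(lab, cc$label)
    if (is.na(i)) NA_real_ else cc$dist[i]
  }
  cand <- list()
  if (!dissoc && all(c("Hg1", "Hg2") %in% names(hg_idx))) {
    ## NO: both bridges of the isolated-pair minimum
    d_no <- c(dist_to("Hg1", sprintf("eA%d-N7", mp$eA)),
              dist_to("Hg1", sprintf("T%d-O4", mp$T)),
              dist_to("Hg2", sprintf("eA%d-N6", mp$eA)),
              dist_to("Hg2", sprintf("T%d-O2", mp$T)))
    if (!anyNA(d_no)) cand$NO <- sum(d_no)
    ## NN: Hg1 between eA-N7 and T-N3
    d_nn <- c(dist_to("Hg1", sprintf("eA%d-N7", mp$eA)),
              dist_to("Hg1", sprintf("T%d-N3", mp$T)))
    if (!anyNA(d_nn)) cand$NN <- sum(d_nn)
  }
  if (!dissoc) {
    for (h in names(hg_idx)) {
      cc <- coord[[h]]
      tn3 <- cc[cc$base == "T" & cc$site == "N3", ]
      if (nrow(tn3) >= 2L && length(unique(tn3$resid)) >= 2L) {
        sc <- sum(sort(tn3$dist)[1:2])
        if (is.null(cand$CROSS_TT) || sc < cand$CROSS_TT) {
          cand$CROSS_TT <- sc
        }
      }
      an1 <- cc[cc$base == "A" & cc$site == "N1", ]
      ean <- cc[cc$base == "eA" & cc$site %in% c("N6", "N3"), ]
      if (nrow(an1) >= 1L && nrow(ean) >= 1L) {
        sc <- min(an1$dist) + min(ean$dist)
        if (is.null(cand$A_EA) || sc < cand$A_EA) cand$A_EA <- sc
      }
    }
  }
  label <- if (dissoc) "DISSOCIATED" else if (length(cand)) {
    names(cand)[which.min(unlist(cand))]
  } else "OTHER"
  structure(list(label = label, coordination = coord,
                 candidates = unlist(cand)),
            class = "bonding_pattern")
}

#' @export
print.bonding_pattern <- function(x, ...) {
  cat("<bonding_pattern>", x$label, "\n")
  for (h in names(x$coordination)) {
    cc <- x$coordination[[h]]
    cat(sprintf("  %s: %s\n", h,
                if (nrow(cc)) paste(sprintf("%s (%.2f Å)", cc$label,
                                            cc$dist), collapse = ", ")
                else "(no acceptors in cutoff)"))
  }
  invisible(x)
}

#' Bonding-pattern time series, oscillation count and residence times
#'
#' Classifies every frame, applies a centred majority filter of width
#' `debounce` (so single-frame flickers do not count as transitions),
#' and reports the number of label changes and per-label residence
#' statistics.
#'
#' @param frames list of frames (position matrices or configurations).
#' @param site_map site map (see [classify_pattern()]).
#' @param dist_cutoff coordination cutoff, Å.
#' @param debounce odd window width of the majority filter (default 3;
#'   1 disables filtering).
#' @return list with `labels` (raw), `filtered`, `transitions`,
#'   `residence` (data.frame: label, visits, total_frames,
#'   mean_residence).
#' @export
pattern_timeseries <- function(frames, site_map, dist_cutoff = 2.6,
                               debounce = 3L) {
  if (length(frames) < 1L) stop("need at least one frame")
  raw <- vapply(frames, function(f) {
    classify_pattern(f, site_map, dist_cutoff)$label
  }, character(1))
  filt <- raw
  half <- (debounce - 1L) %/% 2L
  if (half > 0L && length(raw) >= debounce) {
    for (i in seq_along(raw)) {
      lo <- max(1L, i - half); hi <- min(length(raw), i + half)
      tab <- table(raw[lo:hi])
      top <- names(tab)[tab == max(tab)]
      filt[i] <- if (length(top) == 1L) top else raw[i]
    }
  }
  r <- rle(filt)
  res <- data.frame(label = r$values, frames = r$lengths)
  agg <- stats::aggregate(frames ~ label, data = res, FUN = sum)
  cnt <- stats::aggregate(frames ~ label, data = res, FUN = length)
  residence <- data.frame(label = agg$label, visits = cnt$frames,
                          total_frames = agg$frames,
                          mean_residence = agg$frames / cnt$frames)
  list(labels = raw, filtered = filt,
       transitions = length(r$values) - 1L, residence = residence)
}

#' Site-site distance trace
#'
#' Per-frame Euclidean distance between two named sites, with the
#' summary statistics used for coordinate-bond medians, the
#' proton-transfer monitor (N3...H vs N3...Hg) and the C1'...C1' pair
#' width.  Both the full-trace and tail (last half) medians are
#' reported.
#'
#' @param frames list of frames, or a single frame.
#' @param site_map site map used to resolve labels.
#' @param site_a,site_b labels (or atom indices) of the two sites.
#' @return list with `dist` (per-frame series), `median`,
#'   `median_tail`, `min`, `max`.
#' @export
pair_distance_trace <- function(frames, site_map, site_a, site_b) {
  if (!is.list(frames)) frames <- list(frames)
  ia <- .resolve_site(site_map, site_a)
  ib <- .resolve_site(site_map, site_b)
  d <- vapply(frames, function(f) {
    pos <- .frame_positions(f)
    sqrt(sum((pos[ia, ] - pos[ib, ])^2))
  }, numeric(1))
  tail_part <- d[max(1L, floor(length(d) / 2) + 1L):length(d)]
  list(dist = d, median = stats::median(d),
       median_tail = stats::median(tail_part),
       min = min(d), max = max(d))
}

#' Pyramidalization angle of a trivalent nitrogen
#'
#' The out-of-plane (improper) angle between the N-substituent3 bond and
#' the plane through substituent1, N, substituent2: 0° for a planar
#' sp2 centre, ~54.7° for an ideal tetrahedral sp3 centre.
#'
#' @param frame a frame (positions or configuration).
#' @param site_map site map.
#' @param n_site the nitrogen label/index.
#' @param sub_sites three substituent labels/indices; the third defines
#'   the out-of-plane bond.
#' @return angle in degrees, or NA (with a warning) when the plane atoms
#'   are collinear.
#' @export
pyramidalization <- function(frame, site_map, n_site, sub_sites) {
  stopifnot(length(sub_sites) == 3L)
  pos <- .frame_positions(frame)
  iN <- .resolve_site(site_map, n_site)
  is <- vapply(sub_sites, function(s) .resolve_site(site_map, s),
               integer(1))
  if (anyDuplicated(c(iN, is))) stop("the four sites must be distinct")
  v1 <- pos[is[1L], ] - pos[iN, ]
  v2 <- pos[is[2L], ] - pos[iN, ]
  v3 <- pos[is[3L], ] - pos[iN, ]
  nrm <- c(v1[2L] * v2[3L] - v1[3L] * v2[2L],
           v1[3L] * v2[1L] - v1[1L] * v2[3L],
           v1[1L] * v2[2L] - v1[2L] * v2[1L])
  nn <- sqrt(sum(nrm^2))
  if (nn < 1e-10 * sqrt(sum(v1^2)) * sqrt(sum(v2^2))) {
    warning("plane substituents are collinear; angle undefined")
    return(NA_real_)
  }
  s <- sum(v3 * nrm) / (nn * sqrt(sum(v3^2)))
  asin(max(-1, min(1, abs(s)))) * 180 / pi
}

## signed dihedral a-b-c-d in degrees
.dihedral <- function(pa, pb, pc, pd) {
  b1 <- pb - pa; b2 <- pc - pb; b3 <- pd - pc
  n1 <- c(b1[2L] * b2[3L] - b1[3L] * b2[2L],
          b1[3L] * b2[1L] - b1[1L] * b2[3L],
          b1[1L] * b2[2L] - b1[2L] * b2[1L])
  n2 <- c(b2[2L] * b3[3L] - b2[3L] * b3[2L],
          b2[3L] * b3[1L] - b2[1L] * b3[3L],
          b2[1L] * b3[2L] - b2[2L] * b3[1L])
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) return(NA_real_)
  m1 <- n1 / sqrt(sum(n1^2))
  b2u <- b2 / sqrt(sum(b2^2))
  x <- sum(m1 * n2) / sqrt(sum(n2^2))
  y <- sum((c(m1[2L] * b2u[3L] - m1[3L] * b2u[2L],
              m1[3L] * b2u[1L] - m1[1L] * b2u[3L],
              m1[1L] * b2u[2L] - m1[2L] * b2u[1L])) * n2 /
             sqrt(sum(n2^2)))
  atan2(y, x) * 180 / pi
}

#' Unwrap an angular series
#'
#' Removes artificial ±360° jumps when a dihedral crosses the ±180°
#' branch cut, so cumulative rotation can be read off directly.
#'
#' @param theta angle series, degrees (may contain NA for degenerate
#'   frames; NAs are carried through).
#' @return unwrapped series, degrees.
#' @export
unwrap_angles <- function(theta) {
  out <- theta
  last <- NA_real_; offset <- 0
  for (i in seq_along(theta)) {
    if (is.na(theta[i])) next
    if (!is.na(last)) {
      d <- theta[i] + offset - last
      if (d > 180) offset <- offset - 360
      else if (d < -180) offset <- offset + 360
    }
    out[i] <- theta[i] + offset
    last <- out[i]
  }
  out
}

#' Turnstile dihedral of an amino group
#'
#' Tracks the signed dihedral `ref1 - C6 - N6 - ref2` about the C6-N6
#' single bond across a trajectory (unwrapped), the rotation of the
#' amino group that carries a coordinated Hg(II) between the DNA core
#' and the solvent.  Degenerate frames (collinear geometry) are masked
#' as NA.
#'
#' @param frames list of frames.
#' @param site_map site map.
#' @param ring_site ring reference atom (defines the zero), e.g. the
#'   base N1.
#' @param c_site,n_site the C6 and N6 labels/indices of the rotating
#'   bond.
#' @param ref_site the atom riding on the amino group (an amino H, or
#'   the coordinated Hg).
#' @return list with `dihedral` (raw series, deg), `unwrapped`,
#'   `total_rotation` (deg) and `masked` (count of degenerate frames).
#' @export
turnstile_dihedral <- function(frames, site_map, ring_site, c_site,
                               n_site, ref_site) {
  ia <- .resolve_site(site_map, ring_site)
  ib <- .resolve_site(site_map, c_site)
  ic <- .resolve_site(site_map, n_site)
  id <- .resolve_site(site_map, ref_site)
  th <- vapply(frames, function(f) {
    pos <- .frame_positions(f)
    .dihedral(pos[ia, ], pos[ib, ], pos[ic, ], pos[id, ])
  }, numeric(1))
  un <- unwrap_angles(th)
  ok <- !is.na(un)
  total <- if (sum(ok) >= 2L) un[max(which(ok))] - un[min(which(ok))] else 0
  list(dihedral = th, unwrapped = un, total_rotation = total,
       masked = sum(!ok))
}
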