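#' @title Coarse duplex geometry builder
#' @description
#' Builds idealized coarse-grained DNA duplex models: each nucleotide is a
#' rigid planar template of its named donor/acceptor sites plus the
#' glycosidic C1' and one backbone phosphate bead, placed on an ideal
#' fiber helix (default B-DNA rise 3.38 Å, twist 36 deg).  The builder
#' supports the construction route for parallel-stranded,
#' isoguanine-containing duplexes bearing a central dinuclear
#' Hg(II)-mediated thymine:1,N6-ethenoadenine base pair: build an
#' antiparallel duplex, flip one strand to obtain parallel-stranded DNA,
#' exchange the exocyclic O/NH2 groups of all guanines (isoguanine), and
#' replace the central A:T pair by the mercurated pair.
#' @name geometry_builder
NULL

## half of the C1'-C1' span of a pair (Angstrom)
.C1C1_HALF <- 5.2

## planar base templates: local frame with C1' at the origin and the
## Watson-Crick edge pointing towards +x.  Distances are tuned so that
## paired donor-H...acceptor separations come out near 1.9 Angstrom.
.BASE_TEMPLATES <- list(
  A = data.frame(
    site = c("C1'", "N1", "C6", "N6", "H61", "H62", "N7", "N3", "P"),
    element = c("C", "N", "C", "N", "H", "H", "N", "N", "P"),
    bx = c(0, 4.2, 2.8, 3.7, 4.7, 3.3, 1.9, 1.8, -1.1),
    by = c(0, 0, 1.0, 1.7, 1.7, 2.55, 2.1, -1.7, 2.2)),
  T = data.frame(
    site = c("C1'", "O2", "N3", "H3", "O4", "P"),
    element = c("C", "O", "N", "H", "O", "P"),
    bx = c(0, 3.8, 3.3, 4.3, 3.8, -1.1),
    by = c(0, -1.7, 0, 0, 1.7, 2.2)),
  G = data.frame(
    site = c("C1'", "N1", "H1", "O6", "N2", "H21", "H22", "N7", "N3", "P"),
    element = c("C", "N", "H", "O", "N", "H", "H", "N", "N", "P"),
    bx = c(0, 3.3, 4.3, 4.0, 4.0, 5.0, 3.5, 2.0, 1.6, -1.1),
    by = c(0, 0, 0, 1.8, -1.8, -1.8, -2.65, 2.3, -1.2, 2.2)),
  C = data.frame(
    site = c("C1'", "N3", "N4", "H41", "H42", "O2", "P"),
    element = c("C", "N", "N", "H", "H", "O", "P"),
    bx = c(0, 4.2, 3.5, 4.5, 3.1, 3.5, -1.1),
    by = c(0, 0, 1.8, 1.8, 2.65, -1.8, 2.2))
)

.COMPLEMENT <- c(A = "T", T = "A", G = "C", C = "G")

#' Planar template of a coarse base
#'
#' @param code one of `"A"`, `"T"`, `"G"`, `"C"`.
#' @return data.frame with columns `site`, `element`, `bx`, `by` (local
#'   in-plane coordinates, Å; C1' at the origin, pairing edge at +x).
#' @export
base_template <- function(code) {
  tpl <- .BASE_TEMPLATES[[code]]
  if (is.null(tpl)) stop("unknown base code: '", code, "'")
  tpl
}

## place local (bx, by) for a unit at helix level `level` (1-based)
.place_sites <- function(bx, by, strand, level, rise, twist,
                         orientation) {
  if (strand == 1L) {
    x0 <- -.C1C1_HALF + bx
    y0 <- by
  } else if (orientation == "antiparallel") {
    x0 <- .C1C1_HALF - bx
    y0 <- by
  } else {
    x0 <- .C1C1_HALF - bx
    y0 <- -by
  }
  th <- (level - 1) * twist * pi / 180
  cbind(x = x0 * cos(th) - y0 * sin(th),
        y = x0 * sin(th) + y0 * cos(th),
        z = (level - 1) * rise)
}

.new_duplex <- function(units, atoms, pairing, orientation, rise, twist) {
  atoms$serial <- seq_len(nrow(atoms))
  structure(list(units = units, atoms = atoms, pairing = pairing,
                 orientation = orientation, rise = rise, twist = twist),
            class = "duplex_model")
}

#' @export
print.duplex_model <- function(x, ...) {
  np <- nrow(x$pairing)
  cls <- table(x$pairing$pair_class)
  nion <- sum(x$atoms$site %in% c("Na+", "Cl-"))
  nhg <- sum(x$atoms$element == "Hg")
  cat(sprintf(
    "<duplex_model> %s, %d bp (%s), %d units, %d atoms, %d Hg, %d ions\n",
    x$orientation, np,
    paste(sprintf("%s:%d", names(cls), cls), collapse = " "),
    nrow(x$units), nrow(x$atoms), nhg, nion))
  cat(sprintf("  net charge %+d e\n", duplex_net_charge(x)))
  invisible(x)
}

#' Total charge of a duplex model
#' @param duplex a `duplex_model`.
#' @return integer net charge (e).
#' @export
duplex_net_charge <- function(duplex) {
  as.integer(round(sum(duplex$atoms$charge)))
}

#' Build an idealized antiparallel duplex
#'
#' Generates a coarse fiber-model helix for `seq1` (strand 1, 5'->3')
#' with the base-complementary antiparallel second strand.  Consecutive
#' pairs are separated by `rise` along the helix axis (+z) and rotated by
#' `twist`.  Residues are numbered 1..n along strand 1 and n+1..2n along
#' strand 2 from its own 5' end.
#'
#' Every unit carries one backbone phosphate bead (including the
#' 5'-terminal units, so a 13-mer duplex has 26 backbone charges).
#'
#' @param seq1 strand-1 base string, alphabet `ATGC`, 5'->3'.
#' @param rise helical rise, Å (default 3.38).
#' @param twist helical twist per step, degrees (default 36).
#' @return a `duplex_model` (orientation `"antiparallel"`).
#' @examples
#' d <- build_antiparallel_duplex("GAGGGATAGAAAG")
#' nrow(d$pairing)  # 13
#' @export
build_antiparallel_duplex <- function(seq1, rise = 3.38, twist = 36) {
  if (!nzchar(seq1)) stop("seq1 must be a nonempty base string")
  bases1 <- strsplit(toupper(seq1), "")[[1]]
  bad <- setdiff(unique(bases1), names(.COMPLEMENT))
  if (length(bad)) {
    stop("unknown base code '", bad[1L], "' in seq1 (alphabet is A,C,G,T)")
  }
  n <- length(bases1)
  units <- list(); atoms <- list()
  uid <- 0L
  for (i in seq_len(n)) {
    for (strand in 1:2) {
      uid <- uid + 1L
      code <- if (strand == 1L) bases1[i] else .COMPLEMENT[[bases1[i]]]
      pos5to3 <- if (strand == 1L) i else n + 1L - i
      resid <- if (strand == 1L) i else n + pos5to3
      tpl <- base_template(code)
      xyz <- .place_sites(tpl$bx, tpl$by, strand, i, rise, twist,
                          "antiparallel")
      units[[uid]] <- data.frame(unit_id = uid, base_code = code,
                                 strand = strand, pos5to3 = pos5to3,
                                 resid = resid, level = i,
                                 base_charge = 0L)
      atoms[[uid]] <- data.frame(unit_id = uid, site = tpl$site,
                                 element = tpl$element,
                                 x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                                 charge = ifelse(tpl$site == "P", -1, 0))
    }
  }
  pairing <- data.frame(level = seq_len(n), strand1_pos = seq_len(n),
                        strand2_pos = n + 1L - seq_len(n),
                        pair_class = ifelse(bases1 %in% c("A", "T"),
                                            "AT", "GC"))
  .new_duplex(do.call(rbind, units), do.call(rbind, atoms), pairing,
              "antiparallel", rise, twist)
}

#' Flip strand 2 to obtain a parallel-stranded duplex
#'
#' Reverses the direction of the second strand so that both strands run
#' 5'->3' along +z: every strand-2 nucleotide is rotated in place about
#' the local pair axis (presenting its reversed Watson-Crick edge to the
#' unchanged partner) and the strand's 5'->3' position and residue
#' numbering are re-indexed from the new 5' end.  Pairing partners are
#' preserved -- the strand-2 base pairing strand-1 position i is
#' position i after the flip -- so the duplex stays base-complementary;
#' the pairing geometry becomes reversed Watson-Crick, which is what the
#' subsequent isoguanine transform repairs for the G:C pairs.
#'
#' @param duplex an antiparallel `duplex_model`.
#' @return the parallel-stranded `duplex_model`.
#' @export
parallelize <- function(duplex) {
  if (duplex$orientation != "antiparallel") {
    stop("duplex is already parallel-stranded")
  }
  units <- duplex$units
  atoms <- duplex$atoms
  n <- nrow(duplex$pairing)
  for (uid in units$unit_id[units$strand == 2L]) {
    u <- units[units$unit_id == uid, ]
    sel <- units$unit_id == uid
    units$pos5to3[sel] <- n + 1L - u$pos5to3
    units$resid[sel] <- n + units$pos5to3[sel]
    tpl <- base_template(u$base_code)
    xyz <- .place_sites(tpl$bx, tpl$by, 2L, u$level, duplex$rise,
                        duplex$twist, "parallel")
    asel <- atoms$unit_id == uid
    stopifnot(identical(atoms$site[asel], tpl$site))
    atoms$x[asel] <- xyz[, 1L]; atoms$y[asel] <- xyz[, 2L]
    atoms$z[asel] <- xyz[, 3L]
  }
  pairing <- duplex$pairing
  pairing$strand2_pos <- pairing$strand1_pos
  .new_duplex(units, atoms, pairing, "parallel", duplex$rise, duplex$twist)
}

#' Transform all guanines into isoguanines (and back)
#'
#' Exchanges the exocyclic O6 and N2H2 groups of every guanine: the O6
#' and N2 coordinates are swapped and the amino hydrogens follow their
#' nitrogen.  Applying the operation twice restores the original
#' geometry (it is an involution).  Non-guanine units are untouched.
#'
#' @param duplex a `duplex_model`.
#' @return the transformed `duplex_model` with `G` units relabeled `iG`
#'   (or `iG` back to `G`).
#' @export
guanine_to_isoguanine <- function(duplex) {
  units <- duplex$units
  atoms <- duplex$atoms
  for (uid in units$unit_id[units$base_code %in% c("G", "iG")]) {
    sel <- which(atoms$unit_id == uid)
    st <- atoms$site[sel]
    i_o6 <- sel[st == "O6"]; i_n2 <- sel[st == "N2"]
    o6 <- unlist(atoms[i_o6, c("x", "y", "z")])
    n2 <- unlist(atoms[i_n2, c("x", "y", "z")])
    atoms[i_o6, c("x", "y", "z")] <- n2
    atoms[i_n2, c("x", "y", "z")] <- o6
    shift <- o6 - n2
    for (h in sel[st %in% c("H21", "H22")]) {
      atoms[h, c("x", "y", "z")] <- atoms[h, c("x", "y", "z")] + shift
    }
    units$base_code[units$unit_id == uid] <-
      if (units$base_code[units$unit_id == uid] == "G") "iG" else "G"
  }
  pairing <- duplex$pairing
  gc_levels <- units$level[units$strand == 1L & units$base_code == "iG"]
  pairing$pair_class[pairing$level %in% gc_levels &
                       pairing$pair_class == "GC"] <- "iGC"
  gc_back <- units$level[units$strand == 1L & units$base_code == "G"]
  pairing$pair_class[pairing$level %in% gc_back &
                       pairing$pair_class == "iGC"] <- "GC"
  .new_duplex(units, atoms, pairing, duplex$orientation, duplex$rise,
              duplex$twist)
}

#' Template of the dinuclear Hg(II)-mediated (or Hg-free) modified pair
#'
#' In-plane coordinates of the deprotonated thymine : 1,N6-ethenoadenine
#' pair in the pair frame (strand-1 thymine on the -x side).  In the
#' default NO coordination pattern Hg1 bridges eA-N7/T-O4 and Hg2
#' bridges eA-N6/T-O2, each coordinate bond at `hg_dist`.
#'
#' @param hg logical: include the two Hg(II) ions (and deprotonate
#'   thymine N3)?  `FALSE` gives the Hg-free analogue.
#' @param protonated logical: keep the thymine N3-H proton (only
#'   meaningful with `hg = FALSE`).
#' @param hg_dist Hg--N/O coordinate-bond distance, Å (default 2.15, the
#'   median coordinate-bond length of the mercurated pair).
#' @return list with data.frames `T`, `eA` (site, element, in-pair x, y)
#'   and `hg` (Hg positions, possibly empty).
#' @export
modified_pair_template <- function(hg = TRUE, protonated = !hg,
                                   hg_dist = 2.15) {
  if (hg && protonated) stop("the mercurated pair has N3 deprotonated")
  tT <- data.frame(
    site = c("C1'", "N3", "O4", "O2", "P"),
    element = c("C", "N", "O", "O", "P"),
    x = c(-5.2, -2.9, -2.4, -2.4, -6.3),
    y = c(0, 0, 1.7, -1.7, 2.2))
  if (protonated) {
    tT <- rbind(tT, data.frame(site = "H3", element = "H",
                               x = -1.9, y = 0))
  }
  teA <- data.frame(
    site = c("C1'", "N7", "N6", "N1", "C6", "P"),
    element = c("C", "N", "N", "N", "C", "P"),
    x = c(5.2, 1.9, 1.9, 3.4, 3.1, 6.3),
    y = c(0, 1.7, -1.7, 0.6, -1.2, 2.2))
  ## linear N/O--Hg--N/O bridges: Hg on the O4..N7 and O2..N6 axes
  mid_x <- (-2.4 + 1.9) / 2
  hgdf <- if (hg) {
    data.frame(site = c("Hg1", "Hg2"), element = "Hg",
               x = c(mid_x, mid_x), y = c(1.7, -1.7))
  } else {
    data.frame(site = character(0), element = character(0),
               x = numeric(0), y = numeric(0))
  }
  if (hg && abs((1.9 - (-2.4)) / 2 - hg_dist) > 1e-9) {
    ## template span fixed at 4.3; rescale donor sites along x about the
    ## bridge midpoint so each coordinate bond equals hg_dist
    sc <- hg_dist / 2.15
    for (nm in c("O4", "O2")) {
      k <- tT$site == nm
      tT$x[k] <- mid_x + (tT$x[k] - mid_x) * sc
    }
    for (nm in c("N7", "N6")) {
      k <- teA$site == nm
      teA$x[k] <- mid_x + (teA$x[k] - mid_x) * sc
    }
  }
  list(T = tT, eA = teA, hg = hgdf)
}

#' Replace an A:T pair by the modified T:eA (+/- Hg) pair
#'
#' The pair at helix level `position` must be A:T.  Thymine ends up on
#' whichever strand carried the T (for the packaged default sequence,
#' strand 1, residue 7) and 1,N6-ethenoadenine replaces the adenine
#' (residue 20 for the default).  With the default template the pair
#' carries two Hg(II) ions and a deprotonated thymine N3, raising the
#' base-pair charge to +3.
#'
#' @param duplex a `duplex_model`.
#' @param position helix level (pair index) to replace.
#' @param geometry a template from [modified_pair_template()].
#' @return the modified `duplex_model`.
#' @export
insert_modified_pair <- function(duplex, position,
                                 geometry = modified_pair_template()) {
  pr <- duplex$pairing[duplex$pairing$level == position, ]
  if (nrow(pr) != 1L) stop("no pair at position ", position)
  if (pr$pair_class != "AT") {
    stop("pair at position ", position, " is ", pr$pair_class,
         ", not A:T; the modified pair replaces an A:T pair")
  }
  units <- duplex$units
  atoms <- duplex$atoms
  atoms$serial <- NULL
  lvl_units <- units[units$level == position, ]
  tu <- lvl_units[lvl_units$base_code == "T", ]
  au <- lvl_units[lvl_units$base_code == "A", ]
  stopifnot(nrow(tu) == 1L, nrow(au) == 1L)
  ## the template is defined with T on the -x side; mirror if T sits on
  ## strand 2
  mirror <- tu$strand == 2L
  th <- (position - 1) * duplex$twist * pi / 180
  zlev <- (position - 1) * duplex$rise
  placed <- function(df) {
    x0 <- if (mirror) -df$x else df$x
    y0 <- df$y
    cbind(x = x0 * cos(th) - y0 * sin(th),
          y = x0 * sin(th) + y0 * cos(th),
          z = rep(zlev, length(x0)))
  }
  replace_unit <- function(uid, tpl, code, deprot) {
    xyz <- placed(tpl)
    atoms <<- atoms[atoms$unit_id != uid, ]
    atoms <<- rbind(atoms, data.frame(
      unit_id = uid, site = tpl$site, element = tpl$element,
      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
      charge = ifelse(tpl$site == "P", -1,
                      ifelse(deprot & tpl$site == "N3", -1, 0))))
    units$base_code[units$unit_id == uid] <<- code
    units$base_charge[units$unit_id == uid] <<- if (deprot) -1L else 0L
  }
  has_hg <- nrow(geometry$hg) > 0L
  deprot <- has_hg && !("H3" %in% geometry$T$site)
  replace_unit(tu$unit_id, geometry$T, "T", deprot)
  replace_unit(au$unit_id, geometry$eA, "eA", FALSE)
  ## drop any previous Hg, then add the template's
  atoms <- atoms[!(is.na(atoms$unit_id) & atoms$element == "Hg"), ]
  if (has_hg) {
    xyz <- placed(geometry$hg)
    atoms <- rbind(atoms, data.frame(
      unit_id = NA_integer_, site = geometry$hg$site, element = "Hg",
      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], charge = 2))
  }
  pairing <- duplex$pairing
  pairing$pair_class[pairing$level == position] <- "modified"
  ## re-order atoms by unit, ions/Hg last, and renumber
  atoms <- atoms[order(is.na(atoms$unit_id), atoms$unit_id), ]
  .new_duplex(units, atoms, pairing, duplex$orientation, duplex$rise,
              duplex$twist)
}

#' Neutralize a duplex model with monovalent counter ions
#'
#' Adds `|net charge|` monovalent ions (Na+ for a net-negative system,
#' Cl- for net-positive) at seeded uniform-random positions in the
#' bounding box of the model (8 Å margin), rejecting positions within
#' `exclusion` of any existing atom.  The resulting system has exactly
#' zero net charge.
#'
#' @param duplex a `duplex_model`.
#' @param seed integer seed for ion placement.
#' @param exclusion exclusion-shell radius, Å.
#' @return the neutralized `duplex_model`.
#' @examples
#' \donttest{
#' d <- default_duplex()
#' sum(d$atoms$site == "Na+")   # 23 counter cations
#' duplex_net_charge(d)         # 0
#' }
#' @export
neutralize <- function(duplex, seed = 1L, exclusion = 3) {
  net <- sum(duplex$atoms$charge)
  count <- as.integer(round(abs(net)))
  if (count == 0L) return(duplex)
  species <- if (net < 0) "Na+" else "Cl-"
  elem <- if (net < 0) "Na" else "Cl"
  qion <- if (net < 0) 1 else -1
  atoms <- duplex$atoms
  lo <- c(min(atoms$x), min(atoms$y), min(atoms$z)) - 8
  hi <- c(max(atoms$x), max(atoms$y), max(atoms$z)) + 8
  rng <- .with_seed(seed, {
    placed <- matrix(NA_real_, count, 3L)
    occ <- cbind(atoms$x, atoms$y, atoms$z)
    for (k in seq_len(count)) {
      repeat {
        p <- stats::runif(3L, lo, hi)
        d2 <- rowSums(sweep(occ, 2L, p)^2)
        if (min(d2) >= exclusion^2) break
      }
      placed[k, ] <- p
      occ <- rbind(occ, p)
    }
    placed
  })
  atoms <- rbind(atoms, data.frame(
    unit_id = NA_integer_, site = species, element = elem,
    x = rng[, 1L], y = rng[, 2L], z = rng[, 3L], charge = qion,
    serial = NA_integer_))
  .new_duplex(duplex$units, atoms[, setdiff(names(atoms), "serial")],
              duplex$pairing, duplex$orientation, duplex$rise,
              duplex$twist)
}

#' Remove the Hg ions from a mercurated duplex (structure-3 analogue)
#'
#' Deletes both Hg(II) ions and re-protonates the central thymine N3
#' (restoring a neutral base pair).  Applied to a neutralized mercurated
#' duplex this leaves a net charge of -3 (two Hg2+ removed, one proton
#' added), which a second [neutralize()] balances with three further
#' counter cations.
#'
#' @param duplex a `duplex_model` with a mercurated modified pair.
#' @param protonate add the thymine H3 back (default TRUE).
#' @return the Hg-free `duplex_model`.
#' @export
remove_hg <- function(duplex, protonate = TRUE) {
  atoms <- duplex$atoms
  if (!any(atoms$element == "Hg")) stop("duplex carries no Hg ions")
  atoms <- atoms[atoms$element != "Hg", ]
  atoms$serial <- NULL
  units <- duplex$units
  lev <- duplex$pairing$level[duplex$pairing$pair_class == "modified"]
  if (protonate && length(lev) == 1L) {
    st <- .strand_of(duplex, lev, "T")
    uid <- units$unit_id[units$level == lev & units$strand == st]
    sel <- atoms$unit_id %in% uid
    n3 <- which(sel & atoms$site == "N3")
    c1 <- which(sel & atoms$site == "C1'")
    if (length(n3) == 1L && !any(sel & atoms$site == "H3")) {
      dir <- c(atoms$x[n3] - atoms$x[c1], atoms$y[n3] - atoms$y[c1],
               atoms$z[n3] - atoms$z[c1])
      dir <- dir / sqrt(sum(dir^2))
      atoms <- rbind(atoms, data.frame(
        unit_id = uid, site = "H3", element = "H",
        x = atoms$x[n3] + dir[1L], y = atoms$y[n3] + dir[2L],
        z = atoms$z[n3] + dir[3L], charge = 0))
      atoms$charge[n3] <- 0
      units$base_charge[units$unit_id == uid] <- 0L
    }
    atoms <- atoms[order(is.na(atoms$unit_id), atoms$unit_id), ]
  }
  .new_duplex(units, atoms, duplex$pairing, duplex$orientation,
              duplex$rise, duplex$twist)
}

## run expr with a local, restored RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' The packaged default duplex model
#'
#' The full construction route: antiparallel duplex for the default
#' 13-mer sequence, strand flip to parallel, guanine to isoguanine
#' transform, insertion of the dinuclear Hg-mediated pair at the central
#' position 7, and neutralization (23 Na+ for the default).
#'
#' @param seq1 strand-1 sequence 5'->3' (default `"GAAAGATAGGGAG"`; its
#'   antiparallel complement is 5'-d(CTCCCTATCTTTC)-3', which after the
#'   strand flip reads position-for-position complementary to strand 1,
#'   as required for a parallel-stranded duplex).
#' @param modify_at pair position of the modified pair (default 7).
#' @param hg include Hg(II) ions (default TRUE).
#' @param neutralized add counter ions (default TRUE)?
#' @param seed ion-placement seed.
#' @return a `duplex_model`.
#' @export
default_duplex <- function(seq1 = "GAGGGATAGAAAG", modify_at = 7L,
                           hg = TRUE, neutralized = TRUE, seed = 1L) {
  d <- build_antiparallel_duplex(seq1)
  d <- parallelize(d)
  d <- guanine_to_isoguanine(d)
  d <- insert_modified_pair(d, modify_at,
                            modified_pair_template(hg = hg))
  if (neutralized) d <- neutralize(d, seed = seed)
  d
}

## label of an atom row: e.g. "T7-O4", "eA20-N7", "Hg1", "Na+3"
.duplex_labels <- function(duplex) {
  a <- duplex$atoms
  lab <- character(nrow(a))
  for (r in seq_len(nrow(a))) {
    if (is.na(a$unit_id[r])) next
    u <- duplex$units[duplex$units$unit_id == a$unit_id[r], ]
    lab[r] <- sprintf("%s%d-%s", u$base_code, u$resid, a$site[r])
  }
  free <- which(is.na(a$unit_id))
  if (length(free)) {
    hg <- free[a$element[free] == "Hg"]
    lab[hg] <- a$site[hg]                       # "Hg1", "Hg2"
    ion <- free[a$element[free] != "Hg"]
    lab[ion] <- sprintf("%s%d", a$site[ion], seq_along(ion))
  }
  lab
}

#' Configuration from a duplex model
#'
#' @param duplex a `duplex_model`.
#' @param freeze_modified hold all atoms of the modified pair (and its
#'   Hg ions) fixed, as done while the Hg coordination has no reliable
#'   classical parametrization.
#' @param freeze_ions hold counter ions fixed.
#' @return a [configuration()] whose labels follow the
#'   `<base><resid>-<site>` convention (ions: `Na+1`..., mercury `Hg1`,
#'   `Hg2`).
#' @export
duplex_configuration <- function(duplex, freeze_modified = FALSE,
                                 freeze_ions = FALSE) {
  a <- duplex$atoms
  lab <- .duplex_labels(duplex)
  fixed <- rep(FALSE, nrow(a))
  if (freeze_modified) {
    mod_units <- .modified_unit_ids(duplex)
    fixed[a$unit_id %in% mod_units] <- TRUE
    fixed[is.na(a$unit_id) & a$element == "Hg"] <- TRUE
  }
  if (freeze_ions) fixed[is.na(a$unit_id) & a$element != "Hg"] <- TRUE
  configuration(cbind(a$x, a$y, a$z), masses = atomic_mass(a$element),
                elements = a$element, labels = lab, fixed = fixed)
}

.modified_unit_ids <- function(duplex) {
  lev <- duplex$pairing$level[duplex$pairing$pair_class == "modified"]
  duplex$units$unit_id[duplex$units$level %in% lev]
}

## atom serial for unit at level/strand with a given site name
.site_serial <- function(duplex, level, strand, site) {
  uid <- duplex$units$unit_id[duplex$units$level == level &
                                duplex$units$strand == strand]
  s <- duplex$atoms$serial[duplex$atoms$unit_id %in% uid &
                             duplex$atoms$site == site]
  if (length(s) != 1L) {
    stop("site ", site, " not found uniquely at level ", level,
         " strand ", strand)
  }
  s
}

## which strand carries base `code` at `level` (errors if absent)
.strand_of <- function(duplex, level, code) {
  u <- duplex$units[duplex$units$level == level &
                      duplex$units$base_code %in% code, ]
  if (nrow(u) != 1L) {
    stop("base ", paste(code, collapse = "/"),
         " not found uniquely at level ", level)
  }
  u$strand
}

#' Select the constrained pair set of the dynamic distance
#'
#' Three variants of the collective variable are supported:
#' \describe{
#' \item{EQUI}{all inter-base hydrogen bonds of the regular pairs
#'   (A:T two bonds, (i)G:C three bonds); used to zip up and equilibrate
#'   the hydrogen-bond structure.}
#' \item{DNA}{one N...H hydrogen bond per regular pair (A-N1...T-H3 and
#'   (i)G-H1...C-N3) plus the two Hg-bridged N...O distances of the
#'   modified pair (eA-N7...T-O4 and eA-N6...T-O2); the dissociation
#'   coordinate of the full duplex.}
#' \item{ISO}{only the two N...O distances of the modified pair; the
#'   dissociation coordinate of the isolated pair.}
#' }
#' If the DNA or ISO variant is requested on a model whose modified pair
#' has no Hg, the selection falls back to the same donor/acceptor
#' N...H / N...O pairs of the Hg-free pair geometry (a message is
#' emitted).
#'
#' @param duplex a `duplex_model`.
#' @param variant `"EQUI"`, `"DNA"` or `"ISO"`.
#' @return a [dd_spec()] with atom indices into the duplex atom table
#'   (the same order as [duplex_configuration()]).
#' @export
select_constraint_pairs <- function(duplex,
                                    variant = c("DNA", "EQUI", "ISO")) {
  variant <- match.arg(variant)
  if (nrow(duplex$pairing) == 0L) stop("duplex has no pairs")
  pairs <- matrix(integer(0), 0L, 2L)
  add <- function(s1, s2) pairs <<- rbind(pairs, c(s1, s2))
  regular_bonds <- function(level, class, all_bonds) {
    if (class == "AT") {
      sa <- .strand_of(duplex, level, "A")
      st <- .strand_of(duplex, level, "T")
      add(.site_serial(duplex, level, sa, "N1"),
          .site_serial(duplex, level, st, "H3"))
      if (all_bonds) {
        ## reversed-WC (parallel) pairs through O2, WC through O4
        o_site <- if (duplex$orientation == "parallel") "O2" else "O4"
        add(.site_serial(duplex, level, sa, "H61"),
            .site_serial(duplex, level, st, o_site))
      }
    } else {
      sg <- .strand_of(duplex, level, c("G", "iG"))
      sc <- .strand_of(duplex, level, "C")
      add(.site_serial(duplex, level, sg, "H1"),
          .site_serial(duplex, level, sc, "N3"))
      if (all_bonds) {
        add(.site_serial(duplex, level, sg, "O6"),
            .site_serial(duplex, level, sc, "H41"))
        add(.site_serial(duplex, level, sg, "H21"),
            .site_serial(duplex, level, sc, "O2"))
      }
    }
  }
  modified_pairs <- function() {
    lev <- duplex$pairing$level[duplex$pairing$pair_class == "modified"]
    if (length(lev) == 0L) return(FALSE)
    st <- .strand_of(duplex, lev, "T")
    se <- .strand_of(duplex, lev, "eA")
    has_hg <- any(duplex$atoms$element == "Hg")
    if (!has_hg) {
      message("modified pair carries no Hg; falling back to the ",
              "N...O donor-acceptor pairs of the Hg-free geometry")
    }
    add(.site_serial(duplex, lev, se, "N7"),
        .site_serial(duplex, lev, st, "O4"))
    add(.site_serial(duplex, lev, se, "N6"),
        .site_serial(duplex, lev, st, "O2"))
    TRUE
  }
  pp <- duplex$pairing
  if (variant == "EQUI") {
    for (r in which(pp$pair_class != "modified")) {
      regular_bonds(pp$level[r], pp$pair_class[r], all_bonds = TRUE)
    }
    if (nrow(pairs) == 0L) stop("no regular pairs to constrain")
  } else if (variant == "DNA") {
    for (r in which(pp$pair_class != "modified")) {
      regular_bonds(pp$level[r], pp$pair_class[r], all_bonds = FALSE)
    }
    modified_pairs()
  } else {
    if (!modified_pairs()) {
      stop("ISO variant needs a modified pair in the model")
    }
  }
  conf_mass <- atomic_mass(duplex$atoms$element)
  dd_spec(pairs, conf_mass, variant = variant)
}

#' Site map of a duplex model
#'
#' Tabulates atom serials against residue, base code and site name; the
#' input expected by the bonding-pattern and distance analyses.
#'
#' @param duplex a `duplex_model`.
#' @return data.frame with columns `index`, `label`, `element`, `base`,
#'   `resid`, `site`, `level`, `strand`.
#' @export
duplex_site_map <- function(duplex) {
  a <- duplex$atoms
  lab <- .duplex_labels(duplex)
  u <- duplex$units[match(a$unit_id, duplex$units$unit_id), ]
  data.frame(index = a$serial, label = lab, element = a$element,
             base = ifelse(is.na(a$unit_id), a$site, u$base_code),
             resid = u$resid, site = a$site, level = u$level,
             strand = u$strand)
}
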