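#' Toy energy topology for a coarse duplex model
#'
#' Translates a [duplex_model] into a [toy_topology()]:
#' \itemize{
#' \item every unit is kept near-rigid by harmonic springs between all
#'   of its sites (rest lengths taken from the built template);
#' \item consecutive units along each strand are linked through their
#'   C1' and P beads (the backbone);
#' \item every inter-base hydrogen bond of the regular pairs (the EQUI
#'   pair set) is a Morse well;
#' \item each Hg(II) forms Morse coordinate bonds to its two bridge
#'   acceptors; Hg1 additionally sees a weaker competing well at the
#'   thymine N3, which is what makes the NO/NN coordination bistable;
#' \item purely repulsive (WCA) cores keep paired C1' atoms from
#'   collapsing and counter ions off the charged sites;
#' \item point charges (phosphates -1, Na+ +1, Hg +2, deprotonated
#'   thymine N3 -1) interact through the switched Coulomb term, with the
#'   mercurated-pair core excluded internally (its interactions are the
#'   explicit Morse terms);
#' \item counter ions are weakly restrained to their placement sites
#'   (standing in for the solvent cage).
#' }
#'
#' @param duplex a `duplex_model`.
#' @param hbond_depth,hbond_width,hbond_r0 Morse parameters of the
#'   hydrogen-bond wells (kJ/mol, 1/Å, Å).
#' @param hg_depth,hg_width,hg_r0 Morse parameters of the Hg coordinate
#'   bonds.
#' @param hg_alt_depth depth of the competing Hg1--T-N3 well (kJ/mol);
#'   0 disables it.
#' @param bond_k,bond_k_h intra-unit spring constants (heavy-heavy and
#'   X-H pairs), kJ/mol/Å².
#' @param backbone_k strand-connectivity spring constant.
#' @param ion_restraint_k positional restraint on counter ions.
#' @param dielectric uniform relative permittivity for the Coulomb term
#'   (default 78.5, implicit aqueous screening).
#' @return a [toy_topology()] (finalized).
#' @export
duplex_topology <- function(duplex,
                            hbond_depth = 20, hbond_width = 2,
                            hbond_r0 = 1.9,
                            hg_depth = 25, hg_width = 2, hg_r0 = 2.15,
                            hg_alt_depth = 12,
                            bond_k = 800, bond_k_h = 300,
                            backbone_k = 100, ion_restraint_k = 10,
                            dielectric = 78.5) {
  a <- duplex$atoms
  xyz <- cbind(a$x, a$y, a$z)
  dist_ij <- function(i, j) {
    sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
  }
  bi <- integer(0); bj <- integer(0); bk <- numeric(0)
  ## intra-unit rigidity
  for (uid in duplex$units$unit_id) {
    s <- a$serial[!is.na(a$unit_id) & a$unit_id == uid]
    if (length(s) < 2L) next
    cmb <- utils::combn(s, 2L)
    i <- cmb[1L, ]; j <- cmb[2L, ]
    has_h <- a$element[i] == "H" | a$element[j] == "H"
    bi <- c(bi, i); bj <- c(bj, j)
    bk <- c(bk, ifelse(has_h, bond_k_h, bond_k))
  }
  ## backbone links
  for (s in 1:2) {
    us <- duplex$units[duplex$units$strand == s, ]
    us <- us[order(us$pos5to3), ]
    for (r in seq_len(nrow(us) - 1L)) {
      for (site in c("C1'", "P")) {
        i <- a$serial[a$unit_id %in% us$unit_id[r] & a$site == site]
        j <- a$serial[a$unit_id %in% us$unit_id[r + 1L] & a$site == site]
        if (length(i) == 1L && length(j) == 1L) {
          bi <- c(bi, i); bj <- c(bj, j); bk <- c(bk, backbone_k)
        }
      }
    }
  }

  ## hydrogen bonds of the regular pairs (EQUI pair set)
  hb <- NULL
  if (any(duplex$pairing$pair_class != "modified")) {
    equi <- suppressMessages(select_constraint_pairs(duplex, "EQUI"))
    hb <- data.frame(i = equi$pairs[, 1L], j = equi$pairs[, 2L],
                     depth = hbond_depth, width = hbond_width,
                     r0 = hbond_r0)
  }

  ## Hg coordination (and the Hg-free modified pair's hydrogen bond)
  hg <- NULL
  mod_lev <- duplex$pairing$level[duplex$pairing$pair_class == "modified"]
  hg_serial <- function(nm) {
    s <- a$serial[is.na(a$unit_id) & a$site == nm]
    if (length(s) == 1L) s else NA_integer_
  }
  if (length(mod_lev) == 1L) {
    st <- .strand_of(duplex, mod_lev, "T")
    se <- .strand_of(duplex, mod_lev, "eA")
    hg1 <- hg_serial("Hg1"); hg2 <- hg_serial("Hg2")
    if (!is.na(hg1) && !is.na(hg2)) {
      hg <- data.frame(
        i = c(hg1, hg1, hg2, hg2),
        j = c(.site_serial(duplex, mod_lev, se, "N7"),
              .site_serial(duplex, mod_lev, st, "O4"),
              .site_serial(duplex, mod_lev, se, "N6"),
              .site_serial(duplex, mod_lev, st, "O2")),
        depth = hg_depth, width = hg_width, r0 = hg_r0)
      if (hg_alt_depth > 0) {
        hg <- rbind(hg, data.frame(
          i = hg1, j = .site_serial(duplex, mod_lev, st, "N3"),
          depth = hg_alt_depth, width = hg_width, r0 = hg_r0))
      }
    } else {
      ## Hg-free analogue: the pair is held by its own hydrogen bond
      tH3 <- tryCatch(.site_serial(duplex, mod_lev, st, "H3"),
                      error = function(e) NA_integer_)
      if (!is.na(tH3)) {
        hb <- rbind(hb, data.frame(
          i = tH3, j = .site_serial(duplex, mod_lev, se, "N1"),
          depth = hbond_depth, width = hbond_width, r0 = hbond_r0))
      }
    }
  }

  ## stacking proxy: the Watson-Crick edge site of consecutive bases on
  ## a strand is tethered to its neighbour, restraining base flipping
  ## (the coarse stand-in for aromatic stacking)
  edge_site <- c(A = "N1", T = "N3", G = "N1", iG = "N1", C = "N3",
                 eA = "N1")
  for (s in 1:2) {
    us <- duplex$units[duplex$units$strand == s, ]
    us <- us[order(us$pos5to3), ]
    for (r in seq_len(nrow(us) - 1L)) {
      i <- a$serial[a$unit_id %in% us$unit_id[r] &
                      a$site == edge_site[us$base_code[r]]]
      j <- a$serial[a$unit_id %in% us$unit_id[r + 1L] &
                      a$site == edge_site[us$base_code[r + 1L]]]
      if (length(i) == 1L && length(j) == 1L) {
        bi <- c(bi, i); bj <- c(bj, j); bk <- c(bk, 30)
      }
    }
  }
  bonds <- data.frame(i = bi, j = bj, k = bk, r0 = dist_ij(bi, bj))

  ## sterics
  li <- integer(0); lj <- integer(0); le <- numeric(0); ls <- numeric(0)
  for (r in seq_len(nrow(duplex$pairing))) {
    lev <- duplex$pairing$level[r]
    i <- .site_serial(duplex, lev, 1L, "C1'")
    j <- .site_serial(duplex, lev, 2L, "C1'")
    li <- c(li, i); lj <- c(lj, j); le <- c(le, 2); ls <- c(ls, 8.5)
  }
  if (length(mod_lev) == 1L) {
    ## contact repulsion between the Hg-bridged donor/acceptor heavy
    ## atoms, so compressing the collective coordinate cannot overlap
    ## them
    st <- .strand_of(duplex, mod_lev, "T")
    se <- .strand_of(duplex, mod_lev, "eA")
    li <- c(li, .site_serial(duplex, mod_lev, se, "N7"),
            .site_serial(duplex, mod_lev, se, "N6"))
    lj <- c(lj, .site_serial(duplex, mod_lev, st, "O4"),
            .site_serial(duplex, mod_lev, st, "O2"))
    le <- c(le, 1, 1); ls <- c(ls, 2.5, 2.5)
  }
  ions <- a$serial[is.na(a$unit_id) & a$element %in% c("Na", "Cl")]
  if (length(ions)) {
    chg <- a$serial[a$charge != 0 & !(a$serial %in% ions)]
    for (i in ions) {
      li <- c(li, rep(i, length(chg))); lj <- c(lj, chg)
      le <- c(le, rep(1, length(chg))); ls <- c(ls, rep(3, length(chg)))
    }
  }
  lj <- if (length(li)) {
    data.frame(i = li, j = lj, eps = le, sigma = ls, wca = TRUE)
  } else NULL

  restraints <- if (length(ions)) {
    data.frame(i = ions, x = a$x[ions], y = a$y[ions], z = a$z[ions],
               k = ion_restraint_k)
  } else NULL

  ## the mercurated-pair core: Coulomb excluded within
  groups <- NULL
  if (length(mod_lev) == 1L) {
    mod_units <- .modified_unit_ids(duplex)
    core <- a$serial[(a$unit_id %in% mod_units & a$site != "P") |
                       (is.na(a$unit_id) & a$element == "Hg")]
    groups <- list(core)
  }

  finalize_topology(toy_topology(
    bonds = bonds, hbonds = hb, hg = hg, lj = lj,
    charges = a$charge, restraints = restraints,
    dielectric = dielectric, charge_groups = groups))
}
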