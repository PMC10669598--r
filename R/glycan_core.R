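## Domain model for heparin/heparan-sulfate (Hp/HS) oligosaccharide chains:
## residues, glycosidic linkages, ring puckers, rotatable bonds.
##
## A `gag_chain` is a list with:
##   atoms    : data.frame(eleno, name, element, resno, kind, x, y, z,
##                         formal_charge, atom_type)
##   bonds    : data.frame(i, j)  1-based row indices into atoms
##   residues : data.frame(resno, kind) plus list-column `substituents`
##   linkages : data.frame(donor, acceptor, class, phi, psi) with
##              list-columns phi_atoms / psi_atoms (4 atom indices each)
##   convention : character tag naming the Phi/Psi atom convention
##
## Residue indexing is 1-based from the reducing end; the linkage between
## residues 2 and 1 is the "2->1" glycosidic bond of the reducing terminus.

UA_KINDS <- c("GlcA", "IdoA")
RING_NAMES <- c("C1", "C2", "C3", "C4", "C5", "O5")

## The adopted heavy-atom crystallographic torsion convention for a 1->4
## linkage: Phi = O5-C1-O4'-C4', Psi = C1-O4'-C4'-C3'.
TORSION_CONVENTION <- "phi:O5-C1-Ox-Cx/psi:C1-Ox-Cx-C(x-1)"

#' Construct a gag_chain object
#'
#' Low-level constructor; most users should build chains with
#' [make_chain()] or read them with [read_structure()].
#'
#' @param atoms data.frame with columns eleno, name, element, resno, kind,
#'   x, y, z and optionally formal_charge, atom_type.
#' @param bonds data.frame with integer columns i, j (atom row indices).
#' @param residues data.frame with resno, kind and a list-column
#'   `substituents`.
#' @param validate logical; run [validate_chain()] on the result.
#' @return an object of class `gag_chain`.
#' @export
gag_chain <- function(atoms, bonds, residues, validate = TRUE) {
  if (is.null(atoms$formal_charge)) atoms$formal_charge <- 0
  if (is.null(atoms$atom_type)) atoms$atom_type <- NA_character_
  x <- structure(list(atoms = atoms, bonds = bonds, residues = residues,
                      linkages = NULL, convention = TORSION_CONVENTION),
                 class = "gag_chain")
  x$linkages <- identify_linkages(x)
  if (validate) validate_chain(x)
  x
}

#' @export
print.gag_chain <- function(x, ...) {
  cat(sprintf("gag_chain: %d residues (%s), %d atoms, %d bonds, %d linkages\n",
              nrow(x$residues), paste(x$residues$kind, collapse = "-"),
              nrow(x$atoms), nrow(x$bonds), nrow(x$linkages)))
  invisible(x)
}

#' Heavy-atom coordinate matrix of a chain
#' @param chain a `gag_chain`.
#' @export
coords_of <- function(chain) as.matrix(chain$atoms[, c("x", "y", "z")])

atom_index <- function(chain, resno, name) {
  i <- which(chain$atoms$resno == resno & chain$atoms$name == name)
  if (length(i) != 1) return(NA_integer_)
  i
}

## heavy-atom degree vector
atom_degree <- function(chain) {
  n <- nrow(chain$atoms)
  tabulate(c(chain$bonds$i, chain$bonds$j), nbins = n)
}

#' Validate a gag_chain against the chain invariants
#'
#' Checks finite coordinates, unique atom names within residues, GlcN /
#' uronic-acid alternation, the linkage-count rule (n residues imply n-1
#' linkages with strictly alternating classes), and pyranose ring
#' completeness.
#'
#' @param chain a `gag_chain`.
#' @return invisibly TRUE; stops with a message on violation.
#' @export
validate_chain <- function(chain) {
  a <- chain$atoms
  if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
    stop("malformed chain: non-finite coordinates")
  for (r in chain$residues$resno) {
    nm <- a$name[a$resno == r]
    if (anyDuplicated(nm)) stop("malformed chain: duplicate atom name in residue ", r)
    if (!all(RING_NAMES %in% nm))
      stop("malformed chain: residue ", r, " missing pyranose ring atoms")
  }
  kinds <- chain$residues$kind
  is_ua <- kinds %in% UA_KINDS
  if (length(kinds) > 1 && any(diff(is_ua) == 0))
    stop("malformed chain: residue kinds must alternate GlcN / uronic acid")
  lk <- chain$linkages
  if (nrow(lk) != nrow(chain$residues) - 1)
    stop("malformed chain: expected ", nrow(chain$residues) - 1,
         " linkages, found ", nrow(lk))
  if (nrow(lk) > 1 && any(lk$class[-1] == lk$class[-nrow(lk)]))
    stop("malformed chain: linkage classes must alternate")
  invisible(TRUE)
}

#' Identify glycosidic linkages in a chain
#'
#' Finds every anomeric carbon (C1) bonded to a position-4 oxygen (O4) of
#' a different residue, and measures Phi/Psi under the package convention
#' (Phi = O5-C1-O4'-C4', Psi = C1-O4'-C4'-C3').
#'
#' @param chain a `gag_chain` (linkages may be unset).
#' @return data.frame with columns donor, acceptor, class, phi, psi and
#'   list-columns phi_atoms / psi_atoms (atom row indices).
#' @export
identify_linkages <- function(chain) {
  a <- chain$atoms
  b <- chain$bonds
  res <- list()
  for (k in seq_len(nrow(b))) {
    i <- b$i[k]; j <- b$j[k]
    if (a$resno[i] == a$resno[j]) next
    ## orient: donor C1 -- acceptor O4
    if (a$name[i] == "O4" && a$name[j] == "C1") { tmp <- i; i <- j; j <- tmp }
    if (!(a$name[i] == "C1" && a$name[j] == "O4")) next
    donor <- a$resno[i]; acceptor <- a$resno[j]
    o5 <- atom_index(chain, donor, "O5")
    c4 <- atom_index(chain, acceptor, "C4")
    c3 <- atom_index(chain, acceptor, "C3")
    if (any(is.na(c(o5, c4, c3))))
      stop("malformed chain: incomplete linkage between residues ",
           donor, " and ", acceptor)
    xyz <- as.matrix(a[, c("x", "y", "z")])
    phi_atoms <- c(o5, i, j, c4)
    psi_atoms <- c(i, j, c4, c3)
    cls <- if (a$kind[i] %in% UA_KINDS) "UA->GlcN" else "GlcN->UA"
    res[[length(res) + 1]] <- data.frame(
      donor = donor, acceptor = acceptor, class = cls,
      phi = dihedral_rows(xyz[phi_atoms, ]),
      psi = dihedral_rows(xyz[psi_atoms, ]))
    res[[length(res)]]$phi_atoms <- list(phi_atoms)
    res[[length(res)]]$psi_atoms <- list(psi_atoms)
  }
  if (length(res) == 0)
    return(data.frame(donor = integer(), acceptor = integer(),
                      class = character(), phi = numeric(), psi = numeric()))
  out <- do.call(rbind, res)
  out[order(out$acceptor), , drop = FALSE]
}

#' Re-measure glycosidic torsions from pose coordinates
#'
#' @param chain a `gag_chain` (defines the linkage atom quadruples).
#' @param xyz coordinate matrix in the chain's atom order (defaults to
#'   the chain's own coordinates).
#' @return data.frame(phi, psi), one row per linkage.
#' @export
measure_linkage_torsions <- function(chain, xyz = coords_of(chain)) {
  lk <- chain$linkages
  data.frame(
    phi = vapply(lk$phi_atoms, function(ix) dihedral_rows(xyz[ix, ]), 0),
    psi = vapply(lk$psi_atoms, function(ix) dihedral_rows(xyz[ix, ]), 0))
}

## ---------------------------------------------------------------------
## Cremer-Pople puckering and conformer classification
## ---------------------------------------------------------------------

#' Cremer-Pople puckering coordinates of a six-membered ring
#'
#' @param ring_coords 6x3 matrix of ring atom positions in ring order
#'   (C1, C2, C3, C4, C5, O5 for pyranoses here).
#' @return list(Q, theta, phi, z): total amplitude (Angstrom), polar angle
#'   and azimuth (degrees, phi in [0, 360)), and the out-of-plane
#'   displacements.
#' @export
cremer_pople <- function(ring_coords) {
  m <- as.matrix(ring_coords)
  stopifnot(nrow(m) == 6, ncol(m) == 3)
  ctr <- colMeans(m)
  rj <- sweep(m, 2, ctr)
  jj <- 0:5
  sp <- colSums(rj * sin(2 * pi * jj / 6))
  cp <- colSums(rj * cos(2 * pi * jj / 6))
  ## normal oriented so a counterclockwise-wound ring with alternating
  ## +z,-z displacements starting at atom 1 sits at the theta = 0 pole
  n <- unit(cross3(cp, sp))
  z <- as.numeric(rj %*% n)
  q2c <- sqrt(2 / 6) * sum(z * cos(4 * pi * jj / 6))
  q2s <- -sqrt(2 / 6) * sum(z * sin(4 * pi * jj / 6))
  q3 <- sqrt(1 / 6) * sum(z * (-1)^jj)
  q2 <- sqrt(q2c^2 + q2s^2)
  Q <- sqrt(q2^2 + q3^2)
  theta <- if (Q < 1e-12) 90 else rad2deg(acos(pmin(pmax(q3 / Q, -1), 1)))
  phi <- rad2deg(atan2(q2s, q2c)) %% 360
  list(Q = Q, theta = theta, phi = phi, z = z)
}

## inverse: out-of-plane displacements for given (Q, theta, phi), used by
## the fixture ring templates
cp_displacements <- function(Q, theta, phi) {
  jj <- 0:5
  q2 <- Q * sin(deg2rad(theta))
  q3 <- Q * cos(deg2rad(theta))
  sqrt(1 / 3) * q2 * cos(deg2rad(phi) + 4 * pi * jj / 6) +
    sqrt(1 / 6) * q3 * (-1)^jj
}

## Classification windows (configurable; the conformer names only fix the
## puckers, not the cuts). phi_2so is the canonical 2SO azimuth under the
## C1-first ring indexing used throughout this package.
#' @export
default_pucker_windows <- function() {
  list(theta_chair = 45, theta_inv = 135, phi_2so = 270,
       phi_window = 30, q_min = 0.1)
}

#' Classify a pyranose ring pucker
#'
#' Computes Cremer-Pople coordinates and assigns a conformer label:
#' `4C1` for theta <= 45 deg, `1C4` for theta >= 135 deg, `2SO` in the
#' equatorial band when the azimuth falls within +/-30 deg of the
#' canonical 2SO azimuth, otherwise `other`. Near-planar rings (Q below
#' tolerance) are labelled `other` with `planar = TRUE`.
#'
#' @param ring_coords 6x3 matrix in ring order.
#' @param windows classification windows, see [default_pucker_windows()].
#' @return list(label, Q, theta, phi, planar).
#' @export
classify_pucker <- function(ring_coords, windows = default_pucker_windows()) {
  cp <- cremer_pople(ring_coords)
  planar <- cp$Q < windows$q_min
  label <- if (planar) {
    "other"
  } else if (cp$theta <= windows$theta_chair) {
    "4C1"
  } else if (cp$theta >= windows$theta_inv) {
    "1C4"
  } else if (circular_dist(cp$phi, windows$phi_2so) <= windows$phi_window) {
    "2SO"
  } else {
    "other"
  }
  list(label = label, Q = cp$Q, theta = cp$theta, phi = cp$phi,
       planar = planar)
}

## ---------------------------------------------------------------------
## Rotatable-bond enumeration
## ---------------------------------------------------------------------

#' Enumerate rotatable bonds under a docking regime
#'
#' Rotatable bonds are non-ring single bonds between heavy atoms:
#' glycosidic Phi (C1-O) and Psi (O-C4) bonds of each linkage, the same
#' exocyclic C1-O1 / C4-O4 bonds at the chain termini, and substituent
#' attachment bonds (C-N, C-O-ester, N-S and O-S sulfamate/ester bonds,
#' carboxylate C5-C6). Bonds to single-atom termini (plain hydroxyls,
#' sulfate terminal oxygens, carboxylate oxygens) and bonds within rings
#' are never rotatable. Under the rigid regime glycosidic bonds are
#' dropped; under semi-rigid they are tagged `bounded`; under flexible
#' `free`. Substituent bonds are always `free`.
#'
#' @param chain a `gag_chain`.
#' @param regime one of "rigid", "semi-rigid", "flexible".
#' @return data.frame(i, j, tag, mode, linkage, torsion) where tag is
#'   glycosidic/substituent, mode is free/bounded, linkage is the linkage
#'   row (NA for substituents), torsion is phi/psi/sub.
#' @export
enumerate_rotatable_bonds <- function(chain,
                                      regime = c("flexible", "semi-rigid", "rigid")) {
  regime <- match.arg(regime)
  a <- chain$atoms
  b <- chain$bonds
  heavy <- a$element != "H"
  deg <- atom_degree(chain)
  ## map of glycosidic bonds -> (linkage row, phi/psi)
  lk <- chain$linkages
  glyc <- list()
  if (nrow(lk) > 0) {
    for (r in seq_len(nrow(lk))) {
      pa <- lk$phi_atoms[[r]]  # O5 C1 O4' C4'
      glyc[[paste(sort(pa[2:3]), collapse = "-")]] <- c(r, 1)
      glyc[[paste(sort(pa[3:4]), collapse = "-")]] <- c(r, 2)
    }
  }
  ring_flag <- paste(a$resno, a$name) %in%
    unlist(lapply(chain$residues$resno, function(r) paste(r, RING_NAMES)))
  out <- list()
  for (k in seq_len(nrow(b))) {
    i <- b$i[k]; j <- b$j[k]
    if (!heavy[i] || !heavy[j]) next
    if (ring_flag[i] && ring_flag[j] && a$resno[i] == a$resno[j]) next
    key <- paste(sort(c(i, j)), collapse = "-")
    g <- glyc[[key]]
    if (!is.null(g)) {
      if (regime == "rigid") next
      out[[length(out) + 1]] <- data.frame(
        i = i, j = j, tag = "glycosidic",
        mode = if (regime == "semi-rigid") "bounded" else "free",
        linkage = g[1], torsion = c("phi", "psi")[g[2]])
      next
    }
    ## terminal-cap exocyclic oxygens at positions 1 and 4 stay rotatable
    cap <- (a$name[i] %in% c("O1", "O4") && a$name[j] %in% c("C1", "C4")) ||
           (a$name[j] %in% c("O1", "O4") && a$name[i] %in% c("C1", "C4"))
    if (!cap && (deg[i] < 2 || deg[j] < 2)) next
    out[[length(out) + 1]] <- data.frame(
      i = i, j = j, tag = "substituent", mode = "free",
      linkage = NA_integer_, torsion = "sub")
  }
  if (length(out) == 0)
    return(data.frame(i = integer(), j = integer(), tag = character(),
                      mode = character(), linkage = integer(),
                      torsion = character()))
  do.call(rbind, out)
}

## ---------------------------------------------------------------------
## Sequence-space combinatorics
## ---------------------------------------------------------------------

## exact big-integer power via base-1e4 digit vectors (72^10 exceeds the
## double-precision integer range, so arbitrary precision is required)
big_pow <- function(base, exp) {
  digits <- 1L  # little-endian base-1e4
  for (k in seq_len(exp)) {
    carry <- 0
    prod <- digits * base + carry  # vectorized multiply, then normalize
    digits <- integer(0)
    while (length(prod) > 0 || carry > 0) {
      if (length(prod) == 0) { v <- carry; carry <- 0 }
      else { v <- prod[1] + carry; prod <- prod[-1] }
      digits <- c(digits, v %% 10000L)
      carry <- v %/% 10000L
    }
    digits <- as.integer(digits)
  }
  digits
}

big_to_string <- function(digits) {
  n <- length(digits)
  parts <- sprintf("%04d", rev(digits))
  parts[1] <- as.character(digits[n])
  paste(parts, collapse = "")
}

#' Exact count of theoretical sequence topologies
#'
#' Number of distinct linear sequences of a given length over an opaque
#' building-block alphabet: `alphabet_size ^ length`, computed exactly in
#' arbitrary precision. For Hp/HS hexasaccharides over the 72 building
#' blocks (sulfation patterns x two iduronate puckers) this is
#' 139,314,069,504 (~139 billion), against ~64 million for a hexapeptide
#' (20^6) and 4096 (~4000) for a hexanucleotide.
#'
#' @param alphabet_size,length positive integers.
#' @return character string with the exact decimal integer; attribute
#'   `numeric` holds the double value (exact when below 2^53).
#' @export
topology_count <- function(alphabet_size, length) {
  if (!is.numeric(alphabet_size) || !is.numeric(length) ||
      alphabet_size < 1 || length < 1 ||
      alphabet_size != round(alphabet_size) || length != round(length))
    stop("alphabet_size and length must be positive integers")
  s <- big_to_string(big_pow(as.integer(alphabet_size), as.integer(length)))
  structure(s, numeric = as.numeric(s))
}
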