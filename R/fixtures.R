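## Synthetic fixture generation: idealized sulfated oligosaccharide
## chains with controlled glycosidic torsions, rigid cationic groove
## receptors with planted native poses, decoy pose sets with analytic
## ground truth, and torsion corpora for curation tests.
##
## Ring templates are idealized pyranoses: a regular hexagon footprint
## with Cremer-Pople out-of-plane displacements (Q = 0.57 A for chairs,
## 0.62 A for the 2SO skew-boat), C-C 1.52 A, C-O 1.43 A, giving bond
## lengths and tetrahedral exocyclic directions close to standard
## carbohydrate geometry.

BOND_CC <- 1.52
BOND_CO <- 1.43
BOND_CN <- 1.47
BOND_NS <- 1.60
BOND_OS <- 1.58
BOND_SO_TERM <- 1.45
BOND_C_OCARB <- 1.25
RING_Q_CHAIR <- 0.57
RING_Q_SKEW <- 0.62

## substituent vocabulary per residue kind
GLCN_SUBS <- c("2N-sulfate", "2N-acetate", "2N-amine", "6O-sulfate",
               "3O-sulfate", "6O-hydroxyl")
UA_SUBS <- c("carboxylate", "2O-sulfate", "2O-hydroxyl")

## default (minimal rotatable-bond complement) substituent sets
default_substituents <- function(kind) {
  if (kind %in% UA_KINDS) c("carboxylate", "2O-sulfate")
  else c("2N-sulfate", "6O-sulfate")
}

## Heterogeneous sulfation walk emulating real Hp/HS fine structure
## (N-sulfated and N-acetylated glucosamines, a rare 3-O-sulfate,
## variably 2-O-sulfated uronic acids). A uniformly sulfated chain in
## a complementary groove is register-shift degenerate - every
## disaccharide step looks alike - so redocking fixtures use this
## aperiodic pattern to make the planted pose a well-posed optimum.
heterogeneous_sulfation <- function(kinds) {
  glcn_cycle <- list(c("2N-sulfate", "6O-sulfate"),
                     c("2N-acetate", "6O-sulfate"),
                     c("2N-sulfate", "3O-sulfate", "6O-sulfate"),
                     c("2N-sulfate"),
                     c("2N-acetate"))
  ua_cycle <- list(c("carboxylate", "2O-sulfate"),
                   c("carboxylate"),
                   c("carboxylate", "2O-sulfate"),
                   c("carboxylate"),
                   c("carboxylate", "2O-sulfate"))
  ig <- 0; iu <- 0
  lapply(kinds, function(k) {
    if (k %in% UA_KINDS) {
      iu <<- iu + 1
      ua_cycle[[(iu - 1) %% length(ua_cycle) + 1]]
    } else {
      ig <<- ig + 1
      glcn_cycle[[(ig - 1) %% length(glcn_cycle) + 1]]
    }
  })
}

## literature glycosidic torsion minima by linkage class
#' Default glycosidic torsion centers per linkage class
#'
#' UA->GlcN linkages have two populated (Phi, Psi) minima, near
#' (-80, -100) and (-80, 65) degrees; GlcN->UA linkages one, near
#' (80, -145) degrees.
#' @return named list of matrices with columns phi, psi (one row per mode).
#' @export
default_torsion_centers <- function() {
  list(
    "UA->GlcN" = matrix(c(-80, -100, -80, 65), ncol = 2, byrow = TRUE,
                        dimnames = list(NULL, c("phi", "psi"))),
    "GlcN->UA" = matrix(c(80, -145), ncol = 2, byrow = TRUE,
                        dimnames = list(NULL, c("phi", "psi"))))
}

## ---------------------------------------------------------------------
## residue template
## ---------------------------------------------------------------------

## 6x3 ring coordinates in ring order C1..C5,O5 for a pucker label
ring_coords_for_pucker <- function(pucker) {
  par <- switch(pucker,
    "4C1" = list(Q = RING_Q_CHAIR, theta = 0, phi = 0),
    "1C4" = list(Q = RING_Q_CHAIR, theta = 180, phi = 0),
    "2SO" = list(Q = RING_Q_SKEW, theta = 90,
                 phi = default_pucker_windows()$phi_2so),
    stop("unsupported pucker template: ", pucker))
  z <- cp_displacements(par$Q, par$theta, par$phi)
  rad <- sqrt(max(BOND_CC^2 - (2 * sqrt(1 / 6) * RING_Q_CHAIR)^2, 0.5))
  ang <- 2 * pi * (0:5) / 6
  cbind(x = rad * cos(ang), y = rad * sin(ang), z = z)
}

## the two exocyclic tetrahedral directions at ring position k (1..6);
## returns list(axial=, equatorial=) unit vectors
exocyclic_directions <- function(ring, k) {
  n6 <- nrow(ring)
  prev <- ring[if (k == 1) n6 else k - 1, ]
  nxt <- ring[if (k == n6) 1 else k + 1, ]
  p <- ring[k, ]
  v1 <- unit(prev - p); v2 <- unit(nxt - p)
  bis <- unit(-(v1 + v2))
  w <- unit(cross3(v1, v2))
  delta <- deg2rad(109.47 / 2)
  d1 <- unit(bis * cos(delta) + w * sin(delta))
  d2 <- unit(bis * cos(delta) - w * sin(delta))
  ## ring axis from the mean plane normal
  ctr <- colMeans(ring)
  rj <- sweep(ring, 2, ctr)
  jj <- 0:5
  axis <- unit(cross3(colSums(rj * sin(2 * pi * jj / 6)),
                      colSums(rj * cos(2 * pi * jj / 6))))
  if (abs(sum(d1 * axis)) >= abs(sum(d2 * axis)))
    list(axial = d1, equatorial = d2)
  else
    list(axial = d2, equatorial = d1)
}

## place three terminal sulfate oxygens around S attached at `att`
place_so3 <- function(s_pos, att_pos, ref_pos, prefix) {
  out <- list()
  for (k in 1:3) {
    p <- place_atom(ref_pos, att_pos, s_pos, BOND_SO_TERM, 109.5,
                    60 + 120 * (k - 1))
    out[[k]] <- list(name = sprintf("%s%d", prefix, k), element = "O", pos = p)
  }
  out
}

## Build one residue template in local coordinates. Returns
## list(atoms = data.frame(name, element, x, y, z), bonds = data.frame
## of name pairs). O1 is always present (anomeric probe); the chain
## assembler removes it for non-reducing residues.
build_residue_template <- function(kind, substituents, pucker) {
  ring <- ring_coords_for_pucker(pucker)
  atoms <- list()
  bonds <- list()
  add_atom <- function(name, element, pos) {
    atoms[[length(atoms) + 1]] <<- list(name = name, element = element,
                                        pos = pos)
  }
  add_bond <- function(a, b) bonds[[length(bonds) + 1]] <<- c(a, b)
  for (k in 1:6) add_atom(RING_NAMES[k], if (k == 6) "O" else "C", ring[k, ])
  for (k in 1:6) add_bond(RING_NAMES[k], RING_NAMES[if (k == 6) 1 else k + 1])
  pos_of <- function(name) {
    for (a in atoms) if (a$name == name) return(a$pos)
    stop("no atom ", name)
  }
  ## anomeric oxygen (axial, alpha-like)
  d1 <- exocyclic_directions(ring, 1)
  add_atom("O1", "O", ring[1, ] + BOND_CO * d1$axial)
  add_bond("C1", "O1")
  ## position 2
  d2 <- exocyclic_directions(ring, 2)
  if (kind %in% UA_KINDS) {
    add_atom("O2", "O", ring[2, ] + BOND_CO * d2$equatorial)
    add_bond("C2", "O2")
    if ("2O-sulfate" %in% substituents) {
      s <- place_atom(pos_of("C1"), pos_of("C2"), pos_of("O2"), BOND_OS, 112, 180)
      add_atom("S2", "S", s); add_bond("O2", "S2")
      for (o in place_so3(s, pos_of("O2"), pos_of("C2"), "OS2"))
        { add_atom(o$name, o$element, o$pos); add_bond("S2", o$name) }
    }
  } else {
    add_atom("N2", "N", ring[2, ] + BOND_CN * d2$equatorial)
    add_bond("C2", "N2")
    if ("2N-sulfate" %in% substituents) {
      s <- place_atom(pos_of("C1"), pos_of("C2"), pos_of("N2"), BOND_NS, 115, 180)
      add_atom("SN", "S", s); add_bond("N2", "SN")
      for (o in place_so3(s, pos_of("N2"), pos_of("C2"), "OSN"))
        { add_atom(o$name, o$element, o$pos); add_bond("SN", o$name) }
    } else if ("2N-acetate" %in% substituents) {
      c7 <- place_atom(pos_of("C1"), pos_of("C2"), pos_of("N2"), 1.33, 122, 180)
      add_atom("C7", "C", c7); add_bond("N2", "C7")
      add_atom("O7", "O", place_atom(pos_of("C2"), pos_of("N2"), c7, 1.23, 121, 0))
      add_bond("C7", "O7")
      add_atom("C8", "C", place_atom(pos_of("C2"), pos_of("N2"), c7, 1.50, 116, 180))
      add_bond("C7", "C8")
    }
  }
  ## position 3
  d3 <- exocyclic_directions(ring, 3)
  add_atom("O3", "O", ring[3, ] + BOND_CO * d3$equatorial)
  add_bond("C3", "O3")
  if ("3O-sulfate" %in% substituents && !(kind %in% UA_KINDS)) {
    s <- place_atom(pos_of("C2"), pos_of("C3"), pos_of("O3"), BOND_OS, 112, 180)
    add_atom("S3", "S", s); add_bond("O3", "S3")
    for (o in place_so3(s, pos_of("O3"), pos_of("C3"), "OS3"))
      { add_atom(o$name, o$element, o$pos); add_bond("S3", o$name) }
  }
  ## position 4 (linkage-position oxygen, hydroxyl cap when terminal)
  d4 <- exocyclic_directions(ring, 4)
  add_atom("O4", "O", ring[4, ] + BOND_CO * d4$equatorial)
  add_bond("C4", "O4")
  ## position 5/6
  d5 <- exocyclic_directions(ring, 5)
  c6 <- ring[5, ] + BOND_CC * d5$equatorial
  add_atom("C6", "C", c6)
  add_bond("C5", "C6")
  if (kind %in% UA_KINDS) {
    ## carboxylate (intrinsic to uronic acids)
    add_atom("O6A", "O", place_atom(pos_of("C4"), pos_of("C5"), c6, BOND_C_OCARB, 120, 90))
    add_atom("O6B", "O", place_atom(pos_of("C4"), pos_of("C5"), c6, BOND_C_OCARB, 120, -90))
    add_bond("C6", "O6A"); add_bond("C6", "O6B")
  } else {
    o6 <- place_atom(pos_of("C4"), pos_of("C5"), c6, BOND_CO, 109.5, 180)
    add_atom("O6", "O", o6)
    add_bond("C6", "O6")
    if ("6O-sulfate" %in% substituents) {
      s <- place_atom(pos_of("C5"), c6, o6, BOND_OS, 112, 180)
      add_atom("S6", "S", s); add_bond("O6", "S6")
      for (o in place_so3(s, o6, c6, "OS6"))
        { add_atom(o$name, o$element, o$pos); add_bond("S6", o$name) }
    }
  }
  adf <- data.frame(
    name = vapply(atoms, `[[`, "", "name"),
    element = vapply(atoms, `[[`, "", "element"),
    x = vapply(atoms, function(a) a$pos[1], 0),
    y = vapply(atoms, function(a) a$pos[2], 0),
    z = vapply(atoms, function(a) a$pos[3], 0))
  bdf <- data.frame(a = vapply(bonds, `[`, "", 1),
                    b = vapply(bonds, `[`, "", 2))
  list(atoms = adf, bonds = bdf)
}

check_substituents <- function(kind, substituents) {
  ok <- if (kind %in% UA_KINDS) UA_SUBS else GLCN_SUBS
  bad <- setdiff(substituents, ok)
  if (length(bad) > 0)
    stop("impossible substituent(s) for ", kind, ": ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

## ---------------------------------------------------------------------
## fixture spec and chain assembly
## ---------------------------------------------------------------------

#' Specify a synthetic Hp/HS fixture
#'
#' @param chain_length number of residues (2-10).
#' @param sulfation per-residue substituent sets (list of character
#'   vectors, reducing end first), `"minimal"` / NULL for the minimal
#'   complement (UA: carboxylate + 2-O-sulfate; GlcN: N-sulfate +
#'   6-O-sulfate), or `"heterogeneous"` for an aperiodic realistic
#'   pattern mixing N-sulfated / N-acetylated glucosamines and a rare
#'   3-O-sulfate (redocking fixtures use this: a uniform pattern makes
#'   the pose degenerate under register shifts).
#' @param torsion_plan (chain_length-1) x 2 matrix of (phi, psi) per
#'   linkage, reducing-end linkage first, or NULL for the literature
#'   minima per linkage class (first UA->GlcN mode).
#' @param first_kind residue kind at the reducing end ("GlcN" or a
#'   uronic acid).
#' @param ua_kind which uronic acid ("IdoA" or "GlcA").
#' @param ua_pucker ring pucker for iduronate residues ("1C4", "2SO" or
#'   "4C1"); GlcN and GlcA are always 4C1.
#' @param pocket_tightness receptor complementarity in [0, 1]: the
#'   fraction of ligand anionic groups given a complementary cationic
#'   site (see [make_complex()]).
#' @param seed integer seed for the stochastic parts of complex building.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(chain_length = 6, sulfation = NULL,
                         torsion_plan = NULL, first_kind = "GlcN",
                         ua_kind = "IdoA", ua_pucker = "1C4",
                         pocket_tightness = 1, seed = 1) {
  stopifnot(chain_length >= 1, chain_length <= 12)
  kinds <- character(chain_length)
  for (i in seq_len(chain_length)) {
    even <- (i %% 2) == 0
    kinds[i] <- if ((first_kind == "GlcN") != even) "GlcN" else ua_kind
  }
  if (is.null(sulfation) || identical(sulfation, "minimal"))
    sulfation <- lapply(kinds, default_substituents)
  else if (identical(sulfation, "heterogeneous"))
    sulfation <- heterogeneous_sulfation(kinds)
  stopifnot(length(sulfation) == chain_length)
  for (i in seq_len(chain_length)) check_substituents(kinds[i], sulfation[[i]])
  if (is.null(torsion_plan) && chain_length > 1) {
    ctr <- default_torsion_centers()
    torsion_plan <- t(vapply(seq_len(chain_length - 1), function(j) {
      donor_kind <- kinds[j + 1]
      cls <- if (donor_kind %in% UA_KINDS) "UA->GlcN" else "GlcN->UA"
      ctr[[cls]][1, ]
    }, c(phi = 0, psi = 0)))
  }
  if (chain_length > 1) stopifnot(nrow(torsion_plan) == chain_length - 1)
  structure(list(chain_length = chain_length, kinds = kinds,
                 sulfation = sulfation, torsion_plan = torsion_plan,
                 ua_pucker = ua_pucker,
                 pocket_tightness = pocket_tightness, seed = seed),
            class = "fixture_spec")
}

#' Build an idealized Hp/HS chain from a fixture spec
#'
#' Assembles 1->4 linked idealized pyranose residues with the requested
#' substituents and sets every glycosidic (Phi, Psi) exactly to the
#' torsion plan (re-measured values agree to well under 0.01 degree).
#'
#' @param spec a [fixture_spec()].
#' @return a validated `gag_chain`.
#' @export
make_chain <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$chain_length
  atoms <- NULL
  bonds <- NULL  # integer index pairs
  name_ix <- function(resno, name) {
    which(atoms$resno == resno & atoms$name == name)
  }
  for (i in seq_len(n)) {
    kind <- spec$kinds[i]
    pucker <- if (kind == "IdoA") spec$ua_pucker else "4C1"
    tpl <- build_residue_template(kind, spec$sulfation[[i]], pucker)
    txyz <- as.matrix(tpl$atoms[, c("x", "y", "z")])
    rownames(txyz) <- tpl$atoms$name
    if (i > 1) {
      phi <- spec$torsion_plan[i - 1, 1]
      psi <- spec$torsion_plan[i - 1, 2]
      o4a <- as.numeric(atoms[name_ix(i - 1, "O4"), c("x", "y", "z")])
      c4a <- as.numeric(atoms[name_ix(i - 1, "C4"), c("x", "y", "z")])
      c3a <- as.numeric(atoms[name_ix(i - 1, "C3"), c("x", "y", "z")])
      ## 1. anomeric carbon by NeRF at the Psi torsion
      c1_new <- place_atom(c3a, c4a, o4a, 1.41, 116, psi)
      ## 2. rigidly move the template: C1 -> c1_new, anomeric direction
      ##    (C1->O1 probe) -> (c1_new -> O4 of previous residue)
      u_t <- unit(txyz["O1", ] - txyz["C1", ])
      rot <- align_rotation(u_t, unit(o4a - c1_new))
      txyz <- sweep(txyz, 2, txyz["C1", ])
      txyz <- txyz %*% t(rot)
      txyz <- sweep(txyz, 2, c1_new, "+")
      ## 3. twist about the glycosidic bond to the Phi torsion
      d0 <- compute_dihedral(txyz["O5", ], txyz["C1", ], o4a, c4a)
      axis <- o4a - c1_new
      twist <- function(ang) {
        m <- sweep(txyz, 2, c1_new)
        sweep(m %*% t(rotation_matrix(axis, ang)), 2, c1_new, "+")
      }
      cand <- twist(wrap_angle(phi - d0))
      d1 <- compute_dihedral(cand["O5", ], cand["C1", ], o4a, c4a)
      if (circular_dist(d1, phi) > 1e-6)
        cand <- twist(wrap_angle(-(phi - d0)))
      txyz <- cand
      ## drop the anomeric probe oxygen
      keep <- rownames(txyz) != "O1"
      tpl$atoms <- tpl$atoms[keep, ]
      tpl$bonds <- tpl$bonds[tpl$bonds$a != "O1" & tpl$bonds$b != "O1", ]
      txyz <- txyz[keep, , drop = FALSE]
    }
    base <- if (is.null(atoms)) 0L else nrow(atoms)
    newa <- data.frame(
      eleno = base + seq_len(nrow(tpl$atoms)),
      name = tpl$atoms$name, element = tpl$atoms$element,
      resno = i, kind = kind,
      x = txyz[, 1], y = txyz[, 2], z = txyz[, 3])
    rownames(newa) <- NULL
    atoms <- if (is.null(atoms)) newa else rbind(atoms, newa)
    newb <- data.frame(
      i = base + match(tpl$bonds$a, tpl$atoms$name),
      j = base + match(tpl$bonds$b, tpl$atoms$name))
    bonds <- if (is.null(bonds)) newb else rbind(bonds, newb)
    if (i > 1) {
      bonds <- rbind(bonds,
                     data.frame(i = name_ix(i, "C1"), j = name_ix(i - 1, "O4")))
    }
  }
  residues <- data.frame(resno = seq_len(n), kind = spec$kinds)
  residues$substituents <- spec$sulfation
  chain <- gag_chain(atoms, bonds, residues)
  assign_atom_types(chain)
}

## ---------------------------------------------------------------------
## toy receptor with planted native pose
## ---------------------------------------------------------------------

## anionic anchor atoms of a typed chain: one terminal oxygen per
## sulfate (the one furthest from the chain centroid) plus one
## carboxylate oxygen per uronic acid
anchor_atoms <- function(chain) {
  a <- chain$atoms
  ctr <- colMeans(coords_of(chain))
  out <- integer(0)
  for (s in which(a$element == "S")) {
    nb <- neighbors_of(chain, s)
    term <- nb[a$element[nb] == "O" & atom_degree(chain)[nb] == 1]
    if (length(term) == 0) next
    d <- apply(coords_of(chain)[term, , drop = FALSE], 1,
               function(p) vnorm(p - ctr))
    out <- c(out, term[which.max(d)])
  }
  out <- c(out, which(a$name == "O6A"))
  sort(out)
}

neighbors_of <- function(chain, k) {
  b <- chain$bonds
  c(b$j[b$i == k], b$i[b$j == k])
}

#' Build a toy groove receptor complementary to a chain
#'
#' Places one cationic (ammonium-like, +1) pseudo-residue 2.85 A from a
#' fraction `tightness` of the chain's anionic anchor oxygens (sulfate
#' and carboxylate groups), directed away from the ligand, plus neutral
#' carbon wall atoms under the pyranose rings giving the groove shape.
#' The chain's as-built coordinates are the planted native pose.
#' `tightness = 0` yields a receptor with no atom within 6 A (site
#' definition then fails with an empty-site error).
#'
#' @param chain a typed `gag_chain` (see [make_chain()]).
#' @param tightness fraction in [0, 1] of anchors given a contact site.
#' @param seed integer; fixes which anchors are kept at partial tightness.
#' @return list(receptor, native_pose, chain).
#' @export
make_complex <- function(chain, tightness = 1, seed = 1) {
  stopifnot(tightness >= 0, tightness <= 1)
  xyz <- coords_of(chain)
  ctr <- colMeans(xyz)
  anchors <- anchor_atoms(chain)
  n_keep <- ceiling(tightness * length(anchors))
  keep <- if (n_keep == 0) integer(0) else {
    set.seed(seed)
    anchors[sort(sample.int(length(anchors), n_keep))]
  }
  ## push a candidate receptor atom outward along dir until it clears
  ## every ligand atom by min_d (at most 3 A further out)
  clear_point <- function(base, dir, start, min_d) {
    dir <- unit(dir)
    for (s in seq(start, start + 3, by = 0.2)) {
      p <- base + s * dir
      if (min(sqrt(colSums((t(xyz) - p)^2))) >= min_d) return(p)
    }
    base + (start + 3) * dir
  }
  rows <- list()
  rn <- 0
  deg <- atom_degree(chain)
  for (k in keep) {
    rn <- rn + 1
    ## bidentate salt-bridge geometry: the cationic site straddles two
    ## terminal oxygens of the anionic group at H-bond distance (the
    ## arrangement ammonium/guanidinium groups adopt against sulfates
    ## and carboxylates), which makes the planted contacts the
    ## H-bond-maximal ones
    nb <- neighbors_of(chain, k)
    heavy_nb <- nb[chain$atoms$element[nb] %in% c("S", "C")][1]
    sibs <- neighbors_of(chain, heavy_nb)
    term <- sibs[chain$atoms$element[sibs] == "O" & deg[sibs] == 1]
    pair <- if (length(term) >= 2) {
      others <- setdiff(term, k)
      c(k, others[which.max(sapply(others, function(o)
        vnorm(xyz[o, ] - ctr)))])
    } else c(k, k)
    m <- colMeans(xyz[pair, , drop = FALSE])
    dir <- unit(m - xyz[heavy_nb, ])
    half <- vnorm(xyz[pair[1], ] - xyz[pair[2], ]) / 2
    reach <- sqrt(max(2.85^2 - half^2, 1))
    others <- xyz[-pair, , drop = FALSE]
    p <- m + reach * dir
    for (s in seq(reach, reach + 1.6, by = 0.15)) {
      p <- m + s * dir
      if (min(sqrt(colSums((t(others) - p)^2))) >= 2.75) break
    }
    rows[[length(rows) + 1]] <- data.frame(
      resno = rn, resid = "PRS", name = "NZ", element = "N",
      x = p[1], y = p[2], z = p[3], charge = 1)
  }
  ## neutral walls forming a U-channel: three directions around the
  ## local chain tangent per ring, so off-register or flipped poses
  ## collide with the groove instead of skating over a flat surface
  n_res <- nrow(chain$residues)
  ring_ctr <- t(vapply(seq_len(n_res), function(r) {
    ring_ix <- which(chain$atoms$resno == r & chain$atoms$name %in% RING_NAMES)
    colMeans(xyz[ring_ix, , drop = FALSE])
  }, numeric(3)))
  n_wall <- round(tightness * n_res)
  for (r in seq_len(n_wall)) {
    rc <- ring_ctr[r, ]
    tangent <- if (n_res == 1) c(1, 0, 0) else if (r == 1)
      ring_ctr[2, ] - ring_ctr[1, ] else if (r == n_res)
      ring_ctr[n_res, ] - ring_ctr[n_res - 1, ] else
      ring_ctr[r + 1, ] - ring_ctr[r - 1, ]
    down <- rc - ctr
    down[3] <- down[3] - 1
    down <- unit(down - tangent * sum(unit(tangent) * down) /
                   vnorm(tangent))
    for (ang in c(-55, 0, 55)) {
      d2 <- as.numeric(rotation_matrix(tangent, ang) %*% down)
      p <- clear_point(rc, d2, 4.2, 3.4)
      rn <- rn + 1
      rows[[length(rows) + 1]] <- data.frame(
        resno = rn, resid = "PRS", name = "CW", element = "C",
        x = p[1], y = p[2], z = p[3], charge = 0)
    }
  }
  if (length(rows) == 0) {
    ## distant scaffold so the receptor is never empty
    for (k in 1:4) {
      rn <- rn + 1
      rows[[length(rows) + 1]] <- data.frame(
        resno = rn, resid = "PRS", name = "CW", element = "C",
        x = ctr[1] + 25 + 2 * k, y = ctr[2], z = ctr[3], charge = 0)
    }
  }
  receptor <- structure(list(atoms = do.call(rbind, rows), site = NULL),
                        class = "gag_receptor")
  native <- new_pose(xyz, score = NA_real_)
  list(receptor = receptor, native_pose = native, chain = chain)
}

#' @export
print.gag_receptor <- function(x, ...) {
  cat(sprintf("gag_receptor: %d pseudo-atoms in %d residues\n",
              nrow(x$atoms), length(unique(x$atoms$resno))))
  invisible(x)
}

## ---------------------------------------------------------------------
## poses and decoys
## ---------------------------------------------------------------------

#' Construct a pose object
#' @param coords heavy-atom coordinate matrix (receptor frame).
#' @param score docking score (list with `total` or single number).
#' @param chromosome generating chromosome, if any.
#' @param run_id,replicate_id,rank provenance.
#' @export
new_pose <- function(coords, score = NA_real_, chromosome = NULL,
                     run_id = NA_integer_, replicate_id = NA_integer_,
                     rank = NA_integer_) {
  structure(list(coords = as.matrix(coords), score = score,
                 chromosome = chromosome, run_id = run_id,
                 replicate_id = replicate_id, rank = rank),
            class = "dock_pose")
}

#' Total score of a pose (NA-safe accessor)
#' @param pose a `dock_pose`.
#' @export
pose_total_score <- function(pose) {
  s <- pose$score
  if (is.list(s)) s$total else as.numeric(s)
}

#' Generate decoy pose sets with analytic ground truth
#'
#' `translate` decoys are rigid translations by `magnitude` A along
#' random directions (in-place RMSD to native is exactly `magnitude`);
#' `torsion-perturb` decoys shift the Psi torsion of `linkage` by
#' `magnitude` degrees (known per-linkage deviation); `mixed` applies
#' both.
#'
#' @param native a `dock_pose` (the chain's native coordinates).
#' @param chain the `gag_chain` the pose belongs to.
#' @param kind "translate", "torsion-perturb" or "mixed".
#' @param magnitude A for translations, degrees for torsion shifts.
#' @param n number of decoys.
#' @param seed RNG seed.
#' @param linkage linkage row index perturbed for torsion decoys.
#' @return list of `dock_pose` with attribute `ground_truth`.
#' @export
make_decoys <- function(native, chain, kind = c("translate", "torsion-perturb",
                                                "mixed"),
                        magnitude = 5, n = 6, seed = 1, linkage = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  poses <- vector("list", n)
  truth <- vector("list", n)
  tree <- torsion_tree(chain, enumerate_rotatable_bonds(chain, "flexible"))
  for (k in seq_len(n)) {
    xyz <- native$coords
    dpsi <- 0
    if (kind %in% c("torsion-perturb", "mixed")) {
      xyz <- set_linkage_psi(chain, xyz, linkage, tree,
                             delta = magnitude)
      dpsi <- magnitude
    }
    tvec <- c(0, 0, 0)
    if (kind %in% c("translate", "mixed")) {
      dir <- stats::rnorm(3)
      tvec <- magnitude * unit(dir)
      xyz <- sweep(xyz, 2, tvec, "+")
    }
    poses[[k]] <- new_pose(xyz, rank = k)
    truth[[k]] <- list(translation = tvec, dpsi = dpsi, linkage = linkage)
  }
  attr(poses, "ground_truth") <- truth
  poses
}

## rotate the distal side of linkage `lk`'s Psi bond by `delta` degrees
set_linkage_psi <- function(chain, xyz, lk, tree, delta) {
  pa <- chain$linkages$psi_atoms[[lk]]  # C1 O4' C4' C3'
  key <- paste(sort(pa[2:3]), collapse = "-")
  hit <- NULL
  for (b in tree) {
    if (paste(sort(c(b$i, b$j)), collapse = "-") == key) { hit <- b; break }
  }
  if (is.null(hit)) stop("psi bond of linkage ", lk, " not in torsion tree")
  rotate_about_bond(xyz, hit, delta)
}

## ---------------------------------------------------------------------
## torsion corpus
## ---------------------------------------------------------------------

#' Generate a synthetic torsion-observation corpus
#'
#' Builds chains whose glycosidic torsions are drawn from wrapped
#' normals around the given class centers (a stand-in for a curated set
#' of crystallographic complexes).
#'
#' @param n_chains number of chains.
#' @param class_centers named list as [default_torsion_centers()]; for a
#'   multi-modal class one mode is picked uniformly per linkage.
#' @param noise_sd wrapped-normal standard deviation, degrees.
#' @param seed RNG seed.
#' @param chain_length residues per chain.
#' @return list of `gag_chain` with names usable as source ids.
#' @export
make_torsion_corpus <- function(n_chains = 20,
                                class_centers = default_torsion_centers(),
                                noise_sd = 10, seed = 1, chain_length = 4) {
  set.seed(seed)
  out <- vector("list", n_chains)
  for (c1 in seq_len(n_chains)) {
    sp0 <- fixture_spec(chain_length = chain_length)
    plan <- sp0$torsion_plan
    for (j in seq_len(nrow(plan))) {
      donor_kind <- sp0$kinds[j + 1]
      cls <- if (donor_kind %in% UA_KINDS) "UA->GlcN" else "GlcN->UA"
      modes <- class_centers[[cls]]
      m <- modes[sample.int(nrow(modes), 1), ]
      plan[j, ] <- wrap_angle(m + stats::rnorm(2, 0, noise_sd))
    }
    sp <- fixture_spec(chain_length = chain_length, torsion_plan = plan)
    out[[c1]] <- make_chain(sp)
  }
  names(out) <- sprintf("SYN%03d", seq_len(n_chains))
  out
}
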