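## Structure I/O and preparation: SYBYL-style atom typing with the
## carboxylate-oxygen surrogate for sulfate oxygens, formal-charge
## assignment, binding-site definition, and PDB / mol2 reading and
## writing via bio3d. Coordinates are Angstrom throughout; all metrics
## operate on heavy atoms.

## covalent radii (A) for bond inference on PDB ligands
COVALENT_RADII <- c(C = 0.77, N = 0.70, O = 0.66, S = 1.04, H = 0.31,
                    P = 1.07)
BOND_SLACK <- 0.45

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.10)

## residue kind <-> 3-letter code used in emitted files
KIND_CODES <- c(GlcN = "GCN", GlcA = "GCA", IdoA = "IDA", pseudo = "PSD")

#' Assign SYBYL-style atom types and formal charges to a chain
#'
#' Terminal sulfate oxygens and carboxylate oxygens get the `O.co2`
#' type (the carboxylate-oxygen surrogate typing for sulfates); each
#' sulfate group carries net -1 divided equally over its terminal
#' oxygens, each carboxylate -1 over its two oxygens, free amines +1 on
#' the nitrogen. Unrecognized substituents are warned about and typed
#' neutral.
#'
#' @param chain a `gag_chain`.
#' @return the chain with `atom_type` and `formal_charge` filled.
#' @export
assign_atom_types <- function(chain) {
  a <- chain$atoms
  deg <- atom_degree(chain)
  type <- rep(NA_character_, nrow(a))
  q <- rep(0, nrow(a))
  ring <- paste(a$resno, a$name) %in%
    unlist(lapply(chain$residues$resno, function(r) paste(r, RING_NAMES)))
  for (k in seq_len(nrow(a))) {
    el <- a$element[k]
    nb <- neighbors_of(chain, k)
    if (el == "C") {
      two_term_o <- sum(a$element[nb] == "O" & deg[nb] == 1)
      type[k] <- if (two_term_o >= 2 || a$name[k] == "C7") "C.2" else "C.3"
    } else if (el == "O") {
      if (deg[k] == 1 && any(a$element[nb] == "S")) {
        type[k] <- "O.co2"       # sulfate terminal oxygen, surrogate type
      } else if (deg[k] == 1 && any(a$name[nb] == "C6" &
                                    a$kind[nb] %in% UA_KINDS)) {
        type[k] <- "O.co2"       # carboxylate oxygen
        q[k] <- -0.5
      } else if (a$name[k] == "O7") {
        type[k] <- "O.2"
      } else {
        type[k] <- "O.3"
      }
    } else if (el == "N") {
      if (any(a$element[nb] == "S")) type[k] <- "N.3"
      else if (any(a$name[nb] == "C7")) type[k] <- "N.am"
      else { type[k] <- "N.4"; q[k] <- 1 }   # free amine
    } else if (el == "S") {
      type[k] <- "S.o2"
    } else if (el == "H") {
      type[k] <- "H"
    } else {
      warning("unrecognized element ", el, "; typed neutral")
      type[k] <- el
    }
  }
  ## sulfate groups: -1 split over the terminal oxygens
  for (s in which(a$element == "S")) {
    nb <- neighbors_of(chain, s)
    term <- nb[a$element[nb] == "O" & deg[nb] == 1]
    if (length(term) > 0) q[term] <- q[term] - 1 / length(term)
  }
  chain$atoms$atom_type <- type
  chain$atoms$formal_charge <- q
  chain
}

#' Total formal charge of a chain or residue
#' @param chain a typed `gag_chain`.
#' @param resno optional residue number to restrict to.
#' @export
total_charge <- function(chain, resno = NULL) {
  a <- chain$atoms
  if (!is.null(resno)) a <- a[a$resno == resno, ]
  sum(a$formal_charge)
}

## ---------------------------------------------------------------------
## binding-site definition
## ---------------------------------------------------------------------

#' Define a docking site around a reference pose
#'
#' Selects all receptor residues having at least one atom within
#' `radius` of any heavy atom of the reference pose (the 6 A
#' native-pose site rule), and computes the site bounding box used to
#' bound the GA translation genes.
#'
#' @param receptor a `gag_receptor`.
#' @param reference a `dock_pose` with at least one heavy atom.
#' @param radius site radius in A (default 6).
#' @return list(site_atoms, site_residues, radius, box) of class
#'   `site_definition`; `box` is a 2x3 matrix (min / max over the site
#'   atoms and reference pose).
#' @export
define_site <- function(receptor, reference, radius = 6.0) {
  stopifnot(radius > 0)
  ra <- receptor$atoms
  rxyz <- as.matrix(ra[, c("x", "y", "z")])
  pxyz <- reference$coords
  if (nrow(pxyz) < 1) stop("reference pose has no atoms")
  ## nearest reference-atom distance per receptor atom
  mind <- apply(rxyz, 1, function(p)
    sqrt(min(colSums((t(pxyz) - p)^2))))
  in_res <- unique(ra$resno[mind <= radius])
  if (length(in_res) == 0)
    stop("empty site: no receptor residue within ", radius,
         " A of the reference pose")
  site_atoms <- which(ra$resno %in% in_res)
  allxyz <- rbind(rxyz[site_atoms, , drop = FALSE], pxyz)
  box <- rbind(min = apply(allxyz, 2, min), max = apply(allxyz, 2, max))
  colnames(box) <- c("x", "y", "z")
  structure(list(site_atoms = site_atoms, site_residues = in_res,
                 radius = radius, box = box),
            class = "site_definition")
}

## ---------------------------------------------------------------------
## reading
## ---------------------------------------------------------------------

#' Read a receptor or ligand structure
#'
#' mol2 files (explicit connectivity) are returned as `gag_chain`
#' ligands; PDB files are returned as `gag_receptor` unless
#' `as = "ligand"`, in which case bonds are inferred from covalent radii
#' plus 0.45 A slack. Alternate locations: the first (blank or "A")
#' altloc is kept.
#'
#' @param path file path.
#' @param format "auto" (by extension), "pdb" or "mol2".
#' @param as for PDB input, "receptor" or "ligand".
#' @return `gag_receptor` or `gag_chain`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mol2"),
                           as = c("receptor", "ligand")) {
  format <- match.arg(format)
  as <- match.arg(as)
  if (format == "auto")
    format <- if (grepl("\\.mol2$", path, ignore.case = TRUE)) "mol2" else "pdb"
  if (format == "mol2") return(read_chain_mol2(path))
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), ]
  if (nrow(at) == 0) stop("empty structure: ", path)
  if (as == "receptor") {
    atoms <- data.frame(resno = at$resno, resid = at$resid, name = at$elety,
                        element = guess_element(at$elety, at$elesy),
                        x = at$x, y = at$y, z = at$z,
                        charge = ifelse(is.na(at$o), 0, at$o))
    ## charges for pseudo-receptors travel in the occupancy column
    return(structure(list(atoms = atoms, site = NULL), class = "gag_receptor"))
  }
  pdb_to_chain(at)
}

guess_element <- function(name, elesy = NULL) {
  if (!is.null(elesy)) {
    e <- toupper(trimws(elesy))
    ok <- !is.na(e) & e %in% names(COVALENT_RADII)
    if (all(ok)) return(substr(e, 1, 1))
  }
  substr(gsub("[^A-Za-z].*", "", trimws(name)), 1, 1)
}

infer_bonds <- function(atoms) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- COVALENT_RADII[atoms$element]
  rad[is.na(rad)] <- 0.77
  n <- nrow(xyz)
  out <- list()
  for (i in seq_len(n - 1)) {
    d <- sqrt(colSums((t(xyz[(i + 1):n, , drop = FALSE]) - xyz[i, ])^2))
    cut <- rad[i] + rad[(i + 1):n] + BOND_SLACK
    hit <- which(d <= cut)
    for (h in hit) out[[length(out) + 1]] <- c(i, i + h)
  }
  if (length(out) == 0) return(data.frame(i = integer(), j = integer()))
  m <- do.call(rbind, out)
  data.frame(i = m[, 1], j = m[, 2])
}

kind_from_code <- function(resid, has_n2, has_carb) {
  code <- names(KIND_CODES)[match(resid, KIND_CODES)]
  ifelse(!is.na(code), code,
         ifelse(has_n2, "GlcN", ifelse(has_carb, "GlcA", "pseudo")))
}

pdb_to_chain <- function(at) {
  atoms <- data.frame(eleno = seq_len(nrow(at)), name = at$elety,
                      element = guess_element(at$elety, at$elesy),
                      resno = match(at$resno, unique(at$resno)),
                      kind = NA_character_,
                      x = at$x, y = at$y, z = at$z)
  atoms <- fill_kinds(atoms, at$resid)
  bonds <- infer_bonds(atoms)
  residues <- residues_from_atoms(atoms)
  assign_atom_types(gag_chain(atoms, bonds, residues))
}

fill_kinds <- function(atoms, resid) {
  for (r in unique(atoms$resno)) {
    sel <- atoms$resno == r
    nm <- atoms$name[sel]
    atoms$kind[sel] <- kind_from_code(resid[sel][1],
                                      "N2" %in% nm, "O6A" %in% nm)
  }
  atoms
}

residues_from_atoms <- function(atoms) {
  rn <- unique(atoms$resno)
  res <- data.frame(resno = rn,
                    kind = atoms$kind[match(rn, atoms$resno)])
  res$substituents <- lapply(rn, function(r) {
    nm <- atoms$name[atoms$resno == r]
    subs <- character(0)
    if ("SN" %in% nm) subs <- c(subs, "2N-sulfate")
    if ("C7" %in% nm) subs <- c(subs, "2N-acetate")
    if ("S2" %in% nm) subs <- c(subs, "2O-sulfate")
    if ("S3" %in% nm) subs <- c(subs, "3O-sulfate")
    if ("S6" %in% nm) subs <- c(subs, "6O-sulfate")
    if ("O6A" %in% nm) subs <- c(subs, "carboxylate")
    subs
  })
  res
}

read_chain_mol2 <- function(path) {
  m <- bio3d::read.mol2(path)
  at <- m$atom
  if (nrow(at) == 0) stop("empty structure: ", path)
  atoms <- data.frame(eleno = seq_len(nrow(at)), name = at$elena,
                      element = substr(gsub("\\..*", "", at$elety), 1, 1),
                      resno = match(at$resno, unique(at$resno)),
                      kind = NA_character_,
                      x = at$x, y = at$y, z = at$z)
  atoms <- fill_kinds(atoms, at$resid)
  bonds <- data.frame(i = match(m$bond$origin, at$eleno),
                      j = match(m$bond$target, at$eleno))
  residues <- residues_from_atoms(atoms)
  assign_atom_types(gag_chain(atoms, bonds, residues))
}

## ---------------------------------------------------------------------
## writing
## ---------------------------------------------------------------------

chain_to_mol2 <- function(chain, name = "gag_chain", xyz = NULL) {
  a <- chain$atoms
  if (is.null(xyz)) xyz <- coords_of(chain)
  atom <- data.frame(
    eleno = seq_len(nrow(a)), elena = a$name,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    elety = ifelse(is.na(a$atom_type), a$element, a$atom_type),
    resno = a$resno,
    resid = unname(KIND_CODES[a$kind]),
    charge = a$formal_charge)
  atom$resid[is.na(atom$resid)] <- "UNK"
  bond <- data.frame(id = seq_len(nrow(chain$bonds)),
                     origin = chain$bonds$i, target = chain$bonds$j,
                     type = "1")
  m <- list(atom = atom, bond = bond, substructure = NULL,
            xyz = as.numeric(t(xyz)),
            info = c(nrow(atom), nrow(bond), length(unique(atom$resno)), 0, 0),
            name = name)
  class(m) <- "mol2"
  m
}

#' Write a chain (optionally with replacement coordinates) to mol2
#' @param chain a `gag_chain`.
#' @param path output path.
#' @param xyz optional coordinate matrix overriding the chain's own.
#' @param name molecule name in the file.
#' @export
write_chain_mol2 <- function(chain, path, xyz = NULL, name = "gag_chain") {
  bio3d::write.mol2(chain_to_mol2(chain, name = name, xyz = xyz), file = path)
  invisible(path)
}

#' Write a receptor to PDB
#' @param receptor a `gag_receptor`.
#' @param path output path.
#' @export
write_receptor_pdb <- function(receptor, path) {
  a <- receptor$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$name,
                   chain = rep("A", nrow(a)),
                   o = a$charge, b = rep(0, nrow(a)),
                   elesy = a$element)
  invisible(path)
}

#' Write a pose set
#'
#' mol2 output holds one TRIPOS MOLECULE block per pose preceded by a
#' `# pose`/`# score` comment; PDB output uses MODEL/ENDMDL blocks with
#' a score REMARK. Poses are ordered by rank then pose index
#' (bit-stable ordering).
#'
#' @param poses list of `dock_pose`.
#' @param chain the `gag_chain` giving topology and atom names.
#' @param path output path.
#' @param format "mol2" or "pdb".
#' @export
write_poses <- function(poses, chain, path, format = c("mol2", "pdb")) {
  format <- match.arg(format)
  ord <- order(vapply(poses, function(p)
    ifelse(is.na(p$rank), .Machine$integer.max, p$rank), 0),
    seq_along(poses))
  poses <- poses[ord]
  if (format == "mol2") {
    tmp <- tempfile(fileext = ".mol2")
    on.exit(unlink(tmp), add = TRUE)
    all_lines <- character(0)
    for (k in seq_along(poses)) {
      p <- poses[[k]]
      write_chain_mol2(chain, tmp, xyz = p$coords, name = sprintf("pose_%d", k))
      all_lines <- c(all_lines,
                     sprintf("# pose %d rank %s score %.6f", k,
                             ifelse(is.na(p$rank), "NA", as.character(p$rank)),
                             pose_total_score(p)),
                     readLines(tmp))
    }
    writeLines(all_lines, path)
  } else {
    a <- chain$atoms
    if (file.exists(path)) unlink(path)
    for (k in seq_along(poses)) {
      p <- poses[[k]]
      cat(sprintf("REMARK   6 POSE %d SCORE %.6f\nMODEL %8d\n", k,
                  pose_total_score(p), k),
          file = path, append = TRUE)
      bio3d::write.pdb(file = path, append = TRUE, end = FALSE,
                       xyz = as.numeric(t(p$coords)),
                       type = rep("HETATM", nrow(a)),
                       resno = a$resno,
                       resid = unname(KIND_CODES[a$kind]),
                       eleno = seq_len(nrow(a)), elety = a$name,
                       chain = rep("L", nrow(a)),
                       o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                       elesy = a$element)
      cat("ENDMDL\n", file = path, append = TRUE)
    }
    cat("END\n", file = path, append = TRUE)
  }
  invisible(path)
}

#' Read a multi-pose mol2 file written by [write_poses()]
#' @param path file path.
#' @return list of `dock_pose` (scores recovered from the comments).
#' @export
read_poses <- function(path) {
  lines <- readLines(path)
  starts <- grep("^# pose ", lines)
  if (length(starts) == 0) return(list())
  ends <- c(starts[-1] - 1, length(lines))
  poses <- vector("list", length(starts))
  tmp <- tempfile(fileext = ".mol2")
  on.exit(unlink(tmp), add = TRUE)
  for (k in seq_along(starts)) {
    hdr <- lines[starts[k]]
    score <- as.numeric(sub(".*score ", "", hdr))
    writeLines(lines[(starts[k] + 1):ends[k]], tmp)
    m <- bio3d::read.mol2(tmp)
    poses[[k]] <- new_pose(as.matrix(m$atom[, c("x", "y", "z")]),
                           score = score, rank = k)
  }
  poses
}
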