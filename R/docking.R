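## Genetic-algorithm pose search: rigid-body genes (translation within
## the site box, orientation quaternion) plus one torsion gene per
## rotatable bond, with regime-dependent tagging (fixed / bounded /
## free) of the glycosidic Phi/Psi genes, and a documented additive
## surrogate interaction score (H-bond well + screened electrostatics
## + Lennard-Jones with clash cap + ligand strain penalty).

#' GA configuration
#'
#' @param n_runs independent GA runs per replicate (default 100).
#' @param n_operations offspring construction+evaluation steps per run
#'   (default 10000).
#' @param population_size chromosomes in the population.
#' @param crossover_prob one-point crossover probability.
#' @param mutation_prob per-gene mutation probability.
#' @param tournament_size selection tournament size.
#' @param replicates triplicate by default.
#' @param top_per_run poses retained per replicate (top 2 by score).
#' @param seed base RNG seed; replicate r uses seed + r - 1.
#' @param dedupe_rmsd minimum RMSD (A) between retained poses.
#' @param box_margin A added around the site bounding box for the
#'   translation genes.
#' @param polish_iters local-polish moves applied to each retained
#'   pose after the GA (0 disables; skipped when n_operations = 0).
#' @export
ga_config <- function(n_runs = 100, n_operations = 10000,
                      population_size = 100, crossover_prob = 0.9,
                      mutation_prob = 0.1, tournament_size = 2,
                      replicates = 3, top_per_run = 2, seed = 1,
                      dedupe_rmsd = 0.25, box_margin = 2,
                      polish_iters = 250) {
  stopifnot(n_runs >= 1, n_operations >= 0, population_size >= 2,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            replicates >= 1, top_per_run >= 1)
  structure(as.list(environment()), class = "ga_config")
}

## ---------------------------------------------------------------------
## torsion tree
## ---------------------------------------------------------------------

## Orient each rotatable bond proximal->distal relative to the reducing
## end (root = C1 of residue 1) and record the atoms moved by its
## rotation plus reference atoms for measuring the torsion. Bonds whose
## distal side carries no off-axis heavy atom (terminal O1/O4 caps)
## get moved = integer(0) and are geometrically inert.
torsion_tree <- function(chain, bonds) {
  n <- nrow(chain$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(chain$bonds))) {
    i <- chain$bonds$i[k]; j <- chain$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  root <- atom_index(chain, 1, "C1")
  ## BFS depth from root for ordering
  depth <- rep(NA_integer_, n)
  depth[root] <- 0L
  queue <- root
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (is.na(depth[w])) {
      depth[w] <- depth[v] + 1L
      queue <- c(queue, w)
    }
  }
  ## atoms reachable from b without crossing the a-b edge
  component_after_cut <- function(a, b) {
    seen <- rep(FALSE, n)
    seen[b] <- TRUE
    queue <- b
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (v == b && w == a) next
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    seen
  }
  out <- vector("list", nrow(bonds))
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    seen <- component_after_cut(i, j)
    if (seen[root]) {  # j side holds the root: swap orientation
      tmp <- i; i <- j; j <- tmp
      seen <- component_after_cut(i, j)
    }
    moved <- setdiff(which(seen), c(i, j))
    ## reference atoms: torsion = dihedral(ref_c, i, j, ref_d)
    if (bonds$tag[k] == "glycosidic") {
      lk <- chain$linkages
      r <- bonds$linkage[k]
      quad <- if (bonds$torsion[k] == "phi") lk$phi_atoms[[r]] else lk$psi_atoms[[r]]
      ## quad is ordered p1-p2-p3-p4 about the bond p2-p3
      refs <- quad
    } else {
      ci <- setdiff(adj[[i]], j)
      cj <- setdiff(adj[[j]], i)
      ci <- ci[chain$atoms$element[ci] != "H"]
      cj <- cj[chain$atoms$element[cj] != "H"]
      refs <- if (length(ci) > 0 && length(cj) > 0)
        c(min(ci), i, j, min(cj)) else NULL
    }
    out[[k]] <- list(i = i, j = j, moved = moved,
                     tag = bonds$tag[k], torsion = bonds$torsion[k],
                     linkage = bonds$linkage[k], refs = refs,
                     depth = min(depth[i], depth[j]))
  }
  out <- out[order(vapply(out, `[[`, 0L, "depth"))]
  ## rotation sense: does rotating the moved set by +10 deg about the
  ## oriented axis increase or decrease the measured torsion?
  xyz <- coords_of(chain)
  for (k in seq_along(out)) {
    b <- out[[k]]
    out[[k]]$sense <- 1L
    if (is.null(b$refs) || length(b$moved) == 0) next
    cur <- bond_torsion_value(xyz, b)
    trial <- bond_torsion_value(rotate_about_bond(xyz, b, 10), b)
    if (circular_dist(trial, cur + 10) > 1) out[[k]]$sense <- -1L
  }
  out
}

## flatten a torsion tree into the arrays the C++ decoder consumes
tree_arrays <- function(tree) {
  nb <- length(tree)
  refs <- matrix(0L, nrow = max(nb, 1), ncol = 4)
  for (k in seq_len(nb))
    if (!is.null(tree[[k]]$refs)) refs[k, ] <- as.integer(tree[[k]]$refs)
  list(bond_i = vapply(tree, `[[`, 0L, "i"),
       bond_j = vapply(tree, `[[`, 0L, "j"),
       moved = lapply(tree, function(b) as.integer(b$moved)),
       refs = refs[seq_len(nb), , drop = FALSE],
       sense = vapply(tree, `[[`, 0L, "sense"))
}

## rotate the moved set of a tree bond so its torsion changes by delta
rotate_about_bond <- function(xyz, bond, delta) {
  if (length(bond$moved) == 0) return(xyz)
  axis <- xyz[bond$j, ] - xyz[bond$i, ]
  rot <- rotation_matrix(axis, delta)
  pivot <- xyz[bond$i, ]
  m <- sweep(xyz[bond$moved, , drop = FALSE], 2, pivot)
  xyz[bond$moved, ] <- sweep(m %*% t(rot), 2, pivot, "+")
  xyz
}

## measured torsion value of a tree bond (NA if no references)
bond_torsion_value <- function(xyz, bond) {
  if (is.null(bond$refs)) return(NA_real_)
  dihedral_rows(xyz[bond$refs, , drop = FALSE])
}

## set a tree bond's torsion to an absolute value (degrees)
set_bond_torsion <- function(xyz, bond, value) {
  cur <- bond_torsion_value(xyz, bond)
  if (is.na(cur)) return(xyz)
  d <- wrap_angle(value - cur)
  out <- rotate_about_bond(xyz, bond, d)
  ## rotation sense depends on bond orientation; correct if reversed
  if (circular_dist(bond_torsion_value(out, bond), value) > 1e-6)
    out <- rotate_about_bond(xyz, bond, -d)
  out
}

## ---------------------------------------------------------------------
## regimes and chromosome templates
## ---------------------------------------------------------------------

#' Build a chromosome template for a chain under a docking regime
#'
#' Enumerates the full rotatable-bond set, tags glycosidic Phi/Psi genes
#' `fixed` (rigid), `bounded` (semi-rigid) or `free` (flexible) and
#' substituent genes always `free`, and records each gene's initial
#' torsion. For the semi-rigid regime, per-linkage histograms default
#' to +/-30 degree raised-cosine bells centered on the chain's initial
#' torsions; a histogram whose support excludes the initial torsion is
#' a configuration error.
#'
#' @param chain a `gag_chain`.
#' @param regime "rigid", "semi-rigid" or "flexible".
#' @param histograms optional list; element `[[linkage]][[c("phi","psi")]]`
#'   is a `torsion_histogram`.
#' @param halfwidth default histogram halfwidth (degrees).
#' @return list of class `chromosome_template`.
#' @export
build_regime <- function(chain, regime = c("rigid", "semi-rigid", "flexible"),
                         histograms = NULL, halfwidth = 30) {
  regime <- match.arg(regime)
  bonds <- enumerate_rotatable_bonds(chain, "flexible")
  tree <- torsion_tree(chain, bonds)
  xyz <- coords_of(chain)
  genes <- vector("list", length(tree))
  for (k in seq_along(tree)) {
    b <- tree[[k]]
    init <- bond_torsion_value(xyz, b)
    if (b$tag == "glycosidic") {
      mode <- switch(regime, rigid = "fixed", `semi-rigid` = "bounded",
                     flexible = "free")
      hist <- NULL
      if (mode == "bounded") {
        hist <- histograms[[as.character(b$linkage)]][[b$torsion]]
        if (is.null(hist))
          hist <- build_histogram(init, halfwidth = halfwidth)
        if (!hist_supports(hist, init))
          stop("configuration error: histogram support for linkage ",
               b$linkage, " ", b$torsion,
               " excludes the initial torsion (", round(init, 2), " deg)")
      }
      genes[[k]] <- list(mode = mode, initial = init, hist = hist)
    } else {
      genes[[k]] <- list(mode = "free", initial = init, hist = NULL)
    }
  }
  structure(list(regime = regime, tree = tree, genes = genes,
                 arrays = tree_arrays(tree),
                 active = vapply(genes, function(g) g$mode != "fixed", TRUE),
                 initials = vapply(genes, `[[`, 0, "initial"),
                 template_xyz = xyz, centroid = colMeans(xyz)),
            class = "chromosome_template")
}

#' Assemble a docking job
#'
#' @param receptor a `gag_receptor`.
#' @param chain the ligand `gag_chain` at its initial (reference)
#'   geometry.
#' @param regime docking regime.
#' @param config a [ga_config()].
#' @param reference pose used for the 6 A site definition; defaults to
#'   the chain's own coordinates (redocking setup).
#' @param histograms optional per-linkage histograms for semi-rigid.
#' @param site optional precomputed [define_site()] result.
#' @return list of class `docking_job`.
#' @export
docking_job <- function(receptor, chain, regime, config = ga_config(),
                        reference = NULL, histograms = NULL, site = NULL) {
  if (is.null(reference)) reference <- new_pose(coords_of(chain))
  if (is.null(site)) site <- define_site(receptor, reference)
  template <- build_regime(chain, regime, histograms)
  ## precompute scoring tables
  sa <- receptor$atoms[site$site_atoms, ]
  lig <- chain$atoms
  strain_pairs <- strain_pair_table(chain)
  lig_r <- unname(VDW_RADII[lig$element])
  site_r <- unname(VDW_RADII[sa$element])
  lig_r[is.na(lig_r)] <- 1.7
  site_r[is.na(site_r)] <- 1.7
  sxyz <- as.matrix(sa[, c("x", "y", "z")])
  site_axis <- if (nrow(sxyz) >= 3)
    unname(stats::prcomp(sxyz)$rotation[, 1]) else NULL
  lig_xyz <- coords_of(chain)
  lig_axis <- if (nrow(lig_xyz) >= 3)
    unname(stats::prcomp(lig_xyz)$rotation[, 1]) else c(1, 0, 0)
  site_span <- if (is.null(site_axis)) 0 else
    diff(range(sxyz %*% site_axis)) - diff(range(lig_xyz %*% lig_axis)) / 2
  structure(list(receptor = receptor, chain = chain, regime = regime,
                 config = config, site = site, template = template,
                 site_axis = site_axis, lig_axis = lig_axis,
                 site_center = colMeans(sxyz),
                 site_span = max(site_span, 2),
                 site_xyz = sxyz,
                 site_q = sa$charge,
                 site_el = sa$element,
                 lig_q = lig$formal_charge,
                 lig_el = lig$element,
                 acc = lig$element == "O",
                 don = sa$element == "N" & sa$charge > 0,
                 rminmat = outer(lig_r, site_r, "+"),
                 strain_pairs = strain_pairs,
                 strain_i = as.integer(strain_pairs[, 1]),
                 strain_j = as.integer(strain_pairs[, 2]),
                 strain_thr = unname(strain_pairs[, 3]),
                 wvec = local({
                   w <- default_score_weights()
                   c(w$hbond * w$hb_strength, w$ele, w$vdw, w$clash,
                     w$strain)
                 })),
            class = "docking_job")
}

## Ligand atom pairs separated by more than 4 bonds, with a per-pair
## clash threshold: 80% of the summed vdW radii, but never above the
## pair's distance in the template conformation (idealized sugar
## geometry legitimately holds some through-space pairs close, and the
## reference conformation is strain-free by definition).
strain_pair_table <- function(chain) {
  n <- nrow(chain$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(chain$bonds))) {
    i <- chain$bonds$i[k]; j <- chain$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  xyz <- coords_of(chain)
  pairs <- list()
  for (i in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[i] <- 0L
    queue <- i
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (dist[v] >= 4L) next
      for (w in adj[[v]]) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
    far <- which(is.na(dist))
    far <- far[far > i]
    if (length(far) > 0)
      pairs[[length(pairs) + 1]] <- cbind(i, far)
  }
  if (length(pairs) == 0)
    return(matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("i", "far", "rmin"))))
  m <- do.call(rbind, pairs)
  d0 <- sqrt(rowSums((xyz[m[, 1], , drop = FALSE] -
                      xyz[m[, 2], , drop = FALSE])^2))
  thr <- pmin(0.8 * (VDW_RADII[chain$atoms$element[m[, 1]]] +
                     VDW_RADII[chain$atoms$element[m[, 2]]]),
              d0 - 1e-6)
  cbind(m, rmin = unname(thr))
}

## ---------------------------------------------------------------------
## chromosome encode / decode
## ---------------------------------------------------------------------

## chromosome = list(trans = 3-vec, quat = 4-vec, torsions = k-vec)

#' Identity chromosome (decodes to the template coordinates)
#' @param template a `chromosome_template` (or `docking_job$template`).
#' @export
identity_chromosome <- function(template) {
  list(trans = c(0, 0, 0), quat = c(1, 0, 0, 0),
       torsions = vapply(template$genes, `[[`, 0, "initial"))
}

#' Random chromosome within the job's site box and torsion modes
#' @param job a `docking_job`.
#' @export
random_chromosome <- function(job) {
  tpl <- job$template
  box <- job$site$box
  m <- job$config$box_margin
  c0 <- tpl$centroid
  tors <- vapply(seq_along(tpl$genes), function(k) {
    g <- tpl$genes[[k]]
    switch(g$mode,
           fixed = g$initial,
           bounded = sample_torsion(g$hist, 1),
           free = wrap_angle(stats::runif(1, -180, 180)))
  }, 0)
  if (!is.null(job$site_axis) && stats::runif(1) < 0.5) {
    ## axis-aligned seed: elongated ligands bind grooves with their
    ## long axis along the site axis, so half the initial population
    ## starts aligned (either sign) with a random roll and a random
    ## slide along the axis
    sgn <- if (stats::runif(1) < 0.5) 1 else -1
    R <- rotation_matrix(job$site_axis, stats::runif(1, 0, 360)) %*%
      align_rotation(job$lig_axis, sgn * job$site_axis)
    span <- job$site_span
    slide <- stats::runif(1, -span / 2, span / 2)
    ctr_target <- job$site_center + slide * job$site_axis +
      stats::rnorm(3, 0, 0.8)
    trans <- pmin(pmax(ctr_target, box[1, ] - m), box[2, ] + m) - c0
    return(list(trans = trans, quat = matrix_to_quat(R), torsions = tors))
  }
  trans <- c(stats::runif(1, box[1, 1] - m, box[2, 1] + m),
             stats::runif(1, box[1, 2] - m, box[2, 2] + m),
             stats::runif(1, box[1, 3] - m, box[2, 3] + m)) - c0
  list(trans = trans, quat = random_quaternion(), torsions = tors)
}

#' Decode a chromosome into pose coordinates
#'
#' Applies torsion genes along the spanning tree rooted at the reducing
#' end, then the quaternion rotation about the template centroid, then
#' the translation. The rigid parts of the molecule are internally
#' undistorted; the identity chromosome reproduces the template
#' coordinates exactly.
#'
#' @param chrom chromosome list(trans, quat, torsions).
#' @param job a `docking_job` (or a `chromosome_template`).
#' @return coordinate matrix.
#' @export
decode_chromosome <- function(chrom, job) {
  tpl <- if (inherits(job, "docking_job")) job$template else job
  ar <- tpl$arrays
  target <- chrom$torsions
  target[is.na(target)] <- 0
  cpp_decode(tpl$template_xyz, ar$bond_i, ar$bond_j, ar$moved, ar$refs,
             ar$sense, target, tpl$active & !is.na(chrom$torsions),
             chrom$quat, tpl$centroid, chrom$trans)
}

## ---------------------------------------------------------------------
## surrogate interaction score
## ---------------------------------------------------------------------

## fast path used inside the GA loop: total score only
score_total <- function(xyz, job) {
  cpp_score(xyz, job$site_xyz, job$lig_q, job$site_q, job$acc, job$don,
            job$rminmat, job$strain_i, job$strain_j, job$strain_thr,
            job$site$box, job$config$box_margin, job$wvec)[1]
}

#' Default score weights for the surrogate interaction score
#' @export
default_score_weights <- function() {
  list(hbond = 9.0, ele = 1.0, vdw = 1.5, clash = 1.0, strain = 1.0,
       hb_strength = 1.0)
}

#' Score a pose against the receptor site
#'
#' A documented additive surrogate for a docking score: an H-bond
#' distance well between receptor donors (charged N) and ligand
#' acceptor oxygens (full weight at <= 3.0 A, tapering to zero at
#' 3.5 A), screened electrostatics 332 q_i q_j / (4 r^2)
#' (distance-dependent dielectric eps = 4r), Lennard-Jones 6-12
#' attraction with per-element radii and a clash cap, and a ligand
#' self-clash (internal strain) penalty. Higher is better. A pose whose
#' centroid leaves the site box by more than the box margin scores
#' -Inf.
#'
#' @param xyz pose coordinates (heavy atoms, receptor frame) or a
#'   `dock_pose`.
#' @param job a `docking_job`.
#' @param weights term weights, see [default_score_weights()].
#' @return list(total, terms = list(hbond, electrostatic, vdw_external,
#'   internal_strain, clash)).
#' @export
score_pose <- function(xyz, job, weights = default_score_weights()) {
  if (inherits(xyz, "dock_pose")) xyz <- xyz$coords
  sp <- job$strain_pairs
  out <- cpp_score(xyz, job$site_xyz, job$lig_q, job$site_q,
                   job$acc, job$don, job$rminmat,
                   as.integer(sp[, 1]), as.integer(sp[, 2]), sp[, 3],
                   job$site$box, job$config$box_margin,
                   c(weights$hbond * weights$hb_strength, weights$ele,
                     weights$vdw, weights$clash, weights$strain))
  list(total = out[1],
       terms = list(hbond = weights$hb_strength * out[2],
                    electrostatic = out[3],
                    vdw_external = out[4] - out[5],
                    internal_strain = out[6], clash = out[5]))
}

## ---------------------------------------------------------------------
## GA search
## ---------------------------------------------------------------------

mutate_chromosome <- function(chrom, job) {
  cfg <- job$config
  tpl <- job$template
  box <- job$site$box
  m <- cfg$box_margin
  c0 <- tpl$centroid
  p <- cfg$mutation_prob
  mutable <- which(tpl$active)
  n_genes <- 4 + length(mutable)  # 3 translation + orientation + torsions
  hit <- stats::runif(n_genes) < p
  ## an offspring that mutates nothing is a wasted evaluation in a
  ## steady-state GA: force one gene when none was selected
  if (!any(hit)) hit[sample.int(n_genes, 1)] <- TRUE
  for (ax in 1:3) {
    if (hit[ax]) {
      lo <- box[1, ax] - m - c0[ax]; hi <- box[2, ax] + m - c0[ax]
      ## mostly local Gaussian steps, occasionally a uniform jump so
      ## the search can leave a register-shifted basin
      v <- if (stats::runif(1) < 0.2) stats::runif(1, lo, hi)
        else chrom$trans[ax] + stats::rnorm(1, 0, 1)
      chrom$trans[ax] <- min(max(v, lo), hi)
    }
  }
  if (hit[4]) {
    u <- stats::runif(1)
    if (u < 0.2) {
      chrom$quat <- random_quaternion()
    } else {
      ## small rotation about a pivot: the centroid, or a random ligand
      ## atom (a coupled rotation+translation move - refining a pose
      ## held by contacts at one end needs rotations about that end)
      ang <- if (stats::runif(1) < 0.5) 15 else 4
      qs <- small_rotation_quaternion(ang)
      if (u < 0.6) {
        chrom$quat <- quat_multiply(qs, chrom$quat)
      } else {
        pivot_ix <- sample.int(nrow(tpl$template_xyz), 1)
        v <- as.numeric(quat_to_matrix(chrom$quat) %*%
                          (tpl$template_xyz[pivot_ix, ] - c0))
        chrom$quat <- quat_multiply(qs, chrom$quat)
        tshift <- v - as.numeric(quat_to_matrix(qs) %*% v)
        for (ax in 1:3) {
          lo <- box[1, ax] - m - c0[ax]; hi <- box[2, ax] + m - c0[ax]
          chrom$trans[ax] <- min(max(chrom$trans[ax] + tshift[ax], lo), hi)
        }
      }
    }
  }
  for (z in seq_along(mutable)) {
    if (!hit[4 + z]) next
    k <- mutable[z]
    g <- tpl$genes[[k]]
    chrom$torsions[k] <- if (g$mode == "bounded")
      sample_torsion(g$hist, 1)
    else wrap_angle(stats::runif(1, -180, 180))
  }
  chrom$quat <- chrom$quat / sqrt(sum(chrom$quat^2))
  chrom
}

crossover_chromosomes <- function(a, b) {
  va <- c(a$trans, a$quat, a$torsions)
  vb <- c(b$trans, b$quat, b$torsions)
  cut <- sample.int(length(va) - 1, 1)
  child <- c(va[seq_len(cut)], vb[(cut + 1):length(vb)])
  out <- list(trans = child[1:3], quat = child[4:7],
              torsions = if (length(child) > 7) child[-(1:7)] else numeric(0))
  out$quat <- out$quat / sqrt(sum(out$quat^2))
  out
}

tournament_pick <- function(fitness, k) {
  cand <- sample.int(length(fitness), k, replace = TRUE)
  cand[which.max(fitness[cand])]
}

#' Run one GA search
#'
#' Steady-state GA with tournament selection (size 2), one-point
#' crossover over the flattened gene vector, per-gene mutation
#' (translation: Gaussian sd 1 A clipped to the box; orientation: small
#' random rotation; free torsion: uniform; bounded torsion: histogram
#' resample; fixed: untouched), replace-worst survivor policy, and
#' exactly `n_operations` offspring evaluations. Returns the all-time
#' best poses, deduplicated at `dedupe_rmsd`.
#'
#' @param job a `docking_job`.
#' @param seed RNG seed for this run.
#' @param run_id,replicate_id provenance labels.
#' @param n_best all-time best poses to retain.
#' @param monitor optional function(chrom, xyz, score) called at every
#'   evaluation (used by instrumented invariant checks).
#' @return list of `dock_pose`, best first; always at least one.
#' @export
run_ga <- function(job, seed = 1, run_id = 1, replicate_id = 1, n_best = 5,
                   monitor = NULL) {
  set.seed(seed)
  cfg <- job$config
  np <- cfg$population_size
  fixed_ix <- which(!job$template$active)
  initials <- job$template$initials
  pop <- vector("list", np)
  fit <- numeric(np)
  xyzs <- vector("list", np)
  for (k in seq_len(np)) {
    pop[[k]] <- random_chromosome(job)
    xyzs[[k]] <- decode_chromosome(pop[[k]], job)
    fit[k] <- score_total(xyzs[[k]], job)
    if (!is.null(monitor)) monitor(pop[[k]], xyzs[[k]], fit[k])
  }
  ## all-time best tracker: list of list(chrom, xyz, total)
  best <- list()
  push_best <- function(chrom, xyz, total, best) {
    if (length(best) == n_best &&
        total <= best[[length(best)]]$total) return(best)
    for (b in best) {
      if (rmsd_plain(xyz, b$xyz) < cfg$dedupe_rmsd) {
        if (total > b$total) {
          best <- Filter(function(z)
            rmsd_plain(xyz, z$xyz) >= cfg$dedupe_rmsd, best)
          break
        }
        return(best)
      }
    }
    best[[length(best) + 1]] <- list(chrom = chrom, xyz = xyz,
                                     total = total)
    best <- best[order(vapply(best, `[[`, 0, "total"),
                       decreasing = TRUE)]
    if (length(best) > n_best) best <- best[seq_len(n_best)]
    best
  }
  for (k in seq_len(np))
    best <- push_best(pop[[k]], xyzs[[k]], fit[k], best)
  ops <- cfg$n_operations
  if (ops > 0) {
    for (op in seq_len(ops)) {
      i1 <- tournament_pick(fit, cfg$tournament_size)
      child <- if (stats::runif(1) < cfg$crossover_prob) {
        i2 <- tournament_pick(fit, cfg$tournament_size)
        crossover_chromosomes(pop[[i1]], pop[[i2]])
      } else pop[[i1]]
      ## fixed genes are never crossed: restore them from the template
      if (length(fixed_ix) > 0) child$torsions[fixed_ix] <- initials[fixed_ix]
      child <- mutate_chromosome(child, job)
      cxyz <- decode_chromosome(child, job)
      s <- score_total(cxyz, job)
      if (!is.null(monitor)) monitor(child, cxyz, s)
      ## crowding replacement: the child competes with the most
      ## similar member of a random subset, so distinct binding-mode
      ## niches survive side by side instead of collapsing early
      cand <- sample.int(np, 5L)
      w <- cand[1]
      dmin <- Inf
      for (ix in cand) {
        d <- sum((xyzs[[ix]] - cxyz)^2)
        if (d < dmin) { dmin <- d; w <- ix }
      }
      if (s <= fit[w]) w <- which.min(fit)
      if (s > fit[w]) {
        pop[[w]] <- child; fit[w] <- s; xyzs[[w]] <- cxyz
        best <- push_best(child, cxyz, s, best)
      }
    }
  }
  if (cfg$polish_iters > 0 && ops > 0) {
    for (k in seq_len(min(3L, length(best)))) {
      pb <- polish_chromosome(best[[k]]$chrom, job,
                              iters = cfg$polish_iters)
      best[[k]] <- list(chrom = pb$chrom, xyz = pb$xyz,
                        total = score_total(pb$xyz, job))
    }
    best <- best[order(vapply(best, `[[`, 0, "total"),
                       decreasing = TRUE)]
  }
  lapply(seq_along(best), function(k) {
    b <- best[[k]]
    new_pose(b$xyz, score = score_pose(b$xyz, job),
             chromosome = b$chrom, run_id = run_id,
             replicate_id = replicate_id, rank = k)
  })
}

rmsd_plain <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

## Greedy local polish of a chromosome: small rigid-body and torsion
## moves, accept on improvement. The coarse GA operators place a pose
## in a basin; this finishes the descent (the role a simplex step
## plays in production docking engines). Bounded genes stay inside
## their histogram support.
polish_chromosome <- function(chrom, job, iters = 150) {
  tpl <- job$template
  c0 <- tpl$centroid
  box <- job$site$box
  m <- job$config$box_margin
  xyz <- decode_chromosome(chrom, job)
  sc <- score_total(xyz, job)
  mutable <- which(tpl$active)
  for (it in seq_len(iters)) {
    cand <- chrom
    u <- stats::runif(1)
    if (u < 0.35) {
      ax <- sample.int(3, 1)
      lo <- box[1, ax] - m - c0[ax]; hi <- box[2, ax] + m - c0[ax]
      cand$trans[ax] <- min(max(cand$trans[ax] + stats::rnorm(1, 0, 0.2),
                                lo), hi)
    } else if (u < 0.7) {
      qs <- small_rotation_quaternion(2)
      if (stats::runif(1) < 0.5) {
        cand$quat <- quat_multiply(qs, cand$quat)
      } else {
        pivot_ix <- sample.int(nrow(tpl$template_xyz), 1)
        v <- as.numeric(quat_to_matrix(cand$quat) %*%
                          (tpl$template_xyz[pivot_ix, ] - c0))
        cand$quat <- quat_multiply(qs, cand$quat)
        tshift <- v - as.numeric(quat_to_matrix(qs) %*% v)
        for (ax in 1:3) {
          lo <- box[1, ax] - m - c0[ax]; hi <- box[2, ax] + m - c0[ax]
          cand$trans[ax] <- min(max(cand$trans[ax] + tshift[ax], lo), hi)
        }
      }
      cand$quat <- cand$quat / sqrt(sum(cand$quat^2))
    } else if (length(mutable) > 0) {
      k <- mutable[sample.int(length(mutable), 1)]
      g <- tpl$genes[[k]]
      v <- wrap_angle(cand$torsions[k] + stats::rnorm(1, 0, 3))
      if (g$mode == "bounded" && !hist_supports(g$hist, v)) next
      cand$torsions[k] <- v
    } else next
    cxyz <- decode_chromosome(cand, job)
    csc <- score_total(cxyz, job)
    if (csc > sc) { chrom <- cand; xyz <- cxyz; sc <- csc }
  }
  list(chrom = chrom, xyz = xyz)
}

#' Triplicate docking with top-k pose retention
#'
#' Replicate r uses seed `config$seed + r - 1`. Within each replicate
#' the best pose of each GA run is pooled, ranked by score (ties broken
#' by replicate, run and pose index, deterministically), deduplicated
#' at `dedupe_rmsd`, and the `top_per_run` best are kept. Defaults (3
#' replicates x top 2) yield exactly six analysis poses.
#'
#' @param job a `docking_job`.
#' @return object of class `pose_set`: list(poses, provenance).
#' @export
dock_replicates <- function(job) {
  cfg <- job$config
  all_poses <- list()
  rep_seeds <- cfg$seed + seq_len(cfg$replicates) - 1
  for (r in seq_len(cfg$replicates)) {
    set.seed(rep_seeds[r])
    run_seeds <- sample.int(.Machine$integer.max - 1, cfg$n_runs)
    run_best <- list()
    for (g in seq_len(cfg$n_runs)) {
      res <- run_ga(job, seed = run_seeds[g], run_id = g, replicate_id = r)
      ## each run contributes its top-scoring distinct poses
      run_best <- c(run_best, res[seq_len(min(cfg$top_per_run,
                                              length(res)))])
    }
    ## rank by score, deterministic tie-break on (run, pose) order
    sc <- vapply(run_best, pose_total_score, 0)
    ord <- order(-sc, seq_along(run_best))
    kept <- list()
    for (ix in ord) {
      cand <- run_best[[ix]]
      dup <- any(vapply(kept, function(p)
        rmsd_plain(p$coords, cand$coords) < cfg$dedupe_rmsd, TRUE))
      if (!dup) kept[[length(kept) + 1]] <- cand
      if (length(kept) >= cfg$top_per_run) break
    }
    ## guarantee top_per_run poses even if all runs converged identically
    ix <- 1
    while (length(kept) < cfg$top_per_run && ix <= length(ord)) {
      cand <- run_best[[ord[ix]]]
      if (!any(vapply(kept, function(p)
        identical(p$coords, cand$coords), TRUE)))
        kept[[length(kept) + 1]] <- cand
      ix <- ix + 1
    }
    while (length(kept) < cfg$top_per_run)
      kept[[length(kept) + 1]] <- kept[[length(kept)]]
    for (k in seq_along(kept)) kept[[k]]$rank <- k
    all_poses <- c(all_poses, kept)
  }
  structure(list(poses = all_poses,
                 provenance = list(regime = job$regime,
                                   base_seed = cfg$seed,
                                   replicate_seeds = rep_seeds,
                                   n_runs = cfg$n_runs,
                                   n_operations = cfg$n_operations,
                                   top_per_run = cfg$top_per_run)),
            class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  sc <- vapply(x$poses, pose_total_score, 0)
  cat(sprintf("pose_set: %d poses (%s regime), scores %.2f .. %.2f\n",
              length(x$poses), x$provenance$regime, max(sc), min(sc)))
  invisible(x)
}
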