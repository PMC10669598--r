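## Pose-consistency analysis: the in-place RMSD metric triad
## (RMSD_AVERAGE, RMSD_LOWEST, RMSD_INTRAPOSE), per-linkage torsional
## deviation profiles, recapitulation / consistency classification at
## the 2.5 A geometric-equivalence threshold, and the score-to-RMSD
## selectivity ratio with its threshold-50 parsing rule.
##
## Docked and native poses live in the common receptor frame, so no
## superposition is performed before RMSD: aligning would erase
## translational error.

#' Analysis configuration
#'
#' @param rmsd_threshold geometric-equivalence threshold, A (default
#'   2.5).
#' @param ratio_threshold selectivity cut on mean score / RMSD_AVERAGE
#'   (default 50; score-scale dependent, so configuration rather than a
#'   constant).
#' @param rmsd_mode "mean-of-rmsds" (default) or "rmsd-to-centroid"
#'   for RMSD_AVERAGE.
#' @param symmetry_handling permute equivalent terminal oxygens within
#'   sulfate/carboxylate groups to minimize RMSD.
#' @export
analysis_config <- function(rmsd_threshold = 2.5, ratio_threshold = 50,
                            rmsd_mode = c("mean-of-rmsds",
                                          "rmsd-to-centroid"),
                            symmetry_handling = FALSE) {
  rmsd_mode <- match.arg(rmsd_mode)
  stopifnot(rmsd_threshold > 0, ratio_threshold > 0)
  structure(list(rmsd_threshold = rmsd_threshold,
                 ratio_threshold = ratio_threshold,
                 rmsd_mode = rmsd_mode,
                 symmetry_handling = symmetry_handling),
            class = "analysis_config")
}

## atom-index groups of exchange-equivalent terminal oxygens (the three
## oxygens of each sulfate, the two of each carboxylate)
symmetry_groups <- function(chain) {
  a <- chain$atoms
  deg <- atom_degree(chain)
  groups <- list()
  for (s in which(a$element == "S")) {
    nb <- neighbors_of(chain, s)
    term <- sort(nb[a$element[nb] == "O" & deg[nb] == 1])
    if (length(term) > 1) groups[[length(groups) + 1]] <- term
  }
  for (r in chain$residues$resno) {
    oc <- which(a$resno == r & a$name %in% c("O6A", "O6B"))
    if (length(oc) == 2) groups[[length(groups) + 1]] <- sort(oc)
  }
  groups
}

#' In-place RMSD between two poses
#'
#' Root-mean-square deviation over heavy atoms in canonical atom order,
#' without superposition. With `symmetry_groups` given, equivalent
#' terminal oxygens within each sulfate / carboxylate group of pose `b`
#' are permuted (independently per group, which is globally optimal for
#' disjoint groups) to minimize the RMSD.
#'
#' @param a,b `dock_pose` objects or coordinate matrices with matching
#'   atom order.
#' @param symmetry_groups list of atom-index vectors (see the
#'   `gag_chain` helper [analyze_pose_set()] which derives them), or
#'   NULL for plain RMSD.
#' @return RMSD in A.
#' @export
pose_rmsd <- function(a, b, symmetry_groups = NULL) {
  A <- if (inherits(a, "dock_pose")) a$coords else as.matrix(a)
  B <- if (inherits(b, "dock_pose")) b$coords else as.matrix(b)
  if (!all(dim(A) == dim(B)))
    stop("atom-count mismatch between poses: ", nrow(A), " vs ", nrow(B))
  ss <- rowSums((A - B)^2)
  if (!is.null(symmetry_groups) && length(symmetry_groups) > 0) {
    for (g in symmetry_groups) {
      perms <- permutations_of(length(g))
      base <- sum(ss[g])
      bestv <- base
      for (p in seq_len(nrow(perms))) {
        v <- sum(rowSums((A[g, , drop = FALSE] -
                          B[g[perms[p, ]], , drop = FALSE])^2))
        if (v < bestv) bestv <- v
      }
      ss[g] <- 0
      ss[g[1]] <- bestv  # fold the group minimum back into the sum
    }
  }
  sqrt(sum(ss) / nrow(A))
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(setdiff(seq_len(n), k)[sub], nrow = nrow(sub)))
  }))
}

#' The RMSD metric triad for a pose set
#'
#' RMSD_AVERAGE is the mean over poses of the native-vs-pose RMSD (or,
#' in `rmsd-to-centroid` mode, the RMSD between the native pose and the
#' coordinate centroid of the set); RMSD_LOWEST the minimum
#' native-vs-pose RMSD; RMSD_INTRAPOSE the mean over all unordered pose
#' pairs (15 pairs for six poses). A single-pose set has no intra-pose
#' RMSD (NA, not 0). Flags: `recapitulated` iff RMSD_AVERAGE <=
#' threshold, `consistent` iff RMSD_INTRAPOSE <= threshold.
#'
#' @param native the native `dock_pose`.
#' @param poses a `pose_set` or list of poses.
#' @param cfg an [analysis_config()].
#' @param symmetry_groups optional equivalent-atom groups.
#' @return list(rmsd_average, rmsd_lowest, rmsd_intrapose,
#'   recapitulated, consistent, n_poses).
#' @export
metric_triad <- function(native, poses, cfg = analysis_config(),
                         symmetry_groups = NULL) {
  plist <- if (inherits(poses, "pose_set")) poses$poses else poses
  if (length(plist) == 0) stop("empty pose set")
  sg <- if (cfg$symmetry_handling) symmetry_groups else NULL
  to_native <- vapply(plist, function(p) pose_rmsd(native, p, sg), 0)
  rmsd_average <- if (cfg$rmsd_mode == "rmsd-to-centroid") {
    cen <- Reduce(`+`, lapply(plist, function(p) p$coords)) / length(plist)
    pose_rmsd(native, cen, sg)
  } else mean(to_native)
  rmsd_lowest <- min(to_native)
  rmsd_intrapose <- if (length(plist) < 2) NA_real_ else {
    pairs <- utils::combn(length(plist), 2)
    mean(apply(pairs, 2, function(ix)
      pose_rmsd(plist[[ix[1]]], plist[[ix[2]]], sg)))
  }
  list(rmsd_average = rmsd_average, rmsd_lowest = rmsd_lowest,
       rmsd_intrapose = rmsd_intrapose,
       recapitulated = rmsd_average <= cfg$rmsd_threshold,
       consistent = !is.na(rmsd_intrapose) &&
         rmsd_intrapose <= cfg$rmsd_threshold,
       n_poses = length(plist))
}

#' Per-linkage torsional deviation from the native pose
#'
#' For each glycosidic linkage, the magnitude of the circular
#' difference between the circular mean of the docked Phi (resp. Psi)
#' values and the native value, in [0, 180] degrees, plus the mean of
#' these magnitudes across linkages.
#'
#' @param native the native `dock_pose`.
#' @param poses a `pose_set` or list of poses.
#' @param chain the `gag_chain` defining the linkages.
#' @return list(per_linkage = data.frame(linkage, label, dphi, dpsi),
#'   mean_dphi, mean_dpsi).
#' @export
torsion_deviation <- function(native, poses, chain) {
  plist <- if (inherits(poses, "pose_set")) poses$poses else poses
  nat <- measure_linkage_torsions(chain, native$coords)
  per_pose <- lapply(plist, function(p)
    measure_linkage_torsions(chain, p$coords))
  lk <- chain$linkages
  rows <- lapply(seq_len(nrow(lk)), function(j) {
    phis <- vapply(per_pose, function(m) m$phi[j], 0)
    psis <- vapply(per_pose, function(m) m$psi[j], 0)
    data.frame(linkage = j,
               label = sprintf("%d->%d", lk$donor[j], lk$acceptor[j]),
               dphi = circular_dist(circular_mean(phis), nat$phi[j]),
               dpsi = circular_dist(circular_mean(psis), nat$psi[j]))
  })
  per_linkage <- do.call(rbind, rows)
  list(per_linkage = per_linkage,
       mean_dphi = mean(per_linkage$dphi),
       mean_dpsi = mean(per_linkage$dpsi))
}

#' Score-to-RMSD selectivity ratio
#'
#' ratio = mean docking score / RMSD_AVERAGE; systems at or above the
#' configured threshold (default 50) are flagged selective. A zero
#' RMSD gives a +Inf ratio (selective); a negative mean score computes
#' the ratio but forces `selective = FALSE` with a warning.
#'
#' @param mean_score mean total score of the analysis poses.
#' @param rmsd_average RMSD_AVERAGE in A.
#' @param cfg an [analysis_config()].
#' @return list(ratio, selective).
#' @export
selectivity_ratio <- function(mean_score, rmsd_average,
                              cfg = analysis_config()) {
  if (rmsd_average < 0) stop("rmsd_average must be >= 0")
  if (rmsd_average == 0)
    return(list(ratio = Inf, selective = TRUE))
  ratio <- mean_score / rmsd_average
  if (mean_score < 0) {
    warning("negative mean score; selectivity flag forced FALSE")
    return(list(ratio = ratio, selective = FALSE))
  }
  list(ratio = ratio, selective = ratio >= cfg$ratio_threshold)
}

#' Full metric set for one pose set
#'
#' Combines the RMSD triad, torsional deviations, mean score and the
#' selectivity ratio into one record.
#'
#' @param native native `dock_pose`.
#' @param poses `pose_set` or pose list.
#' @param chain the ligand `gag_chain`.
#' @param cfg an [analysis_config()].
#' @return list of class `pose_set_metrics`.
#' @export
analyze_pose_set <- function(native, poses, chain, cfg = analysis_config()) {
  sg <- if (cfg$symmetry_handling) symmetry_groups(chain) else NULL
  triad <- metric_triad(native, poses, cfg, symmetry_groups = sg)
  dev <- torsion_deviation(native, poses, chain)
  plist <- if (inherits(poses, "pose_set")) poses$poses else poses
  scores <- vapply(plist, pose_total_score, 0)
  mean_score <- mean(scores[is.finite(scores)])
  sel <- if (is.na(mean_score) || is.na(triad$rmsd_average))
    list(ratio = NA_real_, selective = NA) else
    selectivity_ratio(mean_score, triad$rmsd_average, cfg)
  structure(c(triad,
              list(per_linkage = dev$per_linkage,
                   mean_dphi = dev$mean_dphi, mean_dpsi = dev$mean_dpsi,
                   mean_score = mean_score,
                   selectivity_ratio = sel$ratio,
                   selective = sel$selective,
                   thresholds = list(rmsd = cfg$rmsd_threshold,
                                     ratio = cfg$ratio_threshold))),
            class = "pose_set_metrics")
}

#' @export
print.pose_set_metrics <- function(x, ...) {
  cat(sprintf(paste0("pose_set_metrics: RMSD avg %.2f / lowest %.2f / ",
                     "intrapose %s A; mean score %.1f; ratio %s\n"),
              x$rmsd_average, x$rmsd_lowest,
              ifelse(is.na(x$rmsd_intrapose), "NA",
                     sprintf("%.2f", x$rmsd_intrapose)),
              x$mean_score,
              ifelse(is.finite(x$selectivity_ratio),
                     sprintf("%.1f", x$selectivity_ratio), "Inf")))
  cat(sprintf("  recapitulated: %s; consistent: %s; selective: %s\n",
              x$recapitulated, x$consistent, x$selective))
  invisible(x)
}

#' Consolidated per-system, per-protocol report
#'
#' Builds the metric table across systems and regimes, with
#' recapitulation / consistency fractions per protocol and per
#' chain-length stratum (2-4-mers vs 5-10-mers).
#'
#' @param results data.frame-able list: each element list(system,
#'   chain_length, regime, metrics = `pose_set_metrics`).
#' @param cfg an [analysis_config()].
#' @return list(table, fractions, strata) of class `protocol_report`.
#' @export
protocol_report <- function(results, cfg = analysis_config()) {
  if (length(results) == 0) stop("no systems to report")
  tab <- do.call(rbind, lapply(results, function(r) {
    m <- r$metrics
    data.frame(system = r$system, chain_length = r$chain_length,
               regime = r$regime,
               rmsd_average = m$rmsd_average, rmsd_lowest = m$rmsd_lowest,
               rmsd_intrapose = m$rmsd_intrapose,
               mean_dphi = m$mean_dphi, mean_dpsi = m$mean_dpsi,
               mean_score = m$mean_score,
               selectivity_ratio = m$selectivity_ratio,
               recapitulated = m$recapitulated,
               consistent = m$consistent, selective = m$selective)
  }))
  tab$stratum <- ifelse(tab$chain_length <= 4, "2-4", "5-10")
  frac <- do.call(rbind, lapply(split(tab, tab$regime), function(s) {
    data.frame(regime = s$regime[1], n = nrow(s),
               recapitulation_fraction = mean(s$recapitulated),
               consistency_fraction = mean(s$consistent))
  }))
  strata <- do.call(rbind, lapply(split(tab, list(tab$regime, tab$stratum),
                                        drop = TRUE), function(s) {
    data.frame(regime = s$regime[1], stratum = s$stratum[1], n = nrow(s),
               recapitulation_fraction = mean(s$recapitulated))
  }))
  rownames(frac) <- rownames(strata) <- NULL
  structure(list(table = tab, fractions = frac, strata = strata,
                 thresholds = list(rmsd = cfg$rmsd_threshold,
                                   ratio = cfg$ratio_threshold)),
            class = "protocol_report")
}

#' @export
print.protocol_report <- function(x, ...) {
  cat("protocol_report (RMSD threshold", x$thresholds$rmsd, "A)\n")
  print(x$fractions)
  invisible(x)
}

#' Bar plots of the metric triad across systems, per protocol
#' @param report a `protocol_report`.
#' @param file optional PNG path.
#' @export
plot_protocol_report <- function(report, file = NULL) {
  tab <- report$table
  if (!is.null(file)) grDevices::png(file, width = 1000, height = 700)
  op <- graphics::par(mfrow = c(1, 3), mar = c(7, 4, 3, 1))
  on.exit({ graphics::par(op); if (!is.null(file)) grDevices::dev.off() },
          add = TRUE)
  for (metric in c("rmsd_average", "rmsd_lowest", "rmsd_intrapose")) {
    m <- tapply(tab[[metric]], list(tab$regime, tab$system), mean)
    graphics::barplot(m, beside = TRUE, las = 2, main = toupper(metric),
                      ylab = "RMSD (A)",
                      legend.text = rownames(m),
                      args.legend = list(x = "topleft", cex = 0.8))
    graphics::abline(h = report$thresholds$rmsd, col = "red", lty = 2)
  }
  invisible(NULL)
}
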