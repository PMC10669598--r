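test_that("pose_rmsd matches the brute-force oracle, with and without symmetry", {
  ch <- tiny_chain(4)
  nat <- new_pose(coords_of(ch))
  expect_equal(pose_rmsd(nat, nat), 0)
  ## uniform translation has a closed-form RMSD
  t3 <- new_pose(sweep(nat$coords, 2, c(3, 0, 0), "+"))
  expect_equal(pose_rmsd(nat, t3), 3, tolerance = 1e-12)
  set.seed(21)
  for (k in 1:20) {
    b <- new_pose(nat$coords + matrix(stats::rnorm(length(nat$coords), 0, 2),
                                      ncol = 3))
    expect_equal(pose_rmsd(nat, b), oracle_rmsd(nat$coords, b$coords),
                 tolerance = 1e-9)
  }
  ## exhaustive symmetry oracle on a chain with two equivalent-atom
  ## groups (one sulfate, one carboxylate: 3! x 2 permutations total)
  ch2 <- make_chain(fixture_spec(
    chain_length = 2,
    sulfation = list(c("2N-sulfate"), c("carboxylate"))))
  nat2 <- new_pose(coords_of(ch2))
  sg <- glycodock:::symmetry_groups(ch2)
  expect_length(sg, 2)
  set.seed(22)
  for (k in 1:20) {
    b <- new_pose(nat2$coords + matrix(stats::rnorm(length(nat2$coords),
                                                    0, 1.5), ncol = 3))
    expect_equal(pose_rmsd(nat2, b, symmetry_groups = sg),
                 oracle_rmsd_sym(nat2$coords, b$coords, sg),
                 tolerance = 1e-9)
    ## symmetry-corrected RMSD never exceeds the plain one
    expect_lte(pose_rmsd(nat2, b, symmetry_groups = sg),
               pose_rmsd(nat2, b))
  }
  ## swapping two terminal sulfate oxygens is transparent to the
  ## symmetry-aware metric but not to the plain one
  swp <- nat2$coords
  swp[sg[[1]][1:2], ] <- swp[sg[[1]][2:1], ]
  expect_equal(pose_rmsd(nat2, swp, symmetry_groups = sg), 0,
               tolerance = 1e-12)
  expect_gt(pose_rmsd(nat2, swp), 0.5)
  expect_error(pose_rmsd(nat, new_pose(nat$coords[-1, ])), "mismatch")
})

test_that("pose_rmsd is a metric on random triples", {
  ch <- tiny_chain(2)
  base <- coords_of(ch)
  set.seed(23)
  for (k in 1:15) {
    a <- base + matrix(stats::rnorm(length(base), 0, 2), ncol = 3)
    b <- base + matrix(stats::rnorm(length(base), 0, 2), ncol = 3)
    cc <- base + matrix(stats::rnorm(length(base), 0, 2), ncol = 3)
    expect_lte(pose_rmsd(a, cc), pose_rmsd(a, b) + pose_rmsd(b, cc) + 1e-12)
    expect_equal(pose_rmsd(a, b), pose_rmsd(b, a), tolerance = 1e-12)
  }
})

test_that("metric triad reproduces closed-form cases and the consistency flags", {
  ch <- tiny_chain(4)
  nat <- new_pose(coords_of(ch))
  cfg <- analysis_config()
  ## six copies of the native: all zeros, recapitulated and consistent
  same <- replicate(6, nat, simplify = FALSE)
  tr <- metric_triad(nat, same, cfg)
  expect_equal(unlist(tr[c("rmsd_average", "rmsd_lowest",
                           "rmsd_intrapose")]),
               c(rmsd_average = 0, rmsd_lowest = 0, rmsd_intrapose = 0))
  expect_true(tr$recapitulated && tr$consistent)
  ## six identical poses 5 A off: consistent but binding away from site
  set.seed(3); dir <- stats::rnorm(3); dir <- 5 * dir / sqrt(sum(dir^2))
  off <- replicate(6, new_pose(sweep(nat$coords, 2, dir, "+")),
                   simplify = FALSE)
  tr2 <- metric_triad(nat, off, cfg)
  expect_equal(tr2$rmsd_average, 5, tolerance = 1e-9)
  expect_equal(tr2$rmsd_lowest, 5, tolerance = 1e-9)
  expect_equal(tr2$rmsd_intrapose, 0)
  expect_false(tr2$recapitulated)
  expect_true(tr2$consistent)
  ## random set: triad equals the brute-force pairwise computation
  set.seed(4)
  rnd <- replicate(6, new_pose(nat$coords +
                                 matrix(stats::rnorm(length(nat$coords)),
                                        ncol = 3)), simplify = FALSE)
  tr3 <- metric_triad(nat, rnd, cfg)
  to_nat <- vapply(rnd, function(p) oracle_rmsd(nat$coords, p$coords), 0)
  pairs <- utils::combn(6, 2)
  intra <- mean(apply(pairs, 2, function(ix)
    oracle_rmsd(rnd[[ix[1]]]$coords, rnd[[ix[2]]]$coords)))
  expect_equal(tr3$rmsd_average, mean(to_nat), tolerance = 1e-12)
  expect_equal(tr3$rmsd_lowest, min(to_nat), tolerance = 1e-12)
  expect_equal(tr3$rmsd_intrapose, intra, tolerance = 1e-12)
  expect_lte(tr3$rmsd_lowest, tr3$rmsd_average)
  ## intrapose is permutation invariant
  tr4 <- metric_triad(nat, rnd[c(4, 2, 6, 1, 3, 5)], cfg)
  expect_equal(tr4$rmsd_intrapose, tr3$rmsd_intrapose)
  ## single pose: intrapose reported absent, not zero
  tr1 <- metric_triad(nat, rnd[1], cfg)
  expect_true(is.na(tr1$rmsd_intrapose))
  expect_false(tr1$consistent)
  ## alternative centroid mode is available and differs in general
  cfg2 <- analysis_config(rmsd_mode = "rmsd-to-centroid")
  tr5 <- metric_triad(nat, rnd, cfg2)
  expect_lte(tr5$rmsd_average, tr3$rmsd_average + 1e-9)
})

test_that("rmsd_lowest <= rmsd_average over random pose sets", {
  ch <- tiny_chain(2)
  nat <- new_pose(coords_of(ch))
  set.seed(5)
  for (k in 1:20) {
    ps <- replicate(sample(2:8, 1),
                    new_pose(nat$coords +
                               matrix(stats::rnorm(length(nat$coords), 0, 3),
                                      ncol = 3)), simplify = FALSE)
    tr <- metric_triad(nat, ps)
    expect_lte(tr$rmsd_lowest, tr$rmsd_average + 1e-12)
    expect_gte(tr$rmsd_lowest, 0)
  }
})

test_that("torsion deviations use circular means and are rigid-motion invariant", {
  ch <- tiny_chain(4)
  nat <- new_pose(coords_of(ch))
  ## identical poses: zero deviation
  dev0 <- torsion_deviation(nat, replicate(4, nat, simplify = FALSE), ch)
  expect_equal(dev0$per_linkage$dphi, rep(0, 3), tolerance = 1e-9)
  expect_equal(dev0$per_linkage$dpsi, rep(0, 3), tolerance = 1e-9)
  ## constant +20 offset on one psi measures exactly 20 at that linkage
  dec <- make_decoys(nat, ch, kind = "torsion-perturb", magnitude = 20,
                     n = 4, seed = 1, linkage = 2)
  dev <- torsion_deviation(nat, dec, ch)
  expect_equal(dev$per_linkage$dpsi[2], 20, tolerance = 1e-6)
  expect_equal(dev$per_linkage$dpsi[-2], rep(0, 2), tolerance = 1e-6)
  expect_equal(dev$mean_dpsi, 20 / 3, tolerance = 1e-6)
  ## per-linkage labels follow the reducing-end convention
  expect_equal(dev$per_linkage$label, c("2->1", "3->2", "4->3"))
  ## deviations are invariant under a global rigid motion of everything
  set.seed(6)
  R <- rotation_matrix(stats::rnorm(3), 77)
  t <- c(4, -2, 9)
  mv <- function(p) new_pose(sweep(p$coords %*% t(R), 2, t, "+"))
  dev2 <- torsion_deviation(mv(nat), lapply(dec, mv), ch)
  expect_equal(dev2$per_linkage$dpsi, dev$per_linkage$dpsi,
               tolerance = 1e-6)
  ## values straddling the wrap point average circularly, not linearly
  nat179 <- new_pose(coords_of(make_chain(fixture_spec(
    chain_length = 2, torsion_plan = matrix(c(-80, 179), 1, 2)))))
  ch179 <- make_chain(fixture_spec(chain_length = 2,
                                   torsion_plan = matrix(c(-80, 179), 1,
                                                         2)))
  dplus <- make_decoys(nat179, ch179, "torsion-perturb", magnitude = 2,
                       n = 3, seed = 2)
  dminus <- make_decoys(nat179, ch179, "torsion-perturb", magnitude = -2,
                        n = 3, seed = 3)
  dev3 <- torsion_deviation(nat179, c(dplus, dminus), ch179)
  expect_lt(dev3$per_linkage$dpsi[1], 5)
})

test_that("selectivity ratio arithmetic, thresholding and degenerate cases", {
  cfg <- analysis_config()
  r1 <- selectivity_ratio(100, 2, cfg)
  expect_equal(r1$ratio, 50)
  expect_true(r1$selective)
  r2 <- selectivity_ratio(100, 10, cfg)
  expect_equal(r2$ratio, 10)
  expect_false(r2$selective)
  ## homogeneity: doubling the score doubles the ratio exactly
  expect_equal(selectivity_ratio(200, 10, cfg)$ratio, 2 * r2$ratio)
  expect_equal(selectivity_ratio(100, 5, cfg)$ratio, 2 * r2$ratio)
  ## zero RMSD: +Inf sentinel, selective
  r0 <- selectivity_ratio(100, 0, cfg)
  expect_identical(r0$ratio, Inf)
  expect_true(r0$selective)
  ## negative score warns and is never selective
  expect_warning(rn <- selectivity_ratio(-10, 0.1, cfg), "negative")
  expect_false(rn$selective)
})

test_that("protocol report tabulates fractions and strata consistently", {
  ch <- tiny_chain(4)
  nat <- new_pose(coords_of(ch))
  good <- lapply(replicate(6, nat, simplify = FALSE), function(p) {
    p$score <- list(total = 120); p
  })
  bad <- lapply(make_decoys(nat, ch, "translate", magnitude = 6, n = 6,
                            seed = 9), function(p) {
    p$score <- list(total = 80); p
  })
  results <- list(
    list(system = "sysA", chain_length = 4, regime = "rigid",
         metrics = analyze_pose_set(nat, good, ch)),
    list(system = "sysA", chain_length = 4, regime = "flexible",
         metrics = analyze_pose_set(nat, bad, ch)),
    list(system = "sysB", chain_length = 6, regime = "rigid",
         metrics = analyze_pose_set(nat, good, ch)))
  rep <- protocol_report(results)
  expect_equal(nrow(rep$table), 3)
  fr <- rep$fractions
  expect_equal(fr$recapitulation_fraction[fr$regime == "rigid"], 1)
  expect_equal(fr$recapitulation_fraction[fr$regime == "flexible"], 0)
  ## strata partition the totals
  for (rg in unique(rep$table$regime)) {
    st <- rep$strata[rep$strata$regime == rg, ]
    expect_equal(sum(st$n), sum(rep$table$regime == rg))
  }
  ## plot renders to a file without error
  f <- tempfile(fileext = ".png")
  plot_protocol_report(rep, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  unlink(f)
})
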