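make_job <- function(regime = "rigid", n = 4, ops = 300, pop = 30,
                     runs = 1, seed = 1, ...) {
  ch <- make_chain(fixture_spec(chain_length = n,
                                sulfation = "heterogeneous"))
  cx <- make_complex(ch, tightness = 1, seed = 1)
  job <- docking_job(cx$receptor, ch, regime,
                     config = ga_config(n_runs = runs, n_operations = ops,
                                        population_size = pop, seed = seed,
                                        ...))
  list(job = job, cx = cx, ch = ch)
}

test_that("regime templates tag glycosidic genes fixed / bounded / free", {
  ch <- tiny_chain(6)
  for (rg in c("rigid", "semi-rigid", "flexible")) {
    tpl <- build_regime(ch, rg)
    glyc <- vapply(tpl$tree, function(b) b$tag == "glycosidic", TRUE)
    modes <- vapply(tpl$genes, `[[`, "", "mode")
    expected <- switch(rg, rigid = "fixed", `semi-rigid` = "bounded",
                       flexible = "free")
    expect_true(all(modes[glyc] == expected))
    expect_true(all(modes[!glyc] == "free"))
  }
  ## flexible hexasaccharide has at least 36 free genes
  tpl <- build_regime(ch, "flexible")
  expect_gte(sum(vapply(tpl$genes, `[[`, "", "mode") == "free"), 36)
  ## semi-rigid histogram excluding the initial torsion is a config error
  bad_hist <- list("1" = list(phi = build_histogram(100, 10)))
  expect_error(build_regime(ch, "semi-rigid", histograms = bad_hist),
               "configuration error")
})

test_that("decode is the identity for the identity chromosome and composes rigid moves", {
  mj <- make_job("rigid")
  tpl <- mj$job$template
  idc <- identity_chromosome(tpl)
  expect_equal(decode_chromosome(idc, mj$job), coords_of(mj$ch),
               tolerance = 1e-9, ignore_attr = TRUE)
  ## pure translation shifts every atom
  tc <- idc; tc$trans <- c(3, 0, 0)
  expect_equal(decode_chromosome(tc, mj$job),
               sweep(coords_of(mj$ch), 2, c(3, 0, 0), "+"),
               tolerance = 1e-9, ignore_attr = TRUE)
  ## rigid-body genes are exactly invertible: re-measuring the applied
  ## rotation from the coordinates recovers the quaternion rotation
  set.seed(8)
  q <- glycodock:::random_quaternion()
  rc <- idc; rc$quat <- q
  out <- decode_chromosome(rc, mj$job)
  R <- glycodock:::quat_to_matrix(q)
  c0 <- tpl$centroid
  expect_equal(out, sweep(sweep(coords_of(mj$ch), 2, c0) %*% t(R), 2, c0,
                          "+"), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("a single torsion gene moves only distal atoms and re-measures exactly", {
  mj <- make_job("flexible", n = 4)
  tpl <- mj$job$template
  k <- which(vapply(tpl$tree, function(b)
    b$tag == "glycosidic" && b$torsion == "psi", TRUE))[1]
  lk <- tpl$tree[[k]]$linkage
  idc <- identity_chromosome(tpl)
  idc$torsions[k] <- wrap_angle(idc$torsions[k] + 20)
  out <- decode_chromosome(idc, mj$job)
  tor <- measure_linkage_torsions(mj$ch, out)
  init <- measure_linkage_torsions(mj$ch)
  expect_equal(glycodock:::circular_dist(tor$psi[lk], init$psi[lk] + 20), 0,
               tolerance = 1e-6)
  ## all other torsions untouched
  expect_equal(tor$psi[-lk], init$psi[-lk], tolerance = 1e-6)
  expect_equal(tor$phi, init$phi, tolerance = 1e-6)
  ## proximal atoms (towards the reducing end) did not move
  moved <- tpl$tree[[k]]$moved
  still <- setdiff(seq_len(nrow(mj$ch$atoms)), moved)
  expect_equal(out[still, ], coords_of(mj$ch)[still, ], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("score terms behave: asymptotic zero, closed-form electrostatics, clash monotonicity", {
  mj <- make_job("rigid")
  job <- mj$job
  ## ligand far away (but inside a huge box): all interaction terms 0
  far_box <- job
  far_box$site$box <- rbind(min = rep(-1e4, 3), max = rep(1e4, 3))
  s_far <- score_pose(sweep(coords_of(mj$ch), 2, c(5000, 0, 0), "+"),
                      far_box)
  expect_equal(s_far$terms$hbond, 0)
  ## unscreened 1/r^2 tails vanish quadratically with separation
  expect_lt(abs(s_far$terms$electrostatic), 1e-3)
  expect_lt(abs(s_far$terms$vdw_external), 1e-6)
  ## outside the box by more than the margin: -Inf sentinel
  s_out <- score_pose(sweep(coords_of(mj$ch), 2, c(500, 0, 0), "+"), job)
  expect_identical(s_out$total, -Inf)
  ## single +1 / -1 pair at r = 4: ele = 332 * (-1) / (4 * 16)
  rec1 <- structure(list(atoms = data.frame(
    resno = 1, resid = "PRS", name = "NZ", element = "N",
    x = 0, y = 0, z = 0, charge = 1)), class = "gag_receptor")
  ch1 <- tiny_chain(2)
  ch1$atoms$formal_charge <- 0
  ch1$atoms$formal_charge[1] <- -1
  pose1 <- new_pose(coords_of(ch1))
  j1 <- docking_job(rec1, ch1, "rigid", config = ga_config(seed = 1),
                    reference = pose1,
                    site = define_site(rec1, pose1, radius = 50))
  xyz <- coords_of(ch1)
  shift <- c(4, 0, 0) - xyz[1, ]
  xyz1 <- sweep(xyz, 2, shift, "+")
  s1 <- score_pose(xyz1, j1)
  other <- sum(332 * ch1$atoms$formal_charge[-1] /
                 (4 * pmax(sqrt(rowSums(xyz1[-1, , drop = FALSE]^2)), 1.5)^2))
  expect_equal(s1$terms$electrostatic, 332 * (-1) / (4 * 16) + other,
               tolerance = 1e-6)
  ## pushing two heavy atoms into deep overlap engages the clash cap
  xyz_clash <- xyz1
  xyz_clash <- sweep(xyz, 2, c(0.5 * 3.25, 0, 0) - xyz[1, ], "+")
  s_cl <- score_pose(xyz_clash, j1)
  expect_gt(s_cl$terms$clash, 0)
  expect_lt(s_cl$total, s1$total)
})

test_that("scores are deterministic and the GA is reproducible at fixed seed", {
  mj <- make_job("rigid", ops = 200, pop = 20)
  x <- decode_chromosome(identity_chromosome(mj$job$template), mj$job)
  expect_identical(score_pose(x, mj$job), score_pose(x, mj$job))
  r1 <- run_ga(mj$job, seed = 5)
  r2 <- run_ga(mj$job, seed = 5)
  expect_identical(pose_total_score(r1[[1]]), pose_total_score(r2[[1]]))
  expect_identical(r1[[1]]$coords, r2[[1]]$coords)
})

test_that("zero operations returns the best of the initial population", {
  mj <- make_job("rigid", ops = 0, pop = 15)
  res <- run_ga(mj$job, seed = 3)
  expect_gte(length(res), 1)
  ## reconstruct the initial population under the same seed
  set.seed(3)
  best <- -Inf
  for (k in 1:15) {
    cc <- random_chromosome(mj$job)
    best <- max(best, score_pose(decode_chromosome(cc, mj$job), mj$job)$total)
  }
  expect_equal(pose_total_score(res[[1]]), best)
})

test_that("every semi-rigid sample stays within the histogram bound (instrumented)", {
  mj <- make_job("semi-rigid", n = 4, ops = 500, pop = 20)
  tpl <- mj$job$template
  glyc <- which(vapply(tpl$tree, function(b) b$tag == "glycosidic", TRUE))
  init <- vapply(tpl$genes[glyc], `[[`, 0, "initial")
  worst <- 0
  mon <- function(chrom, xyz, score) {
    dev <- glycodock:::circular_dist(chrom$torsions[glyc], init)
    worst <<- max(worst, max(dev))
  }
  run_ga(mj$job, seed = 2, monitor = mon)
  expect_lte(worst, 30)
  expect_gt(worst, 0)  # sampling did exercise the bound
})

test_that("regime nesting: best achievable score is monotone rigid <= semi-rigid <= flexible", {
  ## brute-force grid over a single psi torsion of a disaccharide held
  ## at the native rigid-body placement
  ch <- make_chain(fixture_spec(chain_length = 2,
                                sulfation = "heterogeneous"))
  cx <- make_complex(ch, tightness = 1, seed = 1)
  job <- docking_job(cx$receptor, ch, "flexible",
                     config = ga_config(seed = 1))
  tpl <- job$template
  k <- which(vapply(tpl$tree, function(b)
    b$tag == "glycosidic" && b$torsion == "psi", TRUE))[1]
  init <- tpl$genes[[k]]$initial
  grid <- seq(-179, 180, by = 2)
  sc <- vapply(grid, function(v) {
    cc <- identity_chromosome(tpl)
    cc$torsions[k] <- v
    score_pose(decode_chromosome(cc, job), job)$total
  }, 0)
  best_rigid <- sc[which.min(abs(grid - init))]
  best_semi <- max(sc[glycodock:::circular_dist(grid, init) <= 30])
  best_flex <- max(sc)
  expect_lte(best_rigid, best_semi + 1e-9)
  expect_lte(best_semi, best_flex + 1e-9)
})

test_that("triplicate orchestration yields exactly top_per_run x replicates poses", {
  mj <- make_job("rigid", n = 2, ops = 150, pop = 15, runs = 2,
                 replicates = 3, top_per_run = 2)
  ps <- dock_replicates(mj$job)
  expect_s3_class(ps, "pose_set")
  expect_length(ps$poses, 6)
  reps <- vapply(ps$poses, `[[`, 0L, "replicate_id")
  expect_equal(sort(unique(reps)), 1:3)
  ## within each replicate ranks are 1, 2 and scores are non-increasing
  for (r in 1:3) {
    sub <- ps$poses[reps == r]
    expect_equal(vapply(sub, `[[`, 0L, "rank"), 1:2)
    expect_gte(pose_total_score(sub[[1]]), pose_total_score(sub[[2]]))
  }
  ## provenance carries replicate seeds base+0,1,2
  expect_equal(ps$provenance$replicate_seeds, mj$job$config$seed + 0:2)
  ## single run, single replicate, top 1
  mj1 <- make_job("rigid", n = 2, ops = 100, pop = 10, runs = 1,
                  replicates = 1, top_per_run = 1)
  expect_length(dock_replicates(mj1$job)$poses, 1)
  ## determinism of the whole orchestration
  ps2 <- dock_replicates(mj$job)
  expect_identical(lapply(ps$poses, `[[`, "coords"),
                   lapply(ps2$poses, `[[`, "coords"))
})
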