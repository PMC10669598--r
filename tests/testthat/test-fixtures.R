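test_that("generated chains hit their torsion plans and validate", {
  set.seed(17)
  for (n in c(2, 3, 5, 6, 8)) {
    plan <- if (n > 1)
      matrix(stats::runif(2 * (n - 1), -170, 170), ncol = 2) else NULL
    sp <- fixture_spec(chain_length = n, torsion_plan = plan,
                       sulfation = "heterogeneous")
    ch <- make_chain(sp)
    expect_true(validate_chain(ch))
    expect_equal(nrow(ch$residues), n)
    expect_equal(nrow(ch$linkages), n - 1)
    tt <- measure_linkage_torsions(ch)
    expect_equal(unname(as.matrix(tt)), unname(plan), tolerance = 0.01)
  }
  ## fully reproducible from the spec
  s1 <- fixture_spec(chain_length = 4, sulfation = "heterogeneous")
  expect_identical(coords_of(make_chain(s1)), coords_of(make_chain(s1)))
})

test_that("substituent validation rejects impossible chemistry", {
  expect_error(fixture_spec(chain_length = 2,
                            sulfation = list(c("2O-sulfate"),
                                             c("carboxylate"))),
               "impossible substituent")
  expect_error(fixture_spec(chain_length = 2,
                            sulfation = list(c("2N-sulfate"),
                                             c("2N-acetate"))),
               "impossible substituent")
})

test_that("a fully sulfated hexasaccharide exceeds 36 flexible rotatable bonds", {
  sp <- fixture_spec(
    chain_length = 6,
    sulfation = rep(list(NULL), 6))
  sp$sulfation <- lapply(sp$kinds, function(k)
    if (k %in% c("GlcA", "IdoA")) c("carboxylate", "2O-sulfate")
    else c("2N-sulfate", "3O-sulfate", "6O-sulfate"))
  ch <- make_chain(sp)
  expect_gte(nrow(enumerate_rotatable_bonds(ch, "flexible")), 36)
})

test_that("planted complexes define a site and dominate displaced decoys", {
  ch <- make_chain(fixture_spec(chain_length = 4,
                                sulfation = "heterogeneous"))
  cx <- make_complex(ch, tightness = 1, seed = 1)
  site <- define_site(cx$receptor, cx$native_pose)
  ## every pseudo-residue of a tight complex touches the 6 A site
  expect_equal(sort(site$site_residues),
               sort(unique(cx$receptor$atoms$resno)))
  job <- docking_job(cx$receptor, ch, "rigid",
                     config = ga_config(seed = 1),
                     reference = cx$native_pose)
  s_nat <- score_pose(cx$native_pose, job)$total
  set.seed(33)
  for (k in 1:20) {
    dir <- stats::rnorm(3)
    dec <- sweep(cx$native_pose$coords, 2, 3 * dir / sqrt(sum(dir^2)), "+")
    expect_gt(s_nat, score_pose(dec, job)$total)
  }
})

test_that("tightness zero leaves no receptor atom near the ligand", {
  ch <- make_chain(fixture_spec(chain_length = 4))
  cx0 <- make_complex(ch, tightness = 0, seed = 1)
  expect_gt(nrow(cx0$receptor$atoms), 0)
  expect_error(define_site(cx0$receptor, cx0$native_pose), "empty site")
  ## partial tightness keeps a subset of the full complement
  cx5 <- make_complex(ch, tightness = 0.5, seed = 1)
  cx1 <- make_complex(ch, tightness = 1, seed = 1)
  expect_lt(sum(cx5$receptor$atoms$element == "N"),
            sum(cx1$receptor$atoms$element == "N"))
})

test_that("translation decoys carry their analytic ground truth", {
  ch <- make_chain(fixture_spec(chain_length = 4))
  nat <- new_pose(coords_of(ch))
  dec <- make_decoys(nat, ch, kind = "translate", magnitude = 5, n = 6,
                     seed = 7)
  expect_length(dec, 6)
  for (k in 1:6) {
    gt <- attr(dec, "ground_truth")[[k]]
    expect_equal(sqrt(sum(gt$translation^2)), 5, tolerance = 1e-9)
    expect_equal(pose_rmsd(nat, dec[[k]]), 5, tolerance = 1e-9)
  }
  tr <- metric_triad(nat, dec)
  expect_equal(tr$rmsd_average, 5, tolerance = 1e-9)
  expect_equal(tr$rmsd_lowest, 5, tolerance = 1e-9)
  ## mixed decoys still match the brute-force oracle per pose
  mx <- make_decoys(nat, ch, kind = "mixed", magnitude = 3, n = 4,
                    seed = 8)
  for (k in 1:4)
    expect_equal(pose_rmsd(nat, mx[[k]]),
                 oracle_rmsd(nat$coords, mx[[k]]$coords), tolerance = 1e-9)
  ## decoys are reproducible from the seed
  dec2 <- make_decoys(nat, ch, kind = "translate", magnitude = 5, n = 6,
                      seed = 7)
  expect_identical(lapply(dec, `[[`, "coords"),
                   lapply(dec2, `[[`, "coords"))
})

test_that("torsion corpus draws around the requested centers", {
  chains <- make_torsion_corpus(6, noise_sd = 0, seed = 5,
                                chain_length = 3)
  expect_length(chains, 6)
  for (ch in chains) expect_true(validate_chain(ch))
  obs <- curate_torsions(chains)$observations
  ctr <- default_torsion_centers()
  for (r in seq_len(nrow(obs))) {
    modes <- ctr[[obs$linkage_class[r]]]
    dphi <- min(abs(modes[, "phi"] - obs$phi[r]))
    dpsi <- min(abs(modes[, "psi"] - obs$psi[r]))
    expect_lt(dphi, 0.01)
    expect_lt(dpsi, 0.01)
  }
})
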