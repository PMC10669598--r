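test_that("atom typing assigns the carboxylate-oxygen surrogate and group charges", {
  ch <- make_chain(fixture_spec(
    chain_length = 4,
    sulfation = list(c("2N-sulfate", "6O-sulfate", "3O-sulfate"),
                     c("carboxylate", "2O-sulfate"),
                     c("2N-amine"),
                     c("carboxylate"))))
  ## fully sulfated GlcN(NS,3S,6S) carries -3
  expect_equal(total_charge(ch, 1), -3)
  ## IdoA(2S): carboxylate + 2-O-sulfate = -2
  expect_equal(total_charge(ch, 2), -2)
  ## free amine +1
  expect_equal(total_charge(ch, 3), 1)
  ## bare uronic acid: carboxylate only
  expect_equal(total_charge(ch, 4), -1)
  ## additivity across the chain
  expect_equal(total_charge(ch), -3 - 2 + 1 - 1)
  a <- ch$atoms
  ## sulfate terminal oxygens carry the O.co2 surrogate type
  st <- a$atom_type[grepl("^OS", a$name)]
  expect_true(all(st == "O.co2"))
  expect_true(all(a$atom_type[a$name %in% c("O6A", "O6B")] == "O.co2"))
  ## ring oxygen stays an ether oxygen; plain hydroxyls neutral
  expect_true(all(a$atom_type[a$name == "O5"] == "O.3"))
  expect_true(all(a$formal_charge[a$name == "O3"] == 0))
})

test_that("charge additivity holds across random synthetic chains", {
  set.seed(12)
  for (k in 1:5) {
    n <- sample(2:8, 1)
    ch <- make_chain(fixture_spec(chain_length = n,
                                  sulfation = "heterogeneous"))
    per_res <- vapply(seq_len(n), function(r) total_charge(ch, r), 0)
    expect_equal(total_charge(ch), sum(per_res))
    ## every sulfate contributes exactly -1
    n_sulf <- sum(ch$atoms$element == "S")
    n_carb <- sum(ch$atoms$name == "O6A")
    n_amine <- sum(vapply(seq_len(nrow(ch$atoms)), function(i)
      ch$atoms$element[i] == "N" &&
        !any(ch$atoms$element[glycodock:::neighbors_of(ch, i)] %in% "S") &&
        !any(ch$atoms$name[glycodock:::neighbors_of(ch, i)] == "C7"), TRUE))
    expect_equal(total_charge(ch), -n_sulf - n_carb + n_amine)
  }
})

test_that("mol2 round-trip preserves topology exactly and coordinates to format precision", {
  ch <- tiny_chain(2)
  f <- tempfile(fileext = ".mol2")
  write_chain_mol2(ch, f)
  ch2 <- read_structure(f, format = "mol2")
  expect_equal(nrow(ch2$atoms), nrow(ch$atoms))
  expect_equal(nrow(ch2$bonds), nrow(ch$bonds))
  expect_equal(nrow(ch2$linkages), 1)
  expect_equal(ch2$atoms$name, ch$atoms$name)
  expect_equal(coords_of(ch2), coords_of(ch), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(ch2$residues$kind, ch$residues$kind)
  ## idempotence: second round trip is exact
  f2 <- tempfile(fileext = ".mol2")
  write_chain_mol2(ch2, f2)
  ch3 <- read_structure(f2, format = "mol2")
  expect_identical(coords_of(ch3), coords_of(ch2))
  unlink(c(f, f2))
})

test_that("PDB reading keeps only the first altloc", {
  pdb <- c(
    "ATOM      1  NZ  PRS A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CW APRS A   2       3.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CW BPRS A   2       3.500   0.000   0.000  1.00  0.00           C",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  rec <- read_structure(f, format = "pdb")
  expect_equal(nrow(rec$atoms), 2)
  expect_equal(rec$atoms$x[2], 3.0)
  unlink(f)
})

test_that("receptor PDB round-trips through bio3d", {
  cx <- standard_complex(4)
  f <- tempfile(fileext = ".pdb")
  write_receptor_pdb(cx$receptor, f)
  rec <- read_structure(f, format = "pdb")
  expect_equal(nrow(rec$atoms), nrow(cx$receptor$atoms))
  expect_equal(as.matrix(rec$atoms[, c("x", "y", "z")]),
               as.matrix(cx$receptor$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  ## charges travel in the occupancy column
  expect_equal(rec$atoms$charge, cx$receptor$atoms$charge)
  unlink(f)
})

test_that("site definition obeys the radius rule, monotonicity and the distance oracle", {
  cx <- standard_complex(4)
  site6 <- define_site(cx$receptor, cx$native_pose, radius = 6)
  ## brute-force all-pairs oracle
  rxyz <- as.matrix(cx$receptor$atoms[, c("x", "y", "z")])
  pxyz <- cx$native_pose$coords
  in_oracle <- sort(unique(cx$receptor$atoms$resno[
    apply(rxyz, 1, function(p) {
      any(sqrt(rowSums(sweep(pxyz, 2, p)^2)) <= 6)
    })]))
  expect_equal(sort(site6$site_residues), in_oracle)
  ## monotone in radius
  site3 <- define_site(cx$receptor, cx$native_pose, radius = 3)
  site9 <- define_site(cx$receptor, cx$native_pose, radius = 9)
  expect_true(all(site3$site_residues %in% site6$site_residues))
  expect_true(all(site6$site_residues %in% site9$site_residues))
  ## single pseudo-residue at a controlled distance
  rec1 <- structure(list(atoms = data.frame(
    resno = 1, resid = "PRS", name = "NZ", element = "N",
    x = 7, y = 0, z = 0, charge = 1)), class = "gag_receptor")
  pose1 <- new_pose(matrix(0, 1, 3))
  expect_error(define_site(rec1, pose1, radius = 6), "empty site")
  expect_equal(define_site(rec1, pose1, radius = 8)$site_residues, 1)
})

test_that("pose files round-trip with scores and rank ordering", {
  ch <- tiny_chain(2)
  nat <- new_pose(coords_of(ch), score = list(total = 12.5), rank = 2)
  shifted <- new_pose(sweep(coords_of(ch), 2, c(1, 0, 0), "+"),
                      score = list(total = 50), rank = 1)
  f <- tempfile(fileext = ".mol2")
  write_poses(list(nat, shifted), ch, f)
  back <- read_poses(f)
  expect_length(back, 2)
  ## rank ordering: the rank-1 pose comes first
  expect_equal(back[[1]]$score, 50)
  expect_equal(back[[2]]$score, 12.5)
  expect_equal(back[[1]]$coords, shifted$coords, tolerance = 1e-3,
               ignore_attr = TRUE)
  ## empty set gives a file with no pose blocks
  f0 <- tempfile(fileext = ".mol2")
  write_poses(list(), ch, f0)
  expect_length(read_poses(f0), 0)
  ## PDB pose sets carry MODEL blocks and score remarks
  fp <- tempfile(fileext = ".pdb")
  write_poses(list(nat, shifted), ch, fp, format = "pdb")
  lines <- readLines(fp)
  expect_equal(sum(grepl("^MODEL", lines)), 2)
  expect_equal(sum(grepl("^REMARK   6 POSE", lines)), 2)
  unlink(c(f, f0, fp))
})
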