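# Synthetic systems: construction invariants, determinism, self-consistent
# native contacts, labelled decoys, and on-disk fixtures.

test_that("toy complexes satisfy their invariants across a seed battery", {
  params <- dock_params()
  for (s in 1:5) {
    toy <- make_toy_complex(40, 6, seed = s)
    m <- complex_model(toy$receptor, toy$native_peptide)
    expect_gt(nrow(toy$native_contacts), 0)
    expect_equal(excluded_volume_energy(m, params$hard_radius, 1), 0)
    expect_lte(min(cgdock:::cross_dist(toy$receptor$sc,
                                       toy$native_peptide$sc)), 5.0)
    expect_bond_window(toy$receptor)
    expect_bond_window(toy$native_peptide)
    # lattice compliance of both Calpha traces
    for (ch in list(toy$receptor, toy$native_peptide)) {
      sp <- ch$lattice$spacing
      expect_true(all(abs(ch$ca / sp - round(ch$ca / sp)) < 1e-9))
      n <- nrow(ch$ca)
      mid <- (ch$ca[-n, , drop = FALSE] + ch$ca[-1, , drop = FALSE]) / 2
      expect_equal(ch$bond_centers, mid, tolerance = 1e-9)
    }
  }
})

test_that("toy construction is deterministic under a seed", {
  t1 <- make_toy_complex(30, 5, seed = 4)
  t2 <- make_toy_complex(30, 5, seed = 4)
  expect_identical(t1$receptor$ca, t2$receptor$ca)
  expect_identical(t1$native_peptide$ca, t2$native_peptide$ca)
  expect_identical(t1$peptide$sequence, t2$peptide$sequence)
  expect_identical(t1$native_contacts, t2$native_contacts)
})

test_that("stored native contacts equal a fresh recomputation at 5 A", {
  toy <- fixture_toy()
  fresh <- native_contacts(toy$receptor, toy$native_peptide, cutoff = 5.0)
  expect_identical(toy$native_contacts[, c("resid", "pep_index", "rec_pos")],
                   fresh[, c("resid", "pep_index", "rec_pos")])
})

test_that("decoy sets hit their ligand-RMSD targets and cluster as planted", {
  toy <- fixture_toy()
  native <- complex_model(toy$receptor, toy$native_peptide)
  set.seed(23)
  dec <- make_decoy_set(toy, 6, c(0, 3.0, 8.0))
  expect_length(dec$models, 6)
  expect_equal(dec$labels$achieved[dec$labels$target == 0], c(0, 0))
  for (i in seq_len(6)) {
    ach <- ligand_rmsd(dec$models[[i]], native)
    expect_equal(ach, dec$labels$achieved[i], tolerance = 1e-6)
    if (dec$labels$target[i] > 0)
      expect_lte(abs(ach - dec$labels$target[i]),
                 0.15 * dec$labels$target[i])
  }

  # two tight bundles at 2 and 15 A: k-medoids recovers the planted labels
  set.seed(24)
  bundles <- make_decoy_set(toy, 12, rep(c(2, 15), each = 6))
  d <- ligand_rmsd_matrix(bundles$models)
  km <- k_medoids(d, 2)
  planted <- rep(1:2, each = 6)
  agree <- max(mean(km$assignment == planted),
               mean(km$assignment == 3 - planted))
  expect_equal(agree, 1.0)
})

test_that("toy fixtures round-trip through the plain-text formats", {
  toy <- fixture_toy()
  dir <- withr::local_tempdir()
  write_toy_fixture(toy, dir)
  expect_true(all(file.exists(file.path(dir, c("receptor.pdb", "peptide.pdb",
                                               "native_cg.pdb",
                                               "toy.json")))))
  chains <- read_receptor_pdb(file.path(dir, "receptor.pdb"))
  at <- chains[[1]]
  expect_identical(length(unique(at$reskey)), nrow(toy$receptor$ca))
  ca <- at[at$elety == "CA", ]
  expect_equal(as.matrix(ca[, c("x", "y", "z")]), toy$receptor$ca,
               tolerance = 1e-3, ignore_attr = TRUE)
  side <- jsonlite::read_json(file.path(dir, "toy.json"),
                              simplifyVector = TRUE)
  expect_identical(side$sequence, toy$peptide$sequence)
  expect_identical(nrow(side$native_contacts), nrow(toy$native_contacts))
  cg <- read_models_pdb(file.path(dir, "native_cg.pdb"))
  expect_equal(cg[[1]]$peptide$ca, unname(toy$native_peptide$ca),
               tolerance = 1e-3, ignore_attr = TRUE)
})
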