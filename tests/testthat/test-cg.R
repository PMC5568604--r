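# Coarse-grained representation: lattice snapping, pseudoatom derivation,
# all-atom reduction.

test_that("snap_to_lattice rounds per axis and is idempotent", {
  lat <- lattice_config(0.61)
  expect_equal(snap_to_lattice(c(1, 1, 1), lat), c(1.22, 1.22, 1.22))
  expect_equal(snap_to_lattice(c(0, 0, 0), lat), c(0, 0, 0))
  off <- lattice_config(enabled = FALSE)
  x <- matrix(rnorm(30), 10, 3)
  expect_identical(snap_to_lattice(x, off), x)

  set.seed(42)
  for (rep in 1:20) {
    sp <- runif(1, 0.3, 1.5)
    lat <- lattice_config(sp)
    m <- matrix(rnorm(30, sd = 10), 10, 3)
    s1 <- snap_to_lattice(m, lat)
    expect_equal(snap_to_lattice(s1, lat), s1)           # idempotent
    expect_true(max(abs(s1 - m)) <= sp / 2 + 1e-12)       # max displacement
    expect_true(all(abs(s1 / sp - round(s1 / sp)) < 1e-9))  # on-lattice
  }
  expect_error(snap_to_lattice(c(NA, 0, 0), lat), "non-finite")
})

test_that("bond centers are midpoints of consecutive Calpha pairs", {
  ch <- cg_chain(rbind(c(0, 0, 0), c(3.8, 0, 0)), c("ALA", "GLY"),
                 lattice = lattice_config(enabled = FALSE))
  expect_equal(ch$bond_centers, matrix(c(1.9, 0, 0), 1, 3))

  set.seed(1)
  toy <- fixture_toy()
  for (chain in list(toy$receptor, toy$native_peptide)) {
    n <- nrow(chain$ca)
    expect_identical(nrow(chain$bond_centers), n - 1L)
    mid <- (chain$ca[-n, , drop = FALSE] + chain$ca[-1, , drop = FALSE]) / 2
    expect_equal(chain$bond_centers, mid, tolerance = 1e-9)
  }
})

test_that("coarse_grain reduces atoms to pseudoatoms with fallbacks", {
  at <- tiny_atomic_chain()
  cg <- coarse_grain(at, lattice_config(enabled = FALSE))
  expect_s3_class(cg, "cg_chain")
  expect_identical(nrow(cg$ca), 3L)
  expect_identical(cg$residue_name, c("LEU", "ALA", "GLY"))
  expect_equal(cg$ca[2, ], c(3.8, 0, 0))
  # LEU sc = centroid of CG, CD1, CD2 (side-chain heavy atoms beyond CB)
  leu_side <- at[at$resno == 1 & at$elety %in% c("CG", "CD1", "CD2"), ]
  expect_equal(cg$sc[1, ], c(mean(leu_side$x), mean(leu_side$y),
                             mean(leu_side$z)))
  # ALA: only CB beyond backbone -> sc == cb == atomic CB
  expect_equal(cg$sc[2, ], cg$cb[2, ])
  expect_equal(cg$cb[2, ], c(4.3, -1.0, 1.0))
  # terminal GLY: cb == sc == Calpha (fallback)
  expect_equal(cg$cb[3, ], cg$ca[3, ])
  expect_equal(cg$sc[3, ], cg$ca[3, ])
})

test_that("coarse_grain snaps the trace and keeps bonds in window", {
  at <- tiny_atomic_chain()
  cg <- coarse_grain(at, lattice_config(0.61))
  expect_true(all(abs(cg$ca / 0.61 - round(cg$ca / 0.61)) < 1e-9))
  expect_bond_window(cg)
  # cb/sc ride along with the snap: intra-residue geometry preserved
  cg0 <- coarse_grain(at, lattice_config(enabled = FALSE))
  expect_equal(cg$cb - cg$ca, cg0$cb - cg0$ca, tolerance = 1e-9)
})

test_that("coarse_grain errors on missing CA and warns on chain breaks", {
  at <- tiny_atomic_chain()
  expect_error(coarse_grain(at[at$elety != "CA" | at$resno != 2, ]),
               "no CA atom")
  gap <- at
  gap[gap$resno == 3, c("x")] <- gap[gap$resno == 3, c("x")] + 30
  expect_warning(cg <- coarse_grain(gap, lattice_config(enabled = FALSE)),
                 "chain break")
  expect_identical(attr(cg, "chain_breaks"), 2L)
  expect_identical(nrow(cg$ca), 3L)  # kept, not dropped
})

test_that("residue count and order are preserved; accessors work", {
  toy <- fixture_toy()
  rec <- toy$receptor
  expect_identical(length(rec), nrow(rec$ca))
  r5 <- cg_residue(rec, 5)
  expect_identical(r5$residue_index, rec$residue_index[5])
  expect_equal(r5$ca, rec$ca[5, ])
  expect_error(cg_residue(rec, 0))
})
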