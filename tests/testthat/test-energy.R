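# Energy model: the one-sided linear contact restraint, receptor
# flat-bottom restraints, surrogate statistical terms, and the
# scoring/sampling energy split.

test_that("contact restraint is zero up to D0 and linear beyond", {
  expect_equal(contact_restraint_energy(4.0, 5.0, 1.0), 0)
  expect_equal(contact_restraint_energy(5.0, 5.0, 1.0), 0)   # boundary
  expect_equal(contact_restraint_energy(7.5, 5.0, 1.0), 2.5)
  expect_error(contact_restraint_energy(-0.1), "non-negative")

  set.seed(5)
  for (rep in 1:20) {
    D0 <- runif(1, 1, 8)
    s <- runif(1, 0, 3)
    D <- sort(runif(200, 0, 20))
    e <- contact_restraint_energy(D, D0, s)
    expect_true(all(e[D <= D0] == 0))
    expect_true(all(e >= 0))
    expect_true(all(diff(e) >= -1e-12))                  # non-decreasing
    expect_true(all(abs(diff(e)) <= s * diff(D) + 1e-9))  # s-Lipschitz
  }
})

test_that("receptor flat-bottom restraints vanish at native and grow past tolerance", {
  # bent chain: residues 1 and 4 within 8 A, the only restrained pair
  ca <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(5.0, 3.6, 0), c(2.0, 5.8, 0))
  rec <- cg_chain(ca, rep("SER", 4), lattice = lattice_config(enabled = FALSE),
                  validate = FALSE)
  native <- native_ca_restraints(rec)
  expect_identical(nrow(native), 1L)
  expect_identical(c(native$i, native$j), c(1L, 4L))

  pep <- cg_chain(cbind(seq(0, 7.6, by = 3.8), 50, 50), rep("GLY", 3),
                  role = "peptide", lattice = lattice_config(enabled = FALSE))
  m0 <- complex_model(rec, pep)
  expect_equal(receptor_restraint_energy(m0, native), 0)

  shift_4 <- function(delta) {
    r2 <- rec
    u <- unitv(rec$ca[4, ] - rec$ca[1, ])
    r2$ca[4, ] <- r2$ca[4, ] + delta * u
    complex_model(r2, pep)
  }
  expect_equal(receptor_restraint_energy(shift_4(1.0), native,
                                         tolerance = 1.0), 0)
  expect_equal(receptor_restraint_energy(shift_4(2.0), native,
                                         tolerance = 1.0, weight = 2.0), 2.0)
  bad <- data.frame(i = 1L, j = 9L, d = 5)
  expect_error(receptor_restraint_energy(m0, bad), "absent")
})

test_that("excluded volume counts clashing pseudoatom pairs", {
  far_pep <- cg_chain(cbind(seq(0, 7.6, by = 3.8), 40, 0), rep("GLY", 3),
                      role = "peptide",
                      lattice = lattice_config(enabled = FALSE))
  line <- cg_chain(cbind(seq(0, 11.4, by = 3.8), 0, 0), rep("GLY", 4),
                   lattice = lattice_config(enabled = FALSE))
  expect_equal(excluded_volume_energy(complex_model(line, far_pep)), 0)

  # bring one peptide Calpha within the hard radius of one receptor Calpha
  near <- cg_chain(sweep(far_pep$ca, 2, c(0, 37.5, 0)), rep("GLY", 3),
                   role = "peptide",
                   lattice = lattice_config(enabled = FALSE))  # Ca-Ca 2.5 A
  e <- excluded_volume_energy(complex_model(line, near), hard_radius = 3.0,
                              penalty = 5.0)
  expect_true(e >= 5.0)

  # translational invariance
  toy <- fixture_toy()
  m <- complex_model(toy$receptor, toy$native_peptide)
  shift <- function(ch) {
    ch$ca <- ch$ca + 7.3; ch$cb <- ch$cb + 7.3; ch$sc <- ch$sc + 7.3
    ch
  }
  m2 <- complex_model(shift(toy$receptor), shift(toy$native_peptide))
  expect_equal(excluded_volume_energy(m2), excluded_volume_energy(m))
})

test_that("pair contact energy sums matrix terms over SC contacts", {
  lat <- lattice_config(enabled = FALSE)
  # receptor LEU and peptide PHE with SC centers ~2.5 A apart, rest far
  rec <- cg_chain(cbind(seq(0, 11.4, by = 3.8), 0, 0),
                  c("SER", "LEU", "SER", "SER"), lattice = lat)
  pep <- cg_chain(cbind(c(3.8, 7.6, 11.4), 9, 0), c("PHE", "GLY", "GLY"),
                  role = "peptide", lattice = lat)
  pep$sc[1, ] <- rec$sc[2, ] + c(0, 2.5, 0)
  pep$sc[2, ] <- c(7.6, 40, 0)
  pep$sc[3, ] <- c(11.4, 40, 0)
  pep$cb <- pep$sc
  cm <- matrix(0, 20, 20, dimnames = list(AA1 <- rownames(default_contact_matrix()),
                                          AA1))
  cm["L", "F"] <- cm["F", "L"] <- -1.2
  m <- complex_model(rec, pep)
  expect_equal(pair_contact_energy(m, cm, r_on = 6.0), -1.2)

  none <- pair_contact_energy(m, cm, r_on = 0.5)
  expect_equal(none, 0)

  # invariance under global rotation
  R <- rotation_matrix(c(1, 2, 3), 1.1)
  rot <- function(ch) {
    ch$ca <- ch$ca %*% R; ch$cb <- ch$cb %*% R; ch$sc <- ch$sc %*% R
    ch
  }
  expect_equal(pair_contact_energy(complex_model(rot(rec), rot(pep)), cm, 6.0),
               -1.2, tolerance = 1e-9)
})

test_that("secondary-structure bias matches pseudo-angle bins", {
  lat <- lattice_config(enabled = FALSE)
  # ideal alpha-helix Calpha trace: radius 2.3 A, rise 1.5 A, 100 deg/res
  t <- (0:5) * 100 * pi / 180
  helix <- cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * (0:5))
  pep <- cg_chain(helix, rep("LEU", 6), role = "peptide", lattice = lat,
                  validate = FALSE)
  expect_equal(ss_bias_energy(pep, peptide_spec("LLLLLL", "HHHHHH")), 0)
  expect_equal(ss_bias_energy(pep, peptide_spec("LLLLLL", "CCCCCC")), 0)
  expect_equal(ss_bias_energy(pep, peptide_spec("LLLLLL")), 0)  # no pref
  # helix geometry violates an all-extended preference at every interior res
  expect_equal(ss_bias_energy(pep, peptide_spec("LLLLLL", "EEEEEE"),
                              weight = 2.0), 8.0)
  expect_error(ss_bias_energy(pep, peptide_spec("LLL", "EEE")), "length")
})

test_that("sampling energy = scoring energy + contact restraint, exactly", {
  toy <- fixture_toy()
  rec <- toy$receptor
  pep <- toy$native_peptide
  m <- complex_model(rec, pep)
  spec <- toy$peptide
  native <- native_ca_restraints(rec)

  eb0 <- total_energy(m, NULL, native = native, spec = spec)
  expect_equal(eb0$contact_restraint, 0)
  expect_equal(eb0$sampling_energy, eb0$scoring_energy)
  expect_equal(eb0$scoring_energy,
               eb0$excluded_volume + eb0$pair_contact + eb0$ss_bias +
                 eb0$receptor_restraint, tolerance = 1e-12)

  # a restraint currently satisfied (D < D0): no sampling/scoring gap
  ct <- toy$native_contacts[1, ]
  d_now <- sqrt(sum((rec$sc[ct$rec_pos, ] - pep$sc[ct$pep_index, ])^2))
  ct$D0 <- d_now + 1
  eb1 <- total_energy(m, ct, native = native, spec = spec)
  expect_equal(eb1$sampling_energy, eb1$scoring_energy)

  # a violated restraint: gap equals s * (D - D0)
  ct$D0 <- d_now - 2
  ct$s <- 1.0
  eb2 <- total_energy(m, ct, native = native, spec = spec)
  expect_equal(eb2$sampling_energy - eb2$scoring_energy, 2.0,
               tolerance = 1e-9)
  expect_equal(eb2$scoring_energy, eb1$scoring_energy)
})

test_that("all energy terms are invariant under rigid motion of the complex", {
  toy <- fixture_toy()
  spec <- toy$peptide
  native <- native_ca_restraints(toy$receptor)
  ct <- toy$native_contacts[1:2, ]
  m <- complex_model(toy$receptor, toy$native_peptide)
  e0 <- total_energy(m, ct, native = native, spec = spec)
  set.seed(9)
  for (rep in 1:5) {
    R <- rotation_matrix(unitv(rnorm(3)), runif(1, 0, 2 * pi))
    tr <- rnorm(3, sd = 20)
    move <- function(ch) {
      for (f in c("ca", "cb", "sc"))
        ch[[f]] <- sweep(ch[[f]] %*% R, 2, -tr)
      ch
    }
    m2 <- complex_model(move(toy$receptor), move(toy$native_peptide))
    e1 <- total_energy(m2, ct, native = native, spec = spec)
    for (term in c("excluded_volume", "pair_contact", "ss_bias",
                   "receptor_restraint", "contact_restraint"))
      expect_equal(e1[[term]], e0[[term]], tolerance = 1e-6)
  }
})
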