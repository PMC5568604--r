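# Replica-exchange Monte Carlo: scattering, move proposals, Metropolis and
# exchange rules, trajectory contracts, and a detailed-balance smoke test.

test_that("metropolis rule: downhill always, uphill by Boltzmann factor", {
  set.seed(1)
  expect_true(metropolis_accept(-1, 1))
  expect_true(metropolis_accept(0, 1))
  # zero-temperature limit: uphill move essentially never accepted
  expect_false(any(vapply(1:50, function(i) metropolis_accept(1, 1e-12), TRUE)))
  expect_error(metropolis_accept(1, 0))

  # acceptance probability at delta = T ln 2 is exactly 1/2
  T <- 1.7
  set.seed(123)
  acc <- mean(vapply(1:1e5, function(i)
    metropolis_accept(T * log(2), T), TRUE))
  expect_lt(abs(acc - 0.5), 0.005)
})

test_that("replica exchange swaps temperatures, keeps identities", {
  m <- complex_model(fixture_toy()$receptor, fixture_toy()$native_peptide)
  a <- replica_state(m, 1.0, replica_id = 1, ladder_index = 1, energy = 5)
  b <- replica_state(m, 1.3, replica_id = 2, ladder_index = 2, energy = 5)
  set.seed(2)
  res <- attempt_exchange(a, b)
  expect_true(res$accepted)  # equal energies: delta = 0, always accepted
  expect_identical(res$a$replica_id, 1L)
  expect_equal(res$a$temperature, 1.3)
  expect_equal(res$b$temperature, 1.0)
  expect_identical(res$a$ladder_index, 2L)

  cc <- replica_state(m, 2.0, replica_id = 3, ladder_index = 3, energy = 5)
  expect_error(attempt_exchange(a, cc), "adjacent")
  expect_error(attempt_exchange(replica_state(m, 1, 1, 1), b), "energies")
})

test_that("scatter_peptide respects the surface-distance bound and avoids clashes", {
  toy <- fixture_toy()
  spec <- toy$peptide
  params <- dock_params()
  set.seed(42)
  for (k in 1:100) {
    pep <- scatter_peptide(toy$receptor, spec, max_dist = 20)
    m <- complex_model(toy$receptor, pep)
    dmin <- min(cgdock:::cross_dist(
      rbind(toy$receptor$ca, toy$receptor$cb, toy$receptor$sc),
      rbind(pep$ca, pep$cb, pep$sc)))
    expect_lte(dmin, 20)
    expect_equal(excluded_volume_energy(m, params$hard_radius, 1), 0)
    expect_bond_window(pep)
  }

  # determinism under a fixed seed
  set.seed(7); p1 <- scatter_peptide(toy$receptor, spec)
  set.seed(7); p2 <- scatter_peptide(toy$receptor, spec)
  expect_identical(p1$ca, p2$ca)

  # a bound below the clash radius is geometrically unsatisfiable
  set.seed(8)
  expect_error(scatter_peptide(toy$receptor, spec, max_dist = 0.5,
                               max_retries = 30), "larger max_dist")
})

test_that("propose_move is local and respects configured weights", {
  toy <- fixture_toy()
  set.seed(11)
  pep <- scatter_peptide(toy$receptor, toy$peptide)
  st <- replica_state(complex_model(toy$receptor, pep), 1.0, 1)

  # zero-amplitude translation is a null move
  set.seed(1)
  cand <- propose_move(st, weights = c(translate = 1, rotate = 0, kink = 0,
                                       crankshaft = 0, endflip = 0,
                                       receptor = 0),
                       amplitudes = list(translate = 0, rotate = 0.45,
                                         kink = 2, crankshaft = 1.05,
                                         receptor = 1))
  expect_equal(cand$peptide$ca, pep$ca)
  expect_identical(attr(cand, "move_type"), "translate")

  # kink locality: only the targeted residue (+/- 1 for derived atoms) moves
  set.seed(2)
  for (rep in 1:25) {
    cand <- propose_move(st, weights = c(translate = 0, rotate = 0, kink = 1,
                                         crankshaft = 0, endflip = 0,
                                         receptor = 0))
    moved <- attr(cand, "moved")
    i <- moved$residues
    far <- setdiff(seq_len(nrow(pep$ca)), (i - 1):(i + 1))
    expect_equal(cand$peptide$ca[far, , drop = FALSE],
                 pep$ca[far, , drop = FALSE])
    expect_equal(cand$receptor$ca, toy$receptor$ca)
    expect_bond_window(cand$peptide)
  }

  # move-type frequencies follow the configured weights (3 sigma bounds)
  w <- sim_config()$move_weights
  set.seed(3)
  types <- vapply(1:10000, function(k)
    attr(propose_move(st), "move_type"), "")
  counts <- table(factor(types, levels = names(w)))
  for (ty in names(w)) {
    expected <- 10000 * w[[ty]]
    sdev <- sqrt(10000 * w[[ty]] * (1 - w[[ty]]))
    expect_lt(abs(counts[[ty]] - expected), 3 * sdev + 1e-9)
  }
})

test_that("trajectory contracts: size, finiteness, determinism, no-op run", {
  toy <- fixture_toy()
  cfg <- sim_config(n_replicas = 4, n_cycles = 40, snapshots_per_replica = 20,
                    seed = 5)
  tr1 <- run_remc(toy$receptor, toy$peptide, config = cfg)
  expect_identical(nrow(tr1$meta), 4L * 20L)
  expect_true(all(is.finite(tr1$meta$scoring_energy)))
  expect_identical(dim(tr1$pep_ca), c(6L, 3L, 80L))

  tr2 <- run_remc(toy$receptor, toy$peptide, config = cfg)
  expect_identical(tr1$meta$sampling_energy, tr2$meta$sampling_energy)
  expect_identical(tr1$pep_ca, tr2$pep_ca)

  cfg0 <- sim_config(n_replicas = 3, n_cycles = 0, snapshots_per_replica = 5,
                     seed = 5)
  tr0 <- run_remc(toy$receptor, toy$peptide, config = cfg0)
  expect_identical(nrow(tr0$meta), 15L)
  expect_true(all(tr0$meta$cycle == 0))
  # snapshots are the initial scattered states, repeated
  first <- tr0$pep_ca[, , tr0$meta$replica_id == 1]
  expect_identical(first[, , 1], first[, , dim(first)[3]])
})

test_that("kernel energies equal the R energy model on snapshots", {
  tr <- fixture_traj()
  set.seed(13)
  for (i in sample.int(nrow(tr$meta), 8)) {
    m <- get_model(tr, i)
    eb <- total_energy(m, tr$restraints, tr$params, native = tr$native,
                       spec = tr$spec)
    row <- tr$meta[i, ]
    expect_equal(eb$excluded_volume, row$excluded_volume, tolerance = 1e-8)
    expect_equal(eb$pair_contact, row$pair_contact, tolerance = 1e-8)
    expect_equal(eb$ss_bias, row$ss_bias, tolerance = 1e-8)
    expect_equal(eb$receptor_restraint, row$receptor_restraint,
                 tolerance = 1e-8)
    expect_equal(eb$contact_restraint, row$contact_restraint,
                 tolerance = 1e-8)
  }
})

test_that("Metropolis sampling of a harmonic well reproduces the analytic variance", {
  # 1-dof particle in E = x^2 / 2 at fixed T: Var(x) = T
  set.seed(21)
  for (T in c(0.8, 1.5)) {
    x <- 0
    xs <- numeric(20000)
    for (i in seq_along(xs)) {
      prop <- x + runif(1, -1.5, 1.5)
      if (metropolis_accept(prop^2 / 2 - x^2 / 2, T)) x <- prop
      xs[i] <- x
    }
    v <- var(xs[-(1:2000)])
    expect_lt(abs(v - T) / T, 0.05)
  }
})
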