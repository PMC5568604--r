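# Model selection: energy filter, ligand RMSD, k-medoids against a
# brute-force oracle, density ranking, native contacts, nested RMSD report.

brute_force_k_medoids <- function(d, k) {
  n <- nrow(d)
  best <- NULL
  for (med in utils::combn(n, k, simplify = FALSE)) {
    cost <- sum(apply(d[, med, drop = FALSE], 1, min))
    if (is.null(best) || cost < best$cost) best <- list(medoids = med,
                                                        cost = cost)
  }
  best
}

test_that("top_by_energy selects the lowest scoring energies with clamping", {
  tr <- fixture_traj()
  sel <- top_by_energy(tr, 100)
  expect_length(sel$ids, 100)
  e_sel <- tr$meta$scoring_energy[sel$ids]
  e_rest <- tr$meta$scoring_energy[-sel$ids]
  expect_lte(max(e_sel), min(e_rest))
  expect_true(!is.unsorted(e_sel))
  # clamping: n larger than the pool returns the whole pool sorted
  all_ <- top_by_energy(tr, 10 * nrow(tr$meta))
  expect_length(all_$ids, nrow(tr$meta))
  expect_error(top_by_energy(tr, 0))
})

test_that("ligand RMSD: identity, rigid motion, pure translation", {
  tr <- fixture_traj()
  a <- get_model(tr, 1)
  b <- get_model(tr, 2)
  expect_equal(ligand_rmsd(a, a), 0, tolerance = 1e-9)

  # whole-complex rigid motion is removed by receptor superposition
  R <- rotation_matrix(c(1, 1, 0), 0.9)
  move <- function(ch) {
    for (f in c("ca", "cb", "sc")) ch[[f]] <- sweep(ch[[f]] %*% R, 2, -5)
    ch
  }
  a_rot <- complex_model(move(a$receptor), move(a$peptide))
  expect_equal(ligand_rmsd(a, a_rot), 0, tolerance = 1e-6)

  # translating the peptide by t with the receptor fixed gives RMSD |t|
  shift <- a
  pep <- a$peptide
  pep$ca <- sweep(pep$ca, 2, c(3, 0, 0), "+")
  a_shift <- complex_model(a$receptor, pep)
  expect_equal(ligand_rmsd(a_shift, a), 3.0, tolerance = 1e-9)

  # symmetry and triangle inequality on random snapshot triples
  set.seed(31)
  for (rep in 1:10) {
    ids <- sample.int(nrow(tr$meta), 3)
    m <- lapply(ids, get_model, traj = tr)
    dab <- ligand_rmsd(m[[1]], m[[2]])
    dba <- ligand_rmsd(m[[2]], m[[1]])
    dac <- ligand_rmsd(m[[1]], m[[3]])
    dbc <- ligand_rmsd(m[[2]], m[[3]])
    expect_equal(dab, dba, tolerance = 1e-6)
    expect_lte(dac, dab + dbc + 1e-6)
  }
})

test_that("compiled pairwise RMSD agrees with the R implementation and bio3d", {
  tr <- fixture_traj()
  sel <- top_by_energy(tr, 12)
  D <- ligand_rmsd_matrix(sel)
  expect_identical(dim(D), c(12L, 12L))
  expect_equal(D, t(D), tolerance = 1e-9)
  set.seed(4)
  for (rep in 1:6) {
    ij <- sample.int(12, 2)
    expect_equal(D[ij[1], ij[2]],
                 ligand_rmsd(sel[[ij[1]]], sel[[ij[2]]]), tolerance = 1e-6)
  }
  # independent check via bio3d's least-squares fitting
  a <- sel[[1]]; b <- sel[[2]]
  xyz_a <- as.vector(t(a$receptor$ca))
  xyz_b <- as.vector(t(b$receptor$ca))
  fit <- suppressWarnings(
    bio3d::fit.xyz(fixed = xyz_b, mobile = rbind(xyz_a, xyz_a)))
  R_ref <- ligand_rmsd(a, b)
  # apply the bio3d transform to the peptide via Kabsch on receptor
  k <- kabsch(a$receptor$ca, b$receptor$ca)
  pep_fit <- a$peptide$ca %*% k$R + matrix(k$t, nrow(a$peptide$ca), 3,
                                           byrow = TRUE)
  expect_equal(sqrt(mean(rowSums((pep_fit - b$peptide$ca)^2))), R_ref,
               tolerance = 1e-9)
  # and the receptor-fit RMSD itself matches bio3d's
  # fit.xyz reports coordinates at finite precision; allow a small absolute gap
  expect_lt(abs(bio3d::rmsd(xyz_b, fit[1, ]) - k$rmsd), 5e-3)
})

test_that("k_medoids matches exhaustive search on small instances", {
  # 5 points on a line, k = 2: known optimum
  x <- c(0, 1, 2, 10, 11)
  d <- as.matrix(dist(x))
  set.seed(5)
  km <- k_medoids(d, 2)
  bf <- brute_force_k_medoids(d, 2)
  expect_equal(km$cost, bf$cost)
  expect_setequal(km$medoids, bf$medoids)

  # degenerate k == n
  km_n <- k_medoids(d, 5)
  expect_equal(km_n$cost, 0)
  expect_setequal(km_n$medoids, 1:5)
  expect_error(k_medoids(d, 6), "exceed")

  # random instances: oracle equivalence (total cost)
  set.seed(6)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    k <- sample(2:3, 1)
    pts <- matrix(rnorm(2 * n), n, 2)
    d <- as.matrix(dist(pts))
    km <- k_medoids(d, k)
    bf <- brute_force_k_medoids(d, k)
    expect_equal(km$cost, bf$cost, tolerance = 1e-9)
  }
})

test_that("cluster density is size over mean pairwise spread, with degenerate guard", {
  d <- matrix(2, 4, 4); diag(d) <- 0
  expect_equal(as.numeric(cluster_density(d)), 2.0)  # 4 / 2.0
  expect_false(attr(cluster_density(d), "degenerate"))
  expect_equal(as.numeric(cluster_density(2 * d)),
               as.numeric(cluster_density(d)) / 2)   # inverse-linear
  s <- cluster_density(matrix(0, 1, 1))
  expect_equal(as.numeric(s), 1 / 1e-3)
  expect_true(attr(s, "degenerate"))
})

test_that("medoid ranking: density descending, then size, then energy", {
  tr <- fixture_traj()
  mk_cluster <- function(ids, medoid, size, density)
    list(member_ids = ids, medoid_id = medoid, size = size,
         density = density, degenerate = FALSE)
  rep_ <- structure(list(clusters = list(
    mk_cluster(1:10, 1L, 10L, 5.0),
    mk_cluster(11:30, 11L, 20L, 9.0),
    mk_cluster(31:35, 31L, 5L, 1.0)), cost = 0, trajectory = tr),
    class = "cluster_report")
  out <- rank_models(rep_)
  expect_equal(out$ranking$density, c(9, 5, 1))
  expect_identical(out$ranking$medoid_model_id, c(11L, 1L, 31L))

  # equal densities: larger cluster first
  rep2 <- structure(list(clusters = list(
    mk_cluster(1:10, 1L, 10L, 5.0),
    mk_cluster(11:30, 11L, 20L, 5.0)), cost = 0, trajectory = tr),
    class = "cluster_report")
  out2 <- rank_models(rep2)
  expect_identical(out2$ranking$medoid_model_id[1], 11L)
})

test_that("cluster_models partitions the filtered set and ranks k medoids", {
  tr <- fixture_traj()
  sel <- top_by_energy(tr, 200)
  set.seed(12)
  rep_ <- cluster_models(sel, k = 10)
  expect_identical(nrow(rep_$ranking), 10L)
  members <- unlist(lapply(rep_$clusters, `[[`, "member_ids"))
  expect_setequal(members, sel$ids)          # partition
  expect_length(members, length(sel$ids))
  expect_true(all(diff(rep_$ranking$density) <= 1e-12))  # sorted desc
  for (cl in rep_$clusters)
    expect_true(cl$medoid_id %in% cl$member_ids)
})

test_that("native contact detection uses the distance cutoff exactly", {
  lat <- lattice_config(enabled = FALSE)
  rec <- cg_chain(cbind(c(0, 3.8, 7.6), 0, 0), rep("LEU", 3), lattice = lat)
  mk_pep <- function(gap) {
    ca <- cbind(c(0, 3.8, 7.6), 20, 0)
    p <- cg_chain(ca, rep("PHE", 3), role = "peptide", lattice = lat)
    # place one peptide SC at an exact distance from a receptor SC
    p$sc[2, ] <- rec$sc[2, ] + c(0, gap, 0)
    p
  }
  ct_in <- native_contacts(rec, mk_pep(4.9), cutoff = 5)
  expect_identical(nrow(ct_in), 1L)
  expect_identical(ct_in$pep_index, 2L)
  expect_identical(ct_in$rec_pos, 2L)
  ct_out <- native_contacts(rec, mk_pep(5.1), cutoff = 5)
  expect_identical(nrow(ct_out), 0L)
  expect_true(attr(ct_in, "approximate"))  # pseudoatom-based

  # all-atom route is exact on the rendered toy fixture
  toy <- fixture_toy()
  ct_aa <- native_contacts(toy$receptor_aa, toy$peptide_aa, cutoff = 5)
  expect_false(attr(ct_aa, "approximate"))
  expect_gt(nrow(ct_aa), 0)
})

test_that("select_random_contact draws uniformly and deterministically", {
  toy <- fixture_toy()
  one <- toy$native_contacts[2, , drop = FALSE]
  expect_identical(select_random_contact(one), one)
  expect_error(select_random_contact(one[0, ]), "empty")

  set.seed(17); c1 <- select_random_contact(toy$native_contacts)
  set.seed(17); c2 <- select_random_contact(toy$native_contacts)
  expect_identical(c1, c2)

  four <- toy$native_contacts[1:4, ]
  set.seed(18)
  idx <- vapply(1:10000, function(i) {
    ct <- select_random_contact(four)
    which(four$rec_pos == ct$rec_pos & four$pep_index == ct$pep_index)[1]
  }, 0L)
  tab <- tabulate(idx, 4)
  for (k in 1:4) {
    expected <- 10000 / 4
    sdev <- sqrt(10000 * 0.25 * 0.75)
    expect_lt(abs(tab[k] - expected), 3 * sdev)
  }
})

test_that("minimum-RMSD report respects set containment and is exact on contained references", {
  tr <- fixture_traj()
  sel <- top_by_energy(tr, 200)
  set.seed(19)
  rep_ <- cluster_models(sel, k = 10)
  ranked <- rep_$ranking$medoid_model_id

  toy <- fixture_toy()
  ref <- complex_model(toy$receptor, toy$native_peptide)
  rr <- rmsd_report(tr, sel, ranked, ref)
  expect_lte(rr$rmsd_pool, rr$rmsd_filtered + 1e-9)
  expect_lte(rr$rmsd_filtered, rr$rmsd_top + 1e-9)
  expect_lte(rr$rmsd_filtered, rr$rmsd_ranked + 1e-9)

  # a reference that IS one of the ranked models gives ranked RMSD 0
  rr0 <- rmsd_report(tr, sel, ranked, get_model(tr, ranked[1]))
  expect_equal(rr0$rmsd_ranked, 0, tolerance = 1e-6)
  expect_equal(rr0$rmsd_pool, 0, tolerance = 1e-6)

  expect_null(rmsd_report(tr, sel, ranked, NULL))  # evaluation skipped
})
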