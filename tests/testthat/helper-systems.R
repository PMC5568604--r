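# Shared fixtures, built once per test run and cached.  The toy complex and
# the small trajectory are deterministic (fixed seeds).

.fixture_cache <- new.env(parent = emptyenv())

fixture_toy <- function() {
  if (is.null(.fixture_cache$toy))
    .fixture_cache$toy <- make_toy_complex(40, 6, seed = 7)
  .fixture_cache$toy
}

# a scaled-down but complete trajectory (10 replicas x 100 snapshots)
fixture_traj <- function() {
  if (is.null(.fixture_cache$traj)) {
    toy <- fixture_toy()
    .fixture_cache$traj <- run_remc(
      toy$receptor, toy$peptide,
      config = sim_config(n_cycles = 300, snapshots_per_replica = 100,
                          seed = 11))
  }
  .fixture_cache$traj
}

# a three-residue all-atom chain data frame in the reader's layout
tiny_atomic_chain <- function() {
  mk <- function(elety, resno, resid, x, y, z)
    data.frame(elety = elety, resno = resno, resid = resid,
               reskey = as.character(resno), chain = "A",
               x = x, y = y, z = z, stringsAsFactors = FALSE)
  rbind(
    mk(c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"), 1, "LEU",
       c(-1.2, 0, 1.2, 1.9, 0.4, 0.9, 0.3, 2.0),
       c(0.8, 0, 0.6, 0.1, 1.2, 2.0, 3.2, 2.4),
       c(0, 0, -1, -2, 1.2, 2.2, 2.6, 3.0)),
    mk(c("N", "CA", "C", "O", "CB"), 2, "ALA",
       c(2.4, 3.8, 4.6, 4.2, 4.3),
       c(0.4, 0, 1, 2, -1.0),
       c(-0.5, 0, 0.8, 1.2, 1.0)),
    mk(c("N", "CA", "C", "O"), 3, "GLY",
       c(5.6, 7.6, 8.6, 8.4),
       c(0.8, 0, 0.6, 1.6),
       c(0.2, 0, 1.0, 1.6)))
}

# PDB text for a two-chain, altloc-bearing fixture (written at test time)
write_fixture_pdb <- function(path) {
  fmt <- function(serial, name, alt, resid, chain, resno, x, y, z)
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
            serial, paste0(" ", name), alt, resid, chain, resno, x, y, z,
            1.0, 0.0, substr(name, 1, 1))
  lines <- c(
    fmt(1, "N",  " ", "ALA", "A", 1, -1.2, 0.8, 0.0),
    fmt(2, "CA", "A", "ALA", "A", 1, 0.0, 0.0, 0.0),
    fmt(3, "CA", "B", "ALA", "A", 1, 9.0, 9.0, 9.0),
    fmt(4, "C",  " ", "ALA", "A", 1, 1.2, 0.6, -1.0),
    fmt(5, "CB", " ", "ALA", "A", 1, 0.4, 1.2, 1.2),
    fmt(6, "N",  " ", "GLY", "A", 2, 2.4, 0.4, -0.5),
    fmt(7, "CA", " ", "GLY", "A", 2, 3.8, 0.0, 0.0),
    fmt(8, "N",  " ", "SER", "B", 1, 19.0, 0.8, 0.0),
    fmt(9, "CA", " ", "SER", "B", 1, 20.0, 0.0, 0.0),
    fmt(10, "OG", " ", "SER", "B", 1, 20.5, 1.0, 1.0),
    fmt(11, "O",  " ", "HOH", "A", 90, 30.0, 30.0, 30.0),
    "END")
  writeLines(lines, path)
  path
}

expect_bond_window <- function(chain) {
  ca <- chain$ca
  n <- nrow(ca)
  d <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
  expect_true(all(d >= 3.3 & d <= 4.3))
}
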