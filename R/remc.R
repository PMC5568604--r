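# Replica-exchange Monte Carlo docking: initial scattering of peptide
# copies, the local move set, Metropolis acceptance, replica exchange, and
# the driver that produces the snapshot pool.  The production inner loop
# runs in compiled code (src/remc_kernel.cpp); the R-level operations here
# define the reference semantics and are what the tests exercise.

#' Simulation configuration
#'
#' @param n_replicas Number of Monte Carlo copies run at different
#'   temperatures (default 10).
#' @param t_min,t_max Bounds of the geometric temperature ladder, reduced
#'   units (k_B = 1).
#' @param n_cycles Number of simulation cycles; one cycle attempts one move
#'   per mobile residue (all peptide residues plus all receptor residues).
#'   The default (2000) gives adequate equilibration on toy systems while a
#'   full run stays in the tens of seconds.
#' @param snapshots_per_replica Snapshots collected per replica at evenly
#'   spaced cycles; with the defaults the pool holds
#'   `n_replicas * snapshots_per_replica = 10000` models.
#' @param exchange_period Cycles between replica-exchange attempts
#'   (adjacent ladder pairs, alternating odd/even pairing).
#' @param max_scatter_distance Upper bound (Angstrom) on the distance from
#'   the receptor surface at which peptide copies are initially placed.
#' @param seed Master seed; every stream of randomness in a run derives
#'   from it.
#' @param move_weights Named numeric vector of proposal weights for the six
#'   move types `translate`, `rotate`, `kink`, `crankshaft`, `endflip`,
#'   `receptor`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_replicas = 10, t_min = 1.0, t_max = 2.0,
                       n_cycles = 2000, snapshots_per_replica = 1000,
                       exchange_period = 50, max_scatter_distance = 20,
                       seed = 1,
                       move_weights = c(translate = 0.10, rotate = 0.10,
                                        kink = 0.35, crankshaft = 0.20,
                                        endflip = 0.10, receptor = 0.15)) {
  stopifnot(n_replicas >= 2, t_min > 0, t_max >= t_min, n_cycles >= 0,
            snapshots_per_replica >= 1, exchange_period >= 1,
            max_scatter_distance > 0)
  mw <- move_weights[c("translate", "rotate", "kink", "crankshaft",
                       "endflip", "receptor")]
  stopifnot(!anyNA(mw), all(mw >= 0), sum(mw) > 0)
  structure(list(n_replicas = as.integer(n_replicas), t_min = t_min,
                 t_max = t_max, n_cycles = as.integer(n_cycles),
                 snapshots_per_replica = as.integer(snapshots_per_replica),
                 exchange_period = as.integer(exchange_period),
                 max_scatter_distance = max_scatter_distance,
                 seed = as.integer(seed), move_weights = mw / sum(mw)),
            class = "sim_config")
}

#' Geometric temperature ladder
#'
#' @param t_min,t_max Ladder bounds (reduced units).
#' @param n Number of replicas.
#' @return Numeric vector of `n` temperatures, geometrically spaced.
#' @export
temperature_ladder <- function(t_min, t_max, n) {
  stopifnot(t_min > 0, t_max >= t_min, n >= 1)
  if (n == 1) return(t_min)
  exp(seq(log(t_min), log(t_max), length.out = n))
}

#' Replica state
#'
#' One Monte Carlo copy: its configuration, its current temperature, its
#' stable identity, and its current rung on the temperature ladder.
#' Exchanges swap temperatures (and ladder rungs) between states; the
#' replica id stays with the configuration.
#'
#' @param model A [complex_model()].
#' @param temperature Current temperature, reduced units (> 0).
#' @param replica_id Stable integer identity of the copy.
#' @param ladder_index Current rung (1 = coldest); defaults to `replica_id`.
#' @param energy Current sampling energy of the configuration (used by
#'   [attempt_exchange()]).
#' @return An object of class `replica_state`.
#' @export
replica_state <- function(model, temperature, replica_id,
                          ladder_index = replica_id, energy = NULL) {
  stopifnot(temperature > 0)
  structure(list(model = model, temperature = temperature,
                 replica_id = as.integer(replica_id),
                 ladder_index = as.integer(ladder_index), energy = energy),
            class = "replica_state")
}

#' Metropolis acceptance rule
#'
#' Accepts a proposed move with probability `min(1, exp(-delta_e /
#' temperature))`, where `delta_e` is the change in sampling energy (the
#' scoring energy plus the contact-restraint term).
#'
#' @param delta_e Energy change of the proposal (reduced units).
#' @param temperature Temperature of the replica (> 0).
#' @return `TRUE` (accept) or `FALSE` (reject).
#' @export
metropolis_accept <- function(delta_e, temperature) {
  stopifnot(is.finite(delta_e), temperature > 0)
  if (delta_e <= 0) return(TRUE)
  runif(1) < exp(-delta_e / temperature)
}

#' Attempt a replica exchange between adjacent ladder rungs
#'
#' Swaps the temperatures of two replicas with probability
#' `min(1, exp((1/Ta - 1/Tb) * (Ea - Eb)))` computed on sampling energies;
#' on success the two states trade temperatures and ladder rungs while
#' keeping their configurations and ids.
#'
#' @param a,b [replica_state()] objects adjacent on the ladder, with their
#'   `energy` fields set.
#' @return A list with `accepted` (logical) and the possibly updated states
#'   `a` and `b`.
#' @export
attempt_exchange <- function(a, b) {
  stopifnot(inherits(a, "replica_state"), inherits(b, "replica_state"))
  if (abs(a$ladder_index - b$ladder_index) != 1)
    stop("replica exchange requires ladder-adjacent states")
  if (is.null(a$energy) || is.null(b$energy))
    stop("replica states need their sampling energies for exchange")
  delta <- (1 / a$temperature - 1 / b$temperature) * (a$energy - b$energy)
  accepted <- delta >= 0 || runif(1) < exp(delta)
  if (accepted) {
    tmp_t <- a$temperature; tmp_l <- a$ladder_index
    a$temperature <- b$temperature; a$ladder_index <- b$ladder_index
    b$temperature <- tmp_t; b$ladder_index <- tmp_l
  }
  list(accepted = accepted, a = a, b = b)
}

# integer lattice displacement vectors whose length (in Angstrom) lies in
# the allowed Calpha-Calpha bond window [3.3, 4.3]
allowed_bond_vectors <- function(spacing) {
  key <- sprintf("bond_%.6f", spacing)
  if (!is.null(.cgdock_env[[key]])) return(.cgdock_env[[key]])
  kmax <- ceiling(4.3 / spacing)
  g <- as.matrix(expand.grid(-kmax:kmax, -kmax:kmax, -kmax:kmax))
  len <- sqrt(rowSums(g^2)) * spacing
  v <- g[len >= 3.3 & len <= 4.3, , drop = FALSE]
  .cgdock_env[[key]] <- v
  v
}

# self-avoiding Calpha walk of n residues; on-lattice when enabled, bond
# length near 3.8 A, non-adjacent residues kept >= 4.0 A apart
random_peptide_walk <- function(n, lattice = lattice_config()) {
  stopifnot(n >= 1)
  for (attempt in 1:200) {
    ca <- matrix(0, n, 3)
    ok <- TRUE
    for (i in 2:n) {
      placed <- FALSE
      for (try in 1:60) {
        step <- if (lattice$enabled) {
          v <- allowed_bond_vectors(lattice$spacing)
          v[sample.int(nrow(v), 1), ] * lattice$spacing
        } else {
          unitv(rnorm(3)) * 3.8
        }
        cand <- ca[i - 1, ] + step
        if (i > 2) {
          d <- sqrt(colSums((t(ca[1:(i - 2), , drop = FALSE]) - cand)^2))
          if (min(d) < 4.0) next
        }
        ca[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
      if (n == 1) break
    }
    if (ok) return(ca)
  }
  stop("failed to generate a self-avoiding peptide walk")
}

# minimum pseudoatom-pseudoatom distance between two cg chains; with the
# pseudoatoms standing in for the molecular surface this is the
# peptide-to-receptor surface distance used by the scatter bound
min_chain_distance <- function(a, b) {
  min(cross_dist(chain_pseudoatoms(a)$xyz, chain_pseudoatoms(b)$xyz))
}

#' Scatter a peptide copy around the receptor
#'
#' Draws a random self-avoiding peptide conformation (Calpha bond length
#' 3.8 Angstrom, lattice-snapped when enabled) and places it at a random
#' position and orientation such that its minimum pseudoatom distance to the
#' receptor surface is at most `max_dist` and it does not clash with the
#' receptor (zero excluded-volume energy).
#'
#' @param receptor Receptor [cg_chain()].
#' @param spec [peptide_spec()] giving the sequence.
#' @param max_dist Maximum allowed distance from the receptor surface
#'   (Angstrom, default 20).
#' @param lattice A [lattice_config()].
#' @param params [dock_params()] (for the clash radius).
#' @param max_retries Placement attempts before giving up.
#' @return A peptide [cg_chain()] (chain id `"P"`).
#' @export
scatter_peptide <- function(receptor, spec, max_dist = 20,
                            lattice = lattice_config(),
                            params = dock_params(), max_retries = 300) {
  stopifnot(inherits(receptor, "cg_chain"), inherits(spec, "peptide_spec"),
            max_dist > 0)
  n <- nchar(spec$sequence)
  rname <- aa_three_letter(strsplit(spec$sequence, "")[[1]])
  ratoms <- chain_pseudoatoms(receptor)$xyz
  for (try in seq_len(max_retries)) {
    walk <- random_peptide_walk(n, lattice_config(enabled = FALSE))
    walk <- walk %*% rotation_matrix(unitv(rnorm(3)), runif(1, 0, 2 * pi))
    anchor <- ratoms[sample.int(nrow(ratoms), 1), ]
    u <- unitv(rnorm(3))
    gap_lo <- params$hard_radius + 1
    gap_hi <- max_dist * 0.9
    if (gap_hi <= gap_lo) { gap_lo <- max_dist * 0.25; gap_hi <- max_dist }
    gap <- runif(1, gap_lo, gap_hi)
    target <- anchor + u * gap
    walk <- sweep(walk, 2, colMeans(walk)) +
      matrix(target, n, 3, byrow = TRUE)
    ca <- snap_trace_with_repair(walk, lattice)
    pep <- cg_chain(ca, rname, chain_id = "P", role = "peptide",
                    lattice = lattice, validate = FALSE)
    dmin <- min_chain_distance(receptor, pep)
    if (dmin > max_dist || dmin < params$hard_radius) next
    if (excluded_volume_energy(complex_model(receptor, pep),
                               params$hard_radius, 1) > 0) next
    bonds <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
    if (any(bonds < 3.3 | bonds > 4.3)) next
    return(pep)
  }
  stop("could not place the peptide within ", max_dist,
       " A of the receptor without clashes; try a larger max_dist")
}

# rebuild a peptide chain from a new Calpha trace (derived atoms follow)
with_new_trace <- function(chain, ca) {
  cg_chain(ca, chain$residue_name, chain_id = chain$chain_id,
           role = chain$role, residue_index = chain$residue_index,
           lattice = chain$lattice, validate = FALSE)
}

# move one receptor residue rigidly (its cb/sc ride along)
shift_receptor_residue <- function(chain, i, delta) {
  chain$ca[i, ] <- chain$ca[i, ] + delta
  chain$cb[i, ] <- chain$cb[i, ] + delta
  chain$sc[i, ] <- chain$sc[i, ] + delta
  n <- nrow(chain$ca)
  if (i > 1) chain$bond_centers[i - 1, ] <- (chain$ca[i - 1, ] + chain$ca[i, ]) / 2
  if (i < n) chain$bond_centers[i, ] <- (chain$ca[i, ] + chain$ca[i + 1, ]) / 2
  chain
}

bonds_ok <- function(ca, idx = seq_len(nrow(ca) - 1)) {
  if (nrow(ca) < 2 || !length(idx)) return(TRUE)
  d <- sqrt(rowSums((ca[idx + 1, , drop = FALSE] - ca[idx, , drop = FALSE])^2))
  all(d >= 3.3 & d <= 4.3)
}

#' Propose one Monte Carlo move
#'
#' Draws a move type according to the configured weights and returns the
#' candidate configuration: peptide rigid translation or rotation, a
#' single-residue kink, a two-residue crankshaft, an end flip, or a
#' single-residue receptor perturbation.  Candidates respect the lattice
#' when it is enabled; candidates that would break the Calpha bond-length
#' window are returned as null moves (identical to the current state) and
#' left for the energy model to arbitrate among valid ones.
#'
#' @param state A [replica_state()].
#' @param weights Move-type weights (see [sim_config()]).
#' @param amplitudes Named list of move amplitudes: `translate` and `kink`
#'   in lattice cells (or Angstrom sd off-lattice), `rotate` and
#'   `crankshaft` in radians, `receptor` in lattice cells.
#' @return A candidate [complex_model()] with attributes `move_type` and
#'   `moved` (list with `chain` and the targeted residue positions).
#' @export
propose_move <- function(state,
                         weights = sim_config()$move_weights,
                         amplitudes = list(translate = 2, rotate = 0.45,
                                           kink = 2, crankshaft = 1.05,
                                           receptor = 1)) {
  stopifnot(inherits(state, "replica_state"))
  model <- state$model
  pep <- model$peptide
  rec <- model$receptor
  lat <- pep$lattice
  np <- nrow(pep$ca)
  type <- sample(names(weights), 1, prob = weights)
  moved <- NULL
  if (type == "translate") {
    delta <- if (lat$enabled) {
      round(runif(3, -amplitudes$translate, amplitudes$translate)) * lat$spacing
    } else rnorm(3, 0, 0.5)
    ca <- sweep(pep$ca, 2, -delta)
    pep <- with_new_trace(pep, ca)
    moved <- list(chain = "peptide", residues = seq_len(np))
  } else if (type == "rotate") {
    ang <- runif(1, -amplitudes$rotate, amplitudes$rotate)
    R <- rotation_matrix(unitv(rnorm(3)), ang)
    ctr <- colMeans(pep$ca)
    ca <- sweep(sweep(pep$ca, 2, ctr) %*% R, 2, -ctr)
    ca <- snap_to_lattice(ca, lat)
    if (bonds_ok(ca)) pep <- with_new_trace(pep, ca)
    moved <- list(chain = "peptide", residues = seq_len(np))
  } else if (type == "kink" && np >= 3) {
    i <- sample(2:(np - 1), 1)
    delta <- if (lat$enabled) {
      round(runif(3, -amplitudes$kink, amplitudes$kink)) * lat$spacing
    } else rnorm(3, 0, 0.5)
    ca <- pep$ca
    ca[i, ] <- ca[i, ] + delta
    if (bonds_ok(ca, c(i - 1, i))) pep <- with_new_trace(pep, ca)
    moved <- list(chain = "peptide", residues = i)
  } else if (type == "crankshaft" && np >= 4) {
    i <- sample(2:(np - 2), 1)
    axis <- pep$ca[i + 2, ] - pep$ca[i - 1, ]
    if (vnorm(axis) > 1e-6) {
      R <- rotation_matrix(axis, runif(1, -amplitudes$crankshaft,
                                       amplitudes$crankshaft))
      ca <- pep$ca
      for (j in c(i, i + 1)) {
        ca[j, ] <- as.vector((ca[j, ] - ca[i - 1, ]) %*% R) + ca[i - 1, ]
      }
      ca[c(i, i + 1), ] <- snap_to_lattice(ca[c(i, i + 1), , drop = FALSE], lat)
      if (bonds_ok(ca, c(i - 1, i, i + 1))) pep <- with_new_trace(pep, ca)
    }
    moved <- list(chain = "peptide", residues = c(i, i + 1))
  } else if (type == "endflip" || np < 3) {
    i <- if (runif(1) < 0.5) 1L else np
    nb <- if (i == 1L) 2L else np - 1L
    step <- if (lat$enabled) {
      v <- allowed_bond_vectors(lat$spacing)
      v[sample.int(nrow(v), 1), ] * lat$spacing
    } else unitv(rnorm(3)) * 3.8
    ca <- pep$ca
    ca[i, ] <- ca[nb, ] + step
    pep <- with_new_trace(pep, ca)
    moved <- list(chain = "peptide", residues = i)
  } else {  # receptor perturbation
    j <- sample.int(nrow(rec$ca), 1)
    delta <- if (lat$enabled) {
      round(runif(3, -amplitudes$receptor, amplitudes$receptor)) * lat$spacing
    } else rnorm(3, 0, 0.3)
    ca <- rec$ca
    ca[j, ] <- ca[j, ] + delta
    idx <- intersect(c(j - 1, j), seq_len(nrow(ca) - 1))
    if (bonds_ok(ca, idx)) rec <- shift_receptor_residue(rec, j, delta)
    moved <- list(chain = "receptor", residues = j)
  }
  out <- complex_model(rec, pep)
  attr(out, "move_type") <- type
  attr(out, "moved") <- moved
  out
}
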