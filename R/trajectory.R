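# The run driver and the trajectory container: run_remc() scatters one
# peptide copy per replica, hands the system to the compiled REMC kernel,
# and wraps the snapshot pool as a cg_trajectory.

# derived-atom lengths for a peptide sequence, matching derive_pseudoatoms
pep_derived_lengths <- function(seq1) {
  n <- length(seq1)
  cb_len <- rep(1.53, n)
  sc_len <- unname(SC_LENGTH[seq1])
  sc_len[is.na(sc_len)] <- 2.3
  gly <- seq1 == "G"
  cb_len[gly] <- 1.0
  sc_len[gly] <- 1.0
  term_gly <- gly & (seq_len(n) %in% c(1L, n))
  cb_len[term_gly] <- 0
  sc_len[term_gly] <- 0
  ala <- seq1 == "A"
  sc_len[ala] <- 1.53
  list(cb = cb_len, sc = sc_len)
}

#' Run the replica-exchange Monte Carlo docking simulation
#'
#' Scatters one random-conformation peptide copy per replica around the
#' receptor, runs `n_cycles` of Metropolis Monte Carlo per replica on the
#' sampling energy (scoring energy plus any side-chain contact restraints)
#' with periodic adjacent-pair temperature exchanges, and collects
#' `snapshots_per_replica` evenly spaced snapshots per replica: with the
#' defaults, a pool of 10 x 1000 = 10,000 models.  The receptor is flexible
#' but held near its input conformation by flat-bottom distance restraints
#' built once from the native Calpha-Calpha distances.  The full run is
#' reproducible from `config$seed`.
#'
#' @param receptor Receptor [cg_chain()].
#' @param spec [peptide_spec()].
#' @param restraints Optional `dock_contacts` table from [parse_contacts()];
#'   `NULL` runs default-mode docking.
#' @param config A [sim_config()].
#' @param params A [dock_params()].
#' @return A `cg_trajectory`: snapshot coordinate arrays plus a `meta` data
#'   frame (one row per model) with replica id, cycle, temperature and the
#'   full energy breakdown; `scoring_energy` excludes the contact-restraint
#'   term, `sampling_energy` includes it.
#' @export
run_remc <- function(receptor, spec, restraints = NULL,
                     config = sim_config(), params = dock_params()) {
  stopifnot(inherits(receptor, "cg_chain"), inherits(spec, "peptide_spec"),
            inherits(config, "sim_config"), inherits(params, "dock_params"))
  lattice <- receptor$lattice
  n_rep <- config$n_replicas
  seq1 <- strsplit(spec$sequence, "")[[1]]
  np <- length(seq1)

  set.seed(config$seed)
  child <- sample.int(.Machine$integer.max - 1, 2 * n_rep + 2)
  peps <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(child[r])
    peps[[r]] <- scatter_peptide(receptor, spec,
                                 max_dist = config$max_scatter_distance,
                                 lattice = lattice, params = params)
  }
  kernel_seeds <- child[(n_rep + 1):(2 * n_rep + 2)]

  native <- native_ca_restraints(receptor)
  temps <- temperature_ladder(config$t_min, config$t_max, n_rep)
  lens <- pep_derived_lengths(seq1)
  rec_aa <- match(aa_one_letter(receptor$residue_name), AA1)
  rec_aa[is.na(rec_aa)] <- 0L
  pep_aa <- match(seq1, AA1)
  pep_aa[is.na(pep_aa)] <- 0L
  ss_int <- integer(0)
  if (!is.null(spec$ss_pref))
    ss_int <- match(strsplit(spec$ss_pref, "")[[1]], c("C", "H", "E")) - 1L

  if (is.null(restraints) || !nrow(restraints)) {
    restr_ij <- matrix(integer(0), 0, 2)
    restr_D0 <- numeric(0); restr_s <- numeric(0)
  } else {
    restr_ij <- cbind(restraints$rec_pos - 1L, restraints$pep_index - 1L)
    restr_D0 <- restraints$D0; restr_s <- restraints$s
  }
  native_ij <- if (nrow(native)) cbind(native$i - 1L, native$j - 1L)
               else matrix(integer(0), 0, 2)

  res <- .remc_kernel(
    receptor$ca, receptor$cb, receptor$sc,
    lapply(peps, `[[`, "ca"),
    as.integer(rec_aa - 1L), as.integer(pep_aa - 1L),
    params$contact_matrix, lens$cb, lens$sc,
    matrix(as.integer(native_ij), ncol = 2), native$d,
    matrix(as.integer(restr_ij), ncol = 2), restr_D0, restr_s,
    as.integer(ss_int), temps,
    list(hard_radius = params$hard_radius, ev_penalty = params$ev_penalty,
         box_radius = max(sqrt(rowSums(sweep(receptor$ca, 2,
                                             colMeans(receptor$ca))^2))) +
           config$max_scatter_distance + 5,
         r_on = params$r_on, ss_weight = params$ss_weight,
         rr_tolerance = params$rr_tolerance, rr_weight = params$rr_weight,
         spacing = lattice$spacing, lattice = lattice$enabled,
         n_cycles = config$n_cycles,
         n_snap = config$snapshots_per_replica,
         exch_period = config$exchange_period,
         move_weights = unname(config$move_weights),
         seeds = as.integer(kernel_seeds)))

  m <- res$meta
  scoring <- m[, 4] + m[, 5] + m[, 6] + m[, 7]
  meta <- data.frame(model_id = seq_len(nrow(m)), replica_id = as.integer(m[, 1]),
                     cycle = as.integer(m[, 2]), temperature = m[, 3],
                     excluded_volume = m[, 4], pair_contact = m[, 5],
                     ss_bias = m[, 6], receptor_restraint = m[, 7],
                     contact_restraint = m[, 8],
                     scoring_energy = scoring,
                     sampling_energy = scoring + m[, 8])
  structure(list(rec_ca = res$rec_ca, pep_ca = res$pep_ca, meta = meta,
                 receptor = receptor,
                 rec_cb_off = receptor$cb - receptor$ca,
                 rec_sc_off = receptor$sc - receptor$ca,
                 spec = spec, restraints = restraints, native = native,
                 params = params, config = config, lattice = lattice,
                 stats = list(
                   move_acceptance = res$moves_accepted / max(1, res$moves_attempted),
                   exchange_acceptance = res$exchanges_accepted /
                     max(1, res$exchanges_attempted))),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("cg_trajectory: %d snapshots (%d replicas x %d), %d cycles\n",
              nrow(x$meta), x$config$n_replicas,
              x$config$snapshots_per_replica, x$config$n_cycles))
  cat(sprintf("  scoring energy: min %.2f, median %.2f\n",
              min(x$meta$scoring_energy), stats::median(x$meta$scoring_energy)))
  cat(sprintf("  move acceptance %.2f, exchange acceptance %.2f\n",
              x$stats$move_acceptance, x$stats$exchange_acceptance))
  invisible(x)
}

#' @export
length.cg_trajectory <- function(x) nrow(x$meta)

#' Materialise one snapshot of a trajectory as a complex model
#'
#' Rebuilds the full pseudoatom representation of snapshot `i`: receptor
#' Cbeta/SC ride on their fixed offsets from the (moving) Calpha trace,
#' peptide Cbeta/SC are re-derived from the trace, and the stored energy
#' breakdown is attached.
#'
#' @param traj A `cg_trajectory` from [run_remc()].
#' @param i Model id (1-based snapshot index).
#' @return A [complex_model()].
#' @export
get_model <- function(traj, i) {
  stopifnot(inherits(traj, "cg_trajectory"), i >= 1, i <= nrow(traj$meta))
  rca <- traj$rec_ca[, , i]
  rec <- cg_chain(rca, traj$receptor$residue_name,
                  cb = rca + traj$rec_cb_off, sc = rca + traj$rec_sc_off,
                  chain_id = traj$receptor$chain_id, role = "receptor",
                  residue_index = traj$receptor$residue_index,
                  lattice = traj$lattice, validate = FALSE)
  seq1 <- strsplit(traj$spec$sequence, "")[[1]]
  pep <- cg_chain(traj$pep_ca[, , i], aa_three_letter(seq1), chain_id = "P",
                  role = "peptide", lattice = traj$lattice, validate = FALSE)
  row <- traj$meta[i, ]
  eb <- energy_breakdown(row$excluded_volume, row$pair_contact, row$ss_bias,
                         row$receptor_restraint, row$contact_restraint)
  complex_model(rec, pep, energy = eb,
                meta = list(model_id = row$model_id,
                            replica_id = row$replica_id, cycle = row$cycle,
                            temperature = row$temperature))
}

#' Write the trajectory sidecar table
#'
#' One row per model: id, replica, cycle, temperature and the energy terms.
#'
#' @param traj A `cg_trajectory`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path) {
  stopifnot(inherits(traj, "cg_trajectory"))
  write.table(traj$meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
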