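# Energy model: surrogate statistical terms (excluded volume, SC-SC pair
# contacts, secondary-structure bias), flat-bottom receptor restraints that
# keep the receptor near-native, and the soft one-sided linear side-chain
# contact restraint that drives contact-driven docking.  The contact
# restraint biases sampling only: the scoring energy used for model ranking
# excludes it.

#' Energy-model parameters
#'
#' Bundles the tunable parameters of the surrogate force field.  All
#' energies are in dimensionless reduced units (k_B = 1); distances in
#' Angstroms.
#'
#' @param hard_radius Excluded-volume hard-core radius between pseudoatoms.
#' @param ev_penalty Penalty added per clashing pseudoatom pair.
#' @param r_on Distance cutoff below which two side-chain centers are in
#'   contact for the pairwise statistical term.
#' @param ss_weight Per-residue penalty for violating the peptide
#'   secondary-structure preference.
#' @param rr_tolerance,rr_weight Flat-bottom width (Angstrom) and weight of
#'   the receptor near-native distance restraints.
#' @param contact_matrix 20 x 20 symmetric residue-pair energy matrix with
#'   one-letter dimnames; `NULL` loads the packaged hydropathy-product
#'   surrogate matrix.
#' @return An object of class `dock_params`.
#' @export
dock_params <- function(hard_radius = 3.0, ev_penalty = 5.0, r_on = 6.0,
                        ss_weight = 1.0, rr_tolerance = 1.0, rr_weight = 1.0,
                        contact_matrix = NULL) {
  if (is.null(contact_matrix)) contact_matrix <- default_contact_matrix()
  contact_matrix <- as.matrix(contact_matrix)
  stopifnot(hard_radius > 0, ev_penalty >= 0, r_on > 0,
            nrow(contact_matrix) == 20, ncol(contact_matrix) == 20,
            isTRUE(all.equal(contact_matrix, t(contact_matrix))))
  if (is.null(dimnames(contact_matrix)))
    dimnames(contact_matrix) <- list(AA1, AA1)
  structure(list(hard_radius = hard_radius, ev_penalty = ev_penalty,
                 r_on = r_on, ss_weight = ss_weight,
                 rr_tolerance = rr_tolerance, rr_weight = rr_weight,
                 contact_matrix = contact_matrix),
            class = "dock_params")
}

.cgdock_env <- new.env(parent = emptyenv())

#' Default residue-pair contact matrix
#'
#' The packaged surrogate statistical potential: a 20 x 20 symmetric matrix
#' built from the product of Kyte-Doolittle hydropathies,
#' `e_ij = -0.15 h_i h_j`, so hydrophobic-hydrophobic side-chain contacts
#' are favourable and hydrophobic-polar contacts are penalised.  Any
#' symmetric 20 x 20 matrix (e.g. a statistical contact potential) can be
#' swapped in via [dock_params()].
#'
#' @return A 20 x 20 numeric matrix with one-letter amino-acid dimnames.
#' @export
default_contact_matrix <- function() {
  if (!is.null(.cgdock_env$cmat)) return(.cgdock_env$cmat)
  path <- system.file("extdata", "contact_matrix.tsv", package = "cgdock")
  m <- as.matrix(read.table(path, header = TRUE, row.names = 1,
                            check.names = FALSE))
  colnames(m) <- rownames(m)
  .cgdock_env$cmat <- m
  m
}

#' Soft one-sided contact restraint potential
#'
#' The attractive potential imposed on a restrained side-chain pair: zero for
#' any distance `D` up to the threshold `D0`, then growing linearly with
#' slope `s`.  It pulls the peptide toward the binding site during sampling
#' without rewarding over-tight contacts, and it never enters the scoring
#' energy.
#'
#' @param D Observed side-chain pseudoatom distance(s), Angstrom (vectorised).
#' @param D0 Threshold distance below which the potential vanishes
#'   (default 5.0 Angstrom, the protocol value).
#' @param s Slope in reduced energy units per Angstrom (default 1.0).
#' @return Restraint energy, same length as `D`; non-negative, continuous
#'   and non-decreasing in `D`.
#' @examples
#' contact_restraint_energy(c(4, 5, 7.5))  # 0 0 2.5
#' @export
contact_restraint_energy <- function(D, D0 = 5.0, s = 1.0) {
  stopifnot(is.numeric(D), D0 > 0, s >= 0)
  if (any(!is.finite(D)) || any(D < 0))
    stop("restrained distance D must be finite and non-negative")
  ifelse(D <= D0, 0, s * (D - D0))
}

#' Build the receptor near-native restraint map
#'
#' Records, once, the native Calpha-Calpha distances of all receptor residue
#' pairs with sequence separation of at least `min_sep` and native distance
#' up to `max_dist`; during docking these distances are held by flat-bottom
#' restraints so the receptor stays near its input conformation while
#' remaining flexible.
#'
#' @param receptor The input receptor [cg_chain()].
#' @param max_dist Native distance cutoff (Angstrom).
#' @param min_sep Minimum sequence separation of restrained pairs.
#' @return A data frame with columns `i`, `j` (chain positions) and `d`
#'   (native distance).
#' @export
native_ca_restraints <- function(receptor, max_dist = 8.0, min_sep = 3L) {
  stopifnot(inherits(receptor, "cg_chain"))
  ca <- receptor$ca
  n <- nrow(ca)
  dm <- cross_dist(ca, ca)
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  sel <- (idx[, 2] - idx[, 1]) >= min_sep & dm[idx] <= max_dist
  data.frame(i = idx[sel, 1], j = idx[sel, 2], d = dm[idx][sel])
}

#' Receptor near-native restraint energy
#'
#' Flat-bottom penalty `weight * max(0, |d - d_native| - tolerance)` summed
#' over the restrained Calpha pairs; exactly zero for the unperturbed
#' receptor.
#'
#' @param model A [complex_model()].
#' @param native Restraint map from [native_ca_restraints()].
#' @param tolerance Flat-bottom half-width, Angstrom.
#' @param weight Energy per Angstrom of violation.
#' @return Restraint energy (reduced units).
#' @export
receptor_restraint_energy <- function(model, native, tolerance = 1.0,
                                      weight = 1.0) {
  stopifnot(inherits(model, "complex_model"), is.data.frame(native))
  ca <- model$receptor$ca
  if (nrow(native) == 0) return(0)
  if (max(native$i, native$j) > nrow(ca))
    stop("restrained receptor pair absent from model")
  d <- sqrt(rowSums((ca[native$i, , drop = FALSE] -
                     ca[native$j, , drop = FALSE])^2))
  sum(weight * pmax(0, abs(d - native$d) - tolerance))
}

# stack all pseudoatoms of a chain with residue bookkeeping
chain_pseudoatoms <- function(chain) {
  n <- nrow(chain$ca)
  list(xyz = rbind(chain$ca, chain$cb, chain$sc),
       res = rep(seq_len(n), 3))
}

#' Excluded-volume energy
#'
#' A fixed penalty per pseudoatom pair closer than the hard-core radius,
#' counting pairs across chains and pairs within a chain separated by at
#' least two residues.
#'
#' @param model A [complex_model()].
#' @param hard_radius Hard-core radius, Angstrom.
#' @param penalty Energy per clashing pair.
#' @return Non-negative clash energy.
#' @export
excluded_volume_energy <- function(model, hard_radius = 3.0, penalty = 5.0) {
  stopifnot(inherits(model, "complex_model"), hard_radius > 0)
  r <- chain_pseudoatoms(model$receptor)
  p <- chain_pseudoatoms(model$peptide)
  count_intra <- function(a) {
    d <- cross_dist(a$xyz, a$xyz)
    sep <- abs(outer(a$res, a$res, "-"))
    sum(d < hard_radius & sep >= 2 & upper.tri(d))
  }
  ncl <- count_intra(r) + count_intra(p) +
    sum(cross_dist(r$xyz, p$xyz) < hard_radius)
  penalty * ncl
}

#' Pairwise side-chain contact energy
#'
#' Sums the residue-type pair energies of the contact matrix over all SC-SC
#' pseudoatom pairs within `r_on`, across chains and within chains at
#' sequence separation of at least two.  Residue types outside the standard
#' twenty are scored with the matrix column means (with a message).
#'
#' @param model A [complex_model()].
#' @param contact_matrix Symmetric 20 x 20 matrix, one-letter dimnames.
#' @param r_on Contact cutoff, Angstrom.
#' @return Contact energy (reduced units).
#' @export
pair_contact_energy <- function(model, contact_matrix = default_contact_matrix(),
                                r_on = 6.0) {
  stopifnot(inherits(model, "complex_model"), r_on > 0)
  cm <- as.matrix(contact_matrix)
  stopifnot(isTRUE(all.equal(cm, t(cm), tolerance = 1e-8)))
  row_for <- function(chain) {
    a1 <- aa_one_letter(chain$residue_name)
    idx <- match(a1, rownames(cm))
    if (anyNA(idx)) message("unknown residue type(s) scored as matrix average")
    idx
  }
  avg <- colMeans(cm)
  epair <- function(t1, t2) {
    if (is.na(t1) && is.na(t2)) return(mean(avg))
    if (is.na(t1)) return(avg[t2])
    if (is.na(t2)) return(avg[t1])
    cm[t1, t2]
  }
  ir <- row_for(model$receptor); ip <- row_for(model$peptide)
  e <- 0
  dd <- cross_dist(model$receptor$sc, model$peptide$sc)
  hits <- which(dd <= r_on, arr.ind = TRUE)
  if (nrow(hits))
    e <- e + sum(vapply(seq_len(nrow(hits)), function(k)
      epair(ir[hits[k, 1]], ip[hits[k, 2]]), 0))
  intra <- function(chain, it) {
    d <- cross_dist(chain$sc, chain$sc)
    sep <- abs(outer(seq_len(nrow(d)), seq_len(nrow(d)), "-"))
    hits <- which(d <= r_on & sep >= 2 & upper.tri(d), arr.ind = TRUE)
    if (!nrow(hits)) return(0)
    sum(vapply(seq_len(nrow(hits)), function(k)
      epair(it[hits[k, 1]], it[hits[k, 2]]), 0))
  }
  e + intra(model$receptor, ir) + intra(model$peptide, ip)
}

# does the pseudo-angle at residue i match the ss preference letter?
ss_angle_match <- function(angle, pref) {
  switch(pref,
         H = angle >= 80 && angle <= 105,
         E = angle > 105 && angle <= 145,
         C = TRUE,
         TRUE)
}

#' Secondary-structure bias energy for the peptide
#'
#' Penalises peptide residues whose local Calpha geometry does not match the
#' preferred secondary structure: helix residues should have a
#' Calpha(i-1)-Calpha(i)-Calpha(i+1) pseudo-angle in [80, 105] degrees,
#' extended residues in (105, 145]; coil always matches, as do the chain
#' termini (no angle defined).  Returns 0 when no preference is given.
#'
#' @param peptide Peptide [cg_chain()].
#' @param spec The [peptide_spec()] carrying `ss_pref` (or not).
#' @param weight Penalty per mismatching residue.
#' @return Bias energy (reduced units).
#' @export
ss_bias_energy <- function(peptide, spec, weight = 1.0) {
  stopifnot(inherits(peptide, "cg_chain"), inherits(spec, "peptide_spec"))
  if (is.null(spec$ss_pref)) return(0)
  n <- nrow(peptide$ca)
  if (nchar(spec$ss_pref) != n)
    stop("ss_pref length does not match peptide chain length")
  prefs <- strsplit(spec$ss_pref, "")[[1]]
  e <- 0
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      ang <- pseudo_angle(peptide$ca[i - 1, ], peptide$ca[i, ],
                          peptide$ca[i + 1, ])
      if (!ss_angle_match(ang, prefs[i])) e <- e + weight
    }
  }
  e
}

energy_breakdown <- function(ev, pair, ss, rr, cr) {
  scoring <- ev + pair + ss + rr
  structure(list(excluded_volume = ev, pair_contact = pair, ss_bias = ss,
                 receptor_restraint = rr, contact_restraint = cr,
                 scoring_energy = scoring, sampling_energy = scoring + cr),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(paste0("energy breakdown (reduced units):\n",
                     "  excluded volume    %8.3f\n",
                     "  pair contact       %8.3f\n",
                     "  ss bias            %8.3f\n",
                     "  receptor restraint %8.3f\n",
                     "  contact restraint  %8.3f  (sampling only)\n",
                     "  scoring energy     %8.3f\n",
                     "  sampling energy    %8.3f\n"),
              x$excluded_volume, x$pair_contact, x$ss_bias,
              x$receptor_restraint, x$contact_restraint,
              x$scoring_energy, x$sampling_energy))
  invisible(x)
}

#' Total conformational energy of a complex model
#'
#' Evaluates every term and returns the full breakdown.  The side-chain
#' contact restraint (summed over the restraint list on SC-SC pseudoatom
#' distances) is included in the sampling energy that drives Monte Carlo
#' acceptance but excluded from the scoring energy used to rank models.
#'
#' @param model A [complex_model()].
#' @param restraints A `dock_contacts` table from [parse_contacts()] (or
#'   `NULL` for default-mode docking).
#' @param params A [dock_params()].
#' @param native Receptor restraint map from [native_ca_restraints()], or
#'   `NULL` to skip the receptor restraint term.
#' @param spec Optional [peptide_spec()] providing the secondary-structure
#'   preference; without it the bias term is 0.
#' @return An `energy_breakdown` object.
#' @export
total_energy <- function(model, restraints = NULL, params = dock_params(),
                         native = NULL, spec = NULL) {
  stopifnot(inherits(model, "complex_model"))
  ev <- excluded_volume_energy(model, params$hard_radius, params$ev_penalty)
  pair <- pair_contact_energy(model, params$contact_matrix, params$r_on)
  ss <- if (is.null(spec)) 0 else
    ss_bias_energy(model$peptide, spec, params$ss_weight)
  rr <- if (is.null(native)) 0 else
    receptor_restraint_energy(model, native, params$rr_tolerance,
                              params$rr_weight)
  cr <- 0
  if (!is.null(restraints) && nrow(restraints)) {
    D <- sqrt(rowSums((model$receptor$sc[restraints$rec_pos, , drop = FALSE] -
                       model$peptide$sc[restraints$pep_index, , drop = FALSE])^2))
    cr <- sum(mapply(contact_restraint_energy, D, restraints$D0, restraints$s))
  }
  energy_breakdown(ev, pair, ss, rr, cr)
}
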