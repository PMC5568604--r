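# Synthetic test systems: a compact lattice globule with a concave binding
# pocket plus a native peptide pose laid into the pocket, with known native
# contacts.  The pocket lining is hydrophobic and the peptide sequence
# hydrophobic, so the surrogate pair-contact energy produces a genuine
# funnel toward the native pose.  These systems make every stage of the
# docking pipeline testable without external structures.

# secondary-structure letters from a Calpha trace via the pseudo-angle bins
ss_from_trace <- function(ca) {
  n <- nrow(ca)
  out <- rep("C", n)
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      ang <- pseudo_angle(ca[i - 1, ], ca[i, ], ca[i + 1, ])
      if (ang >= 80 && ang <= 105) out[i] <- "H"
      else if (ang > 105 && ang <= 145) out[i] <- "E"
    }
  }
  paste(out, collapse = "")
}

# minimal all-atom rendering (N, CA, C, O, CB) of a cg chain, as the same
# data frame layout read_receptor_pdb() produces; synthetic backbone
# positions, good enough to exercise all-atom readers and contact detection
aa_render <- function(chain) {
  ca <- chain$ca
  n <- nrow(ca)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    dprev <- if (i > 1) unitv(ca[i - 1, ] - ca[i, ]) else unitv(ca[i, ] - ca[i + 1, ])
    dnext <- if (i < n) unitv(ca[i + 1, ] - ca[i, ]) else unitv(ca[i, ] - ca[i - 1, ])
    Npos <- ca[i, ] + 1.46 * dprev
    Cpos <- ca[i, ] + 1.52 * dnext
    Opos <- Cpos + 1.23 * perp_vector(dnext)
    atoms <- rbind(N = Npos, CA = ca[i, ], C = Cpos, O = Opos,
                   CB = chain$cb[i, ])
    rows[[i]] <- data.frame(
      elety = rownames(atoms), resno = chain$residue_index[i],
      resid = chain$residue_name[i],
      reskey = as.character(chain$residue_index[i]),
      chain = chain$chain_id, x = atoms[, 1], y = atoms[, 2], z = atoms[, 3],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# grow a self-avoiding lattice walk for the toy receptor under the
# geometric constraints of the pocket construction; the walk is biased to
# stay compact and to populate the shell lining the pocket cavity
toy_receptor_walk <- function(n, start, R_core, cavity_centers, r_pocket,
                              pep_atoms, lattice) {
  vecs <- allowed_bond_vectors(lattice$spacing) * lattice$spacing
  valid_point <- function(x, ca, i) {
    if (vnorm(x) > R_core) return(FALSE)
    for (k in seq_len(nrow(cavity_centers)))
      if (vnorm(x - cavity_centers[k, ]) < r_pocket) return(FALSE)
    if (min(sqrt(colSums((t(pep_atoms) - x)^2))) < 3.4) return(FALSE)
    if (i > 2) {
      d <- sqrt(colSums((t(ca[1:(i - 2), , drop = FALSE]) - x)^2))
      if (min(d) < 4.5) return(FALSE)
    }
    TRUE
  }
  for (attempt in 1:60) {
    ca <- matrix(0, n, 3)
    ca[1, ] <- start
    ok <- TRUE
    for (i in 2:n) {
      cand <- sweep(vecs[sample.int(nrow(vecs), 80), , drop = FALSE],
                    2, ca[i - 1, ], "+")
      keep <- vapply(seq_len(nrow(cand)),
                     function(k) valid_point(cand[k, ], ca, i), TRUE)
      cand <- cand[keep, , drop = FALSE]
      if (!nrow(cand)) { ok <- FALSE; break }
      dpock <- do.call(pmin, lapply(seq_len(nrow(cavity_centers)), function(k)
        sqrt(rowSums(sweep(cand, 2, cavity_centers[k, ])^2))))
      w <- exp(-2 * sqrt(rowSums(cand^2)) / R_core) *
        (1 + 4 * (dpock <= r_pocket + 3.5))
      ca[i, ] <- cand[sample.int(nrow(cand), 1, prob = w), ]
    }
    if (ok) return(ca)
  }
  stop("failed to grow the toy receptor globule")
}

# place receptor Cbeta/SC pseudoatoms clash-free: pocket-lining residues
# prefer pointing into the cavity, everything else the outward bisector;
# when the preferred direction clashes, fall back to the direction with the
# best clearance among random alternatives.  Adjacent residues (sequence
# separation < 2) are exempt from clearance, matching the excluded-volume
# convention.
orient_side_chains <- function(rec, pep_atoms, targets, hard_radius) {
  n <- nrow(rec$ca)
  lens <- SC_LENGTH[aa_one_letter(rec$residue_name)]
  lens[is.na(lens)] <- 2.3
  for (pass in 1:2) {
    for (i in sample.int(n)) {
      others <- setdiff(seq_len(n), max(1, i - 1):min(n, i + 1))
      obst <- rbind(rec$ca[others, , drop = FALSE],
                    rec$cb[others, , drop = FALSE],
                    rec$sc[others, , drop = FALSE], pep_atoms)
      dirs <- rbind(sidechain_directions(rec$ca)[i, ],
                    t(vapply(1:24, function(k) unitv(rnorm(3)), numeric(3))))
      if (!is.na(targets[i, 1]))
        dirs <- rbind(unitv(targets[i, ] - rec$ca[i, ]), dirs)
      best <- NULL
      for (k in seq_len(nrow(dirs))) {
        cb <- rec$ca[i, ] + 1.53 * dirs[k, ]
        sc <- rec$ca[i, ] + lens[i] * dirs[k, ]
        clr <- min(cross_dist(rbind(cb, sc), obst))
        if (is.null(best) || clr > best$clr)
          best <- list(cb = cb, sc = sc, clr = clr)
        if (clr >= hard_radius + 0.15) {
          best <- list(cb = cb, sc = sc, clr = clr)
          break
        }
      }
      rec$cb[i, ] <- best$cb
      rec$sc[i, ] <- best$sc
    }
  }
  rec
}

#' Build a synthetic receptor-peptide complex with a known native pose
#'
#' Constructs a compact self-avoiding lattice globule with a concave
#' binding pocket (a spherical cavity carved into the surface), lays a
#' hydrophobic peptide through the pocket in a known native pose, assigns a
#' hydrophobic pocket lining and polar surface, and records the native
#' contact list (5 Angstrom pseudoatom cutoff).  Pocket-lining side chains
#' are oriented into the cavity where that does not create clashes.  The
#' construction retries until the native pose is clash-free, has at least
#' one SC-SC contact within 5 Angstrom, and scores lower surrogate
#' pair-contact energy than at least 95 of 100 random surface placements
#' (the funnel guarantee).
#'
#' @param receptor_size Number of receptor residues (>= 20).
#' @param peptide_length Number of peptide residues (>= 3).
#' @param pocket_depth How deep (Angstrom) the cavity cuts into the globule
#'   surface.
#' @param seed Optional seed (`set.seed` is called when given).
#' @param lattice A [lattice_config()].
#' @param params [dock_params()] used for the clash and funnel checks.
#' @return An object of class `toy_complex`: `receptor` and
#'   `native_peptide` ([cg_chain()]s), `native_contacts` (pseudoatom-based,
#'   flagged approximate), `pocket_center`, `peptide` (a [peptide_spec()]
#'   with the native-derived secondary-structure preference), and all-atom
#'   renderings `receptor_aa`, `peptide_aa`.
#' @export
make_toy_complex <- function(receptor_size = 40, peptide_length = 6,
                             pocket_depth = 4.0, seed = NULL,
                             lattice = lattice_config(),
                             params = dock_params()) {
  stopifnot(receptor_size >= 20, peptide_length >= 3)
  if (!is.null(seed)) set.seed(seed)
  R_core <- max(3.4 * receptor_size^(1 / 3), 11.0)
  r_pocket <- 5.0
  pocket_center <- c(0, 0, R_core + r_pocket - pocket_depth)
  # a second, unoccupied concavity on the opposite face: a hydrophobic decoy
  # binding site, so the docking landscape is ambiguous the way real
  # receptor surfaces are
  decoy_center <- c(0, 0, -(R_core + r_pocket - pocket_depth))
  cavities <- rbind(pocket_center, decoy_center)

  hydroph <- c("LEU", "PHE", "ILE", "VAL", "MET")
  polar <- c("SER", "THR", "ASN", "GLN", "GLU", "LYS", "ASP", "ARG")

  for (attempt in 1:40) {
    # native peptide: gentle zigzag through the pocket mouth so alternating
    # side chains point down into the cavity
    phi <- runif(1, 0, pi)
    u <- c(cos(phi), sin(phi), 0)
    z0 <- pocket_center[3] - 2.6
    idx <- seq_len(peptide_length) - (peptide_length + 1) / 2
    pep_ca <- t(vapply(seq_along(idx), function(i)
      idx[i] * 3.75 * u + c(0, 0, z0 + 0.35 * (-1)^i), numeric(3)))
    pep_ca <- snap_trace_with_repair(pep_ca, lattice)
    pep_seq <- sample(c("L", "F", "I", "V"), peptide_length, replace = TRUE)
    pep <- cg_chain(pep_ca, aa_three_letter(pep_seq), chain_id = "P",
                    role = "peptide", lattice = lattice, validate = FALSE)

    pep_atoms <- chain_pseudoatoms(pep)$xyz
    start <- snap_to_lattice(pocket_center - c(0, 0, r_pocket + 3.2), lattice)
    rec_ca <- tryCatch(
      toy_receptor_walk(receptor_size, start, R_core, cavities,
                        r_pocket, pep_atoms, lattice),
      error = function(e) NULL)
    if (is.null(rec_ca)) next

    near_pocket <- sqrt(rowSums(sweep(rec_ca, 2, pocket_center)^2)) <=
      r_pocket + 3.5
    near_decoy <- sqrt(rowSums(sweep(rec_ca, 2, decoy_center)^2)) <=
      r_pocket + 3.5
    # both cavity linings are hydrophobic; the remaining surface is polar
    rname <- ifelse(near_pocket | near_decoy,
                    sample(hydroph, receptor_size, replace = TRUE),
                    sample(polar, receptor_size, replace = TRUE))
    rec <- cg_chain(rec_ca, rname, chain_id = "A", role = "receptor",
                    lattice = lattice, validate = FALSE)
    targets <- matrix(NA_real_, receptor_size, 3)
    if (any(near_pocket))
      targets[near_pocket, ] <- matrix(pocket_center, sum(near_pocket), 3,
                                       byrow = TRUE)
    if (any(near_decoy))
      targets[near_decoy, ] <- matrix(decoy_center, sum(near_decoy), 3,
                                      byrow = TRUE)
    rec <- orient_side_chains(rec, pep_atoms, targets, params$hard_radius)

    model <- complex_model(rec, pep)
    if (excluded_volume_energy(model, params$hard_radius, 1) > 0) next
    contacts <- native_contacts(rec, pep, cutoff = 5.0)
    if (!nrow(contacts)) next
    if (min(cross_dist(rec$sc, pep$sc)) > 5.0) next

    # funnel guarantee: native pair-contact energy beats random placements
    e_native <- pair_contact_energy(model, params$contact_matrix, params$r_on)
    spec <- peptide_spec(paste(pep_seq, collapse = ""), ss_from_trace(pep$ca))
    e_rand <- vapply(1:100, function(k) {
      p <- tryCatch(scatter_peptide(rec, spec, max_dist = 20,
                                    lattice = lattice, params = params),
                    error = function(e) NULL)
      if (is.null(p)) return(Inf)
      pair_contact_energy(complex_model(rec, p), params$contact_matrix,
                          params$r_on)
    }, 0)
    if (sum(e_native < e_rand) < 95) next

    return(structure(list(receptor = rec, native_peptide = pep,
                          native_contacts = contacts,
                          pocket_center = pocket_center,
                          peptide = spec,
                          receptor_aa = aa_render(rec),
                          peptide_aa = aa_render(pep),
                          pair_energy_native = e_native),
                     class = "toy_complex"))
  }
  stop("failed to construct a toy complex satisfying all invariants")
}

#' @export
print.toy_complex <- function(x, ...) {
  cat(sprintf("toy_complex: receptor %d res, peptide %s, %d native contacts\n",
              nrow(x$receptor$ca), x$peptide$sequence,
              nrow(x$native_contacts)))
  cat(sprintf("  pocket center (%.1f, %.1f, %.1f), native pair energy %.2f\n",
              x$pocket_center[1], x$pocket_center[2], x$pocket_center[3],
              x$pair_energy_native))
  invisible(x)
}

#' Generate labelled decoy poses at prescribed ligand-RMSD targets
#'
#' Perturbs the native peptide pose rigidly (rotation jitter plus a
#' translation whose magnitude is tuned by bisection) so that each decoy's
#' ligand RMSD to the native pose lands within 15 percent of its target.
#' Targets are recycled over `n` decoys.  Decoys carry labels for use as
#' clustering and tier-minimum oracles; they are not guaranteed clash-free.
#'
#' @param toy A [make_toy_complex()] result.
#' @param n Number of decoys (>= number of targets).
#' @param rmsd_targets Target ligand RMSDs in Angstrom (0 reproduces the
#'   native pose).
#' @return List with `models` (list of [complex_model()]) and `labels`
#'   (data frame: target, achieved, ok).
#' @export
make_decoy_set <- function(toy, n, rmsd_targets) {
  stopifnot(inherits(toy, "toy_complex"), n >= length(rmsd_targets),
            all(rmsd_targets >= 0))
  targets <- rep_len(rmsd_targets, n)
  native <- complex_model(toy$receptor, toy$native_peptide)
  models <- vector("list", n)
  labels <- data.frame(target = targets, achieved = NA_real_, ok = FALSE)
  base_dir <- lapply(unique(targets), function(t) unitv(rnorm(3)))
  names(base_dir) <- as.character(unique(targets))
  for (i in seq_len(n)) {
    t <- targets[i]
    if (t == 0) {
      models[[i]] <- native
      labels$achieved[i] <- 0
      labels$ok[i] <- TRUE
      next
    }
    ca0 <- toy$native_peptide$ca
    ctr <- colMeans(ca0)
    R <- rotation_matrix(unitv(rnorm(3)), min(0.06 * t, 0.5))
    # decoys sharing a target form a tight bundle: common displacement
    # direction with a small per-decoy jitter
    dirv <- unitv(base_dir[[as.character(t)]] + 0.12 * rnorm(3))
    pose_at <- function(m) {
      ca <- sweep(sweep(ca0, 2, ctr) %*% R, 2, -ctr)
      sweep(ca, 2, -m * dirv)
    }
    rmsd_at <- function(m) {
      pep <- with_new_trace(toy$native_peptide, pose_at(m))
      ligand_rmsd(complex_model(toy$receptor, pep), native)
    }
    lo <- 0; hi <- t + 5
    while (rmsd_at(hi) < t && hi < 10 * (t + 5)) hi <- hi * 2
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      if (rmsd_at(mid) < t) lo <- mid else hi <- mid
    }
    m <- (lo + hi) / 2
    ach <- rmsd_at(m)
    models[[i]] <- complex_model(toy$receptor,
                                 with_new_trace(toy$native_peptide,
                                                pose_at(m)))
    labels$achieved[i] <- ach
    labels$ok[i] <- abs(ach - t) <= 0.15 * t
  }
  list(models = models, labels = labels)
}

#' Write a toy complex to disk as plain-text fixtures
#'
#' Emits the minimal all-atom rendering as `receptor.pdb` and
#' `peptide.pdb`, the native coarse-grained pose as `native_cg.pdb`, and a
#' JSON sidecar with the native contacts and pocket center.  All files are
#' synthetic constructions.
#'
#' @param toy A [make_toy_complex()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_toy_fixture <- function(toy, dir) {
  stopifnot(inherits(toy, "toy_complex"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_aa_pdb <- function(df, path) {
    lines <- vapply(seq_len(nrow(df)), function(i)
      pdb_atom_line(i, df$elety[i], df$resid[i], df$chain[i], df$resno[i],
                    c(df$x[i], df$y[i], df$z[i])), "")
    writeLines(c(lines, "TER", "END"), path)
  }
  write_aa_pdb(toy$receptor_aa, file.path(dir, "receptor.pdb"))
  write_aa_pdb(toy$peptide_aa, file.path(dir, "peptide.pdb"))
  write_models_pdb(list(complex_model(toy$receptor, toy$native_peptide)),
                   file.path(dir, "native_cg.pdb"))
  sidecar <- list(
    sequence = toy$peptide$sequence, ss_pref = toy$peptide$ss_pref,
    pocket_center = toy$pocket_center,
    native_contacts = toy$native_contacts[, c("chain", "resid", "pep_index")])
  jsonlite::write_json(sidecar, file.path(dir, "toy.json"),
                       auto_unbox = TRUE, digits = 10, dataframe = "rows")
  invisible(dir)
}
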