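# Model selection: reduce the snapshot pool to ten ranked models.
# Energy filter (scoring energy, restraint excluded) -> k-medoid clustering
# on ligand RMSD -> cluster-density ranking; plus the evaluation metrics
# (native contacts, nested minimum-RMSD report).

#' Select the lowest-scoring-energy models from a trajectory
#'
#' Picks the `n` models with the lowest scoring energy (the contact
#' restraint never enters this energy); ties are broken deterministically
#' by cycle, then replica id.
#'
#' @param traj A `cg_trajectory`.
#' @param n Number of models to keep (default 1000); clamped to pool size.
#' @return An object of class `model_set`: the trajectory plus the selected
#'   `model_id`s in ascending-energy order.  Use `[[` to materialise a
#'   member as a [complex_model()].
#' @export
top_by_energy <- function(traj, n = 1000) {
  stopifnot(inherits(traj, "cg_trajectory"), n >= 1)
  if (!nrow(traj$meta)) stop("empty trajectory")
  ord <- order(traj$meta$scoring_energy, traj$meta$cycle,
               traj$meta$replica_id)
  ids <- traj$meta$model_id[ord][seq_len(min(n, nrow(traj$meta)))]
  structure(list(trajectory = traj, ids = ids), class = "model_set")
}

#' @export
length.model_set <- function(x) length(x$ids)

#' @export
`[[.model_set` <- function(x, i) get_model(x$trajectory, x$ids[[i]])

#' @export
print.model_set <- function(x, ...) {
  e <- x$trajectory$meta$scoring_energy[x$ids]
  cat(sprintf("model_set: %d models, scoring energy [%.2f, %.2f]\n",
              length(x$ids), min(e), max(e)))
  invisible(x)
}

#' Ligand RMSD between two complex models
#'
#' Kabsch-superposes the receptor Calpha trace of `a` onto that of `b`,
#' applies the same transform to the peptide of `a`, and returns the
#' peptide Calpha RMSD.  This is the model-similarity measure used for
#' clustering and for accuracy evaluation; it is symmetric and zero exactly
#' when the peptides coincide after receptor superposition.
#'
#' @param a,b [complex_model()] objects with equally sized chains.
#' @return RMSD in Angstroms.
#' @export
ligand_rmsd <- function(a, b) {
  stopifnot(inherits(a, "complex_model"), inherits(b, "complex_model"))
  if (nrow(a$receptor$ca) != nrow(b$receptor$ca) ||
      nrow(a$peptide$ca) != nrow(b$peptide$ca))
    stop("models must have matching receptor and peptide sizes")
  fit <- kabsch(a$receptor$ca, b$receptor$ca)
  pep <- a$peptide$ca %*% fit$R +
    matrix(fit$t, nrow(a$peptide$ca), 3, byrow = TRUE)
  coord_rmsd(pep, b$peptide$ca)
}

# coordinate cubes (n x 3 x m) for a model_set or list of complex models
model_coord_cubes <- function(models) {
  if (inherits(models, "model_set")) {
    ids <- models$ids
    traj <- models$trajectory
    list(rec = traj$rec_ca[, , ids, drop = FALSE],
         pep = traj$pep_ca[, , ids, drop = FALSE])
  } else {
    stopifnot(is.list(models), length(models) >= 1)
    nr <- nrow(models[[1]]$receptor$ca)
    np <- nrow(models[[1]]$peptide$ca)
    rec <- array(0, c(nr, 3, length(models)))
    pep <- array(0, c(np, 3, length(models)))
    for (i in seq_along(models)) {
      rec[, , i] <- models[[i]]$receptor$ca
      pep[, , i] <- models[[i]]$peptide$ca
    }
    list(rec = rec, pep = pep)
  }
}

#' Pairwise ligand-RMSD matrix
#'
#' @param models A `model_set` (from [top_by_energy()]) or a list of
#'   [complex_model()] objects.
#' @return A symmetric matrix of ligand RMSDs (Angstrom).
#' @export
ligand_rmsd_matrix <- function(models) {
  cubes <- model_coord_cubes(models)
  .ligand_rmsd_matrix(cubes$rec, cubes$pep)
}

#' k-medoid clustering on a precomputed distance matrix
#'
#' PAM: alternation (assign every point to its nearest medoid, then replace
#' each medoid by the member minimising the within-cluster distance sum,
#' until stable or `max_iter` rounds) followed by greedy swap refinement
#' (best medoid/non-medoid swap while the total cost decreases).  Run from
#' `n_init` k-medoids++-style seeded starts; the lowest total cost wins.
#' Uses R's RNG (set a seed for reproducibility).
#'
#' @param d Symmetric n x n distance matrix.
#' @param k Number of clusters (2 <= k <= n).
#' @param n_init Number of seeded restarts.
#' @param max_iter Maximum alternation rounds per restart.
#' @return List with `medoids` (indices into 1..n), `assignment` (length-n
#'   cluster labels 1..k) and `cost` (total distance to assigned medoids).
#' @export
k_medoids <- function(d, k, n_init = 5, max_iter = 300) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(n >= 1, k >= 1, ncol(d) == n)
  if (k > n) stop("k must not exceed the number of models")
  # tiny instances: exhaustive search over medoid sets is cheaper than
  # restarts and exactly optimal
  if (choose(n, k) <= 300) {
    best <- NULL
    for (med in utils::combn(n, k, simplify = FALSE)) {
      asg <- max.col(-d[, med, drop = FALSE], ties.method = "first")
      cost <- sum(d[cbind(seq_len(n), med[asg])])
      if (is.null(best) || cost < best$cost)
        best <- list(medoids = med, assignment = asg, cost = cost)
    }
    return(best)
  }
  best <- NULL
  for (rep in seq_len(n_init)) {
    med <- integer(k)
    med[1] <- sample.int(n, 1)
    for (j in seq_len(k - 1)) {
      dmin <- do.call(pmin, lapply(med[seq_len(j)], function(m) d[, m]))
      if (sum(dmin) <= 0) {
        pool <- setdiff(seq_len(n), med[seq_len(j)])
        med[j + 1] <- pool[sample.int(length(pool), 1)]
      } else {
        med[j + 1] <- sample.int(n, 1, prob = dmin / sum(dmin))
      }
    }
    for (iter in seq_len(max_iter)) {
      asg <- max.col(-d[, med, drop = FALSE], ties.method = "first")
      new_med <- med
      for (c in seq_len(k)) {
        members <- which(asg == c)
        if (!length(members)) { new_med[c] <- med[c]; next }
        cost <- colSums(d[members, members, drop = FALSE])
        new_med[c] <- members[which.min(cost)]
      }
      if (all(sort(new_med) == sort(med))) { med <- new_med; break }
      med <- new_med
    }
    med <- .pam_refine(d, as.integer(med))
    asg <- max.col(-d[, med, drop = FALSE], ties.method = "first")
    cost <- sum(d[cbind(seq_len(n), med[asg])])
    if (is.null(best) || cost < best$cost)
      best <- list(medoids = med, assignment = asg, cost = cost)
  }
  best
}

#' Cluster density
#'
#' Number of cluster members divided by their average pairwise dissimilarity
#' (mean over all unordered member pairs).  Singletons and zero-spread
#' clusters get `size / 1e-3` and are flagged via the `"degenerate"`
#' attribute.
#'
#' @param dsub Distance submatrix of the cluster members.
#' @return Density (members per Angstrom), with attribute `degenerate`.
#' @export
cluster_density <- function(dsub) {
  dsub <- as.matrix(dsub)
  n <- nrow(dsub)
  stopifnot(n >= 1)
  if (n == 1) return(structure(n / 1e-3, degenerate = TRUE))
  spread <- mean(dsub[upper.tri(dsub)])
  if (spread <= 0) return(structure(n / 1e-3, degenerate = TRUE))
  structure(n / spread, degenerate = FALSE)
}

#' Cluster an energy-filtered model set and rank the medoids
#'
#' Computes the pairwise ligand-RMSD matrix, clusters with [k_medoids()]
#' (k = 10 by default), measures each cluster's density, and ranks the
#' medoids by density (descending).  The medoids are the final predictions;
#' rank 1 is the densest cluster's medoid.
#'
#' @param models A `model_set` (typically the 1000 top-scored models).
#' @param k Number of clusters / final models.
#' @param density Either `"pairwise"` (mean over all member pairs, the
#'   default) or `"medoid"` (mean distance to the medoid).
#' @param n_init,max_iter Passed to [k_medoids()].
#' @return A `cluster_report`: list with `clusters` (members, medoid,
#'   density, degenerate flag per cluster, in rank order), `ranking` (data
#'   frame with rank, medoid model id, cluster size, density, medoid
#'   scoring energy) and the clustering `cost`.
#' @export
cluster_models <- function(models, k = 10, density = c("pairwise", "medoid"),
                           n_init = 5, max_iter = 300) {
  density <- match.arg(density)
  stopifnot(inherits(models, "model_set"))
  n <- length(models$ids)
  if (k > n) stop("k exceeds the number of models to cluster")
  d <- ligand_rmsd_matrix(models)
  km <- k_medoids(d, k, n_init = n_init, max_iter = max_iter)
  meta <- models$trajectory$meta
  info <- lapply(seq_len(k), function(c) {
    members <- which(km$assignment == c)
    dens <- if (density == "pairwise") {
      cluster_density(d[members, members, drop = FALSE])
    } else {
      md <- mean(d[members, km$medoids[c]])
      if (length(members) == 1 || md <= 0)
        structure(length(members) / 1e-3, degenerate = TRUE)
      else structure(length(members) / md, degenerate = FALSE)
    }
    list(member_ids = models$ids[members],
         medoid_id = models$ids[km$medoids[c]],
         size = length(members), density = as.numeric(dens),
         degenerate = isTRUE(attr(dens, "degenerate")))
  })
  report <- structure(list(clusters = info, cost = km$cost,
                           trajectory = models$trajectory),
                      class = "cluster_report")
  rank_models(report)
}

#' Rank clustered models by density
#'
#' Orders the cluster medoids by density (descending); ties are broken by
#' cluster size (larger first) and then by the medoid's scoring energy
#' (lower first).
#'
#' @param report A `cluster_report` from [cluster_models()].
#' @return The report with its `clusters` reordered and a `ranking` data
#'   frame (rank, medoid_model_id, cluster_size, density, degenerate,
#'   energy).
#' @export
rank_models <- function(report) {
  stopifnot(inherits(report, "cluster_report"))
  meta <- report$trajectory$meta
  dens <- vapply(report$clusters, `[[`, 0, "density")
  size <- vapply(report$clusters, `[[`, 0, "size")
  med <- vapply(report$clusters, `[[`, 0, "medoid_id")
  energy <- meta$scoring_energy[match(med, meta$model_id)]
  ord <- order(-dens, -size, energy)
  report$clusters <- report$clusters[ord]
  report$ranking <- data.frame(rank = seq_along(ord),
                               medoid_model_id = as.integer(med[ord]),
                               cluster_size = size[ord],
                               density = dens[ord],
                               degenerate = vapply(report$clusters, `[[`,
                                                   TRUE, "degenerate"),
                               energy = energy[ord])
  report
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("cluster_report: ranked medoids\n")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}

# heavy-atom (or pseudoatom) coordinates per residue of one chain
residue_atom_list <- function(chain) {
  if (inherits(chain, "cg_chain")) {
    lapply(seq_len(nrow(chain$ca)), function(i)
      rbind(chain$ca[i, ], chain$cb[i, ], chain$sc[i, ]))
  } else {
    stopifnot(is.data.frame(chain))
    lapply(unique(chain$reskey), function(kk) {
      at <- chain[chain$reskey == kk, ]
      cbind(at$x, at$y, at$z)
    })
  }
}

#' Native receptor-peptide contacts
#'
#' Lists every receptor-peptide residue pair with any heavy-atom distance
#' within the cutoff (5 Angstrom by default).  For all-atom inputs the test
#' uses all heavy atoms; for coarse-grained chains it falls back to the
#' pseudoatoms and flags the result as approximate.
#'
#' @param receptor A chain data frame from [read_receptor_pdb()] or a
#'   receptor [cg_chain()].
#' @param peptide A peptide chain in the same representation.
#' @param cutoff Contact distance cutoff, Angstrom.
#' @return A data frame (class `dock_contacts`) with columns `chain`,
#'   `resid`, `pep_index`, `rec_pos`, `min_dist`, `D0`, `s`; attribute
#'   `approximate` is `TRUE` for pseudoatom-based detection.
#' @export
native_contacts <- function(receptor, peptide, cutoff = 5.0) {
  stopifnot(cutoff > 0)
  ratoms <- residue_atom_list(receptor)
  patoms <- residue_atom_list(peptide)
  if (inherits(receptor, "cg_chain")) {
    chain <- rep(receptor$chain_id, length(ratoms))
    resid <- receptor$residue_index
  } else {
    chain <- vapply(unique(receptor$reskey), function(kk)
      receptor$chain[receptor$reskey == kk][1], "")
    resid <- vapply(unique(receptor$reskey), function(kk)
      receptor$resno[receptor$reskey == kk][1], 0L)
  }
  rows <- list()
  for (i in seq_along(ratoms)) {
    for (j in seq_along(patoms)) {
      dmin <- min(cross_dist(ratoms[[i]], patoms[[j]]))
      if (dmin <= cutoff)
        rows[[length(rows) + 1]] <-
          data.frame(chain = chain[i], resid = resid[i], pep_index = j,
                     rec_pos = i, min_dist = dmin, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(chain = character(), resid = integer(),
                         pep_index = integer(), rec_pos = integer(),
                         min_dist = numeric())
  out$D0 <- rep(5.0, nrow(out))
  out$s <- rep(1.0, nrow(out))
  class(out) <- c("dock_contacts", "data.frame")
  attr(out, "approximate") <- inherits(receptor, "cg_chain")
  out
}

#' Draw one contact uniformly at random
#'
#' Emulates contact-driven docking with minimal prior knowledge: a single
#' native contact chosen at random drives the simulation.
#'
#' @param contacts A `dock_contacts` table (non-empty).
#' @return A one-row `dock_contacts` table.
#' @export
select_random_contact <- function(contacts) {
  stopifnot(is.data.frame(contacts))
  if (!nrow(contacts)) stop("contact list is empty")
  contacts[sample.int(nrow(contacts), 1), , drop = FALSE]
}

#' Nested minimum-RMSD accuracy report
#'
#' The accuracy of a docking run against a known reference pose, reported as
#' the lowest ligand RMSD within each stage of the selection funnel: the
#' whole pool, the energy-filtered set, the top 100 by scoring energy, and
#' the final ranked models.  Because the sets are nested, the four minima
#' are monotonically non-decreasing.
#'
#' @param traj A `cg_trajectory`.
#' @param filtered A `model_set` (the energy-filtered models).
#' @param ranked_ids Model ids of the final ranked medoids.
#' @param reference A [complex_model()] holding the reference (native) pose,
#'   or `NULL`, in which case `NULL` is returned (evaluation skipped).
#' @param n_top Size of the intermediate energy tier (default 100).
#' @return A list with `rmsd_pool`, `rmsd_filtered`, `rmsd_top`,
#'   `rmsd_ranked` (Angstrom), or `NULL` without a reference.
#' @export
rmsd_report <- function(traj, filtered, ranked_ids, reference, n_top = 100) {
  if (is.null(reference)) return(NULL)
  stopifnot(inherits(traj, "cg_trajectory"), inherits(filtered, "model_set"),
            inherits(reference, "complex_model"))
  all_r <- .ligand_rmsd_to_ref(traj$rec_ca, traj$pep_ca,
                               reference$receptor$ca, reference$peptide$ca)
  top_ids <- filtered$ids[seq_len(min(n_top, length(filtered$ids)))]
  list(rmsd_pool = min(all_r),
       rmsd_filtered = min(all_r[filtered$ids]),
       rmsd_top = min(all_r[top_ids]),
       rmsd_ranked = min(all_r[ranked_ids]))
}
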