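# Coarse-grained chain representation: one residue = Calpha (on a cubic
# lattice), Cbeta, a single side-chain interaction center (SC), and a
# peptide-bond pseudoatom at the midpoint of each consecutive Calpha pair.

#' Lattice configuration for the Calpha trace
#'
#' Calpha positions are restricted to a cubic lattice; the other pseudoatoms
#' live off-lattice.  The spacing is not dictated by the docking protocol
#' itself; the default of 0.61 Angstrom follows the convention of the CABS
#' model family.  Disabling the lattice turns every snapping operation into a
#' pass-through, which is convenient for continuous-space tests.
#'
#' @param spacing Lattice constant in Angstroms; must be positive.
#' @param enabled If `FALSE`, coordinates are left untouched by
#'   [snap_to_lattice()].
#' @return An object of class `lattice_config`.
#' @export
lattice_config <- function(spacing = 0.61, enabled = TRUE) {
  stopifnot(is.numeric(spacing), length(spacing) == 1, spacing > 0,
            is.logical(enabled), length(enabled) == 1)
  structure(list(spacing = spacing, enabled = enabled),
            class = "lattice_config")
}

#' Snap coordinates to the cubic lattice
#'
#' Rounds each coordinate to the nearest integer multiple of the lattice
#' spacing, independently per axis, so no point moves by more than half a
#' spacing along any axis.  Snapping is idempotent.  With the lattice
#' disabled the input is returned unchanged.
#'
#' @param coords An n x 3 numeric matrix (or length-3 vector) of coordinates
#'   in Angstroms.
#' @param lattice A [lattice_config()].
#' @return Coordinates of the same shape, lattice-snapped.
#' @examples
#' snap_to_lattice(c(1, 1, 1), lattice_config(0.61))  # (1.22, 1.22, 1.22)
#' @export
snap_to_lattice <- function(coords, lattice = lattice_config()) {
  stopifnot(inherits(lattice, "lattice_config"))
  vec <- is.null(dim(coords))
  m <- if (vec) matrix(coords, ncol = 3) else as.matrix(coords)
  if (!all(is.finite(m))) stop("non-finite coordinate passed to snap_to_lattice")
  if (!lattice$enabled) return(if (vec) as.vector(coords) else m)
  out <- round(m / lattice$spacing) * lattice$spacing
  if (vec) as.vector(out) else out
}

# Outward side-chain directions from a Calpha trace: the negated bisector of
# the two bond vectors at interior residues, the backbone continuation at the
# termini, and a deterministic perpendicular where the trace is locally
# straight.  Returns an n x 3 matrix of unit vectors.
sidechain_directions <- function(ca) {
  n <- nrow(ca)
  dir <- matrix(0, n, 3)
  if (n == 1) {
    dir[1, ] <- c(0, 0, 1)
    return(dir)
  }
  for (i in seq_len(n)) {
    if (i == 1) {
      dir[i, ] <- unitv(ca[1, ] - ca[2, ])
    } else if (i == n) {
      dir[i, ] <- unitv(ca[n, ] - ca[n - 1, ])
    } else {
      u1 <- unitv(ca[i - 1, ] - ca[i, ])
      u2 <- unitv(ca[i + 1, ] - ca[i, ])
      v <- u1 + u2
      if (vnorm(v) < 1e-6) {
        dir[i, ] <- perp_vector(u1)
      } else {
        dir[i, ] <- -unitv(v)
      }
    }
  }
  dir
}

# Place Cbeta and SC pseudoatoms from the Calpha trace and sequence alone
# (used for peptides built from sequence and for toy receptors).  Glycine:
# cb == sc at 1 A along the outward direction, collapsing onto Calpha at the
# termini; alanine: sc == cb.
derive_pseudoatoms <- function(ca, seq1) {
  n <- nrow(ca)
  stopifnot(length(seq1) == n)
  dir <- sidechain_directions(ca)
  cb <- ca + 1.53 * dir
  len <- SC_LENGTH[seq1]
  len[is.na(len)] <- 2.3
  sc <- ca + dir * len
  gly <- seq1 == "G"
  if (any(gly)) {
    gd <- ca[gly, , drop = FALSE] + 1.0 * dir[gly, , drop = FALSE]
    cb[gly, ] <- gd
    sc[gly, ] <- gd
    term <- gly & (seq_len(n) %in% c(1L, n))
    if (any(term)) {
      cb[term, ] <- ca[term, , drop = FALSE]
      sc[term, ] <- ca[term, , drop = FALSE]
    }
  }
  ala <- seq1 == "A"
  if (any(ala)) sc[ala, ] <- cb[ala, , drop = FALSE]
  list(cb = cb, sc = sc)
}

#' Construct a coarse-grained chain
#'
#' Bundles per-residue pseudoatom coordinates into a `cg_chain`.  Bond
#' centers (the peptide-bond pseudoatoms) are always recomputed as midpoints
#' of consecutive Calpha pairs.  When `cb`/`sc` are omitted they are derived
#' from the Calpha trace and the sequence via the outward-bisector rule.
#'
#' @param ca n x 3 matrix of Calpha coordinates (Angstrom).
#' @param residue_name Character vector of three-letter residue codes.
#' @param cb,sc Optional n x 3 matrices of Cbeta / side-chain-center
#'   coordinates; derived from the trace when `NULL`.
#' @param chain_id Single character chain identifier.
#' @param role `"receptor"` or `"peptide"`.
#' @param residue_index Integer residue numbering (defaults to 1..n); kept as
#'   author numbering so restraint definitions can refer to PDB residue ids.
#' @param lattice The [lattice_config()] the Calpha trace conforms to
#'   (metadata; the constructor does not snap).
#' @param validate Check Calpha bond lengths against the 3.3-4.3 Angstrom
#'   window (warning on violation).
#' @return An object of class `cg_chain` with elements `ca`, `cb`, `sc`,
#'   `bond_centers`, `residue_name`, `residue_index`, `chain_id`, `role`,
#'   `lattice`.
#' @export
cg_chain <- function(ca, residue_name, cb = NULL, sc = NULL,
                     chain_id = "A", role = c("receptor", "peptide"),
                     residue_index = NULL, lattice = lattice_config(),
                     validate = TRUE) {
  role <- match.arg(role)
  ca <- as.matrix(ca)
  stopifnot(ncol(ca) == 3, nrow(ca) >= 1, all(is.finite(ca)))
  n <- nrow(ca)
  stopifnot(length(residue_name) == n)
  residue_name <- toupper(residue_name)
  if (is.null(residue_index)) residue_index <- seq_len(n)
  stopifnot(length(residue_index) == n)
  if (is.null(cb) || is.null(sc)) {
    der <- derive_pseudoatoms(ca, aa_one_letter(residue_name))
    if (is.null(cb)) cb <- der$cb
    if (is.null(sc)) sc <- der$sc
  }
  cb <- as.matrix(cb); sc <- as.matrix(sc)
  stopifnot(nrow(cb) == n, nrow(sc) == n)
  bc <- if (n > 1) (ca[-n, , drop = FALSE] + ca[-1, , drop = FALSE]) / 2
        else matrix(numeric(0), 0, 3)
  obj <- structure(list(ca = ca, cb = cb, sc = sc, bond_centers = bc,
                        residue_name = residue_name,
                        residue_index = as.integer(residue_index),
                        chain_id = chain_id, role = role, lattice = lattice),
                   class = "cg_chain")
  if (validate && n > 1) {
    d <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
    bad <- d < 3.3 | d > 4.3
    if (any(bad))
      warning(sprintf("%d Calpha-Calpha bond(s) outside [3.3, 4.3] A", sum(bad)))
  }
  obj
}

#' @export
print.cg_chain <- function(x, ...) {
  cat(sprintf("cg_chain (%s): %d residues, chain %s, lattice %s (%.2f A)\n",
              x$role, nrow(x$ca), x$chain_id,
              if (x$lattice$enabled) "on" else "off", x$lattice$spacing))
  cat(" sequence:", paste(aa_one_letter(x$residue_name), collapse = ""), "\n")
  invisible(x)
}

#' @export
length.cg_chain <- function(x) nrow(x$ca)

# one-letter sequence of a cg_chain
cg_sequence <- function(chain) paste(aa_one_letter(chain$residue_name),
                                     collapse = "")

#' Extract one residue of a coarse-grained chain
#'
#' @param chain A `cg_chain`.
#' @param i Position (1-based) along the chain.
#' @return A list with `residue_index`, `residue_name`, `ca`, `cb`, `sc`,
#'   `chain_id`.
#' @export
cg_residue <- function(chain, i) {
  stopifnot(inherits(chain, "cg_chain"), i >= 1, i <= nrow(chain$ca))
  list(residue_index = chain$residue_index[i],
       residue_name = chain$residue_name[i],
       ca = chain$ca[i, ], cb = chain$cb[i, ], sc = chain$sc[i, ],
       chain_id = chain$chain_id)
}

# Snap a Calpha trace to the lattice and repair bonds pushed outside the
# 3.3-4.3 A window by rounding: violating residues are moved to the nearby
# lattice point (within one cell) that restores both flanking bonds while
# staying closest to the original position.
snap_trace_with_repair <- function(ca, lattice) {
  snapped <- snap_to_lattice(ca, lattice)
  if (!lattice$enabled || nrow(ca) < 2) return(snapped)
  sp <- lattice$spacing
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) * sp
  bond_ok <- function(p, q) {
    d <- vnorm(p - q)
    d >= 3.3 && d <= 4.3
  }
  n <- nrow(snapped)
  for (pass in 1:2) {
    d <- sqrt(rowSums((snapped[-1, , drop = FALSE] -
                       snapped[-n, , drop = FALSE])^2))
    bad <- which(d < 3.3 | d > 4.3)
    if (!length(bad)) break
    for (b in bad) {
      for (i in c(b + 1L, b)) {  # try moving either end of the bond
        cand <- sweep(offs, 2, snapped[i, ], "+")
        disp <- sqrt(rowSums(sweep(cand, 2, ca[i, ])^2))
        ord <- order(disp)
        fixed <- FALSE
        for (j in ord) {
          p <- cand[j, ]
          ok <- TRUE
          if (i > 1) ok <- ok && bond_ok(p, snapped[i - 1, ])
          if (i < n) ok <- ok && bond_ok(p, snapped[i + 1, ])
          if (ok) { snapped[i, ] <- p; fixed <- TRUE; break }
        }
        if (fixed) break
      }
    }
  }
  snapped
}

#' Convert an all-atom chain to the coarse-grained representation
#'
#' Reduces each residue to Calpha, Cbeta and a side-chain interaction center
#' (SC, the centroid of the side-chain heavy atoms beyond Cbeta), adds the
#' peptide-bond pseudoatom at each Calpha-Calpha midpoint, and snaps the
#' Calpha trace to the cubic lattice.  When a residue's only side-chain heavy
#' atom is Cbeta (alanine), SC coincides with Cbeta; glycine uses the
#' outward-bisector fallback.  Cbeta and SC ride along with the snap
#' displacement of their Calpha so intra-residue geometry is preserved.
#'
#' @param atomic_chain One chain as returned by [read_receptor_pdb()]: a
#'   data frame of heavy atoms with columns `elety`, `resno`, `resid`,
#'   `reskey`, `x`, `y`, `z`, `chain`.
#' @param lattice A [lattice_config()].
#' @param role Chain role, `"receptor"` by default.
#' @return A [cg_chain()].  Residues separated by a Calpha-Calpha gap above
#'   4.5 Angstrom (pre-snapping) trigger a warning and set the attribute
#'   `chain_breaks` to the positions of the offending bonds.
#' @export
coarse_grain <- function(atomic_chain, lattice = lattice_config(),
                         role = "receptor") {
  stopifnot(is.data.frame(atomic_chain), nrow(atomic_chain) > 0)
  keys <- unique(atomic_chain$reskey)
  n <- length(keys)
  ca <- matrix(NA_real_, n, 3)
  cb <- matrix(NA_real_, n, 3)
  sc <- matrix(NA_real_, n, 3)
  rname <- character(n)
  rindex <- integer(n)
  for (i in seq_len(n)) {
    at <- atomic_chain[atomic_chain$reskey == keys[i], , drop = FALSE]
    rname[i] <- at$resid[1]
    rindex[i] <- at$resno[1]
    ica <- match("CA", at$elety)
    if (is.na(ica))
      stop(sprintf("residue %s %s (chain %s) has no CA atom",
                   at$resid[1], keys[i], at$chain[1]))
    ca[i, ] <- c(at$x[ica], at$y[ica], at$z[ica])
    icb <- match("CB", at$elety)
    if (!is.na(icb)) cb[i, ] <- c(at$x[icb], at$y[icb], at$z[icb])
    side <- !(at$elety %in% c("N", "CA", "C", "O", "OXT", "CB"))
    if (any(side)) {
      sc[i, ] <- c(mean(at$x[side]), mean(at$y[side]), mean(at$z[side]))
    } else if (!is.na(icb)) {
      sc[i, ] <- cb[i, ]  # Ala-like: only CB beyond the backbone
    }
  }
  # fallbacks for residues without side-chain atoms (Gly or stripped)
  need <- which(is.na(cb[, 1]) | is.na(sc[, 1]))
  if (length(need)) {
    der <- derive_pseudoatoms(ca, aa_one_letter(rname))
    miss_cb <- is.na(cb[, 1]); miss_sc <- is.na(sc[, 1])
    cb[miss_cb, ] <- der$cb[miss_cb, , drop = FALSE]
    sc[miss_sc, ] <- der$sc[miss_sc, , drop = FALSE]
  }
  gap <- numeric(0)
  if (n > 1) {
    d <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
    gap <- which(d > 4.5)
    if (length(gap))
      warning(sprintf("chain break(s) after residue position(s) %s (Ca-Ca > 4.5 A); keeping chain",
                      paste(gap, collapse = ", ")))
  }
  snapped <- snap_trace_with_repair(ca, lattice)
  shift <- snapped - ca
  obj <- cg_chain(snapped, rname, cb = cb + shift, sc = sc + shift,
                  chain_id = atomic_chain$chain[1], role = role,
                  residue_index = rindex, lattice = lattice,
                  validate = !length(gap))
  attr(obj, "chain_breaks") <- gap
  obj
}
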