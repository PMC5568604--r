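# File formats and user-input parsing: PDB in/out (via bio3d), peptide
# sequence / secondary-structure-preference strings, and side-chain contact
# tables.

#' Peptide specification
#'
#' A peptide is given by its one-letter sequence plus, optionally, a
#' per-residue secondary-structure preference string over `H` (helix),
#' `E` (extended) and `C` (coil, no preference).
#'
#' @param sequence One-letter amino-acid string, length >= 3.
#' @param ss_pref Optional preference string of the same length over
#'   `H`/`E`/`C`.
#' @return An object of class `peptide_spec`.
#' @examples
#' peptide_spec("GQLGLF", "CCCCCC")
#' @export
peptide_spec <- function(sequence, ss_pref = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(gsub("\\s", "", sequence))
  if (nchar(sequence) < 3)
    stop("peptide sequence must have at least 3 residues")
  letters1 <- strsplit(sequence, "")[[1]]
  bad <- setdiff(letters1, AA1)
  if (length(bad))
    stop("invalid amino-acid letter(s): ", paste(unique(bad), collapse = ", "))
  if (!is.null(ss_pref)) {
    ss_pref <- toupper(gsub("\\s", "", ss_pref))
    if (nchar(ss_pref) != nchar(sequence))
      stop("ss_pref must have the same length as the sequence")
    ssl <- strsplit(ss_pref, "")[[1]]
    if (!all(ssl %in% c("H", "E", "C")))
      stop("ss_pref may only contain H, E, C")
  }
  structure(list(sequence = sequence, ss_pref = ss_pref),
            class = "peptide_spec")
}

#' @export
print.peptide_spec <- function(x, ...) {
  cat("peptide_spec:", x$sequence, "\n")
  if (!is.null(x$ss_pref)) cat("  ss pref:   ", x$ss_pref, "\n")
  invisible(x)
}

#' Read a receptor structure from a PDB file
#'
#' Parses heavy-atom coordinates with bio3d, keeping the first alternate
#' location of each atom, dropping hydrogens, waters and (by default) all
#' HETATM records.  Insertion codes are appended to the residue key so
#' inserted residues remain distinct.
#'
#' @param path Path to a PDB file (single- or multi-chain).
#' @param chain Optional chain identifier(s) to keep; all chains by default.
#' @param keep_hetatm Residue names (3-letter) of HETATM groups to retain.
#' @return A named list (class `aa_structure`) with one data frame per
#'   chain; columns `elety`, `resno`, `resid`, `reskey`, `chain`, `x`, `y`,
#'   `z`.
#' @export
read_receptor_pdb <- function(path, chain = NULL, keep_hetatm = character()) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e) stop("unparsable PDB file: ", path,
                                           " (", conditionMessage(e), ")"))
  at <- pdb$atom
  keep <- at$type == "ATOM" | (at$type == "HETATM" & at$resid %in% keep_hetatm)
  keep <- keep & !(at$resid %in% c("HOH", "WAT", "DOD"))
  keep <- keep & !(at$elesy %in% "H") & !grepl("^H", at$elety)
  keep <- keep & (is.na(at$alt) | at$alt %in% c("", "A"))
  at <- at[keep, , drop = FALSE]
  if (!nrow(at)) stop("no heavy atoms left after filtering in ", path)
  at$chain[is.na(at$chain)] <- "A"
  if (!is.null(chain)) {
    at <- at[at$chain %in% chain, , drop = FALSE]
    if (!nrow(at)) stop("selected chain(s) ", paste(chain, collapse = ","),
                        " empty or absent in ", path)
  }
  at$insert[is.na(at$insert)] <- ""
  at$reskey <- paste0(at$resno, at$insert)
  # first altloc: drop later duplicates of the same atom in the same residue
  dupkey <- paste(at$chain, at$reskey, at$elety)
  at <- at[!duplicated(dupkey), , drop = FALSE]
  out <- split(
    data.frame(elety = at$elety, resno = at$resno, resid = at$resid,
               reskey = at$reskey, chain = at$chain,
               x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE),
    at$chain)
  structure(out[order(names(out))], class = "aa_structure")
}

#' Pair a receptor and a peptide pose into one complex model
#'
#' @param receptor,peptide [cg_chain()] objects with roles `"receptor"` and
#'   `"peptide"`.
#' @param energy Optional energy breakdown attached to the snapshot.
#' @param meta Optional named list of provenance fields (model id, replica,
#'   cycle, temperature).
#' @return An object of class `complex_model`.
#' @export
complex_model <- function(receptor, peptide, energy = NULL, meta = NULL) {
  stopifnot(inherits(receptor, "cg_chain"), inherits(peptide, "cg_chain"))
  structure(list(receptor = receptor, peptide = peptide,
                 energy = energy, meta = meta),
            class = "complex_model")
}

#' @export
print.complex_model <- function(x, ...) {
  cat(sprintf("complex_model: receptor %d res (chain %s) + peptide %s\n",
              nrow(x$receptor$ca), x$receptor$chain_id,
              cg_sequence(x$peptide)))
  if (!is.null(x$energy))
    cat(sprintf("  scoring energy %.3f (restraint %.3f)\n",
                x$energy$scoring_energy, x$energy$contact_restraint))
  invisible(x)
}

pdb_atom_line <- function(serial, name, resid, chain, resno, xyz) {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", name), resid, chain, resno,
          xyz[1], xyz[2], xyz[3], 1.00, 0.00, "C")
}

cg_chain_pdb_lines <- function(chain, serial0) {
  n <- nrow(chain$ca)
  lines <- character(0)
  serial <- serial0
  for (i in seq_len(n)) {
    for (nm in c("CA", "CB", "SC")) {
      xyz <- switch(nm, CA = chain$ca[i, ], CB = chain$cb[i, ],
                    SC = chain$sc[i, ])
      lines <- c(lines, pdb_atom_line(serial, nm, chain$residue_name[i],
                                      chain$chain_id, chain$residue_index[i],
                                      xyz))
      serial <- serial + 1L
    }
    if (i < n) {
      lines <- c(lines, pdb_atom_line(serial, "CN", chain$residue_name[i],
                                      chain$chain_id, chain$residue_index[i],
                                      chain$bond_centers[i, ]))
      serial <- serial + 1L
    }
  }
  list(lines = lines, serial = serial)
}

#' Write complex models as a multi-MODEL PDB file
#'
#' Pseudoatoms are emitted as atom records named `CA`, `CB`, `SC` and `CN`
#' (peptide-bond center), receptor chain first, preserving residue
#' numbering.  The file round-trips through [read_models_pdb()] at PDB
#' coordinate precision (1e-3 Angstrom).
#'
#' @param models A list of [complex_model()] objects (at least one).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_models_pdb <- function(models, path) {
  if (inherits(models, "complex_model")) models <- list(models)
  if (!length(models)) stop("no models to write")
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(models)) {
    mod <- models[[m]]
    stopifnot(inherits(mod, "complex_model"))
    writeLines(sprintf("MODEL     %4d", m), con)
    r <- cg_chain_pdb_lines(mod$receptor, 1L)
    writeLines(r$lines, con)
    writeLines("TER", con)
    p <- cg_chain_pdb_lines(mod$peptide, r$serial)
    writeLines(p$lines, con)
    writeLines("TER", con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read coarse-grained models back from a multi-MODEL PDB file
#'
#' Counterpart of [write_models_pdb()]: interprets atom names `CA`, `CB`,
#' `SC` as the pseudoatoms of the coarse-grained representation (`CN` bond
#' centers are recomputed as midpoints).  The first chain of each MODEL is
#' taken as the receptor and the second as the peptide.
#'
#' @param path Path to a multi-MODEL PDB file written by
#'   [write_models_pdb()].
#' @param lattice Lattice metadata to attach to the chains.
#' @return A list of [complex_model()] objects.
#' @export
read_models_pdb <- function(path, lattice = lattice_config()) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- readLines(path)
  starts <- grep("^MODEL", txt)
  ends <- grep("^ENDMDL", txt)
  if (!length(starts)) { starts <- 1L; ends <- length(txt) }
  stopifnot(length(starts) == length(ends))
  lapply(seq_along(starts), function(m) {
    block <- txt[starts[m]:ends[m]]
    at <- block[grepl("^ATOM", block)]
    df <- data.frame(
      elety = trimws(substr(at, 13, 16)),
      resid = trimws(substr(at, 18, 20)),
      chain = substr(at, 22, 22),
      resno = as.integer(substr(at, 23, 26)),
      x = as.numeric(substr(at, 31, 38)),
      y = as.numeric(substr(at, 39, 46)),
      z = as.numeric(substr(at, 47, 54)),
      stringsAsFactors = FALSE)
    chains <- unique(df$chain)
    if (length(chains) < 2) stop("expected receptor and peptide chains in ", path)
    build <- function(sub, role) {
      ca <- as.matrix(sub[sub$elety == "CA", c("x", "y", "z")])
      cb <- as.matrix(sub[sub$elety == "CB", c("x", "y", "z")])
      sc <- as.matrix(sub[sub$elety == "SC", c("x", "y", "z")])
      rn <- sub$resid[sub$elety == "CA"]
      ri <- sub$resno[sub$elety == "CA"]
      cg_chain(ca, rn, cb = cb, sc = sc, chain_id = sub$chain[1], role = role,
               residue_index = ri, lattice = lattice, validate = FALSE)
    }
    complex_model(build(df[df$chain == chains[1], ], "receptor"),
                  build(df[df$chain == chains[2], ], "peptide"),
                  meta = list(model_id = m))
  })
}

#' Parse a side-chain contact table
#'
#' Contacts are rows of `chain resid pep_index [D0 s]` (whitespace- or
#' comma-separated, `#` comments allowed): a receptor residue identified by
#' chain and author residue number, the 1-based index of the peptide residue
#' it should touch, and optional per-contact overrides of the restraint
#' threshold `D0` (Angstrom) and slope `s`.
#'
#' @param x A file path, a character vector of rows, or a data frame with
#'   columns `chain`, `resid`, `pep_index` (optionally `D0`, `s`).
#' @param receptor A receptor [cg_chain()] used to check residue existence.
#' @param peptide A [peptide_spec()] used to range-check peptide indices.
#' @param D0,s Default restraint parameters for rows without overrides.
#' @return A data frame of class `dock_contacts` with columns `chain`,
#'   `resid`, `pep_index`, `D0`, `s` and `rec_pos` (the 1-based position of
#'   the receptor residue along the chain).
#' @examples
#' rec <- cg_chain(cbind(seq(0, 38, by = 3.8), 0, 0), rep("LEU", 11),
#'                 residue_index = 30:40, lattice = lattice_config(enabled = FALSE))
#' parse_contacts("A 36 4", rec, peptide_spec("GQLGLF"))
#' @export
parse_contacts <- function(x, receptor, peptide, D0 = 5.0, s = 1.0) {
  stopifnot(inherits(receptor, "cg_chain"), inherits(peptide, "peptide_spec"))
  if (is.character(x) && length(x) == 1 && file.exists(x))
    x <- readLines(x)
  if (is.character(x)) {
    x <- sub("#.*$", "", x)
    x <- trimws(gsub(",", " ", x))
    x <- x[nzchar(x)]
    if (!length(x)) stop("no contact rows found")
    parts <- strsplit(x, "\\s+")
    if (any(lengths(parts) < 3))
      stop("each contact row needs at least: chain resid pep_index")
    x <- data.frame(
      chain = vapply(parts, `[`, "", 1),
      resid = as.integer(vapply(parts, `[`, "", 2)),
      pep_index = as.integer(vapply(parts, `[`, "", 3)),
      D0 = as.numeric(vapply(parts, function(p) if (length(p) >= 4) p[4] else NA_character_, "")),
      s = as.numeric(vapply(parts, function(p) if (length(p) >= 5) p[5] else NA_character_, "")),
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x),
            all(c("chain", "resid", "pep_index") %in% names(x)))
  if (is.null(x$D0)) x$D0 <- NA_real_
  if (is.null(x$s)) x$s <- NA_real_
  x$D0[is.na(x$D0)] <- D0
  x$s[is.na(x$s)] <- s
  np <- nchar(peptide$sequence)
  x$rec_pos <- NA_integer_
  for (i in seq_len(nrow(x))) {
    row <- x[i, ]
    if (is.na(row$resid) || is.na(row$pep_index))
      stop("malformed contact row ", i)
    if (row$pep_index < 1 || row$pep_index > np)
      stop(sprintf("row %d: peptide index %d outside 1..%d",
                   i, row$pep_index, np))
    pos <- which(receptor$chain_id == row$chain &
                 receptor$residue_index == row$resid)
    if (length(pos) != 1)
      stop(sprintf("row %d: receptor residue %s/%d not found in structure",
                   i, row$chain, row$resid))
    if (row$D0 <= 0) stop(sprintf("row %d: D0 must be positive", i))
    if (row$s < 0) stop(sprintf("row %d: s must be non-negative", i))
    x$rec_pos[i] <- pos
  }
  class(x) <- c("dock_contacts", "data.frame")
  x
}
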