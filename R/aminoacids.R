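# Amino-acid tables used across the package: one/three letter codes, the
# distance from Calpha at which the single side-chain interaction center is
# placed when no atomic side chain is available, and the Kyte-Doolittle
# hydropathy scale used to build the default surrogate contact matrix.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
names(AA3) <- AA1

AA1_FROM_3 <- setNames(AA1, AA3)

# Ca -> side-chain-center distance (Angstrom) for chains built from sequence
# alone; rough residue-size ladder, Gly/Ala handled by the fallback rules.
SC_LENGTH <- c(A = 1.53, R = 3.5, N = 2.3, D = 2.3, C = 2.0, Q = 2.8,
               E = 2.8, G = 1.0, H = 2.7, I = 2.3, L = 2.3, K = 3.0,
               M = 2.7, F = 2.9, P = 1.9, S = 1.9, T = 1.9, W = 3.3,
               Y = 3.2, V = 2.0)

# Kyte & Doolittle hydropathy index
KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                   Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                   L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                   S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

aa_one_letter <- function(three) {
  out <- AA1_FROM_3[toupper(three)]
  out[is.na(out)] <- "X"
  unname(out)
}

aa_three_letter <- function(one) {
  out <- AA3[toupper(one)]
  out[is.na(out)] <- "UNK"
  unname(out)
}
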