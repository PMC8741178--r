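# Published amino-acid scale constants used by the descriptor pipeline.
# All tables are keyed by the 20 standard one-letter codes in alphabetical
# order. Sources: Kyte & Doolittle (1982) hydropathy; Guruprasad et al.
# (1990) dipeptide instability weights (DIWV); Vihinen et al. (1994)
# normalized B-factor flexibility; Bjellqvist et al. (1993) pKa set as used
# by the standard ProtParam-style pI calculator; Tien et al. (2013)
# theoretical maximum ASA; average residue masses (free amino acids, Da).

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Ambiguity/rare codes tolerated in sequences but excluded from descriptor
# numerators and denominators.
AA_AMBIGUOUS <- c("X", "B", "Z", "U", "O")

KD_HYDROPATHY <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

FLEXIBILITY <- c(
  A = 0.984, C = 0.906, D = 1.068, E = 1.094, F = 0.915, G = 1.031,
  H = 0.950, I = 0.927, K = 1.102, L = 0.935, M = 0.952, N = 1.048,
  P = 1.049, Q = 1.037, R = 1.008, S = 1.046, T = 0.997, V = 0.931,
  W = 0.904, Y = 0.929)

# Average masses of the free amino acids; a peptide of length L weighs
# sum(residues) - (L - 1) * WATER_MASS.
RESIDUE_MASS <- c(
  A = 89.0932, C = 121.158, D = 133.103, E = 147.129, F = 165.189,
  G = 75.0666, H = 155.155, I = 131.173, K = 146.188, L = 131.173,
  M = 149.211, N = 132.118, P = 115.130, Q = 146.144, R = 174.201,
  S = 105.093, T = 119.119, V = 117.146, W = 204.225, Y = 181.189)

WATER_MASS <- 18.0153

# Guruprasad dipeptide instability weights: rows = first residue,
# columns = second residue, alphabetical order.
DIWV <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34),
  nrow = 20, byrow = TRUE, dimnames = list(AA_STANDARD, AA_STANDARD))

# pKa values for the Henderson-Hasselbalch net-charge model.
PKA_POSITIVE <- c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98)
PKA_NEGATIVE <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
# Residue-specific overrides for the terminal pKa values.
PKA_NTERM_BY_RESIDUE <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82,
                          V = 7.44, E = 7.7)
PKA_CTERM_BY_RESIDUE <- c(D = 4.55, E = 4.75)

# Theoretical maximum accessible surface area per residue type (Angstrom^2);
# used only by the heuristic exposure stand-in to convert RSA to ASA.
MAX_ASA <- c(
  A = 129, C = 167, D = 193, E = 223, F = 240, G = 104, H = 224, I = 197,
  K = 236, L = 201, M = 224, N = 195, P = 159, Q = 225, R = 274, S = 155,
  T = 172, V = 174, W = 285, Y = 263)

# Database-wide average amino-acid composition (UniProtKB/Swiss-Prot
# statistics), used as the baseline residue frequency of the synthetic
# sequence generator.
UNIPROT_AA_FREQ <- c(
  A = 0.0825, C = 0.0138, D = 0.0546, E = 0.0672, F = 0.0386, G = 0.0707,
  H = 0.0227, I = 0.0591, K = 0.0580, L = 0.0965, M = 0.0241, N = 0.0406,
  P = 0.0474, Q = 0.0393, R = 0.0553, S = 0.0664, T = 0.0535, V = 0.0686,
  W = 0.0110, Y = 0.0292)
UNIPROT_AA_FREQ <- UNIPROT_AA_FREQ / sum(UNIPROT_AA_FREQ)

# Secondary-structure propensity sets. Note the deliberate overlaps (L in
# both helix and sheet, A in sheet): the four fractions need not sum to 1.
SS_HELIX_SET <- c("V", "I", "Y", "F", "W", "L")
SS_TURN_SET  <- c("N", "P", "G", "S")
SS_SHEET_SET <- c("E", "M", "A", "L")

AROMATIC_SET <- c("F", "W", "Y")

# Nine-residue center-peaked window weights for the flexibility profile,
# normalized to sum 1 when applied.
FLEX_WINDOW_WEIGHTS <- c(0.25, 0.4375, 0.625, 0.8125, 1, 0.8125, 0.625,
                         0.4375, 0.25)
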