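# Amino-acid scales and groups used by the feature catalog.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Fig-2-style composition order
AA_ORDER <- strsplit("IVLAFWYGSPKRHDETQNCM", "")[[1]]

AA_GROUPS <- list(
  aliphatic = c("I", "V", "L", "A"),
  aromatic = c("F", "W", "Y"),
  branching = c("V", "I", "T"),
  charged = c("K", "R", "H", "D", "E"),
  negative = c("D", "E"),
  phosphorylatable = c("S", "T", "Y"),
  polar = c("R", "K", "D", "E", "Q", "N", "Y"),
  hydrophobic = c("V", "I", "L", "F", "W", "C", "M"),
  positive = c("K", "R", "H"),
  sulfur = c("M", "C"),
  tiny = c("G", "A", "S", "P")
)

# mini-motif vocabulary: fine groups (negative, positive, aromatic) and
# coarse groups (polar, nonpolar = complement of polar over the 20 aa)
MINIMOTIF_GROUPS <- list(
  negative = AA_GROUPS$negative,
  positive = AA_GROUPS$positive,
  aromatic = AA_GROUPS$aromatic,
  polar = AA_GROUPS$polar,
  nonpolar = setdiff(AA20, AA_GROUPS$polar)
)

# TOP-IDP disorder propensity (Campen et al. 2008); higher = more disordered
SCALE_TOP_IDP <- c(
  A = 0.060, R = 0.180, N = 0.007, D = 0.192, C = 0.020, Q = 0.318,
  E = 0.736, G = 0.166, H = 0.303, I = -0.486, L = -0.326, K = 0.586,
  M = -0.397, F = -0.697, P = 0.987, S = 0.341, T = 0.059, W = -0.884,
  Y = -0.510, V = -0.121
)

# Pace & Scholtz (1998) helix propensities, ddG kcal/mol; lower = more helical
SCALE_HELIX_PS <- c(
  A = 0.00, L = 0.21, R = 0.21, M = 0.24, K = 0.26, Q = 0.39, E = 0.40,
  I = 0.41, W = 0.49, S = 0.50, Y = 0.53, F = 0.54, H = 0.61, V = 0.61,
  N = 0.65, T = 0.66, C = 0.68, D = 0.69, G = 1.00, P = 3.16
)

.minmax <- function(x) (x - min(x)) / (max(x) - min(x))

# normalized to [0,1]: disorder propensity and helix propensity (inverted
# so higher = more helical)
SCALE_DISORDER01 <- setNames(.minmax(SCALE_TOP_IDP), names(SCALE_TOP_IDP))
SCALE_HELICITY01 <- setNames(1 - .minmax(SCALE_HELIX_PS), names(SCALE_HELIX_PS))

# average residue masses (Da); water added once per peptide
AA_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01524

# EMBOSS pKa set for the Henderson-Hasselbalch net-charge curve
PKA_EMBOSS <- list(
  nterm = 8.6, cterm = 3.6,
  positive = c(K = 10.8, R = 12.5, H = 6.5),
  negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
)
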