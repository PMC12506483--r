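# Shared alphabet definitions and published thermodynamic parameter tables.
#
# Alphabet: standard bases A/C/G/T/U, IUPAC degenerate codes, inosine (I),
# and LNA bases encoded E/F/J/L (locked A/C/G/T respectively).

# IUPAC (plus inosine and LNA) expansion to the pure DNA bases each code
# can stand for.  Inosine is treated as a universal base for matching.
IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"), I = c("A", "C", "G", "T"),
  E = "A", F = "C", J = "G", L = "T"
)

DNA_ALPHABET <- names(IUPAC_EXPANSION)
RNA_ALPHABET <- setdiff(DNA_ALPHABET, "T")

# Complement map.  Degenerate codes complement within IUPAC; LNA bases
# complement within the LNA set (E<->L, F<->J); inosine self-complements
# (universal base).
COMPLEMENT_DNA <- c(
  A = "T", C = "G", G = "C", T = "A", U = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N", I = "I",
  E = "L", L = "E", F = "J", J = "F"
)
COMPLEMENT_RNA <- {
  x <- COMPLEMENT_DNA
  x[x == "T"] <- "U"
  x
}

# --- Nearest-neighbor duplex parameters (unified DNA/DNA set) -------------
# dH in kcal/mol, dS in cal/(mol K).  All 16 propagation steps expanded
# from the 10 unique published values (the table is strand symmetric).
NN_DH <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
NN_DS <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)
# Duplex initiation at each end, by terminal base pair.
NN_INIT_DH <- c(GC = 0.1, AT = 2.3)
NN_INIT_DS <- c(GC = -2.8, AT = 4.1)
# Self-complementary symmetry correction (entropy only).
NN_SYM_DS <- -1.4

# --- Internal-mismatch nearest-neighbor parameters ------------------------
# Single internal mismatches (incl. inosine pairs).  Key "XY/ZW": top
# strand 5'-XY-3' paired with bottom strand 3'-ZW-5'.  dH kcal/mol,
# dS cal/(mol K).  Published internal-mismatch DNA/DNA values.
MM_TABLE <- local({
  raw <- c(
    "AA/TA", 1.2, 1.7,    "AA/TC", 2.3, 4.6,    "AA/TG", -0.6, -2.3,
    "AA/TI", -0.7, -2.6,  "AC/TA", 5.3, 14.6,   "AC/TC", 0.0, -4.4,
    "AC/TI", -8.8, -25.4, "AC/TT", 0.7, 0.2,    "AG/TA", -0.7, -2.3,
    "AG/TG", -3.1, -9.5,  "AG/TI", 0.1, -1.8,   "AG/TT", 1.0, 0.9,
    "AI/TA", -8.3, -25.0, "AI/TC", -8.9, -25.5, "AI/TG", -4.9, -15.8,
    "AI/TI", -3.3, -11.9, "AI/TT", 0.49, -0.7,  "AT/TC", -1.2, -6.2,
    "AT/TG", -2.5, -8.3,  "AT/TI", -5.6, -18.7, "AT/TT", -2.7, -10.8,
    "CA/GA", -0.9, -4.2,  "CA/GC", 1.9, 3.7,    "CA/GG", -0.7, -2.3,
    "CA/GI", -7.0, -20.0, "CC/GA", 0.6, -0.6,   "CC/GC", -1.5, -7.2,
    "CC/GI", -8.3, -23.8, "CC/GT", -0.8, -4.5,  "CG/GA", -4.0, -13.2,
    "CG/GG", -4.9, -15.3, "CG/GI", 5.8, 16.9,   "CG/GT", -4.1, -11.7,
    "CI/GA", 2.6, 8.9,    "CI/GC", -5.4, -13.7, "CI/GG", 7.1, 21.3,
    "CI/GI", 1.3, 3.0,    "CI/GT", -1.0, -2.4,  "CT/GC", -1.5, -6.1,
    "CT/GG", -2.8, -8.0,  "CT/GI", 0.1, -1.0,   "CT/GT", -5.0, -15.8,
    "GA/CA", -2.9, -9.8,  "GA/CC", 5.2, 14.2,   "GA/CG", -0.6, -1.0,
    "GA/CI", -7.6, -20.2, "GC/CA", -0.7, -3.8,  "GC/CC", 3.6, 8.9,
    "GC/CI", -5.0, -12.6, "GC/CT", 2.3, 5.4,    "GG/CA", 0.5, 3.2,
    "GG/CG", -6.0, -15.8, "GG/CI", -7.6, -22.0, "GG/CT", 3.3, 10.4,
    "GG/TT", 5.8, 16.3,   "GI/CA", -7.8, -21.1, "GI/CC", -6.8, -19.1,
    "GI/CG", -1.1, -3.2,  "GI/CI", -0.5, -1.3,  "GI/CT", -3.5, -10.6,
    "GT/CC", 5.2, 13.5,   "GT/CG", -4.4, -12.3, "GT/CI", -4.3, -12.1,
    "GT/CT", -2.2, -8.4,  "GT/TG", 4.1, 9.5,    "TA/AA", 4.7, 12.9,
    "TA/AC", 3.4, 8.0,    "TA/AG", 0.7, 0.7,    "TA/AI", -1.3, -4.6,
    "TC/AA", 7.6, 20.2,   "TC/AC", 6.1, 16.4,   "TC/AI", -4.9, -13.9,
    "TC/AT", 1.2, 0.7,    "TG/AA", 3.0, 7.4,    "TG/AG", 1.6, 3.6,
    "TG/AI", 1.0, 1.0,    "TG/AT", -0.1, -1.7,  "TG/GT", -1.4, -6.2,
    "TI/AA", -3.4, -11.2, "TI/AC", -5.9, -17.4, "TI/AG", -1.9, -8.5,
    "TI/AI", 0.1, -2.3,   "TI/AT", -6.5, -22.0, "TT/AC", 1.0, 0.7,
    "TT/AG", -1.3, -5.3,  "TT/AI", -0.8, -4.3,  "TT/AT", 0.2, -1.5
  )
  keys <- raw[seq(1, length(raw), by = 3)]
  dh <- as.numeric(raw[seq(2, length(raw), by = 3)])
  ds <- as.numeric(raw[seq(3, length(raw), by = 3)])
  list(dh = stats::setNames(dh, keys), ds = stats::setNames(ds, keys))
})

# --- Extinction coefficients (260 nm, L mol-1 cm-1) -----------------------
EPS_MONO_DNA <- c(A = 15400, C = 7400, G = 11500, T = 8700)
EPS_DI_DNA <- c(
  AA = 27400, AC = 21200, AG = 25000, AT = 22800,
  CA = 21200, CC = 14600, CG = 18000, CT = 15200,
  GA = 25200, GC = 17600, GG = 21600, GT = 20000,
  TA = 23400, TC = 16200, TG = 19000, TT = 16800
)
EPS_MONO_RNA <- c(A = 15400, C = 7200, G = 11500, T = 9900)  # T slot holds U
EPS_DI_RNA <- c(
  AA = 27400, AC = 21000, AG = 25000, AT = 24000,
  CA = 21000, CC = 14200, CG = 17800, CT = 16200,
  GA = 25200, GC = 17400, GG = 21600, GT = 21200,
  TA = 24600, TC = 17200, TG = 20000, TT = 19600
)

# --- Residue masses (g/mol); oligo MW = sum(residues) - 61.96 -------------
MW_DNA <- c(A = 313.21, C = 289.18, G = 329.21, T = 304.20, I = 298.20)
MW_RNA <- c(A = 329.21, C = 305.18, G = 345.21, T = 306.17, I = 314.20)
MW_BACKBONE_OFFSET <- -61.96
MW_LNA_OFFSET <- 28.03  # 2'-O,4'-C methylene bridge

GAS_CONSTANT <- 1.9872  # cal/(mol K)

# Fractional G+C content of each alphabet character (fraction of its
# expansions that are G or C).
GC_FRACTION <- vapply(IUPAC_EXPANSION, function(e) {
  mean(e %in% c("G", "C"))
}, numeric(1))

# Precomputed lookup matrices over the full alphabet:
# PAIR_MAT[x, y]  - can top-strand x Watson-Crick pair with bottom y?
# MATCH_MAT[p, t] - can primer base p stand for template base t
#                   (same-strand IUPAC-compatible match)?
PAIR_MAT <- local({
  ab <- DNA_ALPHABET
  m <- matrix(FALSE, length(ab), length(ab), dimnames = list(ab, ab))
  for (x in ab) for (y in ab) {
    m[x, y] <- any(IUPAC_EXPANSION[[x]] %in%
                     COMPLEMENT_DNA[IUPAC_EXPANSION[[y]]])
  }
  m
})
MATCH_MAT <- local({
  ab <- DNA_ALPHABET
  m <- matrix(FALSE, length(ab), length(ab), dimnames = list(ab, ab))
  for (x in ab) for (y in ab) {
    m[x, y] <- any(IUPAC_EXPANSION[[x]] %in% IUPAC_EXPANSION[[y]])
  }
  m
})
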