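# Versioned tables: codon usage, residue masses, pKa set, and the fixed
# building blocks of the synthetic LMW-GS gene architecture.

# One fixed codon per amino acid (wheat-biased common codons). Back-translation
# with a single deterministic table keeps theoretical amplicon sizes and
# sequence identities exactly reproducible.
CODON_TABLE <- c(
  A = "GCC", R = "AGG", N = "AAC", D = "GAC", C = "TGC", E = "GAG",
  Q = "CAA", G = "GGC", H = "CAC", I = "ATC", L = "CTC", K = "AAG",
  M = "ATG", F = "TTC", P = "CCA", S = "TCC", T = "ACC", W = "TGG",
  Y = "TAC", V = "GTG"
)

# Average (not monoisotopic) residue masses in Daltons; free termini add one
# water. Matches the convention used for kDa estimates of storage proteins.
RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

# EMBOSS pKa set for net-charge/pI computation.
PKA_SET <- list(
  nterm = 8.6, cterm = 3.6,
  positive = c(K = 10.8, R = 12.5, H = 6.5),
  negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
)

# Controlled vocabulary for collection regions.
REGION_LEVELS <- c("Iraq", "Iran", "Armenia", "NE Lebanon", "Syria", "SE Turkey")

DOMAIN_LEVELS <- c("signal", "N-terminal", "repetitive",
                   "C-terminal I", "C-terminal II", "C-terminal III", "none")

# ---- synthetic gene architecture ------------------------------------------

# 20-residue signal peptide shared by all templates.
SIGNAL_AA <- "MKTFLVLALLAVVATSAVAQ"

# Type-diagnostic N-terminal regions (as translated, before signal cleavage
# bookkeeping). The s-type carries the MENSHIPGLEKPS block whose MEN tripeptide
# is removed with the signal; i-type has no N-terminal domain and its mature
# protein starts with Ile at the head of the repetitive domain.
NTERM_FULL <- list(i = "", m = "METSHIPGLER", s = "MENSHIPGLEKPS")
NTERM_MATURE <- list(i = "", m = "METSHIPGLER", s = "SHIPGLEKPS")
REPEAT_INTRO <- list(i = "ISQQ", m = "", s = "QQTLSH")

# C-terminal domain scaffolds. C-terminal I carries six cysteines (first and
# last residues included), C-terminal II one (its last residue), C-terminal III
# one. Two blocks of C-terminal I are invariant across genes because they are
# the landing sites of the reverse marker primers.
CTERM1_ANCH_A <- "CSQPVQNLAHSIVQGL"                     # 16 aa, Cys #1
CTERM1_MID    <- "AHLVPCRSLVLQALPCMVNLGLSR"             # 24 aa, Cys #2-3
CTERM1_ANCH_B <- "QSEGSRV"                              #  7 aa, no Cys
CTERM1_TAIL   <- paste0("SQIAQQLPAMSR", "C",            # 58 aa, Cys #4-6
                        "AQHLVQQLVPQSIAQLEAR", "C",
                        "QPTSVAQAQQQILPHQSVLFQGVP", "C")
CTERM2_BASE <- paste0("SIIQQQAQQQGQQQGVQILRPLFQ", "C")  # 25 aa, Cys #7 last
CTERM3_BASE <- paste0("VQGQGIIQP", "C",                 # 55 aa, Cys #8
                      "QVPAQLEVIRSLVLQTLPTMSQAAHLPSAGIFQPQQPVFGQPHQS")

CTERM1_LEN <- 105L
CTERM2_LEN <- 25L
CTERM3_LEN <- 55L
CTERM_TOTAL <- CTERM1_LEN + CTERM2_LEN + CTERM3_LEN

# 0-based cysteine offsets within the assembled C-terminal region.
CYS_OFFSETS <- c(0L, 21L, 31L, 59L, 79L, 104L, 129L, 139L)

# Positions in C-terminal I that must never be touched by divergence or SNPs:
# the two primer anchors and every cysteine (1-based aa indices).
CTERM1_PROTECTED <- sort(unique(c(1:16, 41:47, 1L, 22L, 32L, 60L, 80L, 105L)))

# Shared 68-nt block immediately upstream of ATG housing the three forward
# primer landing sites; generated once from a fixed internal stream and free
# of ATG so the true start codon is always the first.
shared_5p_block <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- dna_without_atg(68L, salt_hash("shared-5p-block"))
    cache
  }
})

# Forward primer windows within the shared block (1-based).
F_WINDOWS <- list(LMWGS1 = c(25L, 44L), LMWGS2 = c(1L, 20L), LMWGS3 = c(49L, 68L))
# Reverse primer windows, 1-based nt offsets within the C-terminal coding
# region (ANCH_A occupies nt 1-48, ANCH_B nt 121-141).
R_WINDOWS <- list(LMWGS1 = c(29L, 48L), LMWGS2 = c(122L, 141L), LMWGS3 = c(25L, 44L))

# Random DNA with no ATG trinucleotide (any ATG is broken by a C).
dna_without_atg <- function(n, seed) {
  s <- lcg_dna(n, seed)
  while (grepl("ATG", s, fixed = TRUE)) s <- sub("ATG", "ACG", s, fixed = TRUE)
  s
}

# Random DNA free of stop trinucleotides at any offset, used for 3' flanks so
# the terminal stop codon of the CDS is the last in-frame stop of the gene.
dna_without_stops <- function(n, seed) {
  s <- lcg_dna(n, seed)
  repeat {
    m <- regexpr("T(AA|AG|GA)", s)
    if (m == -1L) return(s)
    substr(s, m, m) <- "C"
  }
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

encode_protein <- function(aa) {
  chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(CODON_TABLE))
  if (length(bad) > 0) {
    stop("cannot encode residue(s): ", paste(unique(bad), collapse = ", "))
  }
  paste(CODON_TABLE[chars], collapse = "")
}
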