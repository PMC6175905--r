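# The 33-attribute physicochemical feature space.
#
# Attributes per peptide: mole percent of each of the 20 canonical
# residues; five group percents (positive RHK, negative DE, uncharged
# STNQ, special CGP, hydrophobic AVILMFW); GRAVY (mean Kyte-Doolittle
# hydropathy); aliphatic index (Ikai); atom percents of C, H, N, O, S
# over the peptide's molecular formula (free termini, i.e. residues
# minus one water per peptide bond); and the isoelectric point from a
# Henderson-Hasselbalch charge model solved by bisection.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

AA_GROUPS <- list(
  pct_positive    = c("R", "H", "K"),
  pct_negative    = c("D", "E"),
  pct_uncharged   = c("S", "T", "N", "Q"),
  pct_special     = c("C", "G", "P"),
  pct_hydrophobic = c("A", "V", "I", "L", "M", "F", "W"))

# Kyte & Doolittle hydropathy scale.
KD_HYDROPATHY <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)

# Atom counts (C, H, N, O, S) of the free amino acids; a peptide of n
# residues is the column sums minus (n - 1) waters (H2, O1).
AA_ATOMS <- matrix(c(
  # C   H  N  O  S
    3,  7, 1, 2, 0,  # A
    3,  7, 1, 2, 1,  # C
    4,  7, 1, 4, 0,  # D
    5,  9, 1, 4, 0,  # E
    9, 11, 1, 2, 0,  # F
    2,  5, 1, 2, 0,  # G
    6,  9, 3, 2, 0,  # H
    6, 13, 1, 2, 0,  # I
    6, 14, 2, 2, 0,  # K
    6, 13, 1, 2, 0,  # L
    5, 11, 1, 2, 1,  # M
    4,  8, 2, 3, 0,  # N
    5,  9, 1, 2, 0,  # P
    5, 10, 2, 3, 0,  # Q
    6, 14, 4, 2, 0,  # R
    3,  7, 1, 3, 0,  # S
    4,  9, 1, 3, 0,  # T
    5, 11, 1, 2, 0,  # V
   11, 12, 2, 2, 0,  # W
    9, 11, 1, 3, 0   # Y
), nrow = 20, byrow = TRUE,
  dimnames = list(AA20, c("C", "H", "N", "O", "S")))

# Bjellqvist-style pKa set (Expasy lineage): generic termini plus the
# seven ionizable side chains.  Pinned here; documented in the vignette.
PKA <- c(nterm = 7.5, cterm = 3.55,
         D = 4.05, E = 4.45, C = 9.0, Y = 10.0,
         H = 5.98, K = 10.0, R = 12.0)

FEATURE_NAMES <- c(paste0("pct_", AA20), names(AA_GROUPS),
                   "gravy", "aliphatic_index",
                   paste0("pct_atom_", c("C", "H", "N", "O", "S")),
                   "isoelectric_point")

# Residue count matrix (n x 20) for a character vector of peptides.
aa_counts <- function(x) {
  n <- length(x)
  len <- nchar(x)
  if (any(len < 1L)) stop("empty peptide")
  chars <- strsplit(x, "")
  aa <- unlist(chars, use.names = FALSE)
  code <- match(aa, AA20)
  if (anyNA(code))
    stop("non-canonical residue(s): ",
         paste(unique(aa[is.na(code)]), collapse = ", "))
  idx <- rep.int(seq_len(n), len)
  counts <- matrix(0L, n, 20L, dimnames = list(NULL, AA20))
  tab <- table(factor(idx, levels = seq_len(n)),
               factor(code, levels = 1:20))
  counts[] <- as.integer(tab)
  counts
}

# Feature matrix from a residue count matrix; `len` = row sums.
features_from_counts <- function(counts, len = rowSums(counts),
                                 include_length = FALSE) {
  pct <- counts / len * 100
  colnames(pct) <- paste0("pct_", AA20)
  grp <- vapply(AA_GROUPS, function(g) rowSums(pct[, paste0("pct_", g),
                                                   drop = FALSE]),
                numeric(nrow(pct)))
  if (nrow(pct) == 1L) grp <- matrix(grp, 1L, dimnames = list(NULL, names(AA_GROUPS)))
  gravy <- as.numeric(counts %*% KD_HYDROPATHY[AA20]) / len
  ai <- pct[, "pct_A"] + 2.9 * pct[, "pct_V"] +
    3.9 * (pct[, "pct_I"] + pct[, "pct_L"])
  atoms <- counts %*% AA_ATOMS
  atoms[, "H"] <- atoms[, "H"] - 2 * (len - 1)  # one water per bond
  atoms[, "O"] <- atoms[, "O"] - (len - 1)
  pct_atom <- atoms / rowSums(atoms) * 100
  colnames(pct_atom) <- paste0("pct_atom_", colnames(atoms))
  out <- cbind(pct, grp, gravy = gravy, aliphatic_index = ai, pct_atom,
               isoelectric_point = pi_from_counts(counts))
  if (include_length) out <- cbind(out, length = len)
  rownames(out) <- NULL
  out
}

# Net charge of peptides (rows of `counts`) at pH values `ph`
# (recycled): Henderson-Hasselbalch over termini and ionizable side
# chains.
net_charge <- function(counts, ph) {
  pos <- 1 / (1 + 10^(ph - PKA["nterm"])) +
    counts[, "R"] / (1 + 10^(ph - PKA["R"])) +
    counts[, "K"] / (1 + 10^(ph - PKA["K"])) +
    counts[, "H"] / (1 + 10^(ph - PKA["H"]))
  neg <- 1 / (1 + 10^(PKA["cterm"] - ph)) +
    counts[, "D"] / (1 + 10^(PKA["D"] - ph)) +
    counts[, "E"] / (1 + 10^(PKA["E"] - ph)) +
    counts[, "C"] / (1 + 10^(PKA["C"] - ph)) +
    counts[, "Y"] / (1 + 10^(PKA["Y"] - ph))
  unname(pos - neg)
}

# Bisection on [0, 14]: 50 halvings reach pH precision ~1.6e-15, far
# below the 1e-4 net-charge tolerance the pI is defined at (the charge
# curve is flat near the pI, so converging on pH rather than charge is
# what makes the result well defined).
pi_from_counts <- function(counts, tol = 1e-4) {
  lo <- rep(0, nrow(counts)); hi <- rep(14, nrow(counts))
  for (it in 1:50) {
    mid <- (lo + hi) / 2
    up <- net_charge(counts, mid) > 0   # still positive: pI is higher
    lo[up] <- mid[up]; hi[!up] <- mid[!up]
  }
  mid <- (lo + hi) / 2
  stopifnot(all(abs(net_charge(counts, mid)) < tol))
  mid
}

#' Physicochemical feature vectors for peptides
#'
#' Computes the 33-attribute description used by the epitope classifier:
#' the mole percent of each canonical residue, the five charge/character
#' group percents, GRAVY, the aliphatic index, the C/H/N/O/S atom
#' percents of the peptide's molecular formula, and the isoelectric
#' point.  All composition attributes are length-scale invariant.
#'
#' @param x Character vector of peptides (canonical residues only), or a
#'   k-mer data frame from [generate_kmers()] (its `sequence` column is
#'   used).
#' @param include_length Also append the raw peptide length as a 34th
#'   column (off by default; the classifier uses the 33 attributes).
#' @return Numeric matrix, one row per peptide, columns named as in
#'   `epitree_feature_names()`.
#' @examples
#' featurize("AAAA")[, c("pct_A", "pct_hydrophobic", "aliphatic_index")]
#' featurize("III")[, "gravy"]   # Kyte-Doolittle value of Ile, 4.5
#' @export
featurize <- function(x, include_length = FALSE) {
  if (is.data.frame(x)) x <- x$sequence
  stopifnot(is.character(x), length(x) >= 1L)
  x <- toupper(x)
  features_from_counts(aa_counts(x), nchar(x),
                       include_length = include_length)
}

#' @rdname featurize
#' @export
epitree_feature_names <- function() FEATURE_NAMES

#' Atom percentages of a peptide
#'
#' Percent of C, H, N, O and S atoms in the molecular formula of each
#' peptide with free termini (free amino-acid formulas minus one water
#' per peptide bond); a 1-mer equals the free amino acid.
#'
#' @param x Character vector of peptides.
#' @return Matrix with columns `C`, `H`, `N`, `O`, `S` summing to 100.
#' @examples
#' atom_percentages("G")  # glycine C2H5NO2: C 20, H 50, N 10, O 20
#' @export
atom_percentages <- function(x) {
  f <- featurize(x)
  out <- f[, paste0("pct_atom_", c("C", "H", "N", "O", "S")), drop = FALSE]
  colnames(out) <- c("C", "H", "N", "O", "S")
  out
}

#' Isoelectric point of a peptide
#'
#' pH at which the Henderson-Hasselbalch net charge (free N- and
#' C-terminus plus the R, K, H, D, E, C, Y side chains, Bjellqvist-style
#' pKa set) crosses zero, located by bisection on \[0, 14\] to a charge
#' tolerance of 1e-4.
#'
#' @param x Character vector of peptides.
#' @param tol Net-charge tolerance for the bisection.
#' @return Numeric vector of pI values (pH units).
#' @export
isoelectric_point <- function(x, tol = 1e-4) {
  stopifnot(is.character(x))
  pi_from_counts(aa_counts(toupper(x)), tol = tol)
}
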