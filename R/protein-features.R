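# Protein featurization: PDB -> Calpha distance map -> contact map ->
# residue graph with 54-dim node features (one-hot + PPM column +
# physicochemical descriptors).

#' Residue alphabet (20 standard amino acids + "X" other)
#'
#' Order of the one-hot block and of PPM rows. Nonstandard codes
#' (B, Z, U, O and anything unknown) map to the 21st class `"X"`.
#' @format Character vector of length 21.
#' @export
RESIDUE_ALPHABET <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X"
)

#' Width of the residue feature vector
#' @export
RESIDUE_FEATURE_DIM <- 54L

# Physicochemical residue descriptors: free amino-acid molecular weight
# (Da), pKa of the alpha-COOH and alpha-NH3+ groups, side-chain pKa (0
# when not ionizable), isoelectric point, and hydrophobicity indices at
# pH 2 and pH 7 (Monera et al. scale). Standard literature values.
.aaProps <- local({
  tab <- rbind(
    #        weight pka1  pka2  pkaR   pI  hyd2  hyd7
    A = c(89.09, 2.34, 9.69, 0.00, 6.00, 47, 41),
    R = c(174.20, 2.17, 9.04, 12.48, 10.76, -26, -14),
    N = c(132.12, 2.02, 8.80, 0.00, 5.41, -41, -28),
    D = c(133.10, 1.88, 9.60, 3.65, 2.77, -18, -55),
    C = c(121.16, 1.96, 10.28, 8.18, 5.07, 52, 49),
    Q = c(146.15, 2.17, 9.13, 0.00, 5.65, -18, -10),
    E = c(147.13, 2.19, 9.67, 4.25, 3.22, 8, -31),
    G = c(75.07, 2.34, 9.60, 0.00, 5.97, 0, 0),
    H = c(155.16, 1.82, 9.17, 6.00, 7.59, -42, 8),
    I = c(131.17, 2.36, 9.60, 0.00, 6.02, 100, 99),
    L = c(131.17, 2.36, 9.60, 0.00, 5.98, 100, 97),
    K = c(146.19, 2.18, 8.95, 10.53, 9.74, -37, -23),
    M = c(149.21, 2.28, 9.21, 0.00, 5.74, 74, 74),
    F = c(165.19, 1.83, 9.13, 0.00, 5.48, 92, 100),
    P = c(115.13, 1.99, 10.60, 0.00, 6.30, -46, -46),
    S = c(105.09, 2.21, 9.15, 0.00, 5.68, -7, -5),
    T = c(119.12, 2.09, 9.10, 0.00, 5.60, 13, 13),
    W = c(204.23, 2.83, 9.39, 0.00, 5.89, 84, 97),
    Y = c(181.19, 2.20, 9.11, 10.07, 5.66, 49, 63),
    V = c(117.15, 2.32, 9.62, 0.00, 5.96, 79, 76),
    X = c(0, 0, 0, 0, 0, 0, 0)
  )
  colnames(tab) <- c(
    "weight", "pka_cooh", "pka_nh3", "pka_other", "pi", "hyd_ph2",
    "hyd_ph7"
  )
  tab
})

# Residue class membership (aliphatic / aromatic / polar neutral /
# acidic charged / basic charged), standard classification.
.aaClasses <- list(
  aliphatic = c("A", "I", "L", "M", "V"),
  aromatic = c("F", "W", "Y"),
  polar_neutral = c("C", "G", "N", "Q", "S", "T"),
  acidic = c("D", "E"),
  basic = c("H", "K", "R")
)

.residueClassIndex <- function(code) {
  idx <- match(code, RESIDUE_ALPHABET)
  ifelse(is.na(idx), length(RESIDUE_ALPHABET), idx)
}

.normalizeResidue <- function(code, warnUnknown = TRUE) {
  code <- toupper(code)
  unknown <- !(code %in% RESIDUE_ALPHABET[1:20])
  if (any(unknown) && warnUnknown) {
    warning(
      "unknown residue code(s) ",
      paste(unique(code[unknown]), collapse = ", "),
      " mapped to class 'X'",
      call. = FALSE
    )
  }
  code[unknown] <- "X"
  code
}

#' Calpha distance map from a PDB structure
#'
#' Reads the first model of a PDB file (chain selectable), extracts the
#' Calpha atom of each residue, and returns the symmetric matrix of
#' pairwise Euclidean distances in Angstrom. Residues without a Calpha
#' atom are skipped with a warning; the returned matrix carries the
#' surviving residue numbers as dimnames so index gaps are recorded.
#'
#' @param pdbPath Path to a PDB file.
#' @param chain Optional chain identifier; default uses all chains.
#' @return K x K numeric matrix with attributes `resno` (residue
#'   numbers) and `resid` (one-letter residue codes).
#' @export
pdbToDistanceMap <- function(pdbPath, chain = NULL) {
  pdb <- bio3d::read.pdb(pdbPath, multi = FALSE, verbose = FALSE)
  atoms <- pdb$atom
  if (!is.null(chain)) atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
  atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0) stop("no protein atoms in ", pdbPath, call. = FALSE)
  resKey <- paste(atoms$chain, atoms$resno, atoms$insert)
  allRes <- unique(resKey)
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  caKey <- paste(ca$chain, ca$resno, ca$insert)
  missing <- setdiff(allRes, caKey)
  if (length(missing) > 0) {
    warning(
      length(missing), " residue(s) without a Calpha atom skipped",
      call. = FALSE
    )
  }
  if (nrow(ca) == 0) stop("no Calpha atoms in ", pdbPath, call. = FALSE)
  ca <- ca[!duplicated(caKey), , drop = FALSE]
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  dimnames(d) <- list(ca$resno, ca$resno)
  attr(d, "resno") <- ca$resno
  attr(d, "resid") <- unname(bio3d::aa321(ca$resid))
  d
}

#' Threshold a distance map into a binary contact map
#'
#' Contact iff distance strictly below the threshold. The diagonal is
#' set to 0 (self-contacts are handled by the graph-construction rule,
#' not the map).
#'
#' @param dist Symmetric nonnegative K x K distance matrix (Angstrom).
#' @param threshold Distance cutoff in Angstrom (default 8).
#' @return A [ContactMap-class].
#' @export
distanceMapToContactMap <- function(dist, threshold = 8.0) {
  dist <- as.matrix(dist)
  if (nrow(dist) != ncol(dist)) {
    stop("distance map must be square", call. = FALSE)
  }
  m <- (dist < threshold) * 1
  diag(m) <- 0
  dimnames(m) <- NULL
  methods::new("ContactMap", matrix = m, thresholdAngstrom = threshold)
}

#' Position probability matrix from an alignment
#'
#' Computes M\[r, k\] = (F\[r, k\] + p) / (A * N + p) where F counts
#' occurrences of residue class r at column k over the N aligned
#' sequences, p is the pseudocount and A is the `alphabetSize`
#' denominator constant. The default A = 4 follows the source formula
#' as printed; A = 20 (or 21) can be selected instead. Gap characters
#' (`-`, `.`) are not counted in F. When no alignment is available,
#' pass the query sequence alone (N = 1).
#'
#' @param alignment Character vector of equal-length aligned sequences.
#' @param pseudocount Pseudocount p >= 0 (default 0.8).
#' @param alphabetSize Denominator constant A (default 4).
#' @return A [PPM-class] with 21 rows (20 residues + "X").
#' @export
#' @examples
#' ppmMatrix(computePPM("A", pseudocount = 0))[1, 1]  # 1/4
computePPM <- function(alignment, pseudocount = 0.8, alphabetSize = 4) {
  if (length(alignment) == 0) stop("empty alignment", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1) {
    stop("ragged alignment: sequences differ in length", call. = FALSE)
  }
  K <- lens[1]
  if (K == 0) stop("empty alignment", call. = FALSE)
  N <- length(alignment)
  R <- length(RESIDUE_ALPHABET)
  F <- matrix(0L, R, K, dimnames = list(RESIDUE_ALPHABET, NULL))
  for (s in alignment) {
    chars <- strsplit(toupper(s), "")[[1]]
    gap <- chars %in% c("-", ".")
    idx <- .residueClassIndex(chars)
    for (k in which(!gap)) {
      F[idx[k], k] <- F[idx[k], k] + 1L
    }
  }
  M <- (F + pseudocount) / (alphabetSize * N + pseudocount)
  methods::new("PPM",
    matrix = M, frequency = F, pseudocount = pseudocount,
    nSequences = as.integer(N), alphabetSize = alphabetSize
  )
}

#' Residue feature matrix for a protein sequence
#'
#' One 54-long row per residue: 21-way residue one-hot, the 21-entry
#' PPM column for that position, five residue-class flags (aliphatic,
#' aromatic, polar neutral, acidic charged, basic charged), molecular
#' weight, pKa (COOH), pKa (NH3), side-chain pKa, isoelectric point,
#' and hydrophobicity at pH 2 and pH 7. Unknown residue codes map to
#' the 21st class with a warning.
#'
#' @param sequence Protein sequence (one-letter codes).
#' @param ppm Optional [PPM-class]; defaults to the N = 1 self-alignment
#'   of `sequence`.
#' @param pseudocount Pseudocount used for the fallback PPM.
#' @return N x 54 numeric matrix.
#' @export
residueFeatures <- function(sequence, ppm = NULL, pseudocount = 0.8) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(chars) == 0) stop("empty sequence", call. = FALSE)
  chars <- .normalizeResidue(chars)
  if (is.null(ppm)) ppm <- computePPM(sequence, pseudocount = pseudocount)
  M <- ppmMatrix(ppm)
  if (ncol(M) != length(chars)) {
    stop("PPM length does not match sequence length", call. = FALSE)
  }
  n <- length(chars)
  out <- matrix(0, n, RESIDUE_FEATURE_DIM)
  for (i in seq_len(n)) {
    code <- chars[i]
    idx <- .residueClassIndex(code)
    flags <- vapply(.aaClasses, function(cl) code %in% cl, logical(1))
    out[i, ] <- c(
      oneHot(idx, 21L),
      M[, i],
      as.numeric(flags),
      .aaProps[code, ]
    )
  }
  out
}

#' Build a protein graph from a contact map and residue features
#'
#' Edges are the contacts of the map; consecutive residues (i, i+1) are
#' always connected so the peptide backbone keeps the graph connected
#' even when the contact map is sparse. Self-contacts never become
#' edges.
#'
#' @param cmap A [ContactMap-class].
#' @param features N x 54 residue feature matrix (N must equal the map
#'   dimension).
#' @param labels Optional character residue labels.
#' @return A [MolecularGraph-class] with `kind = "protein"`.
#' @export
contactMapToGraph <- function(cmap, features, labels = NULL) {
  m <- contactMatrix(cmap)
  n <- nrow(m)
  features <- as.matrix(features)
  if (nrow(features) != n) {
    stop(
      "contact map dimension (", n, ") does not match feature rows (",
      nrow(features), ")",
      call. = FALSE
    )
  }
  idx <- which(upper.tri(m) & m == 1, arr.ind = TRUE)
  edges <- idx[, c(1, 2), drop = FALSE]
  if (n > 1) {
    backbone <- cbind(seq_len(n - 1), 2:n)
    edges <- rbind(edges, backbone)
  }
  if (is.null(labels)) labels <- rep("X", n)
  molecularGraph(features, edges, labels, kind = "protein")
}

#' Featurize a protein target end to end
#'
#' Convenience wrapper: PDB -> distance map -> contact map -> residue
#' graph. The sequence defaults to the one read from the structure.
#'
#' @param pdbPath Path to the PDB file.
#' @param sequence Optional sequence override (must match the Calpha
#'   count).
#' @param msa Optional alignment (character vector) for the PPM.
#' @param threshold Contact threshold in Angstrom.
#' @param chain Optional chain selector.
#' @param pseudocount PPM pseudocount.
#' @return A [MolecularGraph-class] with `kind = "protein"`.
#' @export
proteinToGraph <- function(pdbPath, sequence = NULL, msa = NULL,
                           threshold = 8.0, chain = NULL,
                           pseudocount = 0.8) {
  d <- pdbToDistanceMap(pdbPath, chain = chain)
  if (is.null(sequence)) sequence <- paste(attr(d, "resid"), collapse = "")
  if (nchar(sequence) != nrow(d)) {
    stop("sequence length does not match Calpha count", call. = FALSE)
  }
  ppm <- if (is.null(msa)) {
    computePPM(sequence, pseudocount = pseudocount)
  } else {
    computePPM(msa, pseudocount = pseudocount)
  }
  cmap <- distanceMapToContactMap(d, threshold)
  feats <- residueFeatures(sequence, ppm)
  contactMapToGraph(cmap, feats, labels = strsplit(sequence, "")[[1]])
}

#' Read an aligned FASTA / A3M file as a character vector
#'
#' Lower-case insert columns (A3M convention) are removed so all rows
#' have the query's aligned length.
#'
#' @param path Alignment file path.
#' @return Character vector of aligned sequences.
#' @export
readMsaFile <- function(path) {
  aln <- Biostrings::readBStringSet(path)
  seqs <- as.character(aln)
  # A3M: lower-case letters are insertions relative to the query
  seqs <- vapply(seqs, function(s) gsub("[a-z]", "", s), character(1))
  unname(seqs)
}
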