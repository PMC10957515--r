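# Drug featurization: SMILES -> heavy-atom graph with 78-dim node features.

#' Atom element vocabulary for the one-hot block
#'
#' Fixed 44-symbol element list (43 named elements plus the catch-all
#' `"X"`); elements outside the list are clamped to `"X"`. The
#' vocabulary is fixed so featurization is reproducible across runs and
#' is serialized with model checkpoints.
#'
#' @format Character vector of length 44.
#' @export
ATOM_ELEMENTS <- c(
  "C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na", "Ca",
  "Fe", "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb", "Sn", "Ag",
  "Pd", "Co", "Se", "Ti", "Zn", "H", "Li", "Ge", "Cu", "Au", "Ni",
  "Cd", "In", "Mn", "Zr", "Cr", "Pt", "Hg", "Pb", "X"
)

# One-hot bins 0..10 for degree and hydrogen counts; values above 10 are
# clamped to the last bin.
.countBins <- 11L

.clampBinOneHot <- function(value, nbins = .countBins) {
  oneHot(min(value, nbins - 1L) + 1L, nbins)
}

# 78 = 44 (element) + 11 (degree) + 11 (total H) + 11 (implicit H) + 1
# (aromatic flag).
#' Width of the atom feature vector
#' @export
ATOM_FEATURE_DIM <- 44L + 3L * .countBins + 1L

.atomFeatureRow <- function(element, degree, numH, numImplicitH, aromatic) {
  idx <- match(element, ATOM_ELEMENTS)
  if (is.na(idx)) idx <- length(ATOM_ELEMENTS)  # clamp to "X"
  c(
    oneHot(idx, length(ATOM_ELEMENTS)),
    .clampBinOneHot(degree),
    .clampBinOneHot(numH),
    .clampBinOneHot(numImplicitH),
    as.numeric(aromatic)
  )
}

# Parse a SMILES through OpenBabel (via ChemmineR/ChemmineOB) into atom
# symbols, formal charges, bonds (with orders) and aromatic-atom flags.
# Explicit hydrogens are returned as atoms here and folded into the
# heavy-atom H counts by the caller.
.parseSmiles <- function(smiles) {
  sdfText <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "SDF", paste0(smiles, "\n")
    )),
    error = function(e) ""
  )
  lines <- strsplit(sdfText, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4) {
    stop("unparsable SMILES: '", smiles, "'", call. = FALSE)
  }
  counts <- lines[4]
  nAtoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nBonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(nAtoms) || nAtoms == 0) {
    stop("unparsable SMILES: '", smiles, "' (empty molecule)", call. = FALSE)
  }
  atomLines <- lines[5:(4 + nAtoms)]
  elements <- vapply(
    atomLines,
    function(l) trimws(substr(l, 32, 34)),
    character(1), USE.NAMES = FALSE
  )
  charges <- integer(nAtoms)
  for (l in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", l)), "\\s+")[[1]])
    nPairs <- f[1]
    for (i in seq_len(nPairs)) {
      charges[f[2 * i]] <- f[2 * i + 1]
    }
  }
  if (nBonds > 0) {
    bondLines <- lines[(5 + nAtoms):(4 + nAtoms + nBonds)]
    bonds <- t(vapply(
      bondLines,
      function(l) {
        c(
          as.integer(substr(l, 1, 3)), as.integer(substr(l, 4, 6)),
          as.integer(substr(l, 7, 9))
        )
      },
      integer(3), USE.NAMES = FALSE
    ))
  } else {
    bonds <- matrix(integer(), 0, 3)
  }
  # Aromaticity perception via ChemmineR ring analysis (works only when
  # the molecule has bonds; bond-less molecules have no rings).
  aromatic <- logical(nAtoms)
  if (nBonds > 0) {
    sdf <- tryCatch(
      suppressWarnings(ChemmineR::read.SDFset(lines)),
      error = function(e) NULL
    )
    if (!is.null(sdf)) {
      ringInfo <- tryCatch(
        ChemmineR::rings(sdf[[1]], upper = 12, type = "arom", arom = TRUE),
        error = function(e) list(AROMATIC_RINGS = list())
      )
      aromNames <- unique(unlist(ringInfo$AROMATIC_RINGS))
      if (length(aromNames)) {
        aromIdx <- as.integer(sub("^.*_", "", aromNames))
        aromatic[aromIdx] <- TRUE
      }
    }
  }
  list(
    elements = elements, charges = charges, bonds = bonds,
    aromatic = aromatic
  )
}

# Default valences used to infer implicit hydrogen counts from the bond
# order sum, adjusted by formal charge (N+ -> 4, O- -> 1, ...).
.defaultValence <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1
)

#' Convert a SMILES string to a featurized molecular graph
#'
#' Parses the SMILES (through OpenBabel), maps heavy atoms to nodes and
#' bonds to edges, and attaches a 78-dimensional feature row per atom:
#' a 44-way element one-hot, 11-bin one-hots for heavy-atom degree,
#' total hydrogen count and implicit hydrogen count, and an aromatic
#' flag. Hydrogens are implicit: explicit `[H]` atoms are folded into
#' their neighbor's hydrogen counts rather than kept as nodes.
#'
#' @param smiles A single non-empty SMILES string.
#' @return A [MolecularGraph-class] with `kind = "drug"`.
#' @export
#' @examples
#' g <- smilesToGraph("c1ccccc1")
#' numNodes(g)           # 6
#' nrow(edgeList(g))     # 6
smilesToGraph <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles)) {
    stop("smiles must be a single non-empty string", call. = FALSE)
  }
  mol <- .parseSmiles(smiles)
  nAll <- length(mol$elements)
  isH <- mol$elements == "H"
  heavyIdx <- which(!isH)
  if (length(heavyIdx) == 0) {
    stop("unparsable SMILES: '", smiles, "' (no heavy atoms)", call. = FALSE)
  }
  # bond order sum and neighbor bookkeeping over the full atom set
  orderSum <- numeric(nAll)
  heavyDeg <- integer(nAll)
  explicitH <- integer(nAll)
  if (nrow(mol$bonds) > 0) {
    for (r in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[r, 1]; j <- mol$bonds[r, 2]; o <- mol$bonds[r, 3]
      oo <- if (o == 4) 1.5 else o  # aromatic bond order
      orderSum[i] <- orderSum[i] + oo
      orderSum[j] <- orderSum[j] + oo
      if (!isH[j]) heavyDeg[i] <- heavyDeg[i] + 1L
      if (!isH[i]) heavyDeg[j] <- heavyDeg[j] + 1L
      if (isH[j]) explicitH[i] <- explicitH[i] + 1L
      if (isH[i]) explicitH[j] <- explicitH[j] + 1L
    }
  }
  features <- matrix(0, length(heavyIdx), ATOM_FEATURE_DIM)
  labels <- character(length(heavyIdx))
  for (a in seq_along(heavyIdx)) {
    i <- heavyIdx[a]
    el <- mol$elements[i]
    valence <- .defaultValence[el]
    if (is.na(valence)) valence <- 0
    target <- valence + mol$charges[i]
    implicitH <- max(0, round(target - orderSum[i]))
    totalH <- implicitH + explicitH[i]
    features[a, ] <- .atomFeatureRow(
      el, heavyDeg[i], totalH, implicitH, mol$aromatic[i]
    )
    labels[a] <- el
  }
  # renumber edges into the heavy-atom index space
  newIdx <- integer(nAll)
  newIdx[heavyIdx] <- seq_along(heavyIdx)
  edges <- mol$bonds[, 1:2, drop = FALSE]
  if (nrow(edges) > 0) {
    keep <- !isH[edges[, 1]] & !isH[edges[, 2]]
    edges <- edges[keep, , drop = FALSE]
    edges <- matrix(newIdx[edges], ncol = 2)
  }
  molecularGraph(features, edges, labels, kind = "drug")
}

#' Read SMILES strings from a file
#'
#' Accepts either a plain file with one SMILES per line (optionally
#' followed by an identifier) or a TSV with a `smiles` column.
#'
#' @param path File path.
#' @return Named character vector of SMILES (names are identifiers).
#' @export
readSmilesFile <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first) && grepl("smiles", tolower(first))) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    cols <- tolower(names(tab))
    sm <- tab[[which(cols == "smiles")[1]]]
    ids <- if ("drug_id" %in% cols) {
      tab[[which(cols == "drug_id")[1]]]
    } else {
      as.character(seq_along(sm))
    }
    stats::setNames(sm, ids)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "\\s+")
    sm <- vapply(parts, `[[`, character(1), 1L)
    ids <- vapply(
      parts,
      function(p) if (length(p) > 1) p[[2]] else p[[1]],
      character(1)
    )
    stats::setNames(sm, ids)
  }
}
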