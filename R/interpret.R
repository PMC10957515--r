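# Interpretability: per-dimension highest-weight atoms/residues from
# the implicit attention, exported as annotated structures and tables.

#' Per-dimension top-weight key positions
#'
#' For each feature dimension i, the implicit-attention weights
#' a\[n, n', i\] are aggregated over the query positions n (mean by
#' default) and the key position n' with the maximal aggregate is
#' returned. Ties are broken by the lowest index and flagged. Scores
#' are the aggregated weights normalized to \[0, 1\] per dimension.
#'
#' @param att Attention tensors from [attentionTensors()] (or
#'   `dtiForward(..., withAttention = TRUE)$attention`).
#' @param branch `"protein"` annotates residues (keys of the
#'   drug-as-query tensor); `"drug"` annotates atoms (keys of the
#'   protein-as-query tensor).
#' @param aggregate `"mean"` (default) or `"max"` over query
#'   positions.
#' @return A list of class `saliencyAnnotation` with
#'   `perDimensionArgmax` (length d), `tie` flags, `scoreMatrix`
#'   (keys x d, normalized), `positionScores` (per key position, mean
#'   of normalized scores over dimensions), `nDimsArgmax`, `entity`
#'   and `aggregate`.
#' @export
topWeightPositions <- function(att, branch = c("protein", "drug"),
                               aggregate = c("mean", "max")) {
  branch <- match.arg(branch)
  aggregate <- match.arg(aggregate)
  a <- if (branch == "protein") att$drugAsQuery$a else att$protAsQuery$a
  dims <- dim(a)
  nKey <- dims[2]
  d <- dims[3]
  agg <- matrix(0, nKey, d)
  for (i in seq_len(d)) {
    slice <- a[, , i, drop = FALSE]
    dim(slice) <- dims[1:2]
    agg[, i] <- if (aggregate == "mean") colMeans(slice) else
      apply(slice, 2, max)
  }
  argmax <- integer(d)
  tie <- logical(d)
  for (i in seq_len(d)) {
    mx <- max(agg[, i])
    hits <- which(agg[, i] == mx)
    argmax[i] <- hits[1]
    tie[i] <- length(hits) > 1
  }
  norm <- apply(agg, 2, function(col) {
    rng <- max(col) - min(col)
    if (rng == 0) rep(0, length(col)) else (col - min(col)) / rng
  })
  structure(
    list(
      entity = if (branch == "protein") "protein" else "drug",
      perDimensionArgmax = argmax,
      tie = tie,
      scoreMatrix = norm,
      positionScores = rowMeans(norm),
      nDimsArgmax = tabulate(argmax, nbins = nKey),
      aggregate = aggregate
    ),
    class = "saliencyAnnotation"
  )
}

#' Export a residue saliency annotation onto a structure
#'
#' Writes the structure with per-residue scores (scaled to 0-100) in
#' the B-factor column, plus a TSV of (residue index, residue name,
#' score, n_dims_argmax).
#'
#' @param annotation A protein [topWeightPositions()] annotation.
#' @param pdbPath Input PDB whose Calpha residues the annotation
#'   indexes.
#' @param outPrefix Output path prefix; writes `<prefix>.pdb` and
#'   `<prefix>.tsv`.
#' @return Invisibly, the two output paths.
#' @export
exportProteinAnnotation <- function(annotation, pdbPath, outPrefix) {
  stopifnot(annotation$entity == "protein")
  pdb <- bio3d::read.pdb(pdbPath, multi = FALSE, verbose = FALSE)
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(paste(ca$chain, ca$resno, ca$insert)), ,
           drop = FALSE]
  nRes <- nrow(ca)
  scores <- annotation$positionScores
  if (length(scores) != nRes) {
    stop(
      "annotation has ", length(scores), " residues but structure has ",
      nRes, "; unmapped residue indices: ",
      paste(utils::head(
        setdiff(seq_len(max(nRes, length(scores))),
                seq_len(min(nRes, length(scores)))), 10
      ), collapse = ", "),
      call. = FALSE
    )
  }
  resKey <- paste(atoms$chain, atoms$resno, atoms$insert)
  caKey <- paste(ca$chain, ca$resno, ca$insert)
  bPerAtom <- round(scores[match(resKey, caKey)] * 100, 2)
  bPerAtom[is.na(bPerAtom)] <- 0
  full <- pdb$atom
  full$b <- 0
  full$b[full$type == "ATOM"] <- bPerAtom
  pdbOut <- paste0(outPrefix, ".pdb")
  bio3d::write.pdb(pdb, file = pdbOut, b = full$b)
  tsvOut <- paste0(outPrefix, ".tsv")
  utils::write.table(
    data.frame(
      residue_index = seq_len(nRes),
      residue_name = unname(bio3d::aa321(ca$resid)),
      score = round(scores, 6),
      n_dims_argmax = annotation$nDimsArgmax
    ),
    tsvOut, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(c(pdb = pdbOut, tsv = tsvOut))
}

#' Export an atom saliency annotation for a drug molecule
#'
#' Writes a TSV of (atom index, symbol, score, n_dims_argmax) plus a
#' JSON highlight list (1-based atom indices that are the argmax of at
#' least one dimension) consumable by 2D depiction tools.
#'
#' @param annotation A drug [topWeightPositions()] annotation.
#' @param smiles The molecule's SMILES.
#' @param outPrefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>_highlights.json`.
#' @return Invisibly, the two output paths.
#' @export
exportDrugAnnotation <- function(annotation, smiles, outPrefix) {
  stopifnot(annotation$entity == "drug")
  g <- smilesToGraph(smiles)
  nAtoms <- numNodes(g)
  if (length(annotation$positionScores) != nAtoms) {
    stop(
      "annotation indexes ", length(annotation$positionScores),
      " atoms but molecule has ", nAtoms,
      call. = FALSE
    )
  }
  tsvOut <- paste0(outPrefix, ".tsv")
  utils::write.table(
    data.frame(
      atom_index = seq_len(nAtoms),
      symbol = nodeLabels(g),
      score = round(annotation$positionScores, 6),
      n_dims_argmax = annotation$nDimsArgmax
    ),
    tsvOut, sep = "\t", row.names = FALSE, quote = FALSE
  )
  jsonOut <- paste0(outPrefix, "_highlights.json")
  jsonlite::write_json(
    list(
      smiles = smiles,
      highlight_atoms = which(annotation$nDimsArgmax > 0),
      tie_dimensions = which(annotation$tie)
    ),
    jsonOut, auto_unbox = TRUE
  )
  invisible(c(tsv = tsvOut, json = jsonOut))
}
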