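# Planted-rule synthetic DTI generator: small valid molecules with a
# designated substructure, random folded-like Calpha chains with a
# designated residue motif, and labels following substructure AND/OR
# motif, optionally noise-flipped.

.syntheticScaffolds <- c(
  "CCO", "CCN", "CC(=O)O", "c1ccccc1C", "CCOC", "C1CCCCC1",
  "c1ccncc1C", "CC(C)C", "CCSC", "CC=CC"
)
.syntheticUnits <- c("C", "CC", "CO", "CN", "C(C)C")

#' Planted substructure and motif of the synthetic generator
#'
#' The drug rule is the presence of a trifluoromethyl tail (SMILES
#' fragment `C(F)(F)F`; background decorations never contain
#' fluorine), the protein rule the presence of the tripeptide motif
#' `WHW` (background sequences never contain W or H), so both rules
#' can be re-checked by plain substring matching.
#' @export
SYNTHETIC_SUBSTRUCTURE <- "C(F)(F)F"
#' @rdname SYNTHETIC_SUBSTRUCTURE
#' @export
SYNTHETIC_MOTIF <- "WHW"

# residues never used in background sequences: the motif letters
.syntheticBackgroundAA <- setdiff(RESIDUE_ALPHABET[1:20], c("W", "H"))

# Self-avoiding random walk with Calpha-like 3.8 A steps; non-adjacent
# residues are kept at least 3.9 A apart.
.randomCaCoords <- function(n, maxRestarts = 50L) {
  step <- 3.8
  minSep <- 3.9
  for (restart in seq_len(maxRestarts)) {
    pos <- matrix(0, n, 3)
    ok <- TRUE
    for (i in 2:n) {
      placed <- FALSE
      for (try in 1:40) {
        dirv <- stats::rnorm(3)
        dirv <- dirv / sqrt(sum(dirv^2))
        cand <- pos[i - 1, ] + step * dirv
        if (i > 2) {
          dists <- sqrt(rowSums(
            (pos[seq_len(i - 2), , drop = FALSE] -
               matrix(cand, i - 2, 3, byrow = TRUE))^2
          ))
          if (any(dists < minSep)) next
        }
        pos[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(pos)
  }
  stop("failed to generate a self-avoiding chain", call. = FALSE)
}

#' Write a Calpha-only PDB file
#'
#' @param coords K x 3 coordinate matrix (Angstrom).
#' @param sequence One-letter sequence of length K.
#' @param path Output file.
#' @param bFactors Optional per-residue B-factor column values.
#' @return Invisibly, `path`.
#' @export
writeCaPdb <- function(coords, sequence, path, bFactors = NULL) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  stopifnot(nrow(coords) == length(chars))
  n <- length(chars)
  if (is.null(bFactors)) bFactors <- numeric(n)
  res3 <- bio3d::aa123(chars)
  res3[is.na(res3) | res3 == "NA"] <- "UNK"
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(coords)),
    type = rep("ATOM", n),
    resno = seq_len(n),
    resid = res3,
    eleno = seq_len(n),
    elety = rep("CA", n),
    chain = rep("A", n),
    o = rep(1, n),
    b = round(bFactors, 2)
  )
  invisible(path)
}

.makeSyntheticDrug <- function(withSub, nUnits) {
  scaffold <- sample(.syntheticScaffolds, 1)
  deco <- paste(
    sample(.syntheticUnits, nUnits, replace = TRUE),
    collapse = ""
  )
  s <- paste0(scaffold, deco)
  if (withSub) s <- paste0(s, SYNTHETIC_SUBSTRUCTURE)
  s
}

.makeSyntheticSequence <- function(len, withMotif) {
  chars <- sample(.syntheticBackgroundAA, len, replace = TRUE)
  s <- paste(chars, collapse = "")
  if (withMotif) {
    at <- sample.int(len - nchar(SYNTHETIC_MOTIF) + 1L, 1)
    substr(s, at, at + nchar(SYNTHETIC_MOTIF) - 1L) <- SYNTHETIC_MOTIF
  }
  s
}

#' Generate a planted-rule synthetic DTI dataset
#'
#' Drugs are curated scaffolds with randomized valid decorations; a
#' configured fraction carries the planted substructure
#' ([SYNTHETIC_SUBSTRUCTURE]). Targets are random sequences (with a
#' fraction carrying the planted motif [SYNTHETIC_MOTIF]) paired with
#' self-avoiding-walk Calpha coordinates, optionally emitted as PDB
#' files. Every drug-target pair becomes one sample; the label is 1
#' iff the rule holds (`"both"`: substructure AND motif;
#' `"motif_only"` / `"substructure_only"`: one side alone), then
#' flipped with probability `noiseRate`. Class balance is kept inside
#' \[0.3, 0.7\] by the construction fractions and checked.
#'
#' @param nDrugs,nTargets Entity counts (default 25 x 20 = 500
#'   samples).
#' @param interactionRule `"both"` (default), `"motif_only"`,
#'   `"substructure_only"`.
#' @param noiseRate Label-flip probability in \[0, 0.5).
#' @param seed Integer seed; the same seed reproduces the dataset
#'   exactly.
#' @param pdbDir Optional directory; when given, one Calpha PDB per
#'   target is written and its path recorded.
#' @param seqLenRange Target sequence length range.
#' @return List with `samples` (data frame: drug_id, smiles,
#'   target_id, sequence, raw_affinity, label, label_rule), `drugs`
#'   (named SMILES vector), `targets` (named list with `sequence`,
#'   `coords`, optional `pdb`), and the rule settings.
#' @export
generateSyntheticDtiset <- function(nDrugs = 25L, nTargets = 20L,
                                    interactionRule = c(
                                      "both", "motif_only",
                                      "substructure_only"
                                    ),
                                    noiseRate = 0, seed = 1L,
                                    pdbDir = NULL,
                                    seqLenRange = c(30L, 50L)) {
  interactionRule <- match.arg(interactionRule)
  stopifnot(nDrugs >= 2, nTargets >= 2, noiseRate >= 0, noiseRate < 0.5)
  # fractions chosen so the expected positive rate sits near 0.5
  fracSub <- switch(interactionRule,
    both = 0.7, motif_only = 0.5, substructure_only = 0.5
  )
  fracMotif <- switch(interactionRule,
    both = 0.7, motif_only = 0.5, substructure_only = 0.5
  )
  out <- withLocalSeed(subSeed(seed, "generator"), {
    nSub <- round(fracSub * nDrugs)
    smiles <- character(nDrugs)
    withSub <- c(rep(TRUE, nSub), rep(FALSE, nDrugs - nSub))
    for (i in seq_len(nDrugs)) {
      repeat {
        s <- .makeSyntheticDrug(withSub[i], nUnits = sample(1:4, 1))
        if (!(s %in% smiles)) {
          smiles[i] <- s
          break
        }
      }
    }
    names(smiles) <- sprintf("D%03d", seq_len(nDrugs))
    nMotif <- round(fracMotif * nTargets)
    withMotif <- c(rep(TRUE, nMotif), rep(FALSE, nTargets - nMotif))
    targets <- vector("list", nTargets)
    names(targets) <- sprintf("T%03d", seq_len(nTargets))
    for (j in seq_len(nTargets)) {
      len <- sample(seqLenRange[1]:seqLenRange[2], 1)
      sq <- .makeSyntheticSequence(len, withMotif[j])
      targets[[j]] <- list(sequence = sq, coords = .randomCaCoords(len))
    }
    pairs <- expand.grid(
      drug_id = names(smiles), target_id = names(targets),
      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
    )
    pairs$smiles <- unname(smiles[pairs$drug_id])
    pairs$sequence <- vapply(
      targets[pairs$target_id], `[[`, character(1), "sequence"
    )
    hasSub <- grepl(SYNTHETIC_SUBSTRUCTURE, pairs$smiles, fixed = TRUE)
    hasMotif <- grepl(SYNTHETIC_MOTIF, pairs$sequence, fixed = TRUE)
    cleanLabel <- switch(interactionRule,
      both = hasSub & hasMotif,
      motif_only = hasMotif,
      substructure_only = hasSub
    )
    flip <- stats::runif(nrow(pairs)) < noiseRate
    pairs$label <- as.integer(xor(cleanLabel, flip))
    pairs$raw_affinity <- NA_real_
    pairs$label_rule <- "synthetic"
    pairs <- pairs[, c(
      "drug_id", "smiles", "target_id", "sequence", "raw_affinity",
      "label", "label_rule"
    )]
    list(samples = pairs, drugs = smiles, targets = targets)
  })
  balance <- mean(out$samples$label)
  if (balance < 0.3 || balance > 0.7) {
    stop(
      sprintf("class balance %.2f outside [0.3, 0.7]", balance),
      call. = FALSE
    )
  }
  if (!is.null(pdbDir)) {
    dir.create(pdbDir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(out$targets)) {
      p <- file.path(pdbDir, paste0(id, ".pdb"))
      writeCaPdb(out$targets[[id]]$coords, out$targets[[id]]$sequence, p)
      out$targets[[id]]$pdb <- p
    }
  }
  out$interactionRule <- interactionRule
  out$noiseRate <- noiseRate
  out$seed <- seed
  out
}
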