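# Dataset ingestion, label construction, negative sampling and splits.

#' Convert a dissociation constant (nM) to pKd
#'
#' pKd = -log10(Kd / 1e9), i.e. the negative log of the molar Kd for a
#' value given in nanomolar units.
#'
#' @param kdNM Positive Kd in nM.
#' @return pKd value(s).
#' @export
#' @examples
#' kdToPkd(100)  # 7
kdToPkd <- function(kdNM) {
  if (any(!is.finite(kdNM)) || any(kdNM <= 0)) {
    stop("Kd must be positive and finite (nM)", call. = FALSE)
  }
  -log10(kdNM / 1e9)
}

#' Binarize a Davis-style pKd value
#'
#' Binding iff pKd >= 7 (inclusive threshold).
#'
#' @param pkd Finite pKd value(s).
#' @return 0/1 label(s).
#' @export
binarizeDavis <- function(pkd) {
  stopifnot(all(is.finite(pkd)))
  as.integer(pkd >= 7)
}

#' Binarize a KIBA score
#'
#' Positive iff the score is strictly larger than 12.1.
#'
#' @param score Finite KIBA score(s).
#' @return 0/1 label(s).
#' @export
binarizeKiba <- function(score) {
  stopifnot(all(is.finite(score)))
  as.integer(score > 12.1)
}

#' Sample BIOSNAP-style negatives
#'
#' Draws, uniformly without replacement, as many unseen drug-target
#' pairs as there are positives from the Cartesian product of the
#' observed drugs and targets minus the positive pairs.
#'
#' @param positives Data frame with columns `drug_id` and `target_id`
#'   (other columns, e.g. `smiles`/`sequence`, are carried over from
#'   the entity's first occurrence).
#' @param seed Integer seed.
#' @return Data frame of negatives with `label = 0` and
#'   `label_rule = "biosnap_sampled_negative"`.
#' @export
sampleBiosnapNegatives <- function(positives, seed = 1L) {
  stopifnot(nrow(positives) >= 1,
            all(c("drug_id", "target_id") %in% names(positives)))
  drugs <- unique(positives$drug_id)
  targets <- unique(positives$target_id)
  universe <- expand.grid(
    drug_id = drugs, target_id = targets,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  posKey <- paste(positives$drug_id, positives$target_id, sep = "\r")
  uniKey <- paste(universe$drug_id, universe$target_id, sep = "\r")
  pool <- universe[!(uniKey %in% posKey), , drop = FALSE]
  nNeed <- nrow(positives)
  if (nrow(pool) < nNeed) {
    stop(
      "universe too small: ", nrow(pool), " non-positive pairs available, ",
      nNeed, " needed",
      call. = FALSE
    )
  }
  pick <- withLocalSeed(seed, sample.int(nrow(pool), nNeed))
  neg <- pool[pick, , drop = FALSE]
  rownames(neg) <- NULL
  if ("smiles" %in% names(positives)) {
    neg$smiles <- positives$smiles[match(neg$drug_id, positives$drug_id)]
  }
  if ("sequence" %in% names(positives)) {
    neg$sequence <-
      positives$sequence[match(neg$target_id, positives$target_id)]
  }
  neg$raw_affinity <- NA_real_
  neg$label <- 0L
  neg$label_rule <- "biosnap_sampled_negative"
  neg
}

#' Validity/dedup filter applied before splitting
#'
#' Drops duplicated (drug, target) pairs and samples whose SMILES does
#' not parse; every removal is reported via message.
#'
#' @param samples DTI sample data frame.
#' @return Filtered data frame.
#' @export
filterDtiSamples <- function(samples) {
  key <- paste(samples$drug_id, samples$target_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message("removing ", sum(dup), " duplicate drug-target pair(s)")
    samples <- samples[!dup, , drop = FALSE]
  }
  if ("smiles" %in% names(samples)) {
    uniq <- unique(samples$smiles)
    ok <- vapply(
      uniq,
      function(s) {
        !inherits(tryCatch(smilesToGraph(s), error = identity,
                           warning = identity), "condition")
      },
      logical(1)
    )
    bad <- uniq[!ok]
    if (length(bad)) {
      message(
        "removing samples with ", length(bad), " unparsable SMILES: ",
        paste(utils::head(bad, 5), collapse = ", ")
      )
      samples <- samples[!(samples$smiles %in% bad), , drop = FALSE]
    }
  }
  rownames(samples) <- NULL
  samples
}

#' Split specification
#'
#' @param mode `"random"`, `"unseen_drug"` or `"unseen_target"`.
#' @param ratios Train/val/test proportions for random mode (default
#'   7:1:2); must sum to 1.
#' @param holdoutFraction Fraction of entities held out in the unseen
#'   modes (default 0.2); remaining samples are divided 7:1 into
#'   train and validation.
#' @param seed Integer seed.
#' @return A list of class `splitSpec`.
#' @export
splitSpec <- function(mode = c("random", "unseen_drug", "unseen_target"),
                      ratios = c(0.7, 0.1, 0.2), holdoutFraction = 0.2,
                      seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-9,
            holdoutFraction > 0, holdoutFraction < 1)
  structure(
    list(mode = mode, ratios = ratios,
         holdoutFraction = holdoutFraction, seed = as.integer(seed)),
    class = "splitSpec"
  )
}

#' Split samples into train/validation/test
#'
#' Random mode partitions samples in the configured ratios (7:1:2 by
#' default, exact when n is divisible by 10). Unseen modes hold out
#' `holdoutFraction` of the drugs (or targets) and place all their
#' samples in the test set, guaranteeing zero entity overlap with
#' train and validation; remaining samples are split 7:1.
#'
#' @param samples DTI sample data frame.
#' @param spec A [splitSpec()].
#' @return List with `train`, `val`, `test` data frames and `spec`.
#' @export
splitSamples <- function(samples, spec) {
  n <- nrow(samples)
  if (n < 3) stop("too few samples to split", call. = FALSE)
  res <- withLocalSeed(subSeed(spec$seed, paste0("split:", spec$mode)), {
    if (spec$mode == "random") {
      nTest <- round(spec$ratios[3] * n)
      nVal <- round(spec$ratios[2] * n)
      perm <- sample.int(n)
      idxTest <- perm[seq_len(nTest)]
      idxVal <- perm[nTest + seq_len(nVal)]
      idxTrain <- perm[(nTest + nVal + 1):n]
      list(train = idxTrain, val = idxVal, test = idxTest)
    } else {
      col <- if (spec$mode == "unseen_drug") "drug_id" else "target_id"
      entities <- unique(samples[[col]])
      nHold <- max(1L, round(spec$holdoutFraction * length(entities)))
      held <- sample(entities, nHold)
      idxTest <- which(samples[[col]] %in% held)
      rest <- setdiff(seq_len(n), idxTest)
      if (length(rest) < 2) {
        stop("split produced an empty partition", call. = FALSE)
      }
      rest <- sample(rest)
      nVal <- max(1L, round(length(rest) / 8))
      idxVal <- rest[seq_len(nVal)]
      idxTrain <- rest[(nVal + 1):length(rest)]
      list(train = idxTrain, val = idxVal, test = idxTest)
    }
  })
  if (any(lengths(res) == 0)) {
    stop("split produced an empty partition", call. = FALSE)
  }
  out <- lapply(res, function(i) {
    s <- samples[sort(i), , drop = FALSE]
    rownames(s) <- NULL
    s
  })
  out$spec <- spec
  out
}

#' Read a tabular DTI dataset
#'
#' Expects a TSV/CSV with columns `drug_id`, `smiles`, `target_id`,
#' `sequence` and either `affinity` or `label`. When an affinity
#' column is present, labels are derived with the requested rule.
#'
#' @param path File path (delimiter inferred from the extension).
#' @param rule `"davis_pkd"` (affinity is Kd in nM, binarized at
#'   pKd >= 7), `"davis_pkd_precomputed"` (affinity already pKd),
#'   `"kiba_score"`, or `"labeled"` (a 0/1 `label` column is present).
#' @return DTI sample data frame with `label` and `label_rule`.
#' @export
readDtiTable <- function(path,
                         rule = c("labeled", "davis_pkd",
                                  "davis_pkd_precomputed", "kiba_score")) {
  rule <- match.arg(rule)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(
    path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
    quote = "\"", comment.char = ""
  )
  need <- c("drug_id", "smiles", "target_id", "sequence")
  if (!all(need %in% names(tab))) {
    stop(
      "missing column(s): ", paste(setdiff(need, names(tab)), collapse = ", "),
      call. = FALSE
    )
  }
  if (rule == "labeled") {
    stopifnot("label" %in% names(tab))
    tab$label <- as.integer(tab$label)
    tab$label_rule <- "labeled"
  } else {
    stopifnot("affinity" %in% names(tab))
    tab$raw_affinity <- tab$affinity
    if (rule == "davis_pkd") {
      tab$label <- binarizeDavis(kdToPkd(tab$affinity))
      tab$label_rule <- "davis_pkd"
    } else if (rule == "davis_pkd_precomputed") {
      tab$label <- binarizeDavis(tab$affinity)
      tab$label_rule <- "davis_pkd"
    } else {
      tab$label <- binarizeKiba(tab$affinity)
      tab$label_rule <- "kiba_score"
    }
  }
  tab
}

#' Write split manifests
#'
#' Writes train/val/test TSV manifests plus a JSON sidecar recording
#' the seed, mode, ratios and label-rule provenance.
#'
#' @param split Result of [splitSamples()].
#' @param dir Output directory.
#' @return Invisibly, the sidecar path.
#' @export
writeSplitManifests <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (part in c("train", "val", "test")) {
    utils::write.table(
      split[[part]], file.path(dir, paste0(part, ".tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
  }
  sidecar <- file.path(dir, "split.json")
  jsonlite::write_json(
    list(
      mode = split$spec$mode, ratios = split$spec$ratios,
      holdout_fraction = split$spec$holdoutFraction,
      seed = split$spec$seed,
      label_rules = as.list(table(split$train$label_rule)),
      sizes = list(
        train = nrow(split$train), val = nrow(split$val),
        test = nrow(split$test)
      )
    ),
    sidecar, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(sidecar)
}
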