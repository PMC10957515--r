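# CPU training loop, metric suite and repeated-run aggregation.

#' Run configuration for training
#'
#' All optimization choices are surfaced here. Defaults: Adam with
#' learning rate 1e-3, batch size 32, at most 100 epochs with early
#' stopping on validation AUROC (patience 10).
#'
#' @param epochs Maximum epochs.
#' @param batchSize Minibatch size.
#' @param lr Adam learning rate.
#' @param patience Early-stopping patience (epochs without validation
#'   AUROC improvement).
#' @param seed Integer seed (fanned out to init/shuffle/dropout
#'   streams).
#' @param nRepeats Repeat count used by [repeatRuns()] (default 5).
#' @param verbose Print per-epoch progress.
#' @return A list of class `runConfig`.
#' @export
runConfig <- function(epochs = 100L, batchSize = 32L, lr = 1e-3,
                      patience = 10L, seed = 1L, nRepeats = 5L,
                      verbose = FALSE) {
  stopifnot(epochs >= 1, batchSize >= 1, lr > 0, patience >= 1,
            nRepeats >= 1)
  structure(
    list(
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      lr = lr, patience = as.integer(patience), seed = as.integer(seed),
      nRepeats = as.integer(nRepeats), verbose = isTRUE(verbose)
    ),
    class = "runConfig"
  )
}

#' Precompute model inputs for every entity of a dataset
#'
#' Featurizes each unique drug (from SMILES) and target (from its
#' Calpha coordinates or PDB file; a backbone-only chain graph is used
#' when no structure is available) once, and precomputes propagation
#' and pooling matrices plus provider embeddings.
#'
#' @param dataset Either the list returned by
#'   [generateSyntheticDtiset()] or a plain sample data frame with
#'   `smiles` and `sequence` columns.
#' @param config A [modelConfig()].
#' @param provider Embedding provider (default [stubEmbed()]).
#' @param contactThreshold Contact-map threshold in Angstrom.
#' @return List with `drugInputs`, `targetInputs` (named lists) and
#'   `samples`.
#' @export
prepareModelInputs <- function(dataset, config, provider = stubEmbed,
                               contactThreshold = 8.0) {
  if (is.data.frame(dataset)) {
    samples <- dataset
    drugs <- samples$smiles[!duplicated(samples$drug_id)]
    names(drugs) <- samples$drug_id[!duplicated(samples$drug_id)]
    targets <- lapply(
      samples$sequence[!duplicated(samples$target_id)],
      function(sq) list(sequence = sq)
    )
    names(targets) <- samples$target_id[!duplicated(samples$target_id)]
  } else {
    samples <- dataset$samples
    drugs <- dataset$drugs
    targets <- dataset$targets
  }
  drugInputs <- lapply(names(drugs), function(id) {
    g <- smilesToGraph(drugs[[id]])
    prepareGraphInput(g, drugs[[id]], config, provider)
  })
  names(drugInputs) <- names(drugs)
  targetInputs <- lapply(names(targets), function(id) {
    tg <- targets[[id]]
    feats <- residueFeatures(tg$sequence)
    labels <- strsplit(tg$sequence, "")[[1]]
    g <- if (!is.null(tg$coords)) {
      d <- as.matrix(stats::dist(tg$coords))
      contactMapToGraph(
        distanceMapToContactMap(d, contactThreshold), feats, labels
      )
    } else if (!is.null(tg$pdb)) {
      d <- pdbToDistanceMap(tg$pdb)
      contactMapToGraph(
        distanceMapToContactMap(d, contactThreshold), feats, labels
      )
    } else {
      # sequence-only fallback: backbone chain graph
      n <- nrow(feats)
      molecularGraph(
        feats,
        if (n > 1) cbind(seq_len(n - 1), 2:n) else NULL,
        labels, "protein"
      )
    }
    prepareGraphInput(g, tg$sequence, config, provider)
  })
  names(targetInputs) <- names(targets)
  list(drugInputs = drugInputs, targetInputs = targetInputs,
       samples = samples)
}

.pairList <- function(set, inputs) {
  lapply(seq_len(nrow(set)), function(i) {
    list(
      drug = inputs$drugInputs[[set$drug_id[i]]],
      prot = inputs$targetInputs[[set$target_id[i]]],
      y = set$label[i]
    )
  })
}

.bceLoss <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the model
#'
#' Minibatch Adam on binary cross-entropy, early stopping on
#' validation AUROC, deterministic under the run seed on CPU. Training
#' aborts with a diagnostic if the loss turns non-finite.
#'
#' @param trainSet,valSet Sample data frames (columns `drug_id`,
#'   `target_id`, `label`).
#' @param inputs Entity inputs from [prepareModelInputs()].
#' @param config A [modelConfig()].
#' @param run A [runConfig()].
#' @return List with `params` (best-validation checkpoint), `config`,
#'   `log` (per-epoch data frame), `bestEpoch`, `bestValAuroc`.
#' @export
trainModel <- function(trainSet, valSet, inputs, config,
                       run = runConfig()) {
  stopifnot(nrow(trainSet) > 0, nrow(valSet) > 0)
  trainPairs <- .pairList(trainSet, inputs)
  valPairs <- .pairList(valSet, inputs)
  params <- initModelParams(config, subSeed(run$seed, "init"))
  state <- adamInit(params, lr = run$lr)
  n <- length(trainPairs)
  bestAuroc <- -Inf
  bestParams <- params
  bestEpoch <- 0L
  wait <- 0L
  log <- data.frame()
  dropRate <- config$dropout
  withLocalSeed(subSeed(run$seed, "sgd"), {
    for (epoch in seq_len(run$epochs)) {
      ord <- sample.int(n)
      epochLoss <- 0
      for (start in seq(1, n, by = run$batchSize)) {
        idx <- ord[start:min(start + run$batchSize - 1L, n)]
        gAcc <- NULL
        for (i in idx) {
          pr <- trainPairs[[i]]
          mask <- if (dropRate > 0) {
            (stats::runif(config$mlpHidden) >= dropRate) / (1 - dropRate)
          } else {
            NULL
          }
          fw <- dtiForwardPrepared(pr$drug, pr$prot, params, config,
                                   dropMask = mask, keepCache = TRUE)
          loss <- .bceLoss(fw$prob, pr$y)
          if (!is.finite(loss)) {
            stop(
              "training diverged at epoch ", epoch,
              " (non-finite loss); lower the learning rate",
              call. = FALSE
            )
          }
          epochLoss <- epochLoss + loss
          g <- dtiBackwardPrepared(fw$cache, params, config,
                                   fw$prob - pr$y)
          gAcc <- if (is.null(gAcc)) {
            g
          } else {
            mapParams(`+`, gAcc, g)
          }
        }
        gAcc <- mapParams(function(x) x / length(idx), gAcc)
        upd <- adamStep(params, gAcc, state)
        params <- upd$params
        state <- upd$state
      }
      epochLoss <- epochLoss / n
      valScores <- vapply(
        valPairs,
        function(pr) {
          dtiForwardPrepared(pr$drug, pr$prot, params, config)$prob
        },
        numeric(1)
      )
      valLabels <- vapply(valPairs, `[[`, numeric(1), "y")
      valAuroc <- if (length(unique(valLabels)) > 1) {
        aurocScore(valScores, valLabels)
      } else {
        NA_real_
      }
      log <- rbind(log, data.frame(
        epoch = epoch, loss = epochLoss, val_auroc = valAuroc
      ))
      if (run$verbose) {
        message(sprintf(
          "epoch %3d  loss %.4f  val AUROC %.4f", epoch, epochLoss,
          valAuroc
        ))
      }
      if (is.na(valAuroc) || valAuroc > bestAuroc) {
        bestAuroc <- if (is.na(valAuroc)) bestAuroc else valAuroc
        bestParams <- params
        bestEpoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= run$patience) break
      }
      # converged: validation ranking is perfect and the training loss
      # is already small
      if (isTRUE(bestAuroc >= 1) && epochLoss < 0.2) break
    }
  })
  list(
    params = bestParams, config = config, log = log,
    bestEpoch = bestEpoch, bestValAuroc = bestAuroc
  )
}

#' Area under the ROC curve
#'
#' Threshold-free ranking metric computed with pROC.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels (both classes present).
#' @return AUROC in \[0, 1\].
#' @export
aurocScore <- function(scores, labels) {
  r <- pROC::roc(
    response = labels, predictor = scores, levels = c(0, 1),
    direction = "<", quiet = TRUE
  )
  as.numeric(pROC::auc(r))
}

#' Area under the precision-recall curve
#'
#' Step-function (average-precision style) integration over the
#' distinct score thresholds, tie-safe.
#'
#' @inheritParams aurocScore
#' @return AUPRC in \[0, 1\].
#' @export
auprcScore <- function(scores, labels) {
  P <- sum(labels == 1)
  if (P == 0 || P == length(labels)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  cumTP <- cumsum(y == 1)
  cumFP <- cumsum(y == 0)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie block
  tp <- cumTP[keep]
  fp <- cumFP[keep]
  prec <- tp / (tp + fp)
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Evaluate a trained model on a test set
#'
#' AUROC and AUPRC from the ranked scores; sensitivity TP/(TP+FN) and
#' specificity TN/(TN+FP) at the classification threshold. With a
#' single-class test set the ranking metrics are reported as NA.
#'
#' @param params Trained parameters.
#' @param config The matching [modelConfig()].
#' @param testSet Sample data frame.
#' @param inputs Entity inputs from [prepareModelInputs()].
#' @param threshold Classification threshold (default 0.5).
#' @return List with `auroc`, `auprc`, `sensitivity`, `specificity`,
#'   `scores`, `labels`.
#' @export
evaluateModel <- function(params, config, testSet, inputs,
                          threshold = 0.5) {
  pairs <- .pairList(testSet, inputs)
  scores <- vapply(
    pairs,
    function(pr) dtiForwardPrepared(pr$drug, pr$prot, params, config)$prob,
    numeric(1)
  )
  labels <- vapply(pairs, `[[`, numeric(1), "y")
  single <- length(unique(labels)) < 2
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  list(
    auroc = if (single) NA_real_ else aurocScore(scores, labels),
    auprc = if (single) NA_real_ else auprcScore(scores, labels),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    scores = scores, labels = labels
  )
}

#' Repeated training runs with aggregated metrics
#'
#' Trains and evaluates `n` times under distinct sub-seeds of the run
#' seed and reports per-run metrics plus mean and sample standard
#' deviation (n - 1 denominator).
#'
#' @param trainSet,valSet,testSet Sample data frames.
#' @param inputs Entity inputs from [prepareModelInputs()].
#' @param config A [modelConfig()].
#' @param run A [runConfig()]; `run$nRepeats` sets the default n.
#' @param n Number of repeats.
#' @return List with `perRun` (data frame) and `summary` (mean/sd per
#'   metric).
#' @export
repeatRuns <- function(trainSet, valSet, testSet, inputs, config,
                       run = runConfig(), n = run$nRepeats) {
  metrics <- c("auroc", "auprc", "sensitivity", "specificity")
  perRun <- data.frame()
  for (i in seq_len(n)) {
    ri <- run
    ri$seed <- subSeed(run$seed, paste0("run", i))
    fit <- trainModel(trainSet, valSet, inputs, config, ri)
    ev <- evaluateModel(fit$params, config, testSet, inputs)
    perRun <- rbind(perRun, data.frame(
      run = i, auroc = ev$auroc, auprc = ev$auprc,
      sensitivity = ev$sensitivity, specificity = ev$specificity
    ))
  }
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(perRun[[m]]), numeric(1)),
    sd = vapply(
      metrics,
      function(m) if (n > 1) stats::sd(perRun[[m]]) else 0,
      numeric(1)
    )
  )
  rownames(summary) <- NULL
  list(perRun = perRun, summary = summary)
}
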