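# Plain-text (JSON) checkpoint serialization: parameters, model
# configuration and featurizer vocabularies in one bundle.

.encodeParams <- function(x) {
  if (is.list(x)) {
    lapply(x, .encodeParams)
  } else if (is.matrix(x)) {
    list(`_dim` = dim(x), `_data` = as.numeric(x))
  } else {
    list(`_data` = as.numeric(x))
  }
}

.decodeParams <- function(x) {
  if (is.list(x) && !is.null(x[["_data"]])) {
    dat <- as.numeric(unlist(x[["_data"]]))
    dims <- as.integer(unlist(x[["_dim"]]))
    if (length(dims) == 2) matrix(dat, dims[1], dims[2]) else dat
  } else {
    lapply(x, .decodeParams)
  }
}

#' Save a model checkpoint as JSON
#'
#' Bundles parameters, the model configuration and the featurizer
#' vocabularies (element list and residue alphabet) so a checkpoint is
#' self-describing.
#'
#' @param params Model parameters.
#' @param config The [modelConfig()].
#' @param path Output `.json` path.
#' @param extra Optional named list of run metadata (e.g. seeds).
#' @return Invisibly, `path`.
#' @export
saveCheckpoint <- function(params, config, path, extra = list()) {
  bundle <- list(
    format = "ngnnDTI-checkpoint-1",
    config = unclass(config),
    vocab = list(
      atom_elements = ATOM_ELEMENTS,
      residue_alphabet = RESIDUE_ALPHABET
    ),
    params = .encodeParams(params),
    extra = extra
  )
  bundle$config$encoder <- unclass(bundle$config$encoder)
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint path written by [saveCheckpoint()].
#' @return List with `params`, `config`, `vocab`, `extra`.
#' @export
loadCheckpoint <- function(path) {
  bundle <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfgRaw <- bundle$config
  enc <- do.call(encoderConfig, cfgRaw$encoder[
    c("kHops", "nLayers", "hiddenDim", "activation", "useVirtualNode",
      "gcnMode")
  ])
  cfg <- do.call(modelConfig, c(
    list(encoder = enc),
    cfgRaw[c(
      "maxDrugLen", "maxProtLen", "mlpHidden", "dropout", "pooling",
      "useNgnn", "useCrossAft", "usePretrained", "drugEmbedDim",
      "protEmbedDim", "fusionDim"
    )]
  ))
  paramsRaw <- jsonlite::read_json(path, simplifyVector = FALSE)$params
  list(
    params = .decodeParams(paramsRaw),
    config = cfg,
    vocab = bundle$vocab,
    extra = bundle$extra
  )
}
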