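#' Create a run configuration
#'
#' Returns a \linkS4class{RunConfig} with the production defaults
#' (768-dimensional gene embeddings, 12 transformer layers with 12 attention
#' heads and 3072 intermediate features, a 512-dimensional shared alignment
#' space, orphan gene sets of size 110, batch size 32, pretraining learning
#' rate 5e-5 and contrastive learning rate 1e-5, cell filter at 200 genes,
#' gene filter at 0.1% of cells, total-count target 10000), overridden by
#' any named arguments.
#'
#' @param ... slot overrides, e.g. \code{embeddingDim = 32}.
#' @return A \linkS4class{RunConfig}.
#' @examples
#' cfg <- runConfig(embeddingDim = 64, nHeads = 4, nLayers = 2)
#' @export
runConfig <- function(...) {
  args <- list(...)
  cfg <- new("RunConfig")
  intSlots <- c("embeddingDim", "nLayers", "nHeads", "intermediateDim",
                "sharedDim", "textDim", "orphanSetSize", "batchSize",
                "minGenes", "seed")
  for (nm in names(args)) {
    if (!nm %in% slotNames("RunConfig"))
      stop("unknown RunConfig field: ", nm)
    val <- args[[nm]]
    if (nm %in% intSlots) val <- as.integer(val)
    slot(cfg, nm) <- val
  }
  validObject(cfg)
  cfg
}

#' Desk-scale configuration
#'
#' A small configuration (32-dim embeddings, 2 layers, 4 heads, 64
#' intermediate features, 32-dim shared space, temperature 0.05, no
#' dropout) suitable for
#' examples, tests and synthetic-data experiments on a single CPU. The
#' production geometry remains the \code{\link{runConfig}} default.
#'
#' @param ... overrides passed on to \code{\link{runConfig}}.
#' @export
tinyRunConfig <- function(...) {
  base <- list(embeddingDim = 32L, nLayers = 2L, nHeads = 4L,
               intermediateDim = 64L, sharedDim = 32L, textDim = 32L,
               orphanSetSize = 60L, batchSize = 8L,
               lrPretrain = 1e-3, lrContrastive = 1e-3,
               temperature = 0.05, dropout = 0)
  over <- list(...)
  base[names(over)] <- over
  do.call(runConfig, base)
}

# snake_case key used in config files -> slot name
.CONFIG_KEYS <- c(
  embedding_dim = "embeddingDim", n_layers = "nLayers", n_heads = "nHeads",
  intermediate_dim = "intermediateDim", shared_dim = "sharedDim",
  text_dim = "textDim", orphan_set_size = "orphanSetSize",
  batch_size = "batchSize", lr_pretrain = "lrPretrain",
  lr_contrastive = "lrContrastive", temperature = "temperature",
  dropout = "dropout", mask_rate = "maskRate", min_genes = "minGenes",
  min_cell_fraction = "minCellFraction", target_sum = "targetSum",
  seed = "seed")

#' Read a run configuration from YAML or JSON
#'
#' Accepts snake_case keys (\code{embedding_dim}, \code{n_layers}, ...) or
#' slot names; unknown keys are an error. The format is chosen by file
#' extension (.yaml/.yml vs .json).
#'
#' @param path config file path.
#' @return A \linkS4class{RunConfig}.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!length(vals)) return(runConfig())
  keys <- names(vals)
  mapped <- ifelse(keys %in% names(.CONFIG_KEYS), .CONFIG_KEYS[keys], keys)
  bad <- mapped[!mapped %in% slotNames("RunConfig")]
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  names(vals) <- mapped
  do.call(runConfig, vals)
}

#' Write a run configuration to YAML or JSON
#'
#' @param config a \linkS4class{RunConfig}.
#' @param path output file ending in .yaml/.yml or .json.
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(is(config, "RunConfig"))
  inv <- stats::setNames(names(.CONFIG_KEYS), .CONFIG_KEYS)
  vals <- lapply(slotNames("RunConfig"), function(s) slot(config, s))
  names(vals) <- inv[slotNames("RunConfig")]
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(vals, path)
  invisible(path)
}

setMethod("show", "RunConfig", function(object) {
  cat(sprintf(
    "RunConfig: D=%d, %d layers x %d heads, intermediate %d, shared %d\n",
    object@embeddingDim, object@nLayers, object@nHeads,
    object@intermediateDim, object@sharedDim))
  cat(sprintf("  batch K=%d, lr %.2g (pretrain) / %.2g (contrastive), tau=%g, dropout=%g\n",
              object@batchSize, object@lrPretrain, object@lrContrastive,
              object@temperature, object@dropout))
  cat(sprintf("  preprocessing: min_genes=%d, min_cell_fraction=%g, target_sum=%g\n",
              object@minGenes, object@minCellFraction, object@targetSum))
})
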