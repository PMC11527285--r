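# Checkpoint directory layout: manifest.json (dims, config, gene list,
# history, provenance, tensor shapes) + one plain-text file per tensor
# (one value per line, %.17g so doubles round-trip exactly).

write_tensor <- function(x, path) {
  writeLines(sprintf("%.17g", as.numeric(x)), path)
}

read_tensor <- function(path, dims) {
  v <- as.numeric(readLines(path))
  if (length(dims) > 1) array(v, dim = dims) else v
}

#' Save a model checkpoint to a directory
#'
#' @param model a `caps_model`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_checkpoint <- function(model, dir) {
  stopifnot(inherits(model, "caps_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- flat_params(model)
  shapes <- lapply(flat, function(x) if (is.null(dim(x))) length(x) else dim(x))
  manifest <- list(
    package = "capstx",
    dims = model$encoder$dims,
    n_heads = model$attention$n_heads,
    hidden_units = model$head$hidden_units,
    config = unclass(model$config),
    gene_ids = model$gene_ids,
    history = model$history,
    provenance = model$provenance,
    tensors = shapes)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (nm in names(flat))
    write_tensor(flat[[nm]], file.path(dir, paste0(nm, ".txt")))
  invisible(dir)
}

#' Load a model checkpoint from a directory
#'
#' @param dir directory written by [save_checkpoint()].
#' @return A `caps_model`.
#' @export
load_checkpoint <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  cfg <- do.call(train_config, mf$config[setdiff(names(mf$config), "verbose")])
  model <- with_seed(0L, init_model(mf$dims$n_genes, mf$gene_ids, cfg))
  flat <- flat_params(model)
  for (nm in names(flat)) {
    dims <- unlist(mf$tensors[[nm]])
    flat[[nm]] <- read_tensor(file.path(dir, paste0(nm, ".txt")), dims)
  }
  model <- set_flat_params(model, flat)
  model$history <- mf$history
  model$provenance <- as.list(mf$provenance)
  model
}
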