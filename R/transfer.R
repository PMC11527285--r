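#' Transfer-learning configuration
#'
#' Two-phase fine-tuning: phase 1 re-trains the dense head with the capsule
#' encoder and attention layers frozen; phase 2 unfreezes and trains the
#' entire network at a lower learning rate. By default a stratified 30% of
#' the target cohort is used for fine-tuning.
#'
#' @param phase1_epochs,phase2_epochs epoch counts (>= 0; at least one > 0).
#' @param phase1_lr,phase2_lr Adam learning rates (defaults 1e-3 and 1e-4).
#' @param fine_tune_fraction stratified fraction of the target used for
#'   fine-tuning (default 0.3).
#' @param batch_size mini-batch size (default 16; bulk cohorts are small).
#' @param seed RNG seed for the stratified subsample and shuffling.
#' @return A `transfer_config` list.
#' @export
transfer_config <- function(phase1_epochs = 10, phase2_epochs = 10,
                            phase1_lr = 1e-3, phase2_lr = 1e-4,
                            fine_tune_fraction = 0.3, batch_size = 16,
                            seed = 1) {
  stopifnot(phase1_epochs >= 0, phase2_epochs >= 0,
            phase1_epochs + phase2_epochs > 0,
            phase1_lr > 0, phase2_lr > 0,
            fine_tune_fraction > 0, fine_tune_fraction <= 1)
  structure(list(phase1_epochs = as.integer(phase1_epochs),
                 phase2_epochs = as.integer(phase2_epochs),
                 phase1_lr = phase1_lr, phase2_lr = phase2_lr,
                 fine_tune_fraction = fine_tune_fraction,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "transfer_config")
}

# names of the trainable tensors belonging to the dense head
head_tensor_names <- function() c("head_W1", "head_b1", "head_w2", "head_b2")

#' Re-initialize the classification head of a checkpoint
#'
#' Draws a fresh dense head from the seeded initializer; encoder and
#' attention tensors are returned bit-identical to the input.
#'
#' @param model a `caps_model`.
#' @param seed integer seed for the new head.
#' @return The checkpoint with a fresh head.
#' @export
reinit_head <- function(model, seed = 1) {
  stopifnot(inherits(model, "caps_model"))
  model$head <- with_seed(seed,
    init_head_params(model$head$input_dim, model$head$hidden_units))
  model$provenance$head_reinit_seed <- seed
  model
}

#' Two-phase fine-tuning on a target cohort
#'
#' Phase 1 freezes every encoder and attention tensor (their update is
#' exactly zero) and trains the dense head; phase 2 trains all parameters
#' with a fresh optimizer at `phase2_lr`. A stratified
#' `config$fine_tune_fraction` of the target is used for gradient updates;
#' the remainder serves as the validation stream recorded in the history.
#'
#' @param model a pretrained `caps_model` (typically after [reinit_head()]).
#' @param target a `labelled_dataset` with both classes, gene-alignable to
#'   the checkpoint.
#' @param config a [transfer_config()].
#' @return Fine-tuned `caps_model`; `provenance$phase1_frozen_delta` records
#'   the max absolute change of frozen tensors during phase 1 (always 0).
#' @export
fine_tune <- function(model, target, config = transfer_config()) {
  stopifnot(inherits(model, "caps_model"),
            inherits(target, "labelled_dataset"))
  if (length(unique(target$labels)) < 2)
    stop("target cohort contains a single class")
  Xv <- align_genes(model, target$matrix)
  y <- target$labels
  idx_ft <- with_seed(config$seed, stratified_sample(y, config$fine_tune_fraction))
  idx_rest <- setdiff(seq_along(y), idx_ft)
  if (length(idx_rest) < 2 || length(unique(y[idx_rest])) < 2)
    idx_rest <- idx_ft  # tiny cohorts: monitor on the tuning split itself
  Xft <- Xv[, idx_ft, drop = FALSE]; yft <- y[idx_ft]
  Xmon <- Xv[, idx_rest, drop = FALSE]; ymon <- y[idx_rest]
  if (length(unique(yft)) < 2)
    stop("fine-tuning split contains a single class")
  frozen <- setdiff(names(flat_params(model)), head_tensor_names())
  before <- flat_params(model)[frozen]
  model$history <- NULL
  with_seed(config$seed + 1L, {
    if (config$phase1_epochs > 0)
      model <- run_optimizer(model, Xft, yft, Xmon, ymon,
                             epochs = config$phase1_epochs,
                             lr = config$phase1_lr,
                             batch_size = config$batch_size,
                             patience = config$phase1_epochs,
                             frozen = frozen, early_stop = FALSE,
                             phase = "transfer_head")
    after <- flat_params(model)[frozen]
    model$provenance$phase1_frozen_delta <-
      max(mapply(function(a, b) max(abs(a - b)), before, after), 0)
    if (config$phase2_epochs > 0)
      model <- run_optimizer(model, Xft, yft, Xmon, ymon,
                             epochs = config$phase2_epochs,
                             lr = config$phase2_lr,
                             batch_size = config$batch_size,
                             patience = config$phase2_epochs,
                             early_stop = FALSE, phase = "transfer_full")
  })
  model$provenance$fine_tune_n <- length(idx_ft)
  model
}

# internal: stratified sample of a fraction of indices per label class
stratified_sample <- function(y, fraction) {
  sort(unlist(lapply(unique(y), function(cls) {
    idx <- which(y == cls)
    n <- max(1L, round(fraction * length(idx)))
    sample(idx, n)
  })))
}

#' Rotated cross-cohort transfer test
#'
#' For every cohort A, the pretrained checkpoint gets a fresh head, is
#' fine-tuned on A, and evaluated (AUROC, AUPRC) on every other cohort B.
#' The diagonal is not applicable. Cohorts with a single label class are
#' skipped with a recorded warning.
#'
#' @param model pretrained `caps_model`.
#' @param cohorts named list of `labelled_dataset`s over a shared gene space
#'   (length >= 2).
#' @param config a [transfer_config()].
#' @return List with `auroc` and `auprc` matrices (tuning cohort x test
#'   cohort, `NA` diagonal), `table` (long format), and `warnings`.
#' @export
rotated_test <- function(model, cohorts, config = transfer_config()) {
  stopifnot(is.list(cohorts), length(cohorts) >= 2,
            !is.null(names(cohorts)))
  nms <- names(cohorts)
  n <- length(nms)
  aur <- matrix(NA_real_, n, n, dimnames = list(tune = nms, test = nms))
  apr <- aur
  warns <- character()
  rows <- list()
  for (a in seq_len(n)) {
    ya <- cohorts[[a]]$labels
    if (length(unique(ya)) < 2) {
      warns <- c(warns, paste0("cohort ", nms[a],
                               " has a single class; skipped as tuning cohort"))
      next
    }
    m <- reinit_head(model, seed = config$seed + a)
    m <- fine_tune(m, cohorts[[a]], config)
    for (b in seq_len(n)) {
      if (b == a) next
      yb <- cohorts[[b]]$labels
      if (length(unique(yb)) < 2) {
        warns <- c(warns, paste0("cohort ", nms[b],
                                 " has a single class; skipped as test cohort"))
        next
      }
      p <- predict(m, cohorts[[b]]$matrix)
      aur[a, b] <- auroc(p, yb)
      apr[a, b] <- auprc(p, yb)
      rows[[length(rows) + 1L]] <-
        data.frame(tune_cohort = nms[a], test_cohort = nms[b],
                   auroc = aur[a, b], auprc = apr[a, b])
    }
  }
  list(auroc = aur, auprc = apr,
       table = if (length(rows)) do.call(rbind, rows) else
         data.frame(tune_cohort = character(), test_cohort = character(),
                    auroc = numeric(), auprc = numeric()),
       warnings = unique(warns))
}
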