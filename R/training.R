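#' Training configuration
#'
#' Defaults follow the reference protocol: 50 epochs, batch size 32, Adam
#' (lr 1e-3, beta 0.9/0.999, eps 1e-8), early stopping on validation loss
#' with patience 5 and best-weight restore, 3 routing iterations, sigmoid
#' hidden activation.
#'
#' @param epochs maximum training epochs (>= 1).
#' @param batch_size mini-batch size (>= 1).
#' @param learning_rate Adam learning rate.
#' @param early_stopping_patience epochs without validation improvement
#'   before stopping.
#' @param routing_iterations dynamic-routing iterations (default 3).
#' @param seed RNG seed controlling initialization and batch shuffling.
#' @param activation hidden activation of the dense head.
#' @param n_primary,n_capsules,d_p,d_c capsule architecture (defaults
#'   8 / 20 / 16 / 16).
#' @param n_heads attention heads (default 4).
#' @param hidden_units dense-head width (default 150).
#' @param softmax_axis routing softmax convention, see [dynamic_routing()].
#' @param beta1,beta2,adam_eps Adam moment parameters.
#' @param verbose print per-epoch progress.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 50, batch_size = 32, learning_rate = 1e-3,
                         early_stopping_patience = 5, routing_iterations = 3,
                         seed = 1, activation = c("sigmoid", "relu", "tanh"),
                         n_primary = 8, n_capsules = 20, d_p = 16, d_c = 16,
                         n_heads = 4, hidden_units = 150,
                         softmax_axis = c("input_capsules", "output_capsules"),
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         verbose = FALSE) {
  activation <- match.arg(activation)
  softmax_axis <- match.arg(softmax_axis)
  stopifnot(epochs >= 1, batch_size >= 1, early_stopping_patience >= 1,
            learning_rate >= 0, routing_iterations >= 1, n_primary >= 1,
            n_capsules >= 1, n_heads >= 1, hidden_units >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 early_stopping_patience = as.integer(early_stopping_patience),
                 routing_iterations = as.integer(routing_iterations),
                 seed = as.integer(seed), activation = activation,
                 n_primary = as.integer(n_primary),
                 n_capsules = as.integer(n_capsules),
                 d_p = as.integer(d_p), d_c = as.integer(d_c),
                 n_heads = as.integer(n_heads),
                 hidden_units = as.integer(hidden_units),
                 softmax_axis = softmax_axis, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Binary cross-entropy loss
#'
#' L = -(1/N) sum(y log p + (1 - y) log(1 - p)), with probabilities clamped
#' to `[1e-7, 1 - 1e-7]` for numerical stability.
#'
#' @param y binary labels.
#' @param p predicted probabilities (same length).
#' @return Non-negative scalar loss.
#' @export
bce_loss <- function(y, p) {
  if (length(y) != length(p))
    stop("length mismatch: ", length(y), " labels vs ", length(p),
         " probabilities")
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# internal: initialize a full model under the current RNG stream
init_model <- function(n_genes, gene_ids, cfg) {
  enc <- init_capsule_params(n_genes, P = cfg$n_primary, J = cfg$n_capsules,
                             d_p = cfg$d_p, d_c = cfg$d_c,
                             gene_ids = gene_ids)
  att <- init_attention_params(d_c = cfg$d_c, n_heads = cfg$n_heads)
  head <- init_head_params(cfg$n_capsules * cfg$d_c * cfg$n_heads,
                           cfg$hidden_units)
  structure(list(encoder = enc, attention = att, head = head,
                 gene_ids = gene_ids, config = cfg,
                 history = NULL, provenance = list()),
            class = "caps_model")
}

#' @export
print.caps_model <- function(x, ...) {
  d <- x$encoder$dims
  cat("<caps_model> ", d$n_genes, " genes -> ", d$P, " primary capsules (d_p=",
      d$d_p, ") -> ", d$J, " capsules (d_c=", d$d_c, ") -> ",
      x$attention$n_heads, "-head attention -> dense(",
      x$head$hidden_units, ") -> sigmoid\n", sep = "")
  if (!is.null(x$history))
    cat("  trained ", nrow(x$history), " epochs; final val loss ",
        signif(utils::tail(x$history$val_loss, 1), 4), "\n", sep = "")
  invisible(x)
}

# internal: predict probabilities from a model on a plain matrix, in chunks
predict_matrix <- function(model, Xv, chunk = 256L) {
  n <- ncol(Xv)
  p <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    p[i:j] <- model_forward(model, Xv[, i:j, drop = FALSE])$p
    i <- j + 1L
  }
  names(p) <- colnames(Xv)
  p
}

# internal: one optimization run over (Xtr, ytr) with optional frozen tensors;
# shared by train_capsnet and the two fine-tuning phases.
run_optimizer <- function(model, Xtr, ytr, Xval, yval, epochs, lr,
                          batch_size, patience, frozen = character(),
                          early_stop = TRUE, verbose = FALSE,
                          phase = NA_character_) {
  cfg <- model$config
  flat <- flat_params(model)
  state <- adam_init(flat)
  n <- length(ytr)
  best <- list(loss = Inf, flat = flat, epoch = 0L)
  bad <- 0L
  hist <- list()
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tr_losses <- numeric(0)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      Xb <- Xtr[, idx, drop = FALSE]
      yb <- ytr[idx]
      fwd <- model_forward(model, Xb, keep_cache = TRUE)
      loss <- bce_loss(yb, fwd$p)
      if (!is.finite(loss))
        stop("non-finite loss at epoch ", ep, ", batch starting at ", start)
      grads <- model_backward(model, fwd, Xb, yb)
      upd <- adam_step(flat, grads, state, lr, cfg$beta1, cfg$beta2,
                       cfg$adam_eps, frozen = frozen)
      flat <- upd$flat
      state <- upd$state
      model <- set_flat_params(model, flat)
      tr_losses <- c(tr_losses, loss)
    }
    pval <- predict_matrix(model, Xval)
    vloss <- bce_loss(yval, pval)
    vauc <- if (length(unique(yval)) == 2) auroc(pval, yval) else NA_real_
    hist[[ep]] <- data.frame(epoch = ep, phase = phase,
                             train_loss = mean(tr_losses), val_loss = vloss,
                             val_auroc = vauc)
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %.4f auc %.3f", ep,
                      mean(tr_losses), vloss, vauc))
    if (vloss < best$loss - 1e-12) {
      best <- list(loss = vloss, flat = flat, epoch = ep)
      bad <- 0L
    } else bad <- bad + 1L
    if (early_stop && bad >= patience) break
  }
  if (early_stop) model <- set_flat_params(model, best$flat)
  model$history <- rbind(model$history, do.call(rbind, hist))
  model
}

#' Train the capsule + attention classifier
#'
#' End-to-end training with mini-batch Adam on the binary cross-entropy
#' loss, per-epoch validation, and early stopping with best-weight restore.
#' All randomness (initialization, shuffling) derives from `config$seed`, so
#' identical seed/config/data reproduce the identical checkpoint.
#'
#' @param train,val `labelled_dataset`s sharing the same gene order. The
#'   training set must contain both classes.
#' @param config a [train_config()].
#' @return A `caps_model` checkpoint with `encoder`, `attention`, `head`,
#'   `gene_ids`, `config`, per-epoch `history` and `provenance`.
#' @export
train_capsnet <- function(train, val, config = train_config()) {
  stopifnot(inherits(train, "labelled_dataset"),
            inherits(val, "labelled_dataset"))
  if (!identical(train$matrix$gene_ids, val$matrix$gene_ids))
    stop("train and val gene order differ")
  if (length(unique(train$labels)) < 2)
    stop("training labels contain a single class")
  gene_ids <- train$matrix$gene_ids
  with_seed(config$seed, {
    model <- init_model(length(gene_ids), gene_ids, config)
    model <- run_optimizer(model, train$matrix$values, train$labels,
                           val$matrix$values, val$labels,
                           epochs = config$epochs,
                           lr = config$learning_rate,
                           batch_size = config$batch_size,
                           patience = config$early_stopping_patience,
                           verbose = config$verbose, phase = "pretrain")
    model$provenance <- list(seed = config$seed,
                             n_train = length(train$labels),
                             n_val = length(val$labels),
                             data_hash = digest_matrix(train$matrix$values))
    model
  })
}

# internal: cheap deterministic content hash of a numeric matrix
digest_matrix <- function(v) {
  s <- sum(v) + sum(v * seq_along(v) %% 97)
  sprintf("%.10e_%dx%d", s, nrow(v), ncol(v))
}

# internal: align an expr_matrix (or plain matrix) to a model's gene order
align_genes <- function(model, X) {
  if (inherits(X, "expr_matrix")) {
    if (identical(X$gene_ids, model$gene_ids)) return(X$values)
    idx <- match(model$gene_ids, X$gene_ids)
    if (anyNA(idx)) {
      miss <- model$gene_ids[is.na(idx)]
      stop(length(miss), " model genes missing from input; first: ",
           paste(utils::head(miss, 10), collapse = ", "))
    }
    return(X$values[idx, , drop = FALSE])
  }
  Xv <- as.matrix(X)
  if (nrow(Xv) != length(model$gene_ids))
    stop("expected ", length(model$gene_ids), " genes, got ", nrow(Xv))
  Xv
}

#' Predict case probabilities
#'
#' @param object a trained `caps_model`.
#' @param newdata an `expr_matrix` (genes reordered to the checkpoint's gene
#'   list; an error lists missing genes) or a plain genes-by-samples matrix
#'   already in checkpoint order.
#' @param ... unused.
#' @return Named vector of probabilities in (0, 1).
#' @export
predict.caps_model <- function(object, newdata, ...) {
  Xv <- align_genes(object, newdata)
  predict_matrix(object, Xv)
}

#' Stratified k-fold cross-validation over a hyperparameter grid
#'
#' Folds are stratified by label under `config$seed`. For every grid point
#' and fold, a model is trained on the remaining folds (with an internal 90/10
#' train/validation sub-split for early stopping) and scored on the held-out
#' fold.
#'
#' @param d a `labelled_dataset`.
#' @param config base [train_config()].
#' @param grid named list of config fields to sweep, e.g.
#'   `list(n_capsules = c(10, 20), activation = c("sigmoid", "relu"))`.
#' @param k number of folds (default 5).
#' @return List with `folds` (one row per grid point x fold: fold, the grid
#'   fields, `auroc`, `auprc`) and `summary` (mean and sd per grid point).
#' @export
crossvalidate <- function(d, config = train_config(), grid = list(), k = 5) {
  stopifnot(inherits(d, "labelled_dataset"), k >= 2)
  y <- d$labels
  if (min(table(y)) < k)
    stop("not enough samples of each class for ", k, " folds")
  fold <- integer(length(y))
  with_seed(config$seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  gpts <- if (length(grid)) expand.grid(grid, stringsAsFactors = FALSE)
          else data.frame(.default = TRUE)
  rows <- list()
  for (g in seq_len(nrow(gpts))) {
    cfg <- config
    if (length(grid))
      for (nm in names(grid)) cfg[[nm]] <- gpts[[nm]][g]
    for (f in seq_len(k)) {
      tr_idx <- which(fold != f)
      te_idx <- which(fold == f)
      inner <- with_seed(cfg$seed + f, {
        ord <- sample(tr_idx)
        nv <- max(1L, floor(0.1 * length(ord)))
        list(val = sort(ord[seq_len(nv)]), train = sort(ord[-seq_len(nv)]))
      })
      m <- train_capsnet(ds_subset(d, inner$train), ds_subset(d, inner$val),
                         cfg)
      p <- predict_matrix(m, d$matrix$values[, te_idx, drop = FALSE])
      yt <- y[te_idx]
      if (length(unique(yt)) < 2)
        stop("fold ", f, " contains a single class")
      row <- data.frame(fold = f, auroc = auroc(p, yt), auprc = auprc(p, yt))
      if (length(grid)) row <- cbind(gpts[g, , drop = FALSE], row,
                                     row.names = NULL)
      rows[[length(rows) + 1L]] <- row
    }
  }
  folds <- do.call(rbind, rows)
  by_cols <- setdiff(colnames(folds), c("fold", "auroc", "auprc"))
  summary <- if (length(by_cols)) {
    agg <- stats::aggregate(folds[c("auroc", "auprc")], folds[by_cols],
                            function(x) c(mean = mean(x), sd = stats::sd(x)))
    do.call(data.frame, agg)
  } else {
    data.frame(auroc.mean = mean(folds$auroc), auroc.sd = stats::sd(folds$auroc),
               auprc.mean = mean(folds$auprc), auprc.sd = stats::sd(folds$auprc))
  }
  list(folds = folds, summary = summary)
}
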