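#' Per-gene weights of the primary capsules
#'
#' Aggregates, for each gene g and primary capsule i, column g of W_i over
#' the d_p rows: `l2_norm` (default), `mean_abs`, or `signed_mean` (for
#' sign-aware displays).
#'
#' @param params a `capsule_params` (or a `caps_model`, whose encoder is
#'   used).
#' @param aggregation reduction over the d_p rows of each W_i.
#' @return A `gene_importance` object: `gene_ids`, `importance` (matrix
#'   n_genes x P), `aggregation_tag`.
#' @export
primary_capsule_gene_weights <- function(params,
                                         aggregation = c("l2_norm", "mean_abs",
                                                         "signed_mean")) {
  aggregation <- match.arg(aggregation)
  if (inherits(params, "caps_model")) params <- params$encoder
  stopifnot(inherits(params, "capsule_params"))
  agg <- switch(aggregation,
                l2_norm = function(W) sqrt(colSums(W^2)),
                mean_abs = function(W) colMeans(abs(W)),
                signed_mean = function(W) colMeans(W))
  imp <- vapply(params$primary_weights, agg,
                numeric(params$dims$n_genes))
  gene_ids <- params$gene_ids %||% paste0("gene_", seq_len(params$dims$n_genes))
  rownames(imp) <- gene_ids
  colnames(imp) <- paste0("primary_", seq_len(params$dims$P))
  structure(list(gene_ids = gene_ids, importance = imp,
                 aggregation_tag = aggregation),
            class = "gene_importance")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select important genes per primary capsule
#'
#' A gene belongs to a capsule's set iff its aggregated weight exceeds
#' `threshold` in absolute value (strict inequality; default 0.06). Also
#' reports the cross-capsule membership pattern counts (upset-style).
#'
#' @param imp a `gene_importance` from [primary_capsule_gene_weights()].
#' @param threshold positive selection threshold (default 0.06).
#' @return List with `sets` (per-capsule gene id vectors), `membership`
#'   (logical matrix genes x capsules) and `combo_counts` (named counts of
#'   non-empty membership patterns).
#' @export
important_genes <- function(imp, threshold = 0.06) {
  stopifnot(inherits(imp, "gene_importance"), threshold > 0)
  mem <- abs(imp$importance) > threshold
  sets <- lapply(seq_len(ncol(mem)), function(i) imp$gene_ids[mem[, i]])
  names(sets) <- colnames(mem)
  pat <- apply(mem, 1, function(r)
    paste(colnames(mem)[r], collapse = "&"))
  pat <- pat[nzchar(pat)]
  combo <- if (length(pat)) sort(table(pat), decreasing = TRUE) else table(character())
  list(sets = sets, membership = mem, combo_counts = combo)
}

# internal: capsule output norms (J x B) for a plain matrix
capsule_norms <- function(model, Xv) {
  cfg <- model$config
  fw <- encoder_forward(model$encoder, Xv, cfg$routing_iterations,
                        cfg$softmax_axis, keep_trace = FALSE)
  d <- model$encoder$dims
  matrix(sqrt(colSums(matrix(fw$V^2, nrow = d$d_c))), d$J, ncol(Xv))
}

#' Occlusion / activation attribution of genes to capsules
#'
#' For every gene, measures the mean change in each output capsule's norm
#' over the reference samples when that single gene is perturbed:
#' `occlude_single` compares the unperturbed pass to one with the gene set
#' to baseline (a positive score means the gene activates the capsule);
#' `activate_single` compares baseline-everything-except-the-gene to
#' baseline-everything. The enumeration covers every gene.
#'
#' @param model a trained `caps_model`.
#' @param reference an `expr_matrix` (aligned to the model) of reference
#'   samples.
#' @param capsule_index output capsule to attribute, or `NULL` for all.
#' @param mode `"occlude_single"` or `"activate_single"`.
#' @param baseline `"zero"` (log-scale zero, default) or `"mean"`
#'   (per-gene reference mean).
#' @return If `capsule_index` is given, a `capsule_attribution`:
#'   `capsule_index`, named `score` per gene, `baseline_tag`, `mode`.
#'   Otherwise a genes x capsules score matrix.
#' @export
capsule_activation_test <- function(model, reference, capsule_index = NULL,
                                    mode = c("occlude_single",
                                             "activate_single"),
                                    baseline = c("zero", "mean")) {
  mode <- match.arg(mode)
  baseline <- match.arg(baseline)
  stopifnot(inherits(model, "caps_model"))
  Xv <- align_genes(model, reference)
  d <- model$encoder$dims
  J <- d$J
  if (!is.null(capsule_index) &&
      (capsule_index < 1 || capsule_index > J))
    stop("capsule index out of range 1..", J)
  base_vec <- if (baseline == "zero") numeric(nrow(Xv)) else rowMeans(Xv)
  n_genes <- nrow(Xv); B <- ncol(Xv)
  scores <- matrix(0, n_genes, J,
                   dimnames = list(model$gene_ids,
                                   paste0("capsule_", seq_len(J))))
  if (mode == "occlude_single") {
    ref_norm <- capsule_norms(model, Xv)           # J x B
    for (g in seq_len(n_genes)) {
      Xg <- Xv
      Xg[g, ] <- base_vec[g]
      scores[g, ] <- rowMeans(ref_norm - capsule_norms(model, Xg))
    }
  } else {
    Xbase <- matrix(base_vec, n_genes, B)
    base_norm <- capsule_norms(model, Xbase)
    for (g in seq_len(n_genes)) {
      Xg <- Xbase
      Xg[g, ] <- Xv[g, ]
      scores[g, ] <- rowMeans(capsule_norms(model, Xg) - base_norm)
    }
  }
  if (is.null(capsule_index)) return(scores)
  structure(list(capsule_index = as.integer(capsule_index),
                 score = stats::setNames(scores[, capsule_index],
                                         rownames(scores)),
                 baseline_tag = baseline, mode = mode),
            class = "capsule_attribution")
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test P[X >= k] for the overlap k between a
#' query gene set (n draws) and each collection set (K successes) in a
#' universe of N genes, with multiple-testing correction across the
#' collection (Benjamini-Hochberg by default). Rows are sorted by p-value.
#'
#' @param query character vector of query genes; must be a subset of
#'   `universe`.
#' @param collection a `gene_set_collection`; sets are intersected with the
#'   universe.
#' @param universe character vector of background genes.
#' @param correction `"bh"`, `"bonferroni"` or `"none"`.
#' @return data.frame with `set_name`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p_value`, `adjusted_p`.
#' @export
hypergeometric_enrichment <- function(query, collection, universe,
                                      correction = c("bh", "bonferroni",
                                                     "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe")
  query <- unique(as.character(query))
  if (!all(query %in% universe))
    stop("query contains genes outside the universe: ",
         paste(utils::head(setdiff(query, universe), 5), collapse = ", "))
  N <- length(universe); n <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    set <- intersect(collection$sets[[nm]], universe)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, set_size = K, query_size = n,
               universe_size = N, p_value = p)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- switch(correction,
                           bh = stats::p.adjust(out$p_value, "BH"),
                           bonferroni = stats::p.adjust(out$p_value,
                                                        "bonferroni"),
                           none = out$p_value)
  out[order(out$p_value), , drop = FALSE]
}

#' Capsule-pathway network
#'
#' Runs enrichment of each capsule's gene set against the collection and
#' keeps edges with BH-adjusted p below `alpha`. Nodes are typed `capsule`
#' or `pathway`; an empty edge table is allowed.
#'
#' @param attributions named list mapping capsule name to its gene set.
#' @param collection a `gene_set_collection`.
#' @param universe background gene vector.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return List with `nodes` (name, type) and `edges` (capsule, pathway,
#'   adjusted_p, overlap).
#' @export
capsule_pathway_network <- function(attributions, collection, universe,
                                    alpha = 0.05) {
  stopifnot(is.list(attributions), length(attributions) >= 1,
            !is.null(names(attributions)))
  edges <- list()
  for (cap in names(attributions)) {
    genes <- intersect(attributions[[cap]], universe)
    if (length(genes) == 0) next
    enr <- hypergeometric_enrichment(genes, collection, universe,
                                     correction = "bh")
    sig <- enr[enr$adjusted_p < alpha, , drop = FALSE]
    if (nrow(sig))
      edges[[cap]] <- data.frame(capsule = cap, pathway = sig$set_name,
                                 adjusted_p = sig$adjusted_p,
                                 overlap = sig$overlap)
  }
  edges <- if (length(edges)) do.call(rbind, c(edges, make.row.names = FALSE))
           else data.frame(capsule = character(), pathway = character(),
                           adjusted_p = numeric(), overlap = integer())
  nodes <- rbind(
    data.frame(name = names(attributions), type = "capsule"),
    if (nrow(edges)) data.frame(name = unique(edges$pathway),
                                type = "pathway"))
  list(nodes = nodes, edges = edges)
}
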