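#' Construct capsule-encoder parameters
#'
#' The encoder has two layers: a linear layer mapping the full gene vector
#' into `P` primary capsules (u_i = W_i x, each W_i of shape d_p x n_genes)
#' and a capsule layer of `J` output capsules of dimension `d_c` computed by
#' dynamic routing over prediction vectors u_hat(j|i) = w_ij u_i. Defaults
#' follow the reference architecture: 8 primary capsules, 20 output capsules
#' of 16 dimensions, with d_p = 16.
#'
#' @param primary_weights list of `P` matrices, each `d_p x n_genes`.
#' @param routing_weights 4-d array of shape `(P, J, d_c, d_p)`.
#' @param gene_ids optional gene list bound to the input dimension.
#' @return An object of class `capsule_params`.
#' @export
capsule_params <- function(primary_weights, routing_weights, gene_ids = NULL) {
  stopifnot(is.list(primary_weights), length(primary_weights) >= 1)
  P <- length(primary_weights)
  d_p <- nrow(primary_weights[[1]])
  n_genes <- ncol(primary_weights[[1]])
  for (W in primary_weights)
    if (!is.matrix(W) || nrow(W) != d_p || ncol(W) != n_genes ||
        !all(is.finite(W)))
      stop("primary_weights must be finite matrices of equal shape d_p x n_genes")
  dw <- dim(routing_weights)
  if (length(dw) != 4 || dw[1] != P || dw[4] != d_p)
    stop("routing_weights must have shape (P, J, d_c, d_p) = (", P,
         ", J, d_c, ", d_p, ")")
  if (!all(is.finite(routing_weights))) stop("non-finite routing weight")
  J <- dw[2]; d_c <- dw[3]
  if (!is.null(gene_ids) && length(gene_ids) != n_genes)
    stop("gene_ids length != n_genes")
  structure(list(primary_weights = primary_weights,
                 routing_weights = routing_weights,
                 gene_ids = gene_ids,
                 dims = list(P = P, J = J, d_p = d_p, d_c = d_c,
                             n_genes = n_genes)),
            class = "capsule_params")
}

#' Initialize capsule-encoder parameters
#'
#' Weights are drawn from a fan-in-scaled uniform distribution
#' U(-1/sqrt(fan_in), 1/sqrt(fan_in)) using the current RNG stream.
#'
#' @param n_genes input dimension.
#' @param P number of primary capsules (default 8).
#' @param J number of output capsules (default 20).
#' @param d_p primary capsule dimension (default 16).
#' @param d_c output capsule dimension (default 16).
#' @param gene_ids optional gene list.
#' @return A `capsule_params` object.
#' @export
init_capsule_params <- function(n_genes, P = 8, J = 20, d_p = 16, d_c = 16,
                                gene_ids = NULL) {
  lim1 <- 1 / sqrt(n_genes)
  pw <- lapply(seq_len(P), function(i)
    matrix(stats::runif(d_p * n_genes, -lim1, lim1), d_p, n_genes))
  lim2 <- 1 / sqrt(d_p)
  rw <- array(stats::runif(P * J * d_c * d_p, -lim2, lim2),
              dim = c(P, J, d_c, d_p))
  capsule_params(pw, rw, gene_ids)
}

#' Squashing nonlinearity
#'
#' Maps a vector s to (||s||^2 / (1 + ||s||^2)) * (s / ||s||): the norm is
#' compressed into `[0, 1)` while the direction is preserved. The zero vector
#' maps to the zero vector via an epsilon guard in the norm denominator.
#'
#' @param s finite numeric vector.
#' @param eps denominator guard (default 1e-8).
#' @return Squashed vector of the same length.
#' @export
squash <- function(s, eps = 1e-8) {
  if (!all(is.finite(s))) stop("non-finite input to squash")
  r <- sqrt(sum(s^2))
  s * (r^2 / (1 + r^2)) / max(r, eps)
}

#' Primary capsules of one expression vector
#'
#' @param x numeric gene vector of length `n_genes`.
#' @param params a `capsule_params`.
#' @return List of `P` primary capsule vectors u_i = W_i x.
#' @export
primary_capsules <- function(x, params) {
  stopifnot(inherits(params, "capsule_params"))
  if (length(x) != params$dims$n_genes)
    stop("expected gene vector of length ", params$dims$n_genes,
         ", got ", length(x))
  lapply(params$primary_weights, function(W) drop(W %*% x))
}

#' Prediction vectors u_hat(j|i) = w_ij u_i
#'
#' @param u list of `P` primary capsule vectors (length `d_p` each).
#' @param params a `capsule_params`.
#' @return Array of shape `(P, J, d_c)`. Constant across routing iterations.
#' @export
prediction_vectors <- function(u, params) {
  stopifnot(inherits(params, "capsule_params"))
  d <- params$dims
  if (length(u) != d$P) stop("expected ", d$P, " primary capsules")
  uhat <- array(0, dim = c(d$P, d$J, d$d_c))
  for (i in seq_len(d$P)) {
    if (length(u[[i]]) != d$d_p) stop("primary capsule ", i, " has wrong length")
    for (j in seq_len(d$J))
      uhat[i, j, ] <- params$routing_weights[i, j, , ] %*% u[[i]]
  }
  uhat
}

# internal: softmax of a matrix along rows (axis = 1 normalizes over rows,
# i.e. each column sums to 1) with max-shift stabilization
softmax_mat <- function(b, axis) {
  if (axis == 1L) {
    e <- exp(sweep(b, 2, apply(b, 2, max), "-"))
    sweep(e, 2, colSums(e), "/")
  } else {
    e <- exp(sweep(b, 1, apply(b, 1, max), "-"))
    sweep(e, 1, rowSums(e), "/")
  }
}

#' Dynamic routing-by-agreement
#'
#' Routing logits start at zero; each iteration computes coupling
#' coefficients c = softmax(b), the weighted sums s_j = sum_i c_ij
#' u_hat(j|i), the squashed outputs v_j, and the agreement update
#' b_ij <- b_ij + u_hat(j|i) . v_j. After `n_iterations` (default 3) the
#' current v is the capsule output. Coefficients are recomputed every forward
#' pass and are not trainable parameters.
#'
#' @param uhat array `(P, J, d_c)` of prediction vectors.
#' @param n_iterations number of routing iterations (>= 1, default 3).
#' @param softmax_axis `"input_capsules"` normalizes c over i for each j (the
#'   printed c_ij = e^b_ij / sum_i e^b_ij); `"output_capsules"` normalizes
#'   over j for each i (the original routing-by-agreement convention).
#' @return List with `v` (matrix `J x d_c`) and `trace`, a list of per-
#'   iteration states (fields `iteration`, `b`, `c`, `s`, `v`; `b` is the
#'   logit matrix after that iteration's agreement update).
#' @export
dynamic_routing <- function(uhat, n_iterations = 3,
                            softmax_axis = c("input_capsules",
                                             "output_capsules")) {
  softmax_axis <- match.arg(softmax_axis)
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  d <- dim(uhat)
  stopifnot(length(d) == 3)
  P <- d[1]; J <- d[2]; d_c <- d[3]
  axis <- if (softmax_axis == "input_capsules") 1L else 2L
  b <- matrix(0, P, J)
  trace <- vector("list", n_iterations)
  v <- NULL
  for (t in seq_len(n_iterations)) {
    cc <- softmax_mat(b, axis)
    s <- matrix(0, J, d_c)
    for (j in seq_len(J))
      s[j, ] <- colSums(cc[, j] * matrix(uhat[, j, ], nrow = P))
    v <- t(apply(s, 1, squash))
    if (any(!is.finite(v)))
      stop("NaN during dynamic routing at iteration ", t)
    agree <- matrix(0, P, J)
    for (j in seq_len(J))
      agree[, j] <- matrix(uhat[, j, ], nrow = P) %*% v[j, ]
    b <- b + agree
    trace[[t]] <- structure(list(iteration = t, b = b, c = cc, s = s, v = v),
                            class = "routing_state")
  }
  list(v = v, trace = trace)
}

#' Encode expression profiles into output capsules
#'
#' Composes primary capsules, prediction vectors and dynamic routing for each
#' sample of a batch. Batch processing is mathematically identical to
#' per-sample processing.
#'
#' @param X an `expr_matrix` or plain genes-by-samples numeric matrix whose
#'   gene order matches `params`.
#' @param params a `capsule_params`.
#' @param n_iterations routing iterations (default 3).
#' @param softmax_axis see [dynamic_routing()].
#' @return Array of shape `(samples, J, d_c)` with sample/capsule dimnames.
#' @export
encode_capsules <- function(X, params, n_iterations = 3,
                            softmax_axis = c("input_capsules",
                                             "output_capsules")) {
  softmax_axis <- match.arg(softmax_axis)
  stopifnot(inherits(params, "capsule_params"))
  if (inherits(X, "expr_matrix")) {
    if (!is.null(params$gene_ids)) {
      bad <- which(X$gene_ids != params$gene_ids)
      if (length(params$gene_ids) != length(X$gene_ids) || length(bad))
        stop("gene list mismatch; first discrepancy at position ",
             if (length(bad)) bad[1] else "length")
    }
    Xv <- X$values
  } else Xv <- as.matrix(X)
  if (nrow(Xv) != params$dims$n_genes)
    stop("expected ", params$dims$n_genes, " genes, got ", nrow(Xv))
  fw <- encoder_forward(params, Xv, n_iterations, softmax_axis,
                        keep_trace = FALSE)
  d <- params$dims
  out <- aperm(fw$V, c(3, 2, 1))  # (B, J, d_c)
  dimnames(out) <- list(colnames(Xv), paste0("capsule_", seq_len(d$J)), NULL)
  out
}
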