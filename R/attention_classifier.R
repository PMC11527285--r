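#' Construct multi-head attention parameters
#'
#' Each head carries full-width projection matrices W_q, W_k, W_v of shape
#' `d_c x d_c`; queries/keys/values are formed as Q = V' W_q', etc., with the
#' capsule outputs V' as rows. The key dimension d_k equals the capsule
#' dimension (default 16).
#'
#' @param Wq,Wk,Wv arrays of shape `(d_c, d_c, n_heads)`.
#' @return An `attention_params` object.
#' @export
attention_params <- function(Wq, Wk, Wv) {
  d <- dim(Wq)
  if (length(d) != 3 || d[1] != d[2]) stop("Wq must be (d_c, d_c, n_heads)")
  if (!identical(dim(Wk), d) || !identical(dim(Wv), d))
    stop("Wq, Wk, Wv must share shapes")
  if (!all(is.finite(Wq), is.finite(Wk), is.finite(Wv)))
    stop("non-finite attention weight")
  structure(list(Wq = Wq, Wk = Wk, Wv = Wv,
                 d_c = d[1], n_heads = d[3], d_k = d[1]),
            class = "attention_params")
}

#' Initialize attention parameters
#' @param d_c capsule dimension (and d_k; default 16).
#' @param n_heads number of attention heads (default 4).
#' @return An `attention_params` drawn fan-in uniform from the current RNG.
#' @export
init_attention_params <- function(d_c = 16, n_heads = 4) {
  if (n_heads < 1) stop("n_heads must be >= 1")
  lim <- 1 / sqrt(d_c)
  draw <- function() array(stats::runif(d_c * d_c * n_heads, -lim, lim),
                           dim = c(d_c, d_c, n_heads))
  attention_params(draw(), draw(), draw())
}

#' Scaled dot-product attention
#'
#' Computes softmax(Q K' / sqrt(d_k)) V with the softmax applied row-wise, so
#' every attention-weight row sums to 1.
#'
#' @param Q,K,V numeric matrices of shape `J x d_k`.
#' @param d_k key dimension used for scaling (> 0).
#' @return `J x d_k` matrix of attended values.
#' @export
scaled_dot_attention <- function(Q, K, V, d_k = ncol(Q)) {
  if (d_k <= 0) stop("d_k must be positive")
  stopifnot(is.matrix(Q), is.matrix(K), is.matrix(V),
            identical(dim(Q), dim(K)), nrow(K) == nrow(V))
  E <- Q %*% t(K) / sqrt(d_k)
  A <- softmax_mat(E, axis = 2L)  # rows sum to 1
  A %*% V
}

#' Multi-head self-attention over capsule outputs
#'
#' Per head h: Z_h = attention(V' Wq_h', V' Wk_h', V' Wv_h'). Head outputs are
#' concatenated in head order, each flattened row-major (capsule-major), into
#' a single vector of length `J * d_c * n_heads`.
#'
#' @param Vp capsule output matrix `J x d_c` (capsules as rows).
#' @param params an `attention_params`.
#' @return Numeric vector of length `J * d_c * n_heads`.
#' @export
multi_head_attention <- function(Vp, params) {
  stopifnot(inherits(params, "attention_params"), is.matrix(Vp))
  if (ncol(Vp) != params$d_c)
    stop("capsule dimension mismatch: got ", ncol(Vp), ", expected ",
         params$d_c)
  out <- lapply(seq_len(params$n_heads), function(h) {
    Q <- Vp %*% t(params$Wq[, , h])
    K <- Vp %*% t(params$Wk[, , h])
    V <- Vp %*% t(params$Wv[, , h])
    Z <- scaled_dot_attention(Q, K, V, params$d_k)
    as.vector(t(Z))  # row-major: capsule-major flatten
  })
  unlist(out, use.names = FALSE)
}

#' Construct dense classifier-head parameters
#'
#' A hidden layer of `hidden_units` neurons (default 150) with a configurable
#' activation, followed by a single logistic output unit.
#'
#' @param W1 `hidden x input` matrix; @param b1 hidden bias vector.
#' @param w2 length-`hidden` output weights; @param b2 scalar output bias.
#' @return A `head_params` object.
#' @export
head_params <- function(W1, b1, w2, b2) {
  stopifnot(is.matrix(W1), length(b1) == nrow(W1), length(w2) == nrow(W1),
            length(b2) == 1, all(is.finite(W1)), all(is.finite(b1)),
            all(is.finite(w2)), is.finite(b2))
  structure(list(W1 = W1, b1 = as.numeric(b1), w2 = as.numeric(w2),
                 b2 = as.numeric(b2),
                 hidden_units = nrow(W1), input_dim = ncol(W1)),
            class = "head_params")
}

#' Initialize classifier-head parameters
#' @param input_dim flattened attention output length (`J * d_c * n_heads`).
#' @param hidden_units hidden layer width (default 150).
#' @return A `head_params` drawn fan-in uniform from the current RNG.
#' @export
init_head_params <- function(input_dim, hidden_units = 150) {
  l1 <- 1 / sqrt(input_dim)
  l2 <- 1 / sqrt(hidden_units)
  head_params(matrix(stats::runif(hidden_units * input_dim, -l1, l1),
                     hidden_units, input_dim),
              stats::runif(hidden_units, -l1, l1),
              stats::runif(hidden_units, -l2, l2),
              stats::runif(1, -l2, l2))
}

# internal: activation and its derivative as a function of the activation value
activation_fun <- function(name) {
  switch(name,
         sigmoid = list(f = function(x) stats::plogis(x),
                        dfda = function(a) a * (1 - a)),
         relu = list(f = function(x) pmax(x, 0),
                     dfda = function(a) as.numeric(a > 0)),
         tanh = list(f = function(x) tanh(x),
                     dfda = function(a) 1 - a^2),
         stop("unknown activation: ", name))
}

#' Classify a flattened attention output
#'
#' hidden = activation(W1 z + b1); p = logistic(w2 . hidden + b2). The output
#' probability is strictly inside (0, 1) for finite inputs.
#'
#' @param z numeric vector matching the head's input dimension.
#' @param head a `head_params`.
#' @param activation hidden activation: `"sigmoid"` (default), `"relu"`,
#'   `"tanh"`.
#' @return Scalar probability in (0, 1).
#' @export
classify <- function(z, head, activation = c("sigmoid", "relu", "tanh")) {
  activation <- match.arg(activation)
  stopifnot(inherits(head, "head_params"))
  if (length(z) != head$input_dim)
    stop("input length ", length(z), " != head input dim ", head$input_dim)
  act <- activation_fun(activation)
  h <- act$f(drop(head$W1 %*% z) + head$b1)
  min(max(stats::plogis(sum(head$w2 * h) + head$b2), 1e-12), 1 - 1e-12)
}
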