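# Independent brute-force oracles used to freeze expected values. These are
# deliberately naive re-implementations (loops, enumeration) kept separate
# from the package's vectorized code paths.

# step-by-step dynamic routing, scalar loops only
oracle_routing <- function(uhat, n_iter, axis = c("input", "output")) {
  axis <- match.arg(axis)
  P <- dim(uhat)[1]; J <- dim(uhat)[2]; d_c <- dim(uhat)[3]
  b <- matrix(0, P, J)
  v <- matrix(0, J, d_c)
  for (t in seq_len(n_iter)) {
    cc <- matrix(0, P, J)
    if (axis == "input") {
      for (j in 1:J) {
        e <- exp(b[, j] - max(b[, j]))
        cc[, j] <- e / sum(e)
      }
    } else {
      for (i in 1:P) {
        e <- exp(b[i, ] - max(b[i, ]))
        cc[i, ] <- e / sum(e)
      }
    }
    for (j in 1:J) {
      s <- numeric(d_c)
      for (i in 1:P) s <- s + cc[i, j] * uhat[i, j, ]
      r <- sqrt(sum(s^2))
      v[j, ] <- if (r < 1e-12) 0 else s * r / (1 + r^2)
    }
    for (i in 1:P) for (j in 1:J)
      b[i, j] <- b[i, j] + sum(uhat[i, j, ] * v[j, ])
  }
  v
}

# scaled dot-product attention by explicit loops
oracle_attention <- function(Q, K, V, d_k) {
  J <- nrow(Q)
  out <- matrix(0, J, ncol(V))
  for (a in 1:J) {
    e <- numeric(J)
    for (b in 1:J) e[b] <- sum(Q[a, ] * K[b, ]) / sqrt(d_k)
    w <- exp(e - max(e)); w <- w / sum(w)
    for (b in 1:J) out[a, ] <- out[a, ] + w[b] * V[b, ]
  }
  out
}

# O(n^2) pairwise AUROC with half-weighted ties
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# AUPRC by explicit threshold sweep with step (rectangle) areas
oracle_auprc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; area <- 0
  n_pos <- sum(labels == 1)
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    prec <- tp / (tp + fp); rec <- tp / n_pos
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# exact upper-tail hypergeometric by enumerating combinations
oracle_hyper <- function(k, K, n, N) {
  kmax <- min(K, n)
  sum(vapply(k:kmax, function(x)
    choose(K, x) * choose(N - K, n - x), numeric(1))) / choose(N, n)
}

# small deterministic model for gradient and consistency checks
tiny_model <- function(seed = 11, n_genes = 6, activation = "sigmoid",
                       softmax_axis = "input_capsules") {
  cfg <- train_config(n_primary = 2, n_capsules = 3, d_p = 2, d_c = 2,
                      n_heads = 2, hidden_units = 5, routing_iterations = 3,
                      seed = seed, activation = activation,
                      softmax_axis = softmax_axis)
  capstx:::with_seed(seed, capstx:::init_model(n_genes,
                                               paste0("g", seq_len(n_genes)),
                                               cfg))
}

# small linearly separable expression dataset: genes 1:10 shifted in cases
toy_separable <- function(n_genes = 50, n_samples = 200, shift = 2,
                          seed = 7) {
  capstx:::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n_samples)
    v <- matrix(stats::rnorm(n_genes * n_samples, 1, 0.5), n_genes, n_samples)
    sig <- seq_len(min(10, n_genes))
    v[sig, y == 1L] <- v[sig, y == 1L] + shift
    v[v < 0] <- 0
    m <- expression_matrix(v, sprintf("g%03d", 1:n_genes),
                           sprintf("s%03d", 1:n_samples),
                           platform_tag = "synthetic")
    labelled_dataset(m, y)
  })
}
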